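#' Class means and scatter matrices of a population-vector set
#'
#' Computes, over the per-image rows, the class mean vectors (m1 = cat,
#' m2 = dog), the within-class scatter
#' \eqn{S_W = \sum_k \sum_{n \in C_k} (x_n - m_k)(x_n - m_k)^\top}
#' and the rank-one between-class scatter
#' \eqn{S_B = (m_2 - m_1)(m_2 - m_1)^\top}.
#'
#' @param vectors a `popvec_set` with both classes present (>= 2 rows each).
#' @return list with `m1`, `m2`, `Sw`, `Sb`, `n1`, `n2`.
#' @export
scatter_matrices <- function(vectors) {
  stopifnot(inherits(vectors, "popvec_set"))
  X <- vectors$matrix
  y <- vectors$labels
  n1 <- sum(y == 0); n2 <- sum(y == 1)
  if (n1 < 2 || n2 < 2)
    stop("degenerate scatter: each class needs >= 2 samples (cat=", n1,
         ", dog=", n2, ")")
  X1 <- X[y == 0, , drop = FALSE]
  X2 <- X[y == 1, , drop = FALSE]
  m1 <- colMeans(X1)
  m2 <- colMeans(X2)
  Sw <- crossprod(sweep(X1, 2, m1)) + crossprod(sweep(X2, 2, m2))
  d <- m2 - m1
  list(m1 = m1, m2 = m2, Sw = Sw, Sb = tcrossprod(d), n1 = n1, n2 = n2)
}

# inversion policies for the within-class scatter. With N features
# approaching the within-class degrees of freedom S_W can be near-singular;
# the default adds a small Tikhonov ridge, `strict` refuses ill-conditioned
# solves, `pinv` truncates the spectrum. Returns the inverse together with
# the effective scatter it inverts, so downstream identities (J = D^2) can
# be evaluated in a consistent metric.
.sw_solver <- function(Sw, inversion = c("ridge", "strict", "pinv")) {
  inversion <- match.arg(inversion)
  N <- nrow(Sw)
  if (inversion == "ridge") {
    eps <- 1e-6 * sum(diag(Sw)) / N
    if (eps == 0) eps <- 1e-12
    Sw_eff <- Sw + diag(eps, N)
    return(list(inv = solve(Sw_eff), Sw_eff = Sw_eff))
  }
  if (inversion == "strict") {
    kap <- kappa(Sw, exact = FALSE)
    if (!is.finite(kap) || kap > 1e12) {
      ev <- eigen(Sw, symmetric = TRUE, only.values = TRUE)$values
      stop("singular within-class scatter under strict inversion ",
           "(condition ", format(kap, digits = 3), ", rank ",
           sum(ev > 1e-10 * max(ev)), "/", N, ")")
    }
    return(list(inv = solve(Sw), Sw_eff = Sw))
  }
  # pinv: truncated pseudo-inverse
  e <- eigen(Sw, symmetric = TRUE)
  keep <- e$values > 1e-10 * max(e$values)
  if (!any(keep)) stop("within-class scatter is numerically zero")
  V <- e$vectors[, keep, drop = FALSE]
  list(inv = V %*% (t(V) / e$values[keep]), Sw_eff = Sw)
}

.invert_sw <- function(Sw, inversion = "ridge") {
  .sw_solver(Sw, inversion)$inv
}

#' Fisher discriminant direction
#'
#' The direction maximising the LDA criterion
#' \eqn{J(w) = (w^\top S_B w)/(w^\top S_W w)}: in the two-class case the
#' generalised eigenproblem \eqn{S_W^{-1} S_B w = \lambda w} has the
#' closed-form top eigenvector \eqn{\hat w \propto S_W^{-1}(m_2 - m_1)}.
#' Returned normalised so that \eqn{\hat w^\top S_W \hat w = 1}, making
#' the squared projected class-mean gap equal J.
#'
#' @param m1,m2 class mean vectors (cat, dog).
#' @param Sw within-class scatter matrix.
#' @param inversion `"ridge"` (Tikhonov-stabilised solve, default),
#'   `"strict"` (plain solve, errors when condition number > 1e12) or
#'   `"pinv"` (truncated pseudo-inverse).
#' @return named numeric vector, the normalised direction (dog-positive
#'   convention: the projected dog mean exceeds the projected cat mean).
#' @export
lda_direction <- function(m1, m2, Sw, inversion = "ridge") {
  d <- m2 - m1
  w <- drop(.invert_sw(Sw, inversion) %*% d)
  nrm2 <- drop(crossprod(w, Sw %*% w))
  if (nrm2 <= 0) stop("degenerate direction: w'Sw w <= 0")
  w <- w / sqrt(nrm2)
  if (drop(crossprod(w, d)) < 0) w <- -w
  names(w) <- names(m1)
  w
}

#' Mahalanobis distance between category means
#'
#' \eqn{D = \sqrt{(m_2 - m_1)^\top S_W^{-1} (m_2 - m_1)}}, the maximum of
#' the LDA criterion: \eqn{J(\hat w) = D^2}. Computed with the same
#' inversion policies as [lda_direction()].
#'
#' @inheritParams lda_direction
#' @return non-negative scalar D.
#' @export
mahalanobis_separation <- function(m1, m2, Sw, inversion = "ridge") {
  d <- m2 - m1
  qf <- drop(crossprod(d, .invert_sw(Sw, inversion) %*% d))
  if (qf < 0) {
    if (qf > -1e-10 * max(1, sum(d^2))) qf <- 0
    else stop("numerical degeneracy: negative Mahalanobis quadratic form")
  }
  sqrt(qf)
}

#' Full category-separation summary for one window
#'
#' Bundles class means, scatter matrices, the Fisher direction, the LDA
#' criterion J, the generalised eigenvalue lambda and the Mahalanobis
#' distance D for one population-vector set, asserting the identities
#' J = lambda = D^2 (to 1e-8 relative) at construction.
#'
#' @param vectors a `popvec_set`
#' @param inversion see [lda_direction()].
#' @return object of class `separation_result` with fields `m1`, `m2`,
#'   `Sw`, `Sb`, `direction`, `criterion` (J), `lambda`, `D`, `D2`,
#'   `window`, `inversion`.
#' @export
separation_result <- function(vectors, inversion = "ridge") {
  sc <- scatter_matrices(vectors)
  sol <- .sw_solver(sc$Sw, inversion)
  d <- sc$m2 - sc$m1
  w <- drop(sol$inv %*% d)
  nrm2 <- drop(crossprod(w, sol$Sw_eff %*% w))
  if (nrm2 <= 0) stop("degenerate direction: w'Sw w <= 0")
  w <- w / sqrt(nrm2)
  if (drop(crossprod(w, d)) < 0) w <- -w
  names(w) <- names(sc$m1)
  qf <- drop(crossprod(d, sol$inv %*% d))
  if (qf < 0) stop("numerical degeneracy: negative Mahalanobis quadratic form")
  D <- sqrt(qf)
  # criterion evaluated in the same (possibly stabilised) metric as the
  # inversion, so J = lambda = D^2 holds to numerical precision
  J <- drop(crossprod(w, sc$Sb %*% w)) / drop(crossprod(w, sol$Sw_eff %*% w))
  lambda <- qf   # the single nonzero eigenvalue of Sw^-1 Sb
  rel <- abs(J - D^2) / max(abs(J), D^2, 1e-300)
  if (rel > 1e-8)
    stop("internal inconsistency: J(w) and D^2 disagree beyond tolerance (",
         format(rel, digits = 3), " relative)")
  structure(list(m1 = sc$m1, m2 = sc$m2, Sw = sc$Sw, Sb = sc$Sb,
                 direction = w, criterion = J, lambda = lambda,
                 D = D, D2 = D^2, window = vectors$window,
                 inversion = inversion, provenance = vectors$provenance),
            class = "separation_result")
}

#' @export
print.separation_result <- function(x, ...) {
  cat("<separation_result> window [", x$window[1], ", ", x$window[2],
      ") ms: D = ", signif(x$D, 5), " (J = D^2 = ", signif(x$D2, 5),
      ", inversion ", x$inversion, ")\n", sep = "")
  invisible(x)
}

#' Project population vectors onto a discriminant direction
#'
#' One scalar per image, \eqn{\hat w^\top x_i}, grouped by category; under
#' the \eqn{\hat w^\top S_W \hat w = 1} normalisation the squared gap
#' between the projected class means equals the LDA criterion.
#'
#' @param vectors a `popvec_set`
#' @param w direction vector of matching dimension (nonzero).
#' @return data.frame with `image_id`, `category`, `projection`; attribute
#'   `class_means` gives the projected cat and dog means.
#' @export
project_1d <- function(vectors, w) {
  stopifnot(inherits(vectors, "popvec_set"))
  if (length(w) != ncol(vectors$matrix))
    stop("direction has dimension ", length(w), " but vectors have ",
         ncol(vectors$matrix), " neurons")
  if (all(w == 0)) stop("degenerate direction: zero vector")
  proj <- drop(vectors$matrix %*% w)
  out <- data.frame(image_id = vectors$image_ids,
                    category = ifelse(vectors$labels == 1, "dog", "cat"),
                    projection = proj)
  attr(out, "class_means") <- c(cat = mean(proj[vectors$labels == 0]),
                                dog = mean(proj[vectors$labels == 1]))
  out
}

#' Mahalanobis category-separation time course
#'
#' Computes the Mahalanobis distance D between the cat and dog mean
#' population vectors for every sliding window.
#'
#' @inheritParams decoding_timecourse
#' @param inversion see [lda_direction()].
#' @return object of class `separation_timecourse`: data.frame with
#'   `window_start`, `D`, `D2`; attributes `inversion`, `width`,
#'   `provenance`.
#' @export
separation_timecourse <- function(datasets, windows, inversion = "ridge") {
  series <- .popvec_series(datasets, windows)
  D <- vapply(series, function(v) {
    sc <- scatter_matrices(v)
    mahalanobis_separation(sc$m1, sc$m2, sc$Sw, inversion)
  }, 0)
  structure(data.frame(window_start = windows$start, D = D, D2 = D^2),
            class = c("separation_timecourse", "data.frame"),
            inversion = inversion,
            width = windows$end[1] - windows$start[1],
            provenance = series[[1]]$provenance)
}
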