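#' Fit a ridge-penalised logistic-regression category decoder
#'
#' Binary classifier \eqn{y(\Phi) = \sigma(w^\top \Phi)} with
#' \eqn{\sigma(a) = 1/(1+e^{-a})}, fitted by minimising the cross-entropy
#' error
#' \deqn{E(w) = -\sum_n \{t_n \ln \sigma(w^\top \phi_n) +
#'   (1-t_n)\ln(1-\sigma(w^\top \phi_n))\} + \frac{\lambda}{2}\|w\|^2}
#' (intercept unpenalised) by Newton-Raphson with step halving. With
#' `lambda = 0` the fit is the plain maximum-likelihood logistic model;
#' the default weak ridge (`lambda = 1`) keeps the optimum finite on
#' separable windows, where population counts can exceed image counts.
#' Deterministic given `(X, y, lambda)`.
#'
#' @param X numeric matrix, one row per sample (a population vector).
#' @param y binary labels (0 = cat, 1 = dog), one per row.
#' @param lambda ridge penalty strength (>= 0).
#' @param intercept include an unpenalised intercept term (default TRUE).
#' @param tol convergence tolerance on the max absolute gradient component.
#' @param maxit maximum Newton iterations.
#' @return object of class `lor_model`: `weights` (intercept first if
#'   present), `lambda`, `cross_entropy` (unpenalised E at the optimum),
#'   `objective`, `grad_max`, `converged`, `n_iter`.
#' @export
fit_logistic <- function(X, y, lambda = 1, intercept = TRUE,
                         tol = 1e-8, maxit = 100) {
  X <- as.matrix(X)
  if (!all(is.finite(X))) stop("non-finite values in feature matrix")
  y <- as.numeric(y)
  if (!all(y %in% c(0, 1))) stop("labels must be 0/1")
  if (length(unique(y)) < 2) stop("single-class labels: cannot fit a classifier")
  if (lambda < 0) stop("lambda must be >= 0")
  Xd <- if (intercept) cbind(`(intercept)` = 1, X) else X
  pmask <- if (intercept) c(0, rep(1, ncol(X))) else rep(1, ncol(Xd))
  p_dim <- ncol(Xd)
  w <- numeric(p_dim)

  obj <- function(w) {
    eta <- drop(Xd %*% w)
    # log(1+exp(.)) computed stably
    ce <- sum(ifelse(eta > 0, eta * (1 - y) + log1p(exp(-eta)),
                     -eta * y + log1p(exp(eta))))
    ce + lambda / 2 * sum(pmask * w^2)
  }
  f_old <- obj(w)
  converged <- FALSE
  it <- 0L
  g <- NULL
  while (it < maxit) {
    it <- it + 1L
    eta <- drop(Xd %*% w)
    p <- 1 / (1 + exp(-eta))
    g <- drop(crossprod(Xd, p - y)) + lambda * pmask * w
    if (max(abs(g)) < tol) { converged <- TRUE; break }
    wt <- pmax(p * (1 - p), 1e-10)
    H <- crossprod(Xd, Xd * wt) + diag(lambda * pmask + 1e-12, p_dim)
    step <- tryCatch(solve(H, g), error = function(e)
      solve(H + diag(1e-6 * mean(diag(H)), p_dim), g))
    alpha <- 1
    repeat {
      w_new <- w - alpha * step
      f_new <- obj(w_new)
      if (f_new <= f_old + 1e-12 || alpha < 1e-8) break
      alpha <- alpha / 2
    }
    if (abs(f_old - f_new) < 1e-14 && max(abs(g)) < sqrt(tol)) {
      w <- w_new
      converged <- TRUE
      break
    }
    w <- w_new
    f_old <- f_new
  }
  eta <- drop(Xd %*% w)
  p <- 1 / (1 + exp(-eta))
  g <- drop(crossprod(Xd, p - y)) + lambda * pmask * w
  names(w) <- colnames(Xd)
  structure(list(weights = w, lambda = lambda, intercept = intercept,
                 cross_entropy = obj(w) - lambda / 2 * sum(pmask * w^2),
                 objective = obj(w), grad_max = max(abs(g)),
                 converged = converged || max(abs(g)) < tol,
                 n_iter = it),
            class = "lor_model")
}

#' @export
predict.lor_model <- function(object, newdata,
                              type = c("response", "class"), ...) {
  type <- match.arg(type)
  X <- as.matrix(newdata)
  Xd <- if (object$intercept) cbind(1, X) else X
  p <- drop(1 / (1 + exp(-Xd %*% object$weights)))
  # ties at exactly 0.5 decide dog (measure zero in practice, documented)
  if (type == "class") as.integer(p >= 0.5) else p
}

#' @export
print.lor_model <- function(x, ...) {
  cat("<lor_model> ", length(x$weights), " weights, lambda=", x$lambda,
      ", cross-entropy ", signif(x$cross_entropy, 5),
      if (x$converged) ", converged" else ", NOT converged",
      " (", x$n_iter, " it)\n", sep = "")
  invisible(x)
}

# seeded stratified k-fold assignment: within each class, shuffle and deal
# round-robin; returns integer fold id per sample
.stratified_folds <- function(labels, k, seed) {
  folds <- integer(length(labels))
  .with_seed(seed, {
    for (cl in unique(labels)) {
      ids <- which(labels == cl)
      ids <- ids[sample.int(length(ids))]
      folds[ids] <- rep_len(seq_len(k), length(ids))
    }
    folds
  })
}

#' Cross-validated decoding accuracy of one population-vector set
#'
#' Stratified k-fold cross-validation: image rows are dealt into k folds
#' (per class, after a seeded shuffle), the decoder is fitted on k-1 folds
#' and hard decisions (probability >= 0.5 decides dog) are scored on the
#' held-out fold.
#'
#' @param vectors a `popvec_set`
#' @param k number of folds (default 10).
#' @param seed seed controlling the single shuffle behind the fold split.
#' @param lambda ridge penalty passed to [fit_logistic()].
#' @param folds optional precomputed integer fold assignment (overrides
#'   `k`/`seed`), used to keep folds identical across sliding windows.
#' @return list with `mean_accuracy`, `fold_accuracy` (length k), `folds`,
#'   `k`, `seed`, `lambda`.
#' @export
cv_accuracy <- function(vectors, k = 10, seed = 1, lambda = 1,
                        folds = NULL) {
  stopifnot(inherits(vectors, "popvec_set"))
  X <- vectors$matrix
  y <- vectors$labels
  if (is.null(folds)) {
    if (nrow(X) < k) stop("need at least k images for k-fold CV")
    folds <- .stratified_folds(y, k, seed)
  }
  k <- max(folds)
  acc <- numeric(k)
  for (f in seq_len(k)) {
    tr <- folds != f
    if (length(unique(y[tr])) < 2)
      stop("stratification bug: a class is absent from training fold ", f)
    fit <- fit_logistic(X[tr, , drop = FALSE], y[tr], lambda = lambda)
    pred <- predict(fit, X[!tr, , drop = FALSE], type = "class")
    acc[f] <- mean(pred == y[!tr])
  }
  list(mean_accuracy = mean(acc), fold_accuracy = acc, folds = folds,
       k = k, seed = seed, lambda = lambda)
}

#' Decoding-accuracy time course over sliding windows
#'
#' For every window: build the (pooled pseudo-population) population
#' vectors, run stratified k-fold cross-validation of the logistic
#' decoder, record the mean and per-fold accuracies. The fold assignment
#' is drawn once from `seed` and reused across windows, so curves differ
#' only through window content and are comparable pointwise.
#'
#' @param datasets a `spike_dataset` or list of them (pooled as a
#'   pseudo-population; stimulus sets must match).
#' @param windows data.frame from [sliding_windows()].
#' @param k,seed,lambda see [cv_accuracy()].
#' @return object of class `decoding_timecourse`: data.frame with
#'   `window_start`, `accuracy` and `fold_1..fold_k` columns; attributes
#'   `k`, `seed`, `lambda`, `width`, `provenance`.
#' @export
decoding_timecourse <- function(datasets, windows, k = 10, seed = 1,
                                lambda = 1) {
  series <- .popvec_series(datasets, windows)
  labels <- series[[1]]$labels
  folds <- .stratified_folds(labels, k, seed)
  res <- lapply(series, cv_accuracy, lambda = lambda, folds = folds)
  fold_mat <- do.call(rbind, lapply(res, `[[`, "fold_accuracy"))
  colnames(fold_mat) <- paste0("fold_", seq_len(k))
  out <- data.frame(window_start = windows$start,
                    accuracy = vapply(res, `[[`, 0, "mean_accuracy"))
  out <- cbind(out, fold_mat)
  structure(out,
            class = c("decoding_timecourse", "data.frame"),
            k = k, seed = seed, lambda = lambda,
            width = windows$end[1] - windows$start[1],
            provenance = series[[1]]$provenance)
}
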