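mk_pv <- function(X, y, window = c(0, 100)) {
  structure(list(matrix = X, labels = as.integer(y),
                 image_ids = sprintf("i%03d", seq_len(nrow(X))),
                 neuron_ids = colnames(X) %||% sprintf("n%d", seq_len(ncol(X))),
                 window = window, provenance = "toy"),
            class = "popvec_set")
}
`%||%` <- function(a, b) if (is.null(a)) b else a

random_instance <- function(n_per_class = 12, p = 4) {
  X <- rbind(matrix(rnorm(n_per_class * p), ncol = p),
             matrix(rnorm(n_per_class * p, mean = 1.5), ncol = p))
  mk_pv(X, rep(0:1, each = n_per_class))
}

test_that("scatter matrices match the hand-computed 2-D oracle", {
  X <- rbind(c(0, 0), c(0, 2), c(2, 0), c(2, 2))
  sc <- scatter_matrices(mk_pv(X, c(0, 0, 1, 1)))
  expect_equal(unname(sc$m1), c(0, 1))
  expect_equal(unname(sc$m2), c(2, 1))
  expect_equal(unname(sc$Sb), matrix(c(4, 0, 0, 0), 2))
  expect_equal(unname(sc$Sw), matrix(c(0, 0, 0, 4), 2))

  # two identical rows per class -> zero within-class scatter
  X0 <- rbind(c(1, 2), c(1, 2), c(5, 5), c(5, 5))
  expect_equal(unname(scatter_matrices(mk_pv(X0, c(0, 0, 1, 1)))$Sw),
               matrix(0, 2, 2))

  expect_error(scatter_matrices(mk_pv(X, c(0, 1, 1, 1))),
               "degenerate scatter")

  set.seed(21)
  for (i in 1:10) {
    pv <- random_instance()
    sc <- scatter_matrices(pv)
    expect_equal(sum(diag(sc$Sb)), sum((sc$m2 - sc$m1)^2), tolerance = 1e-12)
    expect_equal(sc$Sw, t(sc$Sw))
    expect_true(all(eigen(sc$Sw, symmetric = TRUE,
                          only.values = TRUE)$values > -1e-8))
  }
})

test_that("whitened two-feature cases reduce to Euclidean geometry", {
  m1 <- c(0, 0); m2 <- c(2, 0); Sw <- diag(2)
  w <- lda_direction(m1, m2, Sw, "strict")
  expect_equal(abs(w[1]) / sqrt(sum(w^2)), 1, tolerance = 1e-12)
  expect_equal(mahalanobis_separation(m1, m2, Sw, "strict"), 2)
  expect_equal(mahalanobis_separation(m1, m1, Sw, "strict"), 0)
})

test_that("closed form, eigen solution and criterion maximality agree", {
  set.seed(31)
  for (i in 1:20) {
    pv <- random_instance()
    sc <- scatter_matrices(pv)
    w <- lda_direction(sc$m1, sc$m2, sc$Sw, "strict")
    # top eigenvector of Sw^-1 Sb, up to sign/scale
    e <- eigen(solve(sc$Sw) %*% sc$Sb)
    v <- Re(e$vectors[, which.max(Re(e$values))])
    cosim <- abs(sum(w * v)) / sqrt(sum(w^2) * sum(v^2))
    expect_gt(cosim, 1 - 1e-8)

    D <- mahalanobis_separation(sc$m1, sc$m2, sc$Sw, "strict")
    expect_equal(max(Re(e$values)), D^2, tolerance = 1e-8)

    # J(w_hat) >= J(w) over random unit directions
    J <- function(w) drop(crossprod(w, sc$Sb %*% w)) /
      drop(crossprod(w, sc$Sw %*% w))
    Jhat <- J(w)
    rand <- matrix(rnorm(4 * 200), 4)
    expect_true(all(apply(rand, 2, J) <= Jhat + 1e-10))
    # normalisation contract
    expect_equal(drop(crossprod(w, sc$Sw %*% w)), 1, tolerance = 1e-10)
  }
})

test_that("Mahalanobis distance is invariant under invertible feature maps", {
  set.seed(41)
  for (i in 1:10) {
    pv <- random_instance()
    sc <- scatter_matrices(pv)
    D0 <- mahalanobis_separation(sc$m1, sc$m2, sc$Sw, "strict")
    A <- matrix(rnorm(16), 4)
    while (abs(det(A)) < 0.1) A <- matrix(rnorm(16), 4)
    pv2 <- pv
    pv2$matrix <- pv$matrix %*% t(A)
    sc2 <- scatter_matrices(pv2)
    D1 <- mahalanobis_separation(sc2$m1, sc2$m2, sc2$Sw, "strict")
    expect_equal(D1, D0, tolerance = 1e-6)
  }
})

test_that("separation_result enforces J = lambda = D^2 and projections match", {
  set.seed(51)
  pv <- random_instance()
  res <- separation_result(pv, "strict")
  expect_equal(res$criterion, res$D2, tolerance = 1e-8)
  expect_equal(res$lambda, res$D2, tolerance = 1e-8)

  pr <- project_1d(pv, res$direction)
  cm <- attr(pr, "class_means")
  expect_equal(unname((cm["dog"] - cm["cat"])^2), res$criterion,
               tolerance = 1e-8)

  expect_error(project_1d(pv, rep(0, 4)), "zero vector")
  expect_error(project_1d(pv, rep(1, 7)), "dimension")

  # high-contrast data separate visibly in 1-D
  d <- generate_dataset(quick_cfg(n_neurons = 20, images_per_category = 25,
                                  category_contrast = 10,
                                  selective_fraction = 0.8, seed = 55))
  pvd <- population_vectors(d, c(150, 250))
  resd <- separation_result(pvd)
  prd <- project_1d(pvd, resd$direction)
  gap <- abs(diff(attr(prd, "class_means")))
  pooled_sd <- sqrt(mean(tapply(prd$projection, prd$category, var)))
  expect_gt(gap, pooled_sd)
})

test_that("singular scatters trip strict inversion but not ridge", {
  X <- rbind(c(0, 0, 0), c(1, 0, 0), c(3, 0, 0), c(4, 0, 0))
  pv <- mk_pv(X, c(0, 0, 1, 1))
  sc <- scatter_matrices(pv)
  expect_error(lda_direction(sc$m1, sc$m2, sc$Sw, "strict"), "singular")
  expect_silent(mahalanobis_separation(sc$m1, sc$m2, sc$Sw, "ridge"))
  expect_silent(mahalanobis_separation(sc$m1, sc$m2, sc$Sw, "pinv"))
})

test_that("zero-signal time courses are small and trendless", {
  d <- generate_dataset(quick_cfg(n_neurons = 15, images_per_category = 25,
                                  category_contrast = 0,
                                  selective_fraction = 0,
                                  image_idiosyncrasy_sd = 0, seed = 61))
  wins <- sliding_windows(-100, 250, 100, 25)
  tc <- separation_timecourse(d, wins)
  expect_true(all(tc$D >= 0))
  slope <- summary(lm(D ~ window_start, data = tc))$coefficients[2, 4]
  expect_gt(slope, 0.05)   # no significant trend
})

test_that("within-trial growth separates ramp from step profiles", {
  # late/early D ratio is systematically larger for ramping signals
  wins <- data.frame(start = c(100, 250), end = c(200, 350))
  ratios <- vapply(1:4, function(s) {
    mkr <- function(profile, tg)
      generate_dataset(accept_cfg(n_neurons = 25, images_per_category = 25,
                                  profile = profile, training_gain = tg,
                                  ramp_end = 350, seed = 90 + s))
    tstep <- separation_timecourse(mkr("step", 1), wins)
    tramp <- separation_timecourse(mkr("ramp", 1.5), wins)
    (tramp$D[2] / tramp$D[1]) - (tstep$D[2] / tstep$D[1])
  }, 0)
  expect_true(all(ratios > 0))
})
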