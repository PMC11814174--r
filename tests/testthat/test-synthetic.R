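test_that("silent configurations generate no spikes and bad configs error", {
  cfg <- quick_cfg(baseline_rate_mean = 0, baseline_rate_sd = 0,
                   response_gain_mean = 0, response_gain_sd = 0,
                   category_contrast = 0, selective_fraction = 0,
                   image_idiosyncrasy_sd = 0)
  d <- generate_dataset(cfg)
  expect_equal(nrow(d$spikes), 0)
  expect_equal(nrow(d$trials),
               2 * cfg$images_per_category * cfg$trials_per_image)

  expect_error(synthetic_config(n_neurons = 0), "config error")
  expect_error(synthetic_config(training_gain = 0), "config error")
  expect_error(synthetic_config(selective_fraction = 1.5), "config error")
})

test_that("generation is deterministic in the seed and leaves the caller's RNG alone", {
  cfg <- quick_cfg(seed = 123)
  d1 <- generate_dataset(cfg)
  set.seed(777)
  before <- runif(1)
  set.seed(777)
  d2 <- generate_dataset(cfg)
  after <- runif(1)
  expect_identical(d1$spikes, d2$spikes)
  expect_identical(before, after)   # private stream, caller state restored

  d3 <- generate_dataset(quick_cfg(seed = 124))
  expect_false(identical(d1$spikes$spike_time_ms, d3$spikes$spike_time_ms))
})

test_that("homogeneous-baseline counts match the Poisson mean", {
  # pure baseline at 10 spikes/s over a 1-second epoch, 1000 trials
  cfg <- synthetic_config(n_neurons = 1, images_per_category = 1,
                          trials_per_image = 500,
                          baseline_rate_mean = 10, baseline_rate_sd = 0,
                          response_gain_mean = 0, response_gain_sd = 0,
                          category_contrast = 0, selective_fraction = 0,
                          image_idiosyncrasy_sd = 0,
                          analysis_window = c(0, 1000), seed = 5)
  d <- generate_dataset(cfg)
  n_trials <- nrow(d$trials)
  mean_count <- nrow(d$spikes) / n_trials
  se <- sqrt(10 / n_trials)
  expect_lt(abs(mean_count - 10), 3 * se)
})

test_that("per-neuron mean rates converge to the generative rates", {
  # fully post-latency window; rate there is b + g (no category signal)
  cfg <- synthetic_config(n_neurons = 4, images_per_category = 10,
                          trials_per_image = 60,
                          baseline_rate_mean = 6, baseline_rate_sd = 0,
                          latency_mean = 50, latency_sd = 0,
                          response_gain_mean = 9, response_gain_sd = 0,
                          category_contrast = 0, selective_fraction = 0,
                          image_idiosyncrasy_sd = 0, seed = 8)
  d <- generate_dataset(cfg)
  pv <- population_vectors(d, c(100, 300))
  # mean over images of trial-averaged rates, per neuron
  rate_hat <- colMeans(pv$matrix)
  n_total_trials <- 2 * 10 * 60
  se <- sqrt(15 / (0.2 * n_total_trials))   # Poisson count SE in spikes/s
  expect_true(all(abs(rate_hat - 15) < 3 * se))
})

test_that("expected separation has the closed single-neuron form", {
  # one selective neuron, step fully inside the window, sds zero:
  # delta = contrast, sigma^2 = (b+g)/(ntr * dt) + idio^2,
  # D = sqrt(delta^2 / sigma^2 / (n_img - 2))
  cfg <- synthetic_config(n_neurons = 1, images_per_category = 20,
                          trials_per_image = 10,
                          baseline_rate_mean = 8, baseline_rate_sd = 0,
                          latency_mean = 50, latency_sd = 0,
                          response_gain_mean = 12, response_gain_sd = 0,
                          category_contrast = 6, selective_fraction = 1,
                          image_idiosyncrasy_sd = 2, profile = "step",
                          seed = 1)
  delta <- 6
  sigma2 <- (8 + 12) / (10 * 0.1) + 2^2
  hand <- sqrt(delta^2 / sigma2 / (40 - 2))
  expect_equal(expected_window_separation(cfg, c(100, 200)), hand,
               tolerance = 1e-9)

  # entirely pre-onset window carries no signal
  expect_identical(expected_window_separation(cfg, c(-200, -100)), 0)
})

test_that("expected separation is monotone in contrast and reflects the profile", {
  base <- list(latency_mean = 60, latency_sd = 0, profile = "step", seed = 2)
  cfg1 <- do.call(quick_cfg, c(base, list(category_contrast = 4)))
  cfg2 <- do.call(quick_cfg, c(base, list(category_contrast = 8)))
  for (w in list(c(80, 180), c(150, 250), c(250, 350)))
    expect_gt(expected_window_separation(cfg2, w),
              expected_window_separation(cfg1, w))

  # step: constant across windows fully past the latency
  Ds <- vapply(seq(100, 250, by = 50), function(s)
    expected_window_separation(cfg1, c(s, s + 100)), 0)
  expect_equal(max(Ds) - min(Ds), 0, tolerance = 1e-12)

  # ramp: strictly increasing while the ramp is still rising
  cfgr <- do.call(quick_cfg, c(list(latency_mean = 60, latency_sd = 0,
                                    profile = "ramp", ramp_end = 350)))
  Dr <- vapply(seq(60, 250, by = 25), function(s)
    expected_window_separation(cfgr, c(s, s + 100)), 0)
  expect_true(all(diff(Dr) > 0))
})

test_that("empirical separation agrees with the analytic oracle", {
  # medium-size Monte Carlo; the full-scale recovery check runs in the
  # acceptance suite
  cfg <- synthetic_config(n_neurons = 8, images_per_category = 60,
                          trials_per_image = 80,
                          baseline_rate_mean = 8, baseline_rate_sd = 0,
                          latency_mean = 50, latency_sd = 0,
                          response_gain_mean = 8, response_gain_sd = 0,
                          category_contrast = 6, selective_fraction = 1,
                          image_idiosyncrasy_sd = 2, profile = "step",
                          analysis_window = c(-100, 400), seed = 3)
  d <- generate_dataset(cfg)
  tc <- separation_timecourse(d, data.frame(start = c(120, 220),
                                            end = c(220, 320)))
  expD <- expected_window_separation(cfg, c(120, 220))
  expect_true(all(abs(tc$D / expD - 1) < 0.2))
})
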