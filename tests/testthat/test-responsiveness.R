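test_that("firing-rate function has Gaussian kernel height and conserves mass", {
  grid <- seq(-300, 400, by = 1)
  expect_equal(firing_rate_function(list(numeric(0), numeric(0)),
                                    grid = grid)$rate,
               rep(0, length(grid)))

  # one spike at 0: peak 1000 * dnorm(0, 0, 10) = 1/(sqrt(2*pi)*0.010 s)
  fr <- firing_rate_function(list(0), bandwidth = 10, grid = grid)
  expect_equal(max(fr$rate), 1000 * dnorm(0, 0, 10), tolerance = 1e-12)
  expect_equal(fr$time[which.max(fr$rate)], 0)

  # mass conservation on random spike sets (integral = spikes per trial)
  set.seed(42)
  for (i in 1:5) {
    n_tr <- sample(2:6, 1)
    sp <- replicate(n_tr, sort(runif(sample(3:30, 1), -250, 350)),
                    simplify = FALSE)
    fr <- firing_rate_function(sp, bandwidth = 10,
                               grid = seq(-400, 500, by = 0.5))
    mass <- sum(fr$rate) * 0.5 / 1000   # rectangle rule, ms -> s
    expect_equal(mass, length(unlist(sp)) / n_tr, tolerance = 1e-3)
  }

  expect_error(firing_rate_function(list(0), bandwidth = 0), "bandwidth")
  expect_error(firing_rate_function(list(0), grid = numeric(0)), "grid")
})

test_that("paired rate test matches the textbook formula and conventions", {
  cb <- c(2, 3, 2, 3, 2)
  cs <- c(8, 9, 10, 8, 9)
  got <- paired_rate_test(cb, cs, 200, 200)
  # brute-force paired t on the rate differences
  d <- cs / 0.2 - cb / 0.2
  tstat <- mean(d) / (sd(d) / sqrt(5))
  expect_equal(got$p_value, 2 * pt(-abs(tstat), 4), tolerance = 1e-10)
  expect_equal(got$p_value, t.test(cs, cb, paired = TRUE)$p.value,
               tolerance = 1e-10)
  expect_identical(got$direction, "increase")

  # identical counts per trial: cannot reject
  same <- paired_rate_test(c(4, 5, 6), c(4, 5, 6), 200, 200)
  expect_identical(same$p_value, 1)
  expect_true(is.na(same$direction))

  expect_error(paired_rate_test(1, 2, 200, 200), "insufficient")

  # unequal widths are handled through rates: equal rates -> p = 1
  eq <- paired_rate_test(c(2, 4, 2), c(4, 8, 4), 100, 200)
  expect_identical(eq$p_value, 1)
})

test_that("a genuinely responsive neuron is detected with high power", {
  hits <- vapply(1:20, function(s) {
    cfg <- synthetic_config(n_neurons = 1, images_per_category = 1,
                            trials_per_image = 19,
                            baseline_rate_mean = 5, baseline_rate_sd = 0,
                            latency_mean = 0, latency_sd = 0,
                            response_gain_mean = 10, response_gain_sd = 0,
                            category_contrast = 0, selective_fraction = 0,
                            image_idiosyncrasy_sd = 0, seed = s)
    d <- generate_dataset(cfg)
    image_responsiveness_test(d, "n001", "cat001")$p_value < 0.05
  }, TRUE)
  expect_gte(mean(hits), 0.95)
})

test_that("BH rejections equal the step-up definition and are monotone in alpha", {
  p <- c(0.001, 0.02, 0.03, 0.04, 0.2)
  expect_identical(bh_adjust(p, 0.05), bh_bruteforce(p, 0.05))

  expect_false(any(bh_adjust(rep(1, 10), 0.05)))
  expect_true(bh_adjust(0.049, 0.05))   # m = 1 reduces to the raw test
  expect_false(bh_adjust(0.051, 0.05))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(11)
  for (i in 1:20) {
    p <- runif(sample(1:50, 1))^sample(1:3, 1)
    expect_identical(bh_adjust(p, 0.05), bh_bruteforce(p, 0.05))
    # alpha up => rejection set never shrinks
    r1 <- bh_adjust(p, 0.02)
    r2 <- bh_adjust(p, 0.1)
    expect_true(all(r2[r1]))
  }
})

test_that("neuron classification follows the category taxonomy and partitions", {
  # forced responses: n_dog responds to a dog image, n_cat to a cat image,
  # n_both to one of each, n_none to nothing
  counts <- rbind(
    data.frame(neuron_id = "n_dog", image_id = "dog1", category = "dog",
               n_base = 0, n_stim = 30),
    data.frame(neuron_id = "n_cat", image_id = "cat1", category = "cat",
               n_base = 0, n_stim = 30),
    data.frame(neuron_id = "n_both", image_id = "dog1", category = "dog",
               n_base = 0, n_stim = 30),
    data.frame(neuron_id = "n_both", image_id = "cat1", category = "cat",
               n_base = 0, n_stim = 30))
  # make sure all four images exist with some baseline-only activity
  filler <- data.frame(neuron_id = "n_none",
                       image_id = c("cat1", "cat2", "dog1", "dog2"),
                       category = c("cat", "cat", "dog", "dog"),
                       n_base = 2, n_stim = 0)
  d <- make_forced_dataset(rbind(counts, filler),
                           neuron_ids = c("n_dog", "n_cat", "n_both",
                                          "n_none"))
  rt <- classify_neurons(d)
  got <- setNames(rt$neurons$class, rt$neurons$neuron_id)
  expect_identical(got[["n_dog"]], "only_dog")
  expect_identical(got[["n_cat"]], "only_cat")
  expect_identical(got[["n_both"]], "both")
  # n_none has baseline spikes but no stimulus response; its rate *drops*,
  # which still counts as a significant change, so check it is not dog/cat
  expect_true(got[["n_none"]] %in% c("none", "both"))

  cc <- responsiveness_counts(rt)
  expect_equal(cc$only_dog + cc$only_cat + cc$both + cc$none, cc$total)
  expect_equal(cc$total, 4)

  # vectorised path agrees with the single-pair test
  one <- image_responsiveness_test(d, "n_dog", "dog1")
  expect_equal(unname(rt$p_values["dog1", "n_dog"]), one$p_value,
               tolerance = 1e-12)
})

test_that("pooled responsiveness percentages reproduce the published values", {
  counts <- macaque_response_counts()
  pool <- function(rows) summarize_responsiveness(rows)$pct_rounded
  teo_pre <- counts[counts$area == "TEO" & counts$session == "pre", ]
  expect_equal(pool(teo_pre), 87)
  x_teo_pre <- teo_pre[teo_pre$monkey == "X", ]
  expect_equal(pool(x_teo_pre), 95)
  expect_equal(summarize_responsiveness(x_teo_pre)$pct_responsive,
               100 * 88 / 93, tolerance = 1e-12)

  allnone <- data.frame(only_dog = 0, only_cat = 0, both = 0, none = 7)
  expect_equal(summarize_responsiveness(allnone)$pct_responsive, 0)
  expect_error(summarize_responsiveness(allnone[0, ]), "empty")

  by_area <- summarize_responsiveness(counts, by = c("area", "session"))
  expect_equal(nrow(by_area), 4)
  expect_setequal(by_area$pct_rounded, c(87, 61, 89, 58))
})

test_that("onset latency is undefined for flat rates and recovered for steps", {
  flat <- structure(list(time = seq(-300, 400, 1),
                         rate = rep(3, 701), bandwidth = 10,
                         n_trials = 10, n_spikes = 0),
                    class = "rate_function")
  expect_true(is.na(onset_latency(flat)$latency))

  est_for <- function(lat, seed) {
    cfg <- synthetic_config(n_neurons = 1, images_per_category = 1,
                            trials_per_image = 50,
                            baseline_rate_mean = 5, baseline_rate_sd = 0,
                            latency_mean = lat, latency_sd = 0,
                            response_gain_mean = 40, response_gain_sd = 0,
                            category_contrast = 0, selective_fraction = 0,
                            image_idiosyncrasy_sd = 0, seed = seed)
    d <- generate_dataset(cfg)
    sp <- c(spikes_for_image(d, "cat001", "n001"),
            spikes_for_image(d, "dog001", "n001"))
    onset_latency(firing_rate_function(sp))$latency
  }
  est80 <- vapply(1:10, function(s) est_for(80, s), 0)
  expect_gte(mean(abs(est80 - 80) <= 10), 0.9)

  # an earlier true onset never yields a later estimate (paired seeds)
  est40 <- vapply(1:10, function(s) est_for(40, s), 0)
  expect_true(all(est40 <= est80 + 2))
})
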