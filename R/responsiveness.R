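#' Trial-pooled Gaussian-kernel firing-rate function
#'
#' Kernel density estimate of the instantaneous firing rate: every spike
#' from every trial contributes a Gaussian bump of sd `bandwidth` (10 ms by
#' default), the pooled sum is divided by the number of trials, and the
#' result is expressed in spikes/s. The time integral of the rate over the
#' grid equals the mean spike count per trial (up to kernel mass outside
#' the grid).
#'
#' @param trial_spikes list of numeric vectors: spike times (ms) of one
#'   neuron on each trial.
#' @param bandwidth Gaussian kernel sd in ms; must be > 0.
#' @param grid evaluation grid in ms.
#' @return object of class `rate_function`: list with `time`, `rate`
#'   (spikes/s), `bandwidth`, `n_trials`, `n_spikes`.
#' @export
firing_rate_function <- function(trial_spikes, bandwidth = 10,
                                 grid = seq(-300, 400, by = 1)) {
  if (!is.list(trial_spikes) || length(trial_spikes) < 1)
    stop("trial_spikes must be a non-empty list (one element per trial)")
  if (bandwidth <= 0) stop("bandwidth must be > 0")
  if (length(grid) == 0) stop("empty evaluation grid")
  spikes <- unlist(trial_spikes, use.names = FALSE)
  n_trials <- length(trial_spikes)
  rate <- numeric(length(grid))
  if (length(spikes)) {
    # chunk the outer product to bound memory on dense spike sets
    chunk <- max(1L, floor(5e6 / length(grid)))
    for (i in seq(1L, length(spikes), by = chunk)) {
      sp <- spikes[i:min(i + chunk - 1L, length(spikes))]
      rate <- rate + colSums(matrix(dnorm(rep(grid, each = length(sp)),
                                          mean = sp, sd = bandwidth),
                                    nrow = length(sp)))
    }
    rate <- rate * 1000 / n_trials  # per-ms density -> spikes/s
  }
  structure(list(time = grid, rate = rate, bandwidth = bandwidth,
                 n_trials = n_trials, n_spikes = length(spikes)),
            class = "rate_function")
}

#' @export
print.rate_function <- function(x, ...) {
  cat("<rate_function> ", x$n_spikes, " spikes / ", x$n_trials,
      " trials, bandwidth ", x$bandwidth, " ms, grid [",
      min(x$time), ", ", max(x$time), "] ms, peak ",
      signif(max(x$rate), 4), " spikes/s\n", sep = "")
  invisible(x)
}

#' Paired t-test on per-trial firing rates in two windows
#'
#' The building block of visual-responsiveness testing: per trial, the
#' spike count in each window is converted to a rate (spikes/s) so that
#' windows of unequal width are comparable, and a two-sided paired t-test
#' is applied to the per-trial differences (stimulus minus baseline).
#' When every difference is exactly zero the test cannot reject and p = 1
#' with undefined direction; a zero-variance but non-zero mean difference
#' yields p = 0.
#'
#' @param baseline_counts,stimulus_counts integer spike counts per trial
#'   (same length, >= 2).
#' @param baseline_width,stimulus_width window widths in ms.
#' @return list with `p_value`, `direction` (`"increase"`, `"decrease"` or
#'   `NA`), `statistic`, `df`, `mean_difference` (spikes/s).
#' @export
paired_rate_test <- function(baseline_counts, stimulus_counts,
                             baseline_width, stimulus_width) {
  n <- length(baseline_counts)
  if (length(stimulus_counts) != n)
    stop("baseline and stimulus counts must pair up trial by trial")
  if (n < 2) stop("insufficient data: need >= 2 trials for a paired test")
  d <- stimulus_counts / (stimulus_width / 1000) -
    baseline_counts / (baseline_width / 1000)
  m <- mean(d)
  s <- sd(d)
  if (s == 0) {
    return(list(p_value = if (m == 0) 1 else 0,
                direction = if (m == 0) NA_character_
                            else if (m > 0) "increase" else "decrease",
                statistic = if (m == 0) 0 else sign(m) * Inf,
                df = n - 1, mean_difference = m))
  }
  tstat <- m / (s / sqrt(n))
  list(p_value = 2 * pt(-abs(tstat), df = n - 1),
       direction = if (m > 0) "increase" else if (m < 0) "decrease"
                   else NA_character_,
       statistic = tstat, df = n - 1, mean_difference = m)
}

#' Responsiveness test of one neuron to one image
#'
#' Applies [paired_rate_test()] to the trials of `image_id`, comparing the
#' pre-onset baseline window against the stimulus window.
#'
#' @param dataset a `spike_dataset`
#' @param neuron_id,image_id identifiers within the dataset
#' @param baseline_window,stimulus_window half-open `c(start, end)` in ms.
#' @return as [paired_rate_test()]
#' @export
image_responsiveness_test <- function(dataset, neuron_id, image_id,
                                      baseline_window = c(-200, 0),
                                      stimulus_window = c(0, 350)) {
  sp <- spikes_for_image(dataset, image_id, neuron_id)
  count_in <- function(x, w) sum(x >= w[1] & x < w[2])
  cb <- vapply(sp, count_in, 0L, w = baseline_window)
  cs <- vapply(sp, count_in, 0L, w = stimulus_window)
  paired_rate_test(cb, cs, diff(baseline_window), diff(stimulus_window))
}

#' Benjamini-Hochberg rejection set
#'
#' Step-up false-discovery-rate control: with sorted p-values
#' \eqn{p_{(1)} \le \dots \le p_{(m)}}, reject hypotheses
#' \eqn{1..k^*} where \eqn{k^* = \max\{k : p_{(k)} \le k\alpha/m\}}.
#'
#' @param p_values numeric vector in `[0, 1]`.
#' @param alpha target false discovery rate.
#' @return logical vector: `TRUE` where rejected.
#' @export
bh_adjust <- function(p_values, alpha = 0.05) {
  if (any(!is.finite(p_values)) || any(p_values < 0 | p_values > 1))
    stop("p-values must lie in [0, 1]")
  if (alpha < 0 || alpha > 1) stop("alpha must lie in [0, 1]")
  p.adjust(p_values, method = "BH") <= alpha
}

#' Classify neurons by visual responsiveness
#'
#' Runs the paired baseline-vs-stimulus rate test for every (neuron, image)
#' pair, controls the false discovery rate with Benjamini-Hochberg within
#' the chosen family, and classifies each neuron by which categories it
#' responded to: `only_dog` (significant for at least one dog image and no
#' cat image), `only_cat` (the converse), `both`, or `none`. A neuron in
#' any class but `none` is visually responsive.
#'
#' @param dataset a `spike_dataset`
#' @param baseline_window,stimulus_window half-open `c(start, end)` ms.
#'   Defaults: the 200 ms of enforced fixation before onset, and the
#'   minimum 350 ms presentation.
#' @param alpha false-discovery-rate level.
#' @param family `"per_neuron"` (BH across the images of one neuron; the
#'   default, keeping each neuron's classification self-contained) or
#'   `"global"` (one family across all neuron-image tests).
#' @return object of class `responsiveness_table`: `$neurons` data.frame
#'   (neuron_id, class, n_sig_dog, n_sig_cat), plus p-value / rejection /
#'   direction matrices (images x neurons) and the settings used.
#' @export
classify_neurons <- function(dataset,
                             baseline_window = c(-200, 0),
                             stimulus_window = c(0, 350),
                             alpha = 0.05,
                             family = c("per_neuron", "global")) {
  stopifnot(inherits(dataset, "spike_dataset"))
  family <- match.arg(family)
  idx <- .spike_index(dataset)
  if (min(idx$trials_per_img) < 2)
    stop("insufficient data: every image needs >= 2 trials")
  wb <- diff(baseline_window) / 1000
  ws <- diff(stimulus_window) / 1000

  # per-(trial, neuron) rates, then per-(image, neuron) paired t statistics
  rb <- .trial_counts(idx, baseline_window[1], baseline_window[2]) / wb
  rs <- .trial_counts(idx, stimulus_window[1], stimulus_window[2]) / ws
  d <- rs - rb
  grp <- idx$img_of_trial
  k <- idx$trials_per_img
  s1 <- rowsum(d, grp)                      # n_img x N sums
  s2 <- rowsum(d * d, grp)
  mean_d <- s1 / k
  var_d <- (s2 - s1^2 / k) / (k - 1)
  var_d[var_d < 0] <- 0  # guard against cancellation
  tstat <- ifelse(var_d > 0, mean_d / sqrt(var_d / k),
                  ifelse(mean_d == 0, 0, sign(mean_d) * Inf))
  p <- ifelse(is.infinite(tstat), 0,
              ifelse(var_d == 0, 1, 2 * pt(-abs(tstat), df = k - 1)))

  rejected <- if (family == "per_neuron") {
    apply(p, 2, bh_adjust, alpha = alpha)
  } else {
    matrix(bh_adjust(as.vector(p), alpha = alpha), nrow = nrow(p))
  }
  direction <- matrix(ifelse(mean_d > 0, "increase",
                             ifelse(mean_d < 0, "decrease", NA_character_)),
                      nrow = nrow(p))

  is_dog <- dataset$stimuli$category == "dog"
  n_sig_dog <- colSums(rejected & is_dog)
  n_sig_cat <- colSums(rejected & !is_dog)
  class <- ifelse(n_sig_dog > 0 & n_sig_cat == 0, "only_dog",
           ifelse(n_sig_cat > 0 & n_sig_dog == 0, "only_cat",
           ifelse(n_sig_dog > 0 & n_sig_cat > 0, "both", "none")))

  dimnames(p) <- dimnames(rejected) <- dimnames(direction) <-
    list(dataset$stimuli$image_id, dataset$neuron_ids)
  structure(
    list(neurons = data.frame(neuron_id = dataset$neuron_ids,
                              class = class,
                              n_sig_dog = as.integer(n_sig_dog),
                              n_sig_cat = as.integer(n_sig_cat)),
         p_values = p, rejected = rejected, direction = direction,
         alpha = alpha, family = family,
         baseline_window = baseline_window,
         stimulus_window = stimulus_window,
         dataset_id = dataset_id(dataset)),
    class = "responsiveness_table")
}

#' @export
print.responsiveness_table <- function(x, ...) {
  tab <- table(factor(x$neurons$class,
                      levels = c("only_dog", "only_cat", "both", "none")))
  cat("<responsiveness_table> ", x$dataset_id, " (alpha=", x$alpha,
      ", family=", x$family, ")\n", sep = "")
  print(tab)
  invisible(x)
}

#' Class counts of a responsiveness table
#'
#' @param table a `responsiveness_table`
#' @return one-row data.frame with columns `only_dog`, `only_cat`, `both`,
#'   `none`, `total`.
#' @export
responsiveness_counts <- function(table) {
  stopifnot(inherits(table, "responsiveness_table"))
  cl <- factor(table$neurons$class,
               levels = c("only_dog", "only_cat", "both", "none"))
  n <- as.list(table(cl))
  data.frame(only_dog = n$only_dog, only_cat = n$only_cat,
             both = n$both, none = n$none,
             total = nrow(table$neurons))
}

#' Pool responsiveness counts into percent-responsive summaries
#'
#' A neuron is responsive if it responded to at least one image (any class
#' but `none`), so the pooled percentage over a group of tables/sessions is
#' `100 * sum(total - none) / sum(total)`.
#'
#' @param counts data.frame with columns `only_dog`, `only_cat`, `both`,
#'   `none` (a `total` column is recomputed if absent), e.g. rows of
#'   [macaque_response_counts()] or [responsiveness_counts()] outputs,
#'   possibly with extra grouping columns.
#' @param by optional character vector of grouping columns in `counts`;
#'   `NULL` pools everything into one row.
#' @return data.frame with `n_total`, `n_responsive`, `pct_responsive`
#'   (unrounded) and `pct_rounded` (whole percent), one row per group.
#' @export
summarize_responsiveness <- function(counts, by = NULL) {
  .require_columns(counts, c("only_dog", "only_cat", "both", "none"),
                   "counts")
  if (nrow(counts) == 0) stop("empty pool: no counts to summarize")
  counts$total <- counts$only_dog + counts$only_cat + counts$both +
    counts$none
  counts$responsive <- counts$total - counts$none
  if (is.null(by)) {
    groups <- data.frame(row.names = 1)
    key <- rep(1L, nrow(counts))
  } else {
    key_str <- do.call(paste, c(counts[by], sep = "\r"))
    key <- match(key_str, unique(key_str))
    groups <- counts[!duplicated(key), by, drop = FALSE]
    rownames(groups) <- NULL
  }
  n_total <- as.vector(rowsum(counts$total, key))
  n_resp <- as.vector(rowsum(counts$responsive, key))
  out <- cbind(groups,
               data.frame(n_total = n_total, n_responsive = n_resp,
                          pct_responsive = 100 * n_resp / n_total,
                          pct_rounded = round(100 * n_resp / n_total)))
  rownames(out) <- NULL
  out
}

#' Published neuron-classification counts for three macaques
#'
#' Per-monkey, per-area, per-session counts of neurons classified as
#' responding only to dog images, only to cat images, to both, or to
#' neither, from chronic Utah-array recordings in areas TEO and TE of
#' three macaques (X, R, L) before and after cat/dog category training.
#' Shipped so that pooled responsiveness percentages can be reproduced
#' without the (non-deposited) raw recordings.
#'
#' @return data.frame with columns `monkey`, `area`, `session`,
#'   `only_dog`, `only_cat`, `both`, `none`.
#' @export
macaque_response_counts <- function() {
  path <- system.file("extdata", "macaque_it_response_counts.csv",
                      package = "popsep", mustWork = TRUE)
  read.csv(path, colClasses = c(monkey = "character", area = "character",
                                session = "character"))
}

#' Response-onset latency from a firing-rate function
#'
#' Detection-then-localisation rule. Detection: the rate must exceed
#' baseline mean + `threshold_sd` baseline sds continuously for at least
#' `min_duration` ms at some point after onset, otherwise the latency is
#' undefined (`NA`). Localisation: because Gaussian smoothing pulls a
#' threshold crossing earlier by an amount that grows with response
#' height, the reported latency is the first post-onset time the rate
#' reaches halfway between the baseline mean and the post-onset maximum --
#' for a step response smoothed by any symmetric kernel this mid-height
#' crossing sits exactly at the true onset.
#'
#' @param rate_fn a [firing_rate_function()] result covering both the
#'   baseline epoch and the post-onset epoch.
#' @param baseline_window half-open `c(start, end)` ms before onset.
#' @param threshold_sd detection threshold in baseline sds.
#' @param min_duration minimum continuous supra-threshold time (ms).
#' @return object of class `latency_estimate`: list with `latency` (ms or
#'   `NA`), `threshold` and `threshold_rule` (the parameters used).
#' @export
onset_latency <- function(rate_fn, baseline_window = c(-200, 0),
                          threshold_sd = 3, min_duration = 20) {
  stopifnot(inherits(rate_fn, "rate_function"))
  tt <- rate_fn$time
  rr <- rate_fn$rate
  base <- rr[tt >= baseline_window[1] & tt < baseline_window[2]]
  post <- tt >= 0
  if (length(base) < 2 || !any(post))
    stop("rate function must cover the baseline window and t >= 0")
  m <- mean(base)
  s <- sd(base)
  rule <- list(threshold_sd = threshold_sd, min_duration = min_duration,
               baseline_window = baseline_window,
               localisation = "mid-height crossing")
  undefined <- structure(list(latency = NA_real_, threshold = NA_real_,
                              threshold_rule = rule),
                         class = "latency_estimate")
  if (s == 0 && all(rr[post] <= m)) return(undefined)
  thr <- m + threshold_sd * s

  # detection: earliest run of >= min_duration ms above threshold
  pt_ <- tt[post]
  above <- rr[post] > thr
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ok <- r$values & (pt_[ends] - pt_[starts]) >= min_duration
  if (!any(ok)) return(undefined)
  t_detect <- pt_[starts[which(ok)[1]]]

  # localisation: mid-height between baseline mean and post-onset max
  peak <- max(rr[post])
  half <- (m + peak) / 2
  cross <- which(post & rr >= half)
  latency <- if (length(cross)) tt[cross[1]] else t_detect
  structure(list(latency = latency, threshold = thr, threshold_rule = rule),
            class = "latency_estimate")
}

#' @export
print.latency_estimate <- function(x, ...) {
  cat("<latency_estimate> latency = ",
      if (is.na(x$latency)) "undefined" else paste0(x$latency, " ms"),
      " (", x$threshold_rule$threshold_sd, " sd / ",
      x$threshold_rule$min_duration, " ms persistence, ",
      x$threshold_rule$localisation, ")\n", sep = "")
  invisible(x)
}
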