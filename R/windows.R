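#' Sliding analysis windows
#'
#' Generates the grid of half-open time windows `[start, start + width)`
#' used by the decoding and separation time courses: starts run from
#' `start_min` to `start_max` in steps of `step`.
#'
#' @param start_min,start_max first and last window start (ms).
#' @param width window width in ms (default 100: wide enough to capture
#'   response structure, narrow enough not to smooth over within-trial
#'   dynamics).
#' @param step slide between consecutive starts in ms (default 1).
#' @return data.frame with columns `start` and `end` (`end = start + width`).
#' @export
sliding_windows <- function(start_min, start_max, width = 100, step = 1) {
  if (start_min > start_max) stop("start_min must be <= start_max")
  if (width <= 0) stop("width must be > 0")
  if (step <= 0) stop("step must be > 0")
  starts <- seq(start_min, start_max, by = step)
  data.frame(start = starts, end = starts + width)
}

# ---- internal spike-count engine ------------------------------------------
# Index a dataset once: spikes sorted by time with integer (trial, neuron,
# image) codes, so counts in any half-open window are two binary searches
# plus one tabulate.

.spike_index <- function(dataset) {
  tr <- dataset$trials
  st <- dataset$stimuli
  img_of_trial <- match(tr$image_id, st$image_id)
  sp <- dataset$spikes
  ti <- match(sp$trial_id, tr$trial_id)
  ni <- match(sp$neuron_id, dataset$neuron_ids)
  o <- order(sp$spike_time_ms)
  list(time = sp$spike_time_ms[o],
       trial = ti[o],
       neuron = ni[o],
       img = img_of_trial[ti][o],
       img_of_trial = img_of_trial,
       n_img = nrow(st),
       n_neuron = length(dataset$neuron_ids),
       n_trial = nrow(tr),
       trials_per_img = tabulate(img_of_trial, nbins = nrow(st)))
}

# rows of the sorted spike vector falling in [start, end)
.window_rows <- function(idx, start, end) {
  lo <- findInterval(start, idx$time, left.open = TRUE)  # #{t < start}
  hi <- findInterval(end, idx$time, left.open = TRUE)    # #{t < end}
  if (hi <= lo) integer(0) else (lo + 1L):hi
}

# spike counts per (image, neuron) summed over trials, one window
.image_counts <- function(idx, start, end) {
  rows <- .window_rows(idx, start, end)
  cell <- idx$img[rows] + (idx$neuron[rows] - 1L) * idx$n_img
  matrix(tabulate(cell, nbins = idx$n_img * idx$n_neuron),
         nrow = idx$n_img, ncol = idx$n_neuron)
}

# spike counts per (trial, neuron), one window
.trial_counts <- function(idx, start, end) {
  rows <- .window_rows(idx, start, end)
  cell <- idx$trial[rows] + (idx$neuron[rows] - 1L) * idx$n_trial
  matrix(tabulate(cell, nbins = idx$n_trial * idx$n_neuron),
         nrow = idx$n_trial, ncol = idx$n_neuron)
}

# trial-averaged rates (spikes/s) per (image, neuron) for many windows:
# returns array [n_img, n_neuron, n_windows]
.window_rate_array <- function(dataset, windows, idx = .spike_index(dataset)) {
  n_win <- nrow(windows)
  out <- array(0, dim = c(idx$n_img, idx$n_neuron, n_win))
  for (w in seq_len(n_win)) {
    width_s <- (windows$end[w] - windows$start[w]) / 1000
    out[, , w] <- .image_counts(idx, windows$start[w], windows$end[w]) /
      (idx$trials_per_img * width_s)
  }
  out
}
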