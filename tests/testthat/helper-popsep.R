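# Shared fixtures and independent oracles, built in code at test time.

# tiny handcrafted dataset: 2 neurons, 4 images (2 cat / 2 dog),
# 2 trials per image, deterministic spike times
make_toy_dataset <- function() {
  stimuli <- data.frame(image_id = c("catA", "catB", "dogA", "dogB"),
                        category = c("cat", "cat", "dog", "dog"))
  trials <- data.frame(
    trial_id = sprintf("t%02d", 1:8),
    image_id = rep(stimuli$image_id, each = 2),
    presentation_duration_ms = 375)
  spikes <- data.frame(
    trial_id = c("t01", "t01", "t01", "t02", "t03", "t05", "t05", "t07"),
    neuron_id = c("n1", "n1", "n2", "n1", "n2", "n1", "n2", "n2"),
    spike_time_ms = c(-150, 50, 120, 60.5, 10, 200, 220, -20))
  spike_dataset(stimuli, trials, spikes, neuron_ids = c("n1", "n2"),
                area = "TEO", session = "pre", monkey_id = "toy")
}

# dataset with spike counts forced per (neuron, image, window): every trial
# of `image` gets `n_base` spikes in the baseline window and `n_stim` in the
# stimulus window for `neuron`, at deterministic times
make_forced_dataset <- function(counts, trials_per_image = 5,
                                neuron_ids = NULL) {
  # counts: data.frame(neuron_id, image_id, category, n_base, n_stim)
  stimuli <- unique(counts[c("image_id", "category")])
  if (is.null(neuron_ids)) neuron_ids <- unique(counts$neuron_id)
  trials <- data.frame(
    trial_id = sprintf("t%03d", seq_len(nrow(stimuli) * trials_per_image)),
    image_id = rep(stimuli$image_id, each = trials_per_image),
    presentation_duration_ms = 375)
  sp <- list()
  for (i in seq_len(nrow(counts))) {
    row <- counts[i, ]
    tr <- trials$trial_id[trials$image_id == row$image_id]
    for (k in seq_along(tr)) {
      # jitter per trial index keeps times distinct but deterministic
      if (row$n_base > 0)
        sp[[length(sp) + 1]] <- data.frame(
          trial_id = tr[k], neuron_id = row$neuron_id,
          spike_time_ms = seq(-190, -30, length.out = row$n_base) + 0.1 * k)
      if (row$n_stim > 0)
        sp[[length(sp) + 1]] <- data.frame(
          trial_id = tr[k], neuron_id = row$neuron_id,
          spike_time_ms = seq(20, 330, length.out = row$n_stim) + 0.1 * k)
    }
  }
  spikes <- if (length(sp)) do.call(rbind, sp) else
    data.frame(trial_id = character(0), neuron_id = character(0),
               spike_time_ms = numeric(0))
  spike_dataset(stimuli, trials, spikes, neuron_ids = neuron_ids,
                area = "TE", session = "pre", monkey_id = "forced")
}

# small fast synthetic config for module tests
quick_cfg <- function(...) {
  args <- list(n_neurons = 12, images_per_category = 15, trials_per_image = 5,
               baseline_rate_mean = 5, baseline_rate_sd = 2,
               latency_mean = 60, latency_sd = 20,
               response_gain_mean = 10, response_gain_sd = 5,
               category_contrast = 5, selective_fraction = 0.5,
               image_idiosyncrasy_sd = 2, seed = 1)
  over <- list(...)
  args[names(over)] <- over
  do.call(synthetic_config, args)
}

# study-condition config at the reduced acceptance scale
accept_cfg <- function(...) {
  args <- list(n_neurons = 50, images_per_category = 40,
               trials_per_image = 10,
               baseline_rate_mean = 5, baseline_rate_sd = 2,
               latency_mean = 60, latency_sd = 20,
               response_gain_mean = 10, response_gain_sd = 5,
               category_contrast = 5, selective_fraction = 0.5,
               image_idiosyncrasy_sd = 2,
               analysis_window = c(-300, 450), seed = 1)
  over <- list(...)
  args[names(over)] <- over
  do.call(synthetic_config, args)
}

# brute-force step-up Benjamini-Hochberg oracle (definition, not p.adjust)
bh_bruteforce <- function(p, alpha) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  ok <- which(ps <= seq_len(m) * alpha / m)
  reject <- logical(m)
  if (length(ok)) reject[o[seq_len(max(ok))]] <- TRUE
  reject
}

# explicit double-loop population-vector oracle
popvec_bruteforce <- function(dataset, window) {
  st <- dataset$stimuli
  out <- matrix(0, nrow(st), length(dataset$neuron_ids),
                dimnames = list(st$image_id, dataset$neuron_ids))
  width_s <- diff(window) / 1000
  for (img in st$image_id) {
    tr <- trials_for_image(dataset, img)
    for (nr in dataset$neuron_ids) {
      total <- 0
      for (tid in tr$trial_id) {
        sp <- dataset$spikes
        times <- sp$spike_time_ms[sp$trial_id == tid & sp$neuron_id == nr]
        total <- total + sum(times >= window[1] & times < window[2])
      }
      out[img, nr] <- total / nrow(tr) / width_s
    }
  }
  out
}

# pooled per-trial spike lists of one neuron across all images
all_trial_spikes <- function(dataset, neuron_id) {
  out <- list()
  for (img in dataset$stimuli$image_id)
    out <- c(out, spikes_for_image(dataset, img, neuron_id))
  out
}
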