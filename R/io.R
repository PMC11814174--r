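#' Write a spike dataset to a directory of plain-text files
#'
#' Emits `stimuli.csv` (image_id, category), `trials.csv` (trial_id,
#' image_id, presentation_duration_ms), `spikes.csv` (trial_id, neuron_id,
#' spike_time_ms; long format) and `meta.yaml` (area, session, monkey_id,
#' neuron_ids, analysis_window). Numeric fields are written with 17
#' significant digits so that [load_spike_dataset()] reproduces the dataset
#' exactly and a write/load/write cycle is byte-identical.
#'
#' @param dataset a `spike_dataset`
#' @param out_dir output directory (created if absent)
#' @return named character vector of the four file paths, invisibly.
#' @export
write_spike_dataset <- function(dataset, out_dir) {
  stopifnot(inherits(dataset, "spike_dataset"))
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", out_dir)

  paths <- c(stimuli = file.path(out_dir, "stimuli.csv"),
             trials = file.path(out_dir, "trials.csv"),
             spikes = file.path(out_dir, "spikes.csv"),
             meta = file.path(out_dir, "meta.yaml"))

  writeLines(c("image_id,category",
               sprintf("%s,%s", dataset$stimuli$image_id,
                       dataset$stimuli$category)),
             paths[["stimuli"]])
  writeLines(c("trial_id,image_id,presentation_duration_ms",
               sprintf("%s,%s,%s", dataset$trials$trial_id,
                       dataset$trials$image_id,
                       .num17(dataset$trials$presentation_duration_ms))),
             paths[["trials"]])
  writeLines(c("trial_id,neuron_id,spike_time_ms",
               sprintf("%s,%s,%s", dataset$spikes$trial_id,
                       dataset$spikes$neuron_id,
                       .num17(dataset$spikes$spike_time_ms))),
             paths[["spikes"]])
  yaml::write_yaml(
    list(area = dataset$area, session = dataset$session,
         monkey_id = dataset$monkey_id,
         neuron_ids = as.list(dataset$neuron_ids),
         analysis_window = as.numeric(dataset$analysis_window)),
    paths[["meta"]])
  invisible(paths)
}

#' Load a spike dataset written by [write_spike_dataset()]
#'
#' Reads the three tabular files plus metadata, re-validates every dataset
#' invariant (referential integrity, spike times within the analysis
#' window) and returns the dataset with spikes in canonical sorted order.
#'
#' @param dir directory containing `stimuli.csv`, `trials.csv`,
#'   `spikes.csv` and `meta.yaml`; alternatively pass the four paths
#'   explicitly.
#' @param stimuli_path,trials_path,spikes_path,meta_path explicit file
#'   paths, overriding `dir`.
#' @return a validated `spike_dataset`
#' @export
load_spike_dataset <- function(dir = NULL,
                               stimuli_path = file.path(dir, "stimuli.csv"),
                               trials_path = file.path(dir, "trials.csv"),
                               spikes_path = file.path(dir, "spikes.csv"),
                               meta_path = file.path(dir, "meta.yaml")) {
  for (p in c(stimuli_path, trials_path, spikes_path, meta_path))
    if (!file.exists(p)) stop("file not found: ", p)

  stimuli <- read.csv(stimuli_path, colClasses = "character")
  .require_columns(stimuli, c("image_id", "category"), basename(stimuli_path))
  trials <- read.csv(trials_path,
                     colClasses = c(trial_id = "character",
                                    image_id = "character",
                                    presentation_duration_ms = "numeric"))
  .require_columns(trials, c("trial_id", "image_id",
                             "presentation_duration_ms"),
                   basename(trials_path))
  spikes <- read.csv(spikes_path,
                     colClasses = c(trial_id = "character",
                                    neuron_id = "character",
                                    spike_time_ms = "numeric"))
  .require_columns(spikes, c("trial_id", "neuron_id", "spike_time_ms"),
                   basename(spikes_path))
  meta <- yaml::read_yaml(meta_path)
  needed <- c("area", "session", "monkey_id", "neuron_ids", "analysis_window")
  miss <- setdiff(needed, names(meta))
  if (length(miss))
    stop("format error in ", basename(meta_path), ": missing field(s) ",
         paste(miss, collapse = ", "))

  spike_dataset(stimuli = stimuli, trials = trials, spikes = spikes,
                neuron_ids = unlist(meta$neuron_ids),
                area = meta$area, session = meta$session,
                monkey_id = meta$monkey_id,
                analysis_window = as.numeric(unlist(meta$analysis_window)))
}

# 17 significant digits: doubles survive the text round trip exactly
.num17 <- function(x) {
  out <- sprintf("%.17g", x)
  intish <- is.finite(x) & x == round(x) & abs(x) < 2^53
  out[intish] <- sprintf("%.0f", x[intish])
  out
}
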