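#' Construct a trial-aligned spike dataset
#'
#' The central container of the package: spike times for every neuron on
#' every stimulus presentation, together with the stimulus catalogue
#' (image identity and cat/dog category) and session metadata. All spike
#' times are in milliseconds relative to stimulus onset and must lie within
#' `analysis_window`. Validation is strict: any violated invariant raises
#' an error rather than being silently repaired.
#'
#' @param stimuli data.frame with columns `image_id` (unique character)
#'   and `category` (`"cat"` or `"dog"`).
#' @param trials data.frame with columns `trial_id` (unique character),
#'   `image_id` (must resolve to a row of `stimuli`) and
#'   `presentation_duration_ms`.
#' @param spikes long-format data.frame with columns `trial_id`,
#'   `neuron_id`, `spike_time_ms`; one row per spike. Neurons that never
#'   fired on a trial simply have no rows for it.
#' @param neuron_ids character vector of all recorded units, in a fixed
#'   order that defines population-vector columns.
#' @param area recording area, `"TEO"` or `"TE"`.
#' @param session `"pre"` or `"post"` (relative to category training).
#' @param monkey_id subject identifier.
#' @param analysis_window numeric `c(start, end)` in ms; spikes outside it
#'   are a validation error. Default `c(-300, 400)` covers the pre-onset
#'   baseline and a full 350-400 ms presentation.
#'
#' @return An object of class `spike_dataset`.
#' @export
spike_dataset <- function(stimuli, trials, spikes, neuron_ids,
                          area = c("TEO", "TE"), session = c("pre", "post"),
                          monkey_id = "unknown",
                          analysis_window = c(-300, 400)) {
  area <- match.arg(area)
  session <- match.arg(session)
  .require_columns(stimuli, c("image_id", "category"), "stimuli")
  .require_columns(trials, c("trial_id", "image_id", "presentation_duration_ms"),
                   "trials")
  .require_columns(spikes, c("trial_id", "neuron_id", "spike_time_ms"), "spikes")
  stimuli$image_id <- as.character(stimuli$image_id)
  stimuli$category <- as.character(stimuli$category)
  trials$trial_id <- as.character(trials$trial_id)
  trials$image_id <- as.character(trials$image_id)
  spikes$trial_id <- as.character(spikes$trial_id)
  spikes$neuron_id <- as.character(spikes$neuron_id)
  neuron_ids <- as.character(neuron_ids)

  if (anyDuplicated(stimuli$image_id))
    stop("duplicate image_id in stimuli: ",
         paste(unique(stimuli$image_id[duplicated(stimuli$image_id)]),
               collapse = ", "))
  bad_cat <- setdiff(unique(stimuli$category), c("cat", "dog"))
  if (length(bad_cat))
    stop("category must be 'cat' or 'dog'; found: ",
         paste(bad_cat, collapse = ", "))
  if (anyDuplicated(trials$trial_id))
    stop("duplicate trial_id in trials")
  unknown_img <- setdiff(trials$image_id, stimuli$image_id)
  if (length(unknown_img))
    stop("trials reference unknown image_id: ",
         paste(utils::head(unknown_img, 5), collapse = ", "))
  if (nrow(trials) > 0) {
    orphan <- setdiff(stimuli$image_id, trials$image_id)
    if (length(orphan))
      stop("every image needs >= 1 trial; missing trials for: ",
           paste(utils::head(orphan, 5), collapse = ", "))
  }
  unknown_tr <- setdiff(spikes$trial_id, trials$trial_id)
  if (length(unknown_tr))
    stop("spikes reference unknown trial_id: ",
         paste(utils::head(unknown_tr, 5), collapse = ", "))
  unknown_nr <- setdiff(spikes$neuron_id, neuron_ids)
  if (length(unknown_nr))
    stop("spikes reference neuron_id absent from metadata: ",
         paste(utils::head(unknown_nr, 5), collapse = ", "))
  if (length(analysis_window) != 2L || diff(analysis_window) <= 0)
    stop("analysis_window must be c(start, end) with end > start")
  out_of_win <- spikes$spike_time_ms < analysis_window[1] |
    spikes$spike_time_ms >= analysis_window[2]
  if (any(out_of_win)) {
    off <- spikes[out_of_win, , drop = FALSE]
    stop("spike times outside analysis_window [",
         analysis_window[1], ", ", analysis_window[2], "): ",
         nrow(off), " offender(s), first: trial ", off$trial_id[1],
         " neuron ", off$neuron_id[1], " t=", off$spike_time_ms[1])
  }

  # canonical order: trial, neuron, time (also enforces sortedness)
  o <- order(match(spikes$trial_id, trials$trial_id),
             match(spikes$neuron_id, neuron_ids),
             spikes$spike_time_ms)
  spikes <- spikes[o, c("trial_id", "neuron_id", "spike_time_ms")]
  rownames(spikes) <- NULL
  rownames(stimuli) <- NULL
  rownames(trials) <- NULL

  structure(
    list(area = area, session = session, monkey_id = monkey_id,
         neuron_ids = neuron_ids,
         stimuli = stimuli[, c("image_id", "category")],
         trials = trials[, c("trial_id", "image_id", "presentation_duration_ms")],
         spikes = spikes,
         analysis_window = as.numeric(analysis_window)),
    class = "spike_dataset")
}

#' @export
print.spike_dataset <- function(x, ...) {
  cat("<spike_dataset> ", x$area, "/", x$session, " monkey=", x$monkey_id,
      "\n  ", length(x$neuron_ids), " neurons, ", nrow(x$stimuli),
      " images (", sum(x$stimuli$category == "cat"), " cat / ",
      sum(x$stimuli$category == "dog"), " dog), ", nrow(x$trials),
      " trials, ", nrow(x$spikes), " spikes\n  analysis window [",
      x$analysis_window[1], ", ", x$analysis_window[2], ") ms\n", sep = "")
  invisible(x)
}

#' Short identifier for a dataset (area_session_monkey)
#' @param dataset a `spike_dataset`
#' @return character scalar
#' @export
dataset_id <- function(dataset) {
  stopifnot(inherits(dataset, "spike_dataset"))
  paste(dataset$area, dataset$session, dataset$monkey_id, sep = "_")
}

#' All trials of one image
#'
#' @param dataset a `spike_dataset`
#' @param image_id image identifier present in the dataset
#' @return data.frame of trial records (subset of `dataset$trials`),
#'   order-stable with respect to the dataset's trial order.
#' @export
trials_for_image <- function(dataset, image_id) {
  stopifnot(inherits(dataset, "spike_dataset"))
  if (!image_id %in% dataset$stimuli$image_id)
    stop("unknown image_id: ", image_id)
  out <- dataset$trials[dataset$trials$image_id == image_id, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Spike times of one neuron on the trials of one image
#'
#' @inheritParams trials_for_image
#' @param neuron_id neuron identifier
#' @return list of numeric vectors (sorted spike times, ms), one per trial,
#'   named by trial_id.
#' @export
spikes_for_image <- function(dataset, image_id, neuron_id) {
  tr <- trials_for_image(dataset, image_id)
  if (!neuron_id %in% dataset$neuron_ids)
    stop("unknown neuron_id: ", neuron_id)
  sp <- dataset$spikes
  sp <- sp[sp$neuron_id == neuron_id & sp$trial_id %in% tr$trial_id, ,
           drop = FALSE]
  out <- split(sp$spike_time_ms, factor(sp$trial_id, levels = tr$trial_id))
  lapply(out, as.numeric)
}

.require_columns <- function(df, cols, what) {
  if (!is.data.frame(df)) stop(what, " must be a data.frame")
  missing <- setdiff(cols, names(df))
  if (length(missing))
    stop("format error in ", what, ": missing column(s) ",
         paste(missing, collapse = ", "))
  invisible(TRUE)
}
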