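#' Per-image population vectors in one time window
#'
#' Builds the n_images x N matrix whose entry (i, n) is neuron n's firing
#' rate for image i in the window: the spike count in `[start, end)` summed
#' over the image's trials, divided by the number of trials and the window
#' width, in spikes/s. Row order follows the dataset's stimulus order;
#' labels are 0 for cat and 1 for dog.
#'
#' @param dataset a `spike_dataset`
#' @param window half-open `c(start, end)` in ms, inside the dataset's
#'   analysis window.
#' @return object of class `popvec_set`: list with `matrix` (rates),
#'   `labels` (0/1 integer per row), `image_ids`, `neuron_ids`, `window`,
#'   `provenance` (contributing dataset ids).
#' @export
population_vectors <- function(dataset, window) {
  stopifnot(inherits(dataset, "spike_dataset"), length(window) == 2L)
  if (window[2] <= window[1]) stop("window must satisfy end > start")
  if (window[1] < dataset$analysis_window[1] ||
      window[2] > dataset$analysis_window[2])
    stop("window [", window[1], ", ", window[2],
         ") outside the analysis window")
  idx <- .spike_index(dataset)
  width_s <- diff(window) / 1000
  mat <- .image_counts(idx, window[1], window[2]) /
    (idx$trials_per_img * width_s)
  dimnames(mat) <- list(dataset$stimuli$image_id, dataset$neuron_ids)
  structure(
    list(matrix = mat,
         labels = as.integer(dataset$stimuli$category == "dog"),
         image_ids = dataset$stimuli$image_id,
         neuron_ids = dataset$neuron_ids,
         window = as.numeric(window),
         provenance = dataset_id(dataset)),
    class = "popvec_set")
}

#' @export
print.popvec_set <- function(x, ...) {
  cat("<popvec_set> ", nrow(x$matrix), " images x ", ncol(x$matrix),
      " neurons, window [", x$window[1], ", ", x$window[2],
      ") ms, sources: ", paste(x$provenance, collapse = " + "),
      "\n", sep = "")
  invisible(x)
}

#' Pool population-vector sets into a pseudo-population
#'
#' Column-concatenates sets recorded non-simultaneously (different arrays,
#' monkeys or sessions) into one wider set. Valid because rows are indexed
#' by shared image identity: every set must cover the same stimuli in the
#' same order, with the same labels and the same time window. Neuron ids
#' are prefixed with their source dataset id and provenance records all
#' sources.
#'
#' @param sets list of `popvec_set` objects (>= 1).
#' @return a pooled `popvec_set`.
#' @export
pool_pseudopopulation <- function(sets) {
  if (inherits(sets, "popvec_set")) sets <- list(sets)
  stopifnot(length(sets) >= 1, all(vapply(sets, inherits, TRUE, "popvec_set")))
  ref <- sets[[1]]
  for (s in sets[-1]) {
    if (!isTRUE(all.equal(s$window, ref$window)))
      stop("alignment error: sets have different time windows")
    if (!identical(s$image_ids, ref$image_ids))
      stop("alignment error: sets cover different image sets or orders")
    if (!identical(s$labels, ref$labels))
      stop("alignment error: sets have different labels")
  }
  mats <- lapply(sets, function(s) {
    m <- s$matrix
    colnames(m) <- paste(s$provenance[1], s$neuron_ids, sep = ".")
    m
  })
  pooled <- do.call(cbind, mats)
  structure(
    list(matrix = pooled, labels = ref$labels, image_ids = ref$image_ids,
         neuron_ids = colnames(pooled), window = ref$window,
         provenance = unlist(lapply(sets, `[[`, "provenance"))),
    class = "popvec_set")
}

# population vectors for one or several datasets pooled, many windows:
# list of popvec_set, one per window (shared fast path of the time courses)
.popvec_series <- function(datasets, windows) {
  if (inherits(datasets, "spike_dataset")) datasets <- list(datasets)
  stopifnot(all(vapply(datasets, inherits, TRUE, "spike_dataset")))
  idxs <- lapply(datasets, .spike_index)
  arrays <- mapply(function(d, i) .window_rate_array(d, windows, i),
                   datasets, idxs, SIMPLIFY = FALSE)
  ref <- datasets[[1]]
  ids <- vapply(datasets, dataset_id, "")
  for (d in datasets[-1]) {
    if (!identical(d$stimuli, ref$stimuli))
      stop("alignment error: datasets have different stimulus sets")
  }
  neuron_ids <- unlist(mapply(function(d, id)
    paste(id, d$neuron_ids, sep = "."), datasets, ids, SIMPLIFY = FALSE))
  labels <- as.integer(ref$stimuli$category == "dog")
  lapply(seq_len(nrow(windows)), function(w) {
    mat <- do.call(cbind, lapply(arrays, function(a) a[, , w, drop = TRUE]))
    if (is.null(dim(mat))) mat <- matrix(mat, nrow = nrow(ref$stimuli))
    dimnames(mat) <- list(ref$stimuli$image_id, neuron_ids)
    structure(list(matrix = mat, labels = labels,
                   image_ids = ref$stimuli$image_id,
                   neuron_ids = neuron_ids,
                   window = c(windows$start[w], windows$end[w]),
                   provenance = ids),
              class = "popvec_set")
  })
}
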