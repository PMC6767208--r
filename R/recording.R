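#' Event classes and person statuses
#'
#' The six event classes and two person statuses used to annotate floor-sensor
#' recordings. A signal is labelled `staff` only when every person on the
#' floor belongs to the medical staff.
#'
#' @name annotation-levels
#' @keywords internal
EVENT_CLASSES <- c("walk_single", "walk_multi", "wheelchair",
                   "wheelchair_pushed", "cart_walk", "other")
PERSON_STATUSES <- c("staff", "elderly")

#' Step bounding boxes
#'
#' Step boxes delimit the samples occupied by one footstep on the raw 100 Hz
#' grid. Coordinates are 0-based, half-open `[start, end)` sample indices.
#'
#' @param start,end integer vectors of equal length; `0 <= start < end`.
#' @return An integer matrix with columns `start` and `end`, class
#'   `step_boxes`.
#' @export
step_boxes <- function(start = integer(), end = integer()) {
  if (length(start) != length(end))
    stop("`start` and `end` must have equal length", call. = FALSE)
  start <- as.integer(start); end <- as.integer(end)
  if (length(start) && any(start < 0L | end <= start))
    stop("step boxes require 0 <= start < end", call. = FALSE)
  m <- cbind(start = start, end = end)
  class(m) <- c("step_boxes", class(m))
  m
}

empty_boxes <- function() step_boxes()

#' Annotation of a floor-sensor event
#'
#' @param event_class one of `walk_single`, `walk_multi`, `wheelchair`,
#'   `wheelchair_pushed`, `cart_walk`, `other`.
#' @param person_status `"staff"` or `"elderly"`.
#' @param n_persons number of persons on the floor; must be 1 for
#'   `walk_single` and greater than 1 for `walk_multi`.
#' @param step_boxes a [step_boxes()] matrix (may be empty for non-walk
#'   classes).
#' @return An object of class `event_annotation`.
#' @export
event_annotation <- function(event_class, person_status, n_persons = 1L,
                             step_boxes = empty_boxes()) {
  event_class <- match.arg(event_class, EVENT_CLASSES)
  person_status <- match.arg(person_status, PERSON_STATUSES)
  n_persons <- as.integer(n_persons)
  if (n_persons < 1L) stop("`n_persons` must be positive", call. = FALSE)
  if (event_class == "walk_single" && n_persons != 1L)
    stop("walk_single implies n_persons = 1", call. = FALSE)
  if (event_class == "walk_multi" && n_persons <= 1L)
    stop("walk_multi implies n_persons > 1", call. = FALSE)
  if (!inherits(step_boxes, "step_boxes"))
    step_boxes <- do.call("step_boxes",
                          list(start = step_boxes[, 1], end = step_boxes[, 2]))
  structure(list(event_class = event_class, person_status = person_status,
                 n_persons = n_persons, step_boxes = step_boxes),
            class = "event_annotation")
}

empty_annotation <- function() {
  structure(list(event_class = NA_character_, person_status = NA_character_,
                 n_persons = NA_integer_, step_boxes = empty_boxes()),
            class = "event_annotation")
}

#' A multichannel floor-sensor recording
#'
#' A recording holds the K-channel signal emitted by the piezoelectric floor
#' bands (one row per channel, amplifier units) sampled at `rate_hz`,
#' together with its event annotation.
#'
#' @param channels numeric matrix, K rows (channels) by T columns (samples).
#' @param rate_hz sampling frequency in Hz (default 100).
#' @param id character identifier.
#' @param annotation an [event_annotation()] or `NULL`.
#' @return An object of class `recording`.
#' @export
recording <- function(channels, rate_hz = 100, id = "rec",
                      annotation = NULL) {
  channels <- as.matrix(channels)
  storage.mode(channels) <- "double"
  if (nrow(channels) < 1L || ncol(channels) < 1L)
    stop("`channels` must have K >= 1 rows and T > 0 columns", call. = FALSE)
  if (!is.numeric(rate_hz) || rate_hz <= 0)
    stop("`rate_hz` must be positive", call. = FALSE)
  ann <- annotation %||% empty_annotation()
  if (!inherits(ann, "event_annotation"))
    stop("`annotation` must be an event_annotation", call. = FALSE)
  Tn <- ncol(channels)
  if (nrow(ann$step_boxes) && any(ann$step_boxes[, "end"] > Tn))
    stop("step boxes must lie within [0, T)", call. = FALSE)
  structure(list(channels = channels, rate_hz = rate_hz, id = as.character(id),
                 annotation = ann),
            class = "recording")
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording '%s'> %d channels x %d samples @ %g Hz\n",
              x$id, nrow(x$channels), ncol(x$channels), x$rate_hz))
  a <- x$annotation
  if (!is.na(a$event_class))
    cat(sprintf("  %s / %s, %d person(s), %d step box(es)\n", a$event_class,
                a$person_status, a$n_persons, nrow(a$step_boxes)))
  invisible(x)
}

#' A collection of recordings
#'
#' @param recordings list of [recording()] objects.
#' @return An object of class `floor_dataset`.
#' @export
floor_dataset <- function(recordings) {
  if (!length(recordings)) stop("empty dataset", call. = FALSE)
  if (!all(vapply(recordings, inherits, TRUE, "recording")))
    stop("all elements must be recordings", call. = FALSE)
  structure(list(recordings = recordings), class = "floor_dataset")
}

#' @export
length.floor_dataset <- function(x) length(x$recordings)

#' @export
print.floor_dataset <- function(x, ...) {
  cat(sprintf("<floor_dataset> %d recordings\n", length(x)))
  print(dataset_manifest(x))
  invisible(x)
}

#' Manifest of a dataset
#'
#' Counts of recordings per (event class, person status) cell.
#'
#' @param ds a [floor_dataset()].
#' @return A data frame with columns `event_class`, `person_status`, `count`.
#' @export
dataset_manifest <- function(ds) {
  ec <- vapply(ds$recordings, function(r) r$annotation$event_class, "")
  ps <- vapply(ds$recordings, function(r) r$annotation$person_status, "")
  tab <- as.data.frame(table(
    event_class = factor(ec, EVENT_CLASSES),
    person_status = factor(ps, PERSON_STATUSES)), stringsAsFactors = FALSE)
  names(tab)[3] <- "count"
  tab <- tab[tab$count > 0L, ]
  rownames(tab) <- NULL
  tab[order(tab$event_class, tab$person_status), ]
}

# Activity label used for stratification: single walk / multiple walks /
# other (all non-walk classes pooled).
activity_label <- function(event_class) {
  ifelse(event_class == "walk_single", "single",
         ifelse(event_class == "walk_multi", "multi", "other"))
}

#' Subset a dataset
#'
#' @param ds a [floor_dataset()].
#' @param classes event classes to keep (default all).
#' @param statuses person statuses to keep (default all).
#' @return A [floor_dataset()] with the matching recordings.
#' @export
dataset_subset <- function(ds, classes = EVENT_CLASSES,
                           statuses = PERSON_STATUSES) {
  keep <- vapply(ds$recordings, function(r)
    r$annotation$event_class %in% classes &&
      r$annotation$person_status %in% statuses, TRUE)
  if (!any(keep)) stop("subset is empty", call. = FALSE)
  floor_dataset(ds$recordings[keep])
}

#' Stratified train/test split
#'
#' Splits a dataset into train and test sets by stratified random sampling.
#' Strata are the crossing of the activity label (single walk, multiple
#' walks, other) with the person status (staff, elderly). Within each
#' stratum the test count is `round(stratum_size * test_fraction)`
#' (half-up), clamped so that neither side is empty whenever the stratum has
#' at least two recordings; the remainder goes to train.
#'
#' @param ds a [floor_dataset()].
#' @param test_fraction fraction of each stratum assigned to test, in (0,1).
#' @param seed integer seed; the partition is deterministic given the seed.
#' @return A list with elements `train` and `test`, both [floor_dataset()]s.
#' @export
stratified_split <- function(ds, test_fraction = 0.3, seed = 1L) {
  if (!length(ds$recordings)) stop("empty dataset", call. = FALSE)
  if (test_fraction <= 0 || test_fraction >= 1)
    stop("`test_fraction` must be in (0, 1)", call. = FALSE)
  ec <- vapply(ds$recordings, function(r) r$annotation$event_class, "")
  ps <- vapply(ds$recordings, function(r) r$annotation$person_status, "")
  stratum <- paste(activity_label(ec), ps, sep = ".")
  test_idx <- integer(0)
  with_seed(seed, {
    for (s in sort(unique(stratum))) {
      idx <- which(stratum == s)
      n <- length(idx)
      k <- floor(n * test_fraction + 0.5)  # round half-up
      if (n >= 2L) k <- min(max(k, 1L), n - 1L) else k <- 0L
      if (k > 0L) test_idx <- c(test_idx, sample(idx, k))
    }
  })
  train_idx <- setdiff(seq_along(ds$recordings), test_idx)
  if (!length(test_idx)) stop("test set is empty; increase test_fraction",
                              call. = FALSE)
  list(train = floor_dataset(ds$recordings[train_idx]),
       test = floor_dataset(ds$recordings[test_idx]))
}
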