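#' Read a floor-sensor recording
#'
#' Reads the delimited-text signal container written by [write_recording()]:
#' two header lines `# rate_hz=<r>` and `# channels=<K>` followed by one row
#' per sample with K comma-separated columns (one per channel). If a JSON
#' sidecar `<path-without-extension>.json` exists it is loaded as the event
#' annotation; otherwise the recording carries an empty annotation and a
#' warning is raised.
#'
#' @param path path to the `.csv` signal file.
#' @return A [recording()].
#' @export
read_recording <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path),
                               call. = FALSE)
  lines <- readLines(path)
  if (length(lines) < 3L)
    stop(sprintf("%s: too short to be a recording file", path), call. = FALSE)
  hdr <- lines[1:2]
  rate <- sub("^#\\s*rate_hz=", "", hdr[1])
  nch <- sub("^#\\s*channels=", "", hdr[2])
  if (identical(rate, hdr[1]) || identical(nch, hdr[2]))
    stop(sprintf("%s: malformed header (lines 1-2)", path), call. = FALSE)
  rate <- suppressWarnings(as.numeric(rate))
  nch <- suppressWarnings(as.integer(nch))
  if (is.na(rate) || is.na(nch))
    stop(sprintf("%s: non-numeric header values (lines 1-2)", path),
         call. = FALSE)
  body <- lines[-(1:2)]
  body <- body[nzchar(body)]
  parts <- strsplit(body, ",", fixed = TRUE)
  lens <- lengths(parts)
  if (any(lens != nch)) {
    bad <- which(lens != nch)[1]
    stop(sprintf("%s: line %d has %d columns, expected %d", path, bad + 2L,
                 lens[bad], nch), call. = FALSE)
  }
  vals <- suppressWarnings(as.numeric(unlist(parts)))
  if (anyNA(vals)) {
    bad <- which(vapply(parts, function(p)
      anyNA(suppressWarnings(as.numeric(p))), TRUE))[1]
    stop(sprintf("%s: line %d does not parse as numbers", path, bad + 2L),
         call. = FALSE)
  }
  channels <- matrix(vals, nrow = nch)  # file rows are samples -> K x T
  sidecar <- paste0(tools::file_path_sans_ext(path), ".json")
  id <- tools::file_path_sans_ext(basename(path))
  if (file.exists(sidecar)) {
    ann <- read_annotation(sidecar)
  } else {
    warning(sprintf("no annotation sidecar for %s", path), call. = FALSE)
    ann <- empty_annotation()
  }
  recording(channels, rate_hz = rate, id = id, annotation = ann)
}

read_annotation <- function(path) {
  j <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  boxes <- j$step_boxes
  if (is.null(boxes) || length(boxes) == 0L) {
    sb <- empty_boxes()
  } else {
    if (!is.matrix(boxes))   # list of [start, end] pairs
      boxes <- do.call(rbind, boxes)
    sb <- step_boxes(boxes[, 1], boxes[, 2])
  }
  event_annotation(j$event_class, j$person_status,
                   n_persons = j$n_persons %||% 1L, step_boxes = sb)
}

#' Write a floor-sensor recording
#'
#' Writes the signal container (see [read_recording()] for the format) and a
#' JSON annotation sidecar next to it. `read_recording()` inverts this
#' within floating-point round-trip.
#'
#' @param rec a [recording()].
#' @param path destination `.csv` path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "recording"))
  K <- nrow(rec$channels)
  rows <- apply(rec$channels, 2, function(col)
    paste(sprintf("%.17g", col), collapse = ","))
  out <- c(sprintf("# rate_hz=%.17g", rec$rate_hz),
           sprintf("# channels=%d", K), rows)
  ok <- tryCatch({ writeLines(out, path); TRUE },
                 error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop(sprintf("cannot write %s", path), call. = FALSE)
  ann <- rec$annotation
  if (!is.na(ann$event_class)) {
    sidecar <- paste0(tools::file_path_sans_ext(path), ".json")
    bx <- ann$step_boxes
    boxes <- if (nrow(bx)) lapply(seq_len(nrow(bx)), function(i)
      c(bx[i, "start"], bx[i, "end"])) else list()
    json <- jsonlite::toJSON(list(event_class = ann$event_class,
                                  person_status = ann$person_status,
                                  n_persons = ann$n_persons,
                                  step_boxes = boxes),
                             auto_unbox = TRUE, digits = NA)
    writeLines(json, sidecar)
  }
  invisible(path)
}

#' Write or read a whole dataset directory
#'
#' One `.csv` + `.json` pair per recording plus a `manifest.csv` summarising
#' counts per (event class, person status).
#'
#' @param ds a [floor_dataset()].
#' @param dir directory (created if missing).
#' @return `dir` (write) or a [floor_dataset()] (read).
#' @export
write_dataset <- function(ds, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (r in ds$recordings)
    write_recording(r, file.path(dir, paste0(r$id, ".csv")))
  utils::write.csv(dataset_manifest(ds), file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.csv$", full.names = TRUE))
  files <- files[basename(files) != "manifest.csv"]
  if (!length(files)) stop(sprintf("no recordings in %s", dir), call. = FALSE)
  floor_dataset(lapply(files, read_recording))
}
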