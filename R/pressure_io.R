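#' Construct a pressure frame
#'
#' A pressure frame is one snapshot of the sensor mat: a non-negative matrix
#' of raw pressure values (prv) with rows running cranial to caudal (index j)
#' and columns from the subject's left to right (index i).
#'
#' @param values numeric matrix of non-negative, finite pressure values.
#' @param pixel_mm edge length of one sensor cell in millimetres.
#' @return An object of class `pressure_frame`.
#' @export
#' @examples
#' f <- pressure_frame(matrix(0, 160, 100))
#' dim(f$values)
pressure_frame <- function(values, pixel_mm = torso_defaults()$pixel_mm) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix", call. = FALSE)
  if (anyNA(values) || any(!is.finite(values)))
    stop("pressure values must be finite", call. = FALSE)
  if (any(values < 0))
    stop("pressure values must be non-negative", call. = FALSE)
  if (!is.numeric(pixel_mm) || length(pixel_mm) != 1L || pixel_mm <= 0)
    stop("`pixel_mm` must be a positive scalar", call. = FALSE)
  structure(list(values = unname(values), pixel_mm = pixel_mm),
            class = "pressure_frame")
}

#' @export
print.pressure_frame <- function(x, ...) {
  cat(sprintf("<pressure_frame> %d x %d px (%.1f mm/px), mean %.1f prv\n",
              nrow(x$values), ncol(x$values), x$pixel_mm, mean(x$values)))
  invisible(x)
}

#' Construct a recording
#'
#' A recording is an ordered sequence of pressure frames sharing one shape
#' and resolution, nominally 100 frames (10 s at 10 Hz) per measurement.
#'
#' @param frames list of [pressure_frame()] objects (length >= 1).
#' @param sample_rate_hz sampling rate in Hz.
#' @param subject_id,repetition_id opaque labels carried through the pipeline.
#' @return An object of class `torso_recording`.
#' @export
recording <- function(frames, sample_rate_hz = torso_defaults()$sample_rate_hz,
                      subject_id = NA_character_,
                      repetition_id = NA_character_) {
  if (!is.list(frames) || length(frames) < 1L)
    stop("`frames` must be a non-empty list of pressure frames", call. = FALSE)
  if (!all(vapply(frames, inherits, logical(1), "pressure_frame")))
    stop("all elements of `frames` must be pressure_frame objects",
         call. = FALSE)
  dims <- vapply(frames, function(f) dim(f$values), integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("all frames must share one shape", call. = FALSE)
  px <- vapply(frames, function(f) f$pixel_mm, numeric(1))
  if (any(px != px[1]))
    stop("all frames must share one pixel_mm", call. = FALSE)
  structure(list(frames = frames, sample_rate_hz = sample_rate_hz,
                 subject_id = subject_id, repetition_id = repetition_id),
            class = "torso_recording")
}

#' @export
print.torso_recording <- function(x, ...) {
  cat(sprintf("<torso_recording> %d frame(s) @ %g Hz, subject=%s rep=%s\n",
              length(x$frames), x$sample_rate_hz, x$subject_id,
              x$repetition_id))
  invisible(x)
}

#' @export
length.torso_recording <- function(x) length(x$frames)

frame_filename <- function(k) sprintf("frame_%03d.csv", k)

#' Read a recording from a directory of CSV frames
#'
#' The on-disk dialect is one comma-separated matrix per frame
#' (`frame_000.csv`, `frame_001.csv`, ..., rows = j, no header) plus an
#' optional JSON sidecar `meta.json` with keys `shape`, `pixel_mm`,
#' `sample_rate_hz`, `subject_id`, `repetition_id`. Missing sidecar entries
#' fall back to the system defaults (160 x 100, 5.1 mm/px, 10 Hz).
#'
#' @param path directory containing at least one frame file.
#' @return A [recording()].
#' @export
read_recording <- function(path) {
  if (!dir.exists(path))
    stop("input error: not a directory: ", path, call. = FALSE)
  files <- sort(list.files(path, pattern = "^frame_\\d+\\.csv$",
                           full.names = TRUE))
  if (length(files) == 0L)
    stop("input error: no frame files in ", path, call. = FALSE)
  d <- torso_defaults()
  meta <- list(pixel_mm = d$pixel_mm, sample_rate_hz = d$sample_rate_hz,
               subject_id = NA_character_, repetition_id = NA_character_)
  meta_path <- file.path(path, "meta.json")
  if (file.exists(meta_path)) {
    m <- jsonlite::fromJSON(meta_path)
    for (nm in intersect(names(m), names(meta)))
      if (!is.null(m[[nm]])) meta[[nm]] <- m[[nm]]
  }
  frames <- lapply(files, function(f) {
    mat <- tryCatch(
      as.matrix(read.table(f, sep = ",", header = FALSE,
                           colClasses = "numeric")),
      error = function(e)
        stop("format error in ", basename(f), ": ", conditionMessage(e),
             call. = FALSE))
    bad <- which(mat < 0, arr.ind = TRUE)
    if (nrow(bad) > 0L)
      stop(sprintf("format error in %s: negative value %g at row %d, col %d",
                   basename(f), mat[bad[1, 1], bad[1, 2]],
                   bad[1, 1], bad[1, 2]), call. = FALSE)
    pressure_frame(mat, pixel_mm = meta$pixel_mm)
  })
  recording(frames, sample_rate_hz = meta$sample_rate_hz,
            subject_id = as.character(meta$subject_id),
            repetition_id = as.character(meta$repetition_id))
}

#' Write a recording to a directory of CSV frames
#'
#' Inverse of [read_recording()]; the round trip is lossless for the values.
#'
#' @param rec a [recording()].
#' @param path output directory (created if absent).
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "torso_recording"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  for (k in seq_along(rec$frames)) {
    write.table(rec$frames[[k]]$values,
                file.path(path, frame_filename(k - 1L)),
                sep = ",", row.names = FALSE, col.names = FALSE)
  }
  meta <- list(shape = dim(rec$frames[[1]]$values),
               pixel_mm = rec$frames[[1]]$pixel_mm,
               sample_rate_hz = rec$sample_rate_hz,
               subject_id = rec$subject_id,
               repetition_id = rec$repetition_id)
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Select the medial frame of a recording
#'
#' A single frame is analysed per measurement to suppress the influence of
#' breathing and small movements: the frame whose mean pressure intensity is
#' the median of the per-frame means. For an even frame count the frame at
#' ascending rank ceiling(n/2) is taken (deterministic; frames are never
#' averaged).
#'
#' @param rec a [recording()].
#' @return The selected [pressure_frame()].
#' @export
select_medial_frame <- function(rec) {
  stopifnot(inherits(rec, "torso_recording"))
  n <- length(rec$frames)
  if (n == 0L) stop("input error: empty recording", call. = FALSE)
  means <- vapply(rec$frames, function(f) mean(f$values), numeric(1))
  ord <- order(means)           # stable: ties keep frame order
  rec$frames[[ord[ceiling(n / 2)]]]
}
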