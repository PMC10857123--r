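# End-to-end orchestration: recording -> parameter set, and a directory of
# labelled recordings -> reliability table. Parameter families are isolated:
# a failed waist fit must not void the sagittal parameters of the same
# measurement.

#' Canonical parameter universe
#'
#' Named character vector mapping every scalar the pipeline reports to its
#' unit (`px`, `px2`, `nd`, `deg`, `prv`, `prv_per_px`, `percent`). This is
#' also the row universe of the reliability table.
#'
#' @return Named character vector of units.
#' @export
param_template <- function() {
  c(jts = "px", jt = "px", jtmax = "px", jtl = "px", jlmin = "px",
    jl = "px", jsmax = "px", il = "px", ir = "px",
    dl = "px", dw = "px", dth = "px", dlu = "px", ds = "px",
    FC1 = "px", FC2 = "px2", FC3 = "nd", FC4 = "px", FC5 = "px",
    FC6 = "px", FC7 = "nd",
    SC1 = "nd", SC2 = "nd", SC3 = "nd", SC4 = "nd", SC5 = "nd",
    SC6 = "nd", SC7 = "nd", SC8 = "nd",
    S0_l = "px", S0_r = "px", S1 = "px", S2 = "nd", S2_l = "nd",
    S2_r = "nd",
    SB0_vl = "px", SB0_vr = "px", SB0_hl = "px", SB0_hr = "px",
    SB1 = "px", SB2 = "px", SB3 = "deg", SB4 = "nd", SB4_l = "prv",
    SB4_r = "prv", SB5 = "nd", SB5_l = "prv", SB5_r = "prv",
    TS1 = "px", TS2 = "nd", TS2_l = "prv", TS2_r = "prv", TS3 = "nd",
    TS3_l = "prv", TS3_r = "prv", TS4 = "nd", TS4_l = "prv",
    TS4_r = "prv", TS5 = "percent",
    W0_vl = "px", W0_vr = "px", W0_hl = "px", W0_hr = "px",
    W1 = "px", W2 = "px", W3 = "deg", W4 = "nd", W4_l = "nd", W4_r = "nd",
    P0_ul = "px", P0_ur = "px", P0_ll = "px", P0_lr = "px",
    P1 = "prv_per_px", P2 = "px", P3 = "nd", P3_l = "prv", P3_r = "prv",
    P4 = "nd", P4_l = "prv", P4_r = "prv")
}

take_params <- function(res, names_wanted) {
  out <- rep(NA_real_, length(names_wanted))
  names(out) <- names_wanted
  for (nm in names_wanted) {
    v <- res[[nm]]
    if (!is.null(v) && is.numeric(v) && length(v) == 1L) out[nm] <- v
  }
  out
}

#' Analyse one recording
#'
#' Runs the full pipeline: medial-frame selection, filtering, symmetry
#' alignment, ROI mask fitting, landmark detection and every parameter
#' family. Parameter families that fail are recorded in `failures` and their
#' entries set to NA; the rest of the set is still produced.
#'
#' @param rec a [recording()] (or a single [pressure_frame()]).
#' @param config a [torso_config()] list.
#' @return A `torso_params` object: `values` (named numeric vector over
#'   [param_template()]), `units`, `failures`, `warnings`, plus the
#'   intermediate `aligned`, `roi`, `landmarks` and family details.
#' @export
analyze_recording <- function(rec, config = torso_config()) {
  frame <- if (inherits(rec, "pressure_frame")) rec
           else select_medial_frame(rec)
  warns <- character(0)
  wcollect <- function(expr)
    withCallingHandlers(expr, warning = function(w) {
      warns <<- c(warns, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  f <- wcollect(filter_frames(frame))
  al <- wcollect(align(f$I, f$Is, config))
  roi <- wcollect(fit_roi(al$I, config))
  lm <- wcollect(detect_landmarks(roi, al$I, config))
  tmpl <- param_template()
  values <- rep(NA_real_, length(tmpl))
  names(values) <- names(tmpl)
  failures <- list()
  details <- list()
  run_family <- function(name, fun) {
    res <- tryCatch(wcollect(fun()), error = function(e) e)
    if (inherits(res, "error")) {
      failures[[name]] <<- conditionMessage(res)
      NULL
    } else {
      details[[name]] <<- res
      res
    }
  }
  values[names(take_params(lm, names(tmpl)))] <-
    take_params(lm, names(tmpl))
  dist <- run_family("distances", function()
    reference_distances(lm, nrow(roi$mask), frame$pixel_mm))
  if (!is.null(dist))
    values[c("dl", "dw", "dth", "dlu", "ds")] <-
      unlist(dist[c("dl", "dw", "dth", "dlu", "ds")])
  fc <- run_family("frontal", function() {
    curve <- extract_frontal_curve(roi, lm, config)
    c(frontal_params(curve, lm), list(curve = curve))
  })
  if (!is.null(fc)) values[names(tmpl)] <-
    ifelse(is.na(values), take_params(fc, names(tmpl)), values)
  sc <- run_family("sagittal", function() sagittal_params(lm))
  if (!is.null(sc)) values[names(tmpl)] <-
    ifelse(is.na(values), take_params(sc, names(tmpl)), values)
  sh <- run_family("shoulder", function() shoulder_params(roi, lm))
  if (!is.null(sh)) values[names(tmpl)] <-
    ifelse(is.na(values), take_params(sh, names(tmpl)), values)
  centres <- run_family("scapula_centres", function()
    locate_scapulae(al$Is, lm, config))
  if (!is.null(centres)) {
    sb <- run_family("scapula", function()
      scapula_params(al$Is, centres, lm))
    if (!is.null(sb)) values[names(tmpl)] <-
      ifelse(is.na(values), take_params(sb, names(tmpl)), values)
    ts <- run_family("torso_symmetry", function()
      torso_symmetry_params(roi, lm, centres))
    if (!is.null(ts)) values[names(tmpl)] <-
      ifelse(is.na(values), take_params(ts, names(tmpl)), values)
  }
  w <- run_family("waist", function() waist_params(roi, lm))
  if (!is.null(w)) values[names(tmpl)] <-
    ifelse(is.na(values), take_params(w, names(tmpl)), values)
  p1 <- run_family("sacral_slope", function() list(P1 = sacral_slope(lm)))
  if (!is.null(p1)) values["P1"] <- p1$P1
  pp <- run_family("pelvic", function() pelvic_params(roi, lm))
  if (!is.null(pp)) values[names(tmpl)] <-
    ifelse(is.na(values), take_params(pp, names(tmpl)), values)
  structure(list(values = values, units = tmpl, failures = failures,
                 warnings = warns, aligned = al, roi = roi, landmarks = lm,
                 details = details,
                 subject_id = if (inherits(rec, "torso_recording"))
                   rec$subject_id else NA_character_,
                 repetition_id = if (inherits(rec, "torso_recording"))
                   rec$repetition_id else NA_character_,
                 pixel_mm = frame$pixel_mm),
            class = "torso_params")
}

#' @export
print.torso_params <- function(x, ...) {
  ok <- sum(!is.na(x$values))
  cat(sprintf("<torso_params> %d/%d parameters extracted", ok,
              length(x$values)))
  if (length(x$failures))
    cat(sprintf(", %d family failure(s): %s", length(x$failures),
                paste(names(x$failures), collapse = ", ")))
  cat("\n")
  invisible(x)
}

#' @export
as.data.frame.torso_params <- function(x, ...) {
  data.frame(parameter = names(x$values), value = unname(x$values),
             units = unname(x$units), stringsAsFactors = FALSE)
}

#' Analyse a phantom or recorded study
#'
#' Accepts either a directory laid out as `<study>/<subject>/<repetition>/`
#' (each leaf a recording directory for [read_recording()]) or a list of
#' entries with fields `subject_id`, `repetition_id` and `recording` (the
#' format produced by [generate_study()]). Every recording is analysed and
#' per-parameter subjects x repetitions matrices are assembled; subjects
#' with fewer than 2 usable repetitions are dropped with a warning.
#'
#' @param study directory path or list of measurement entries.
#' @param config a [torso_config()] list.
#' @param progress print a dot per recording.
#' @return A `reliability_table` data.frame (one row per parameter) with
#'   attribute `matrices` holding the underlying measurement matrices.
#' @export
analyze_study <- function(study, config = torso_config(),
                          progress = FALSE) {
  entries <- if (is.character(study)) {
    subjects <- list.dirs(study, recursive = FALSE)
    if (length(subjects) == 0L)
      stop("input error: no subject directories in ", study, call. = FALSE)
    do.call(c, lapply(subjects, function(sd) {
      reps <- list.dirs(sd, recursive = FALSE)
      lapply(reps, function(rd) {
        rec <- read_recording(rd)
        list(subject_id = basename(sd), repetition_id = basename(rd),
             recording = rec)
      })
    }))
  } else study
  results <- lapply(entries, function(e) {
    if (progress) cat(".")
    ps <- tryCatch(analyze_recording(e$recording, config),
                   error = function(err) err)
    list(subject = e$subject_id, rep = e$repetition_id, ps = ps)
  })
  if (progress) cat("\n")
  ok <- !vapply(results, function(r) inherits(r$ps, "error"), logical(1))
  if (!all(ok))
    warning(sprintf("%d recording(s) failed the pipeline and were dropped",
                    sum(!ok)))
  results <- results[ok]
  subj <- vapply(results, `[[`, character(1), "subject")
  tmpl <- param_template()
  tab <- do.call(rbind, lapply(names(tmpl), function(nm) {
    vals <- vapply(results, function(r) r$ps$values[[nm]], numeric(1))
    m <- build_measurement_matrix(vals, subj)
    if (is.null(m)) return(NULL)
    tryCatch(reliability_row(m, nm, tmpl[[nm]]),
             error = function(e) {
               # e.g. undefined ICC for a parameter constant over all cells;
               # report the row with NA statistics instead of aborting
               warning(nm, ": ", conditionMessage(e))
               gm <- mean(m, na.rm = TRUE)
               px <- identical(tmpl[[nm]], "px")
               data.frame(parameter = nm, units = tmpl[[nm]],
                          mean = gm,
                          mean_mm = if (px) gm * torso_defaults()$pixel_mm
                                    else NA_real_,
                          sd = NA_real_, sd_mm = NA_real_,
                          cv_percent = NA_real_, icc = NA_real_,
                          ci_low = NA_real_, ci_high = NA_real_,
                          icc_band = NA_character_,
                          cv_band = NA_character_,
                          sd_band = NA_character_,
                          stringsAsFactors = FALSE)
             })
  }))
  mats <- lapply(names(tmpl), function(nm) {
    vals <- vapply(results, function(r) r$ps$values[[nm]], numeric(1))
    build_measurement_matrix(vals, subj)
  })
  names(mats) <- names(tmpl)
  attr(tab, "matrices") <- mats
  class(tab) <- c("reliability_table", class(tab))
  tab
}

# reshape a flat vector of per-measurement values into subjects x reps
build_measurement_matrix <- function(vals, subj) {
  sp <- split(vals, subj)
  keep <- vapply(sp, function(v) sum(!is.na(v)) >= 2L, logical(1))
  if (!all(keep))
    warning(sprintf("dropping %d subject(s) with <2 usable repetitions",
                    sum(!keep)))
  sp <- sp[keep]
  if (length(sp) < 2L) return(NULL)
  k <- max(lengths(sp))
  m <- t(vapply(sp, function(v) c(v, rep(NA_real_, k - length(v))),
                numeric(k)))
  # keep only complete repetitions per subject (listwise inside icc)
  m
}

#' Write a reliability table
#'
#' CSV (paper-style column layout) or JSON.
#'
#' @param tab a `reliability_table`.
#' @param path output file; format chosen by extension (.csv or .json).
#' @return `path`, invisibly.
#' @export
write_reliability_table <- function(tab, path) {
  ext <- tolower(tools::file_ext(path))
  plain <- as.data.frame(tab)
  attr(plain, "matrices") <- NULL
  if (ext == "json") {
    jsonlite::write_json(plain, path, auto_unbox = TRUE, digits = NA,
                         na = "null")
  } else {
    write.table(plain, path, sep = ",", row.names = FALSE, qmethod = "double")
  }
  invisible(path)
}
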