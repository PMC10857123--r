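# Parametric phantom generator. Synthetic torso imprints are built from
# smooth anisotropic Gaussian structures on a torso-shaped support: thoracic
# bulk, a carved paraspinal canal, per-side scapula peaks, shoulder caps,
# waist concavities and sacral/gluteal maxima, followed by placement
# (rotation/translation), sensor noise and optional thin fold-artifact
# lines. Every recoverable quantity is returned as ground truth.

#' Phantom specification
#'
#' Defaults describe a realistic adult torso imprint on the 160 x 100 mat in
#' raw sensor units: a ~120-row torso (start near row 31 after bottom
#' anchoring), ~52 px wide, base plateau 8000 prv, thoracic and sacral
#' intensity maxima of roughly 11,000-13,000 prv so that row sums cross the
#' tv = 7000 detection threshold at the torso edge, and sensor noise of
#' sigma = 150 prv. All asymmetry knobs default to the symmetric value.
#'
#' @param ... overrides of the default fields (see the returned list).
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(...) {
  spec <- list(
    n_rows = 160L, n_cols = 100L,
    torso_length = 128,         # rows of support
    torso_halfwidth = 26,       # px
    base_amp = 8000,            # plateau, prv
    kyphosis_amp = 3500,        # thoracic bump, prv
    kyphosis_row = 20,          # rows below torso start
    kyphosis_sigma = 11,
    sacral_amp = 2500,          # central sacral bump, prv
    sacral_row_up = 28,         # rows above torso bottom
    sacral_sigma = 8,
    lumbar_dip = 800,           # lordosis lifts the lumbar spine: local
    lumbar_row_up = 70,         # reduction of the base plateau, prv
    lumbar_sigma = 16,          # cranial width of the dip
    lumbar_sigma_caudal = 26,   # slow caudal recovery: the lordosis gap
                                # stays low until the steep sacral rise
    canal_depth = 2500,         # prv
    canal_sigma = 3,            # px
    canal_dev = c(0, 0, 0),     # lateral deviation polynomial (px, px/row,
                                # px/row^2) in centred row units
    scapula_amp_l = 3200, scapula_amp_r = 3200,   # prv
    scapula_row = 19,           # rows below torso start
    scapula_offset = 18,        # px lateral of axis
    scapula_sigma = c(5, 4),    # (row, col) sigmas
    shoulder_amp_l = 2600, shoulder_amp_r = 2600, # cap height, prv
    shoulder_offset = 20,       # px lateral of axis
    shoulder_row_l = 0, shoulder_row_r = 0,  # cranial shift per side (rows)
    waist_depth_l = 0.22, waist_depth_r = 0.22,  # fractional inset
    waist_row_up = 69,          # rows above torso bottom
    waist_sigma = 13,
    gluteal_amp_l = 5000, gluteal_amp_r = 5000,  # prv; the gluteal blobs,
                                # not the central sacral bump, dominate the
                                # sacral maxima so pelvic asymmetries
                                # transfer to the segmented edges
    gluteal_offset = 13,        # px lateral of axis
    gluteal_row_up = 23,        # rows above torso bottom
    gluteal_row_l = 0, gluteal_row_r = 0,    # caudal shift per side (rows)
    gluteal_sigma = c(4, 11, 13),  # (row cranial, row caudal, col): the
                                 # imprint rises steeply at the top of the
                                 # buttocks and decays slowly caudally
    side_gain_r = 1,            # multiplicative gain of the right half
    rot_deg = 0, trans_px = 0, vtrans_px = 0,    # placement
    noise_sigma = 150,          # additive Gaussian, prv
    fold_prob = 0,              # per-frame probability of a fold line
    bottom_row = 154            # canonical support bottom before anchoring
  )
  dots <- list(...)
  if (length(dots) == 1L && is.list(dots[[1]]) && is.null(names(dots)))
    dots <- dots[[1]]
  for (nm in names(dots)) {
    if (!nm %in% names(spec))
      stop("unknown phantom_spec field: ", nm, call. = FALSE)
    spec[[nm]] <- dots[[nm]]
  }
  if (abs(spec$rot_deg) > 15)
    stop("spec error: |rot_deg| must be <= 15 (alignment search range)",
         call. = FALSE)
  if (abs(spec$trans_px) > 15)
    warning("|trans_px| > 15 exceeds the recoverable centring range")
  if (spec$bottom_row - spec$torso_length < 5 ||
      spec$bottom_row > spec$n_rows)
    stop("spec error: torso placed outside the sensor grid", call. = FALSE)
  structure(spec, class = "phantom_spec")
}

# Clean (noise-free, unplaced) phantom image in the canonical frame:
# symmetry axis at (n_cols + 1)/2, support bottom at spec$bottom_row.
phantom_clean_image <- function(spec) {
  nr <- spec$n_rows; nc <- spec$n_cols
  axis <- symmetry_axis(nc)
  top <- spec$bottom_row - spec$torso_length + 1
  j <- matrix(seq_len(nr), nr, nc)
  i <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  # smooth row envelope of the support; a raised shoulder lifts the cranial
  # edge locally around that side's shoulder position
  ramp <- function(t) pmin(1, pmax(0, t))
  top_i <- top -
    spec$shoulder_row_l * stats::plogis((axis - i) / 4) -
    spec$shoulder_row_r * stats::plogis((i - axis) / 4)
  env <- ramp((j - top_i + 2) / 4) * ramp((spec$bottom_row + 1 - j) / 2)
  # per-side half-width with waist inset
  jw <- spec$bottom_row - spec$waist_row_up
  u <- (j - top) / spec$torso_length
  base_w <- 1 - 0.22 * pmax(0, 1 - (u / 0.10)^2)        # shoulder taper
  inset <- exp(-((j - jw) / spec$waist_sigma)^2)
  wl <- spec$torso_halfwidth * base_w * (1 - spec$waist_depth_l * inset)
  wr <- spec$torso_halfwidth * base_w * (1 - spec$waist_depth_r * inset)
  d <- i - axis
  w <- ifelse(d < 0, wl, wr)
  lateral <- exp(-(abs(d) / w)^16)
  g2 <- function(jc, ic, sj, si)
    exp(-((j - jc)^2) / (2 * sj^2) - ((i - ic)^2) / (2 * si^2))
  jk <- top + spec$kyphosis_row
  js <- spec$bottom_row - spec$sacral_row_up
  jlu <- spec$bottom_row - spec$lumbar_row_up
  lsig <- ifelse(j < jlu, spec$lumbar_sigma, spec$lumbar_sigma_caudal)
  # pelvic obliquity shifts a side's entire sacral complex: the central
  # sacral bump is side-resolved and shares the per-side gluteal row offsets
  js_side <- js + ifelse(d < 0, spec$gluteal_row_l, spec$gluteal_row_r)
  ridge <- spec$base_amp +
    spec$kyphosis_amp * exp(-((j - jk)^2) / (2 * spec$kyphosis_sigma^2)) +
    spec$sacral_amp * exp(-((j - js_side)^2) / (2 * spec$sacral_sigma^2)) -
    spec$lumbar_dip * exp(-((j - jlu)^2) / (2 * lsig^2))
  img <- env * ridge * lateral
  # scapula peaks (on the lightly filtered image these stay sharp)
  jsb <- top + spec$scapula_row
  img <- img + env * lateral *
    (spec$scapula_amp_l * g2(jsb, axis - spec$scapula_offset,
                             spec$scapula_sigma[1], spec$scapula_sigma[2]) +
     spec$scapula_amp_r * g2(jsb, axis + spec$scapula_offset,
                             spec$scapula_sigma[1], spec$scapula_sigma[2]))
  # shoulder caps at the cranial edge, per-side row shift
  jsh_l <- top + 5 - spec$shoulder_row_l
  jsh_r <- top + 5 - spec$shoulder_row_r
  img <- img + lateral *
    (spec$shoulder_amp_l * g2(jsh_l, axis - spec$shoulder_offset, 4, 6) +
     spec$shoulder_amp_r * g2(jsh_r, axis + spec$shoulder_offset, 4, 6))
  # gluteal maxima, per-side caudal shift
  jg_l <- spec$bottom_row - spec$gluteal_row_up + spec$gluteal_row_l
  jg_r <- spec$bottom_row - spec$gluteal_row_up + spec$gluteal_row_r
  gsig_l <- ifelse(j < jg_l, spec$gluteal_sigma[1], spec$gluteal_sigma[2])
  gsig_r <- ifelse(j < jg_r, spec$gluteal_sigma[1], spec$gluteal_sigma[2])
  # per-side row bump confined to its half so pelvic asymmetries stay
  # side-resolved; a mild lateral dome peaks over the gluteal muscle
  dome <- exp(-((abs(d) - spec$gluteal_offset)^2) /
                (2 * spec$gluteal_sigma[3]^2))
  gl_row <- spec$gluteal_amp_l * exp(-((j - jg_l)^2) / (2 * gsig_l^2))
  gr_row <- spec$gluteal_amp_r * exp(-((j - jg_r)^2) / (2 * gsig_r^2))
  img <- img + env * lateral * dome * ifelse(d < 0, gl_row, gr_row)
  # carved paraspinal canal following the lateral deviation polynomial
  jc <- j - (top + spec$torso_length / 2)
  dev <- spec$canal_dev[1] + spec$canal_dev[2] * jc +
    spec$canal_dev[3] * jc^2
  canal_win <- ramp((j - (top + 6)) / 6) *
    ramp(((spec$bottom_row - 24) - j) / 6)
  img <- img - spec$canal_depth * canal_win * env *
    exp(-((d - dev)^2) / (2 * spec$canal_sigma^2))
  img <- pmax(img, 0)
  # one-sided gain (rib-hump style intensity asymmetry)
  if (spec$side_gain_r != 1) {
    right <- i > axis
    img[right] <- img[right] * spec$side_gain_r
  }
  img
}

# Ground truth landmarks from the clean canonical image: the noise-free,
# unplaced imprint is filtered like the pipeline's smooth variant and
# bottom-anchored by the same row-sum rule, so the truth is what an ideal
# measurement (no noise, no placement) would yield, independent of the
# alignment, masking and detection code paths.
phantom_ground_truth <- function(spec, clean) {
  tv <- torso_defaults()$tv
  smooth <- gaussian_filter(median_filter(clean, 15, 5), 3, 3)
  rs <- rowSums(smooth)
  shift <- spec$n_rows - max(which(rs > tv))
  anch <- translate_rows(smooth, shift)
  z <- mean_intensity_curve(anch)
  jts <- min(which(rowSums(anch) > tv))
  top0 <- spec$bottom_row - spec$torso_length + 1      # canonical frame
  top <- top0 + shift                                  # anchored frame
  near <- function(j0, w = 15) max(jts, j0 - w):min(spec$n_rows, j0 + w)
  jk <- top + spec$kyphosis_row
  jsac <- spec$bottom_row - spec$sacral_row_up + shift
  jtmax <- near(jk)[which.max(z[near(jk)])]
  jsmax <- near(jsac)[which.max(z[near(jsac)])]
  jlmin <- (jtmax:jsmax)[which.min(z[jtmax:jsmax])]
  bd <- tryCatch(region_boundaries(z, jts, jtmax, jlmin),
                 error = function(e) NULL)
  axis <- symmetry_axis(spec$n_cols)
  # expected scapula window maxima through the nominal observation model of
  # the light image (5 x 1 median), noise-free
  light <- median_filter(clean, 5, 1)
  jsb0 <- top0 + spec$scapula_row
  win <- function(ic) {
    jr <- max(1, jsb0 - 5):min(spec$n_rows, jsb0 + 5)
    irng <- max(1, round(ic) - 5):min(spec$n_cols, round(ic) + 5)
    max(light[jr, irng])
  }
  vl <- win(axis - spec$scapula_offset)
  vr <- win(axis + spec$scapula_offset)
  list(shift = shift, jts = jts, jtmax = jtmax, jlmin = jlmin,
       jsmax = jsmax,
       jt = bd$jt, jtl = bd$jtl, jl = bd$jl, vz = bd$vz,
       scapula_l = c(row = top + spec$scapula_row,
                     col = axis - spec$scapula_offset),
       scapula_r = c(row = top + spec$scapula_row,
                     col = axis + spec$scapula_offset),
       sb4_expected = max(vl / vr, vr / vl),
       shoulder_offset_rows = spec$shoulder_row_l - spec$shoulder_row_r,
       p2_expected = 2 * abs(spec$gluteal_row_l - spec$gluteal_row_r),
       side_gain_r = spec$side_gain_r,
       canal_dev = spec$canal_dev,
       rot_deg = spec$rot_deg, trans_px = spec$trans_px,
       vtrans_px = spec$vtrans_px)
}

#' Generate a phantom frame
#'
#' Builds the clean canonical imprint, derives the ground truth, applies
#' placement (rotation about the image centre, then column/row translation),
#' then adds sensor noise and optional fold lines. Bit-reproducible for a
#' given seed.
#'
#' @param spec a [phantom_spec()].
#' @param seed integer seed (NULL = use current RNG state).
#' @return List with `frame` (a [pressure_frame()]) and `truth`.
#' @export
generate_phantom <- function(spec = phantom_spec(), seed = NULL) {
  if (!inherits(spec, "phantom_spec")) spec <- phantom_spec(spec)
  if (!is.null(seed)) set.seed(seed)
  clean <- phantom_clean_image(spec)
  truth <- phantom_ground_truth(spec, clean)
  img <- clean
  if (spec$rot_deg != 0) img <- rotate_image(img, spec$rot_deg)
  if (spec$trans_px != 0) img <- translate_cols(img, spec$trans_px)
  if (spec$vtrans_px != 0) img <- translate_rows(img, spec$vtrans_px)
  if (spec$noise_sigma > 0)
    img <- img + matrix(stats::rnorm(length(img), 0, spec$noise_sigma),
                        nrow(img), ncol(img))
  if (spec$fold_prob > 0 && stats::runif(1) < spec$fold_prob) {
    # thin high-intensity line, what the 15 x 5 median is meant to remove
    if (stats::runif(1) < 0.5) {
      r <- sample.int(nrow(img), 1)
      img[r, ] <- img[r, ] + 1.5 * max(clean)
    } else {
      cc <- sample.int(ncol(img), 1)
      img[, cc] <- img[, cc] + 1.5 * max(clean)
    }
  }
  img <- pmax(img, 0)
  list(frame = pressure_frame(img), truth = truth, spec = spec)
}

#' Generate a phantom recording
#'
#' Repeats one phantom placement over `n_frames` frames with a small global
#' intensity modulation emulating breathing, plus fresh sensor noise per
#' frame.
#'
#' @param spec a [phantom_spec()].
#' @param n_frames frames in the recording.
#' @param seed integer seed.
#' @param subject_id,repetition_id labels.
#' @return List with `recording` and `truth`.
#' @export
generate_phantom_recording <- function(spec = phantom_spec(), n_frames = 3L,
                                       seed = NULL,
                                       subject_id = NA_character_,
                                       repetition_id = NA_character_) {
  if (!inherits(spec, "phantom_spec")) spec <- phantom_spec(spec)
  if (!is.null(seed)) set.seed(seed)
  clean <- phantom_clean_image(spec)
  truth <- phantom_ground_truth(spec, clean)
  placed <- clean
  if (spec$rot_deg != 0) placed <- rotate_image(placed, spec$rot_deg)
  if (spec$trans_px != 0) placed <- translate_cols(placed, spec$trans_px)
  if (spec$vtrans_px != 0) placed <- translate_rows(placed, spec$vtrans_px)
  breath <- 0.01 * sin(2 * pi * seq_len(n_frames) / max(n_frames, 2))
  frames <- lapply(seq_len(n_frames), function(f) {
    img <- placed * (1 + breath[f])
    if (spec$noise_sigma > 0)
      img <- img + matrix(stats::rnorm(length(img), 0, spec$noise_sigma),
                          nrow(img), ncol(img))
    pressure_frame(pmax(img, 0))
  })
  list(recording = recording(frames, subject_id = subject_id,
                             repetition_id = repetition_id),
       truth = truth, spec = spec)
}

#' Study specification
#'
#' Describes a repeated-measurement phantom study: `n_subjects` subjects
#' measured `k_repetitions` times each. Between-subject variation draws the
#' anatomy knobs from population distributions; within-subject variation
#' redraws the placement (the protocol's repositioning) and jitters the
#' amplitude knobs by ~2%.
#'
#' @param n_subjects,k_repetitions study size (defaults 40 x 10, the
#'   reliability-study protocol).
#' @param frames_per_recording frames generated per measurement.
#' @param symmetric_population if TRUE (default) all asymmetry knobs stay at
#'   their symmetric values, emulating a cohort without postural deformity.
#' @param noise_sigma sensor noise (prv).
#' @param reposition if FALSE, repetitions repeat the identical placement
#'   and knobs (zero within-subject variance apart from `noise_sigma`).
#' @return A `study_spec` list.
#' @export
study_spec <- function(n_subjects = 40L, k_repetitions = 10L,
                       frames_per_recording = 3L,
                       symmetric_population = TRUE, noise_sigma = 150,
                       reposition = TRUE) {
  stopifnot(n_subjects >= 2L, k_repetitions >= 2L)
  structure(list(n_subjects = n_subjects, k_repetitions = k_repetitions,
                 frames_per_recording = frames_per_recording,
                 symmetric_population = symmetric_population,
                 noise_sigma = noise_sigma, reposition = reposition),
            class = "study_spec")
}

rtrunc_int <- function(n, sd, lim) {
  v <- round(stats::rnorm(n, 0, sd))
  pmin(pmax(v, -lim), lim)
}

#' Generate a phantom study
#'
#' Draws one anatomy per subject, then `k` repeated measurements with fresh
#' placement and noise. Returns the recordings with per-measurement ground
#' truth.
#'
#' @param study a [study_spec()].
#' @param seed integer seed for the whole study.
#' @return List of measurement entries (`subject_id`, `repetition_id`,
#'   `recording`, `truth`, `spec`).
#' @export
generate_study <- function(study = study_spec(), seed = 1L) {
  set.seed(seed)
  out <- vector("list", study$n_subjects * study$k_repetitions)
  idx <- 1L
  for (s in seq_len(study$n_subjects)) {
    # population distributions centred on the calibrated default anatomy
    anat <- list(
      torso_length = round(stats::rnorm(1, 128, 7)),
      torso_halfwidth = stats::rnorm(1, 26, 1.8),
      base_amp = stats::rnorm(1, 8000, 500),
      kyphosis_amp = max(1500, stats::rnorm(1, 3500, 700)),
      kyphosis_row = round(stats::rnorm(1, 20, 2)),
      sacral_amp = max(1200, stats::rnorm(1, 2500, 400)),
      canal_depth = max(1200, stats::rnorm(1, 2500, 400)),
      scapula_amp_l = max(1500, stats::rnorm(1, 3200, 500)),
      waist_depth_l = min(0.32, max(0.12, stats::rnorm(1, 0.22, 0.035))),
      gluteal_amp_l = max(2500, stats::rnorm(1, 5000, 600)),
      noise_sigma = study$noise_sigma)
    anat$scapula_amp_r <- anat$scapula_amp_l
    anat$waist_depth_r <- anat$waist_depth_l
    anat$gluteal_amp_r <- anat$gluteal_amp_l
    if (!study$symmetric_population) {
      anat$side_gain_r <- exp(stats::rnorm(1, 0, 0.05))
      anat$shoulder_row_l <- rtrunc_int(1, 1, 3)
      anat$gluteal_row_r <- rtrunc_int(1, 1, 3)
      anat$canal_dev <- c(stats::rnorm(1, 0, 1), 0, 0)
    }
    for (r in seq_len(study$k_repetitions)) {
      rep_spec <- anat
      if (isTRUE(study$reposition)) {
        # repositioning: fresh placement and ~2% knob jitter
        rep_spec$rot_deg <- rtrunc_int(1, 3, 10)
        rep_spec$trans_px <- rtrunc_int(1, 4, 12)
        rep_spec$vtrans_px <- rtrunc_int(1, 2, 5)
        for (nm in c("base_amp", "kyphosis_amp", "sacral_amp",
                     "scapula_amp_l", "scapula_amp_r",
                     "gluteal_amp_l", "gluteal_amp_r"))
          rep_spec[[nm]] <- rep_spec[[nm]] * exp(stats::rnorm(1, 0, 0.02))
      }
      g <- generate_phantom_recording(
        phantom_spec(rep_spec), n_frames = study$frames_per_recording,
        subject_id = sprintf("S%02d", s),
        repetition_id = sprintf("R%02d", r))
      out[[idx]] <- list(subject_id = sprintf("S%02d", s),
                         repetition_id = sprintf("R%02d", r),
                         recording = g$recording, truth = g$truth,
                         spec = g$spec)
      idx <- idx + 1L
    }
  }
  out
}
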