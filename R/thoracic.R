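# Thoracic-region structures: shoulder contour, scapulae and generalised
# torso symmetry. Ratio parameters are "max ratios" max(a/b, b/a) of a
# left/right pair: >= 1 by construction and exactly 1 under perfect mirror
# symmetry.

max_ratio <- function(a, b) max(a / b, b / a)

#' Shoulder contour parameters S0/S1/S2
#'
#' The shoulder regions are the left and right thirds of the upper third of
#' the segment AS (rows `[jts, jsmax]`, columns `[il - 10, ir + 10]`). Each
#' region is adaptively segmented at its own mean intensity; per column the
#' first supra-threshold row forms the shoulder contour, whose minimum row is
#' the upper shoulder edge `js`. Linear regressions of the contour (ordered
#' lateral to medial so both sides slope comparably) give the slope
#' coefficients; S1 is the magnitude of the edge shift, S2 the max ratio of
#' the absolute slopes.
#'
#' @param roi a `roi_image`.
#' @param lm a `landmark_set`.
#' @return List with `S0_l`, `S0_r`, `S1`, `S1_signed`, `S2`, `S2_l`, `S2_r`,
#'   `ms_l`, `ms_r`.
#' @export
shoulder_params <- function(roi, lm) {
  x <- roi_values(roi)
  nr <- nrow(x); nc <- ncol(x)
  rows <- lm$jts:lm$jsmax
  cols <- max(1L, as.integer(round(lm$il)) - 10L):
    min(nc, as.integer(round(lm$ir)) + 10L)
  up_rows <- rows[seq_len(max(2L, floor(length(rows) / 3)))]
  third <- max(2L, floor(length(cols) / 3))
  side <- function(side_cols, lateral_first) {
    reg <- x[up_rows, side_cols, drop = FALSE]
    thr <- mean(reg)
    contour_rows <- c(); contour_cols <- c()
    for (k in seq_along(side_cols)) {
      hit <- which(reg[, k] > thr)
      if (length(hit)) {
        contour_rows <- c(contour_rows, up_rows[hit[1]])
        contour_cols <- c(contour_cols, side_cols[k])
      }
    }
    if (length(contour_rows) < 2L)
      stop("detection error: empty shoulder region", call. = FALSE)
    # order lateral -> medial so left and right slopes are comparable
    ord <- if (lateral_first) order(contour_cols)
           else order(-contour_cols)
    rr <- contour_rows[ord]
    u <- seq_along(rr)
    list(js = min(contour_rows), ms = reg_slope(u, rr),
         rows = contour_rows, cols = contour_cols)
  }
  left <- side(cols[seq_len(third)], lateral_first = TRUE)
  right <- side(cols[(length(cols) - third + 1L):length(cols)],
                lateral_first = FALSE)
  S1s <- left$js - right$js
  S2l <- abs(left$ms); S2r <- abs(right$ms)
  list(S0_l = left$js, S0_r = right$js,
       S1 = abs(S1s), S1_signed = S1s,
       S2 = max_ratio(S2l, S2r), S2_l = S2l, S2_r = S2r,
       ms_l = left$ms, ms_r = right$ms,
       contour_l = left[c("rows", "cols")],
       contour_r = right[c("rows", "cols")])
}

# local maxima of a matrix (8-neighbourhood, plateaus count at their first
# scan position), returned as (row, col, value) ordered by decreasing value
local_maxima <- function(x) {
  nr <- nrow(x); nc <- ncol(x)
  res <- NULL
  for (j in 2:(nr - 1)) for (i in 2:(nc - 1)) {
    v <- x[j, i]
    if (v <= 0) next
    nb <- x[(j - 1):(j + 1), (i - 1):(i + 1)]
    if (v >= max(nb)) res <- rbind(res, c(j, i, v))
  }
  if (is.null(res)) return(res)
  res[order(-res[, 3], res[, 1], res[, 2]), , drop = FALSE]
}

#' Locate the scapula centres
#'
#' The scapulae accentuate maxima in the upper thoracic region of the
#' lightly filtered image Is. Search intervals per side are rows `[jt, jtl]`
#' and the lateral column bands excluding the central quarter torso width;
#' each band is presegmented at the pixel threshold `tv`, smoothed with a
#' 3 x 3 Gaussian (sigma = 2), and the two highest local maxima are scored
#' by a composite rule (more lateral rank + higher intensity rank, lateral
#' wins ties) to select the centre.
#'
#' @param Is aligned lightly filtered image.
#' @param lm a `landmark_set`.
#' @param config a [torso_config()] list.
#' @return List with `jsb_l`, `isb_l`, `jsb_r`, `isb_r`, and the raw
#'   candidate tables per side.
#' @export
locate_scapulae <- function(Is, lm, config = torso_config()) {
  x <- if (inherits(Is, "pressure_frame")) Is$values else Is
  nc <- ncol(x)
  axis <- lm$isym
  quarter <- (lm$ir - lm$il) / 4
  rows <- lm$jt:lm$jtl
  side <- function(cols, is_left) {
    band <- x[rows, cols, drop = FALSE]
    band[band < config$tv] <- 0
    band <- gaussian_filter(band, 3, 2)
    mx <- local_maxima(band)
    if (is.null(mx) || nrow(mx) == 0L)
      stop("detection error: no scapula maximum on one side", call. = FALSE)
    mx <- mx[seq_len(min(2L, nrow(mx))), , drop = FALSE]
    jj <- rows[mx[, 1]]
    ii <- cols[mx[, 2]]
    lat <- abs(ii - axis)
    # composite: lateral rank + intensity rank; lateral offset wins ties
    score <- rank(lat, ties.method = "min") +
      rank(mx[, 3], ties.method = "min")
    best <- order(-score, -lat, -mx[, 3])[1]
    list(j = jj[best], i = ii[best],
         candidates = cbind(row = jj, col = ii, value = mx[, 3]))
  }
  lcols <- 1:max(2L, as.integer(floor(axis - quarter)))
  rcols <- min(nc - 1L, as.integer(ceiling(axis + quarter))):nc
  left <- side(lcols, TRUE)
  right <- side(rcols, FALSE)
  list(jsb_l = left$j, isb_l = left$i, jsb_r = right$j, isb_r = right$i,
       cand_l = left$candidates, cand_r = right$candidates)
}

scapula_window <- function(x, j, i, half = 5L) {
  nr <- nrow(x); nc <- ncol(x)
  jr <- max(1L, j - half):min(nr, j + half)
  ir <- max(1L, i - half):min(nc, i + half)
  if (length(jr) < 2L * half + 1L || length(ir) < 2L * half + 1L)
    warning("scapula window clipped at the image border")
  x[jr, ir, drop = FALSE]
}

#' Scapula symmetry parameters SB0-SB5
#'
#' Symmetric 11 x 11 segments centred on the located scapula centres within
#' Is quantify positional (SB1 vertical shift, SB2 lateral-offset difference,
#' SB3 centre-to-centre angle in degrees) and intensity asymmetry (SB4 max
#' ratio of window maxima, SB5 max ratio of window means). Side values carry
#' the raw window maxima/means.
#'
#' @param Is aligned lightly filtered image.
#' @param centres result of [locate_scapulae()].
#' @param lm a `landmark_set`.
#' @return Named list SB0_* and SB1..SB5 with side values.
#' @export
scapula_params <- function(Is, centres, lm) {
  x <- if (inherits(Is, "pressure_frame")) Is$values else Is
  wl <- scapula_window(x, centres$jsb_l, centres$isb_l)
  wr <- scapula_window(x, centres$jsb_r, centres$isb_r)
  if (max(wl) == 0 || max(wr) == 0)
    stop("undefined ratio: zero scapula window intensity", call. = FALSE)
  axis <- lm$isym
  SB1s <- centres$jsb_l - centres$jsb_r
  SB2s <- abs(centres$isb_r - axis) - abs(axis - centres$isb_l)
  ang <- atan((centres$jsb_r - centres$jsb_l) /
              (centres$isb_r - centres$isb_l)) * 180 / pi
  list(SB0_vl = centres$jsb_l, SB0_hl = centres$isb_l - axis,
       SB0_vr = centres$jsb_r, SB0_hr = centres$isb_r - axis,
       SB1 = abs(SB1s), SB1_signed = SB1s,
       SB2 = abs(SB2s), SB2_signed = SB2s,
       SB3 = abs(ang), SB3_signed = ang,
       SB4 = max_ratio(max(wl), max(wr)),
       SB4_l = max(wl), SB4_r = max(wr),
       SB5 = max_ratio(mean(wl), mean(wr)),
       SB5_l = mean(wl), SB5_r = mean(wr))
}

#' Torso symmetry parameters TS1-TS5
#'
#' Longitudinal symmetry of the pressure distribution: TS1 sums the
#' deviation of the centre-of-pressure curve Lcop(j) from the symmetry axis
#' over the torso rows; TS2/TS3 are max ratios of means/maxima over the
#' combined thoracolumbar side segments (rows from each side's scapula row
#' + 10 down to jl, half torso width wide); TS4 the max ratio of the summed
#' intensities over the thoracic side segments (rows `[jts, jlmin]`, +/- 10
#' columns beyond the reference positions); TS5 the mean percentage
#' difference between the mean-thresholded imprint and its mirror over
#' pixels of `[jts, jlmin]` where both are positive, in percent.
#'
#' @param roi a `roi_image`.
#' @param lm a `landmark_set`.
#' @param centres result of [locate_scapulae()].
#' @return Named list TS1..TS5 with side values and `TS1_signed`.
#' @export
torso_symmetry_params <- function(roi, lm, centres) {
  x <- roi_values(roi)
  nr <- nrow(x); nc <- ncol(x)
  axis <- lm$isym
  ihalf_l <- floor(axis)      # last left column (50)
  ihalf_r <- ceiling(axis)    # first right column (51)
  il10 <- max(1L, as.integer(round(lm$il)) - 10L)
  ir10 <- min(nc, as.integer(round(lm$ir)) + 10L)
  # centre of pressure curve over the torso width
  wcols <- as.integer(round(lm$il)):as.integer(round(lm$ir))
  cop_rows <- lm$jts:lm$jl
  Lcop <- vapply(cop_rows, function(j) {
    w <- x[j, wcols]
    if (sum(w) == 0) return(NA_real_)
    sum(w * wcols) / sum(w)
  }, numeric(1))
  dev <- Lcop - axis
  TS1s <- sum(dev, na.rm = TRUE)
  TS1 <- sum(abs(dev), na.rm = TRUE)
  # thoracic side segments (support pixels only)
  trows <- lm$jts:lm$jlmin
  seg <- function(rows, cols) {
    v <- x[rows, cols, drop = FALSE]
    v[v > 0]
  }
  t_l <- seg(trows, il10:ihalf_l)
  t_r <- seg(trows, ihalf_r:ir10)
  # combined thoracolumbar side segments, caudal of each scapula
  halfw <- (lm$ir - lm$il) / 2
  tl_l_rows <- min(nr, centres$jsb_l + 10L):lm$jl
  tl_r_rows <- min(nr, centres$jsb_r + 10L):lm$jl
  tl_l <- seg(tl_l_rows, max(1L, as.integer(ceiling(axis - halfw))):ihalf_l)
  tl_r <- seg(tl_r_rows, ihalf_r:min(nc, as.integer(floor(axis + halfw))))
  if (!length(t_l) || !length(t_r) || !length(tl_l) || !length(tl_r))
    stop("detection error: empty torso-symmetry segment", call. = FALSE)
  # mirror comparison of the mean-thresholded imprint
  thr <- mean(x[x > 0])
  xstar <- x; xstar[xstar <= thr] <- 0
  xmir <- mirror_image(xstar)
  sel <- matrix(FALSE, nr, nc)
  sel[trows, ] <- TRUE
  both <- sel & xstar > 0 & xmir > 0
  TS5 <- if (any(both)) {
    mean(abs(1 - xstar[both] / xmir[both])) * 100
  } else NA_real_
  if (is.na(TS5))
    warning("TS5 undefined: empty overlap between imprint and mirror")
  list(TS1 = TS1, TS1_signed = TS1s, Lcop = Lcop, cop_rows = cop_rows,
       TS2 = max_ratio(mean(tl_l), mean(tl_r)),
       TS2_l = mean(tl_l), TS2_r = mean(tl_r),
       TS3 = max_ratio(max(tl_l), max(tl_r)),
       TS3_l = max(tl_l), TS3_r = max(tl_r),
       TS4 = max_ratio(sum(t_l), sum(t_r)),
       TS4_l = sum(t_l), TS4_r = sum(t_r),
       TS5 = TS5)
}
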