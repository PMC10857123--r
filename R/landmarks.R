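# Longitudinal landmark detection. The torso imprint is subdivided cranial
# to caudal into thoracic, lumbar and sacral regions using the mean
# intensity curve z(j) of a 31-column central band: its extrema give the
# thoracic maximum, lumbar minimum and sacral maximum, and crossings with
# the reference value vz give the region boundaries.

#' Detect the torso start row
#'
#' Smallest row whose ROI row sum exceeds the threshold `tv` (default 7000
#' raw units, the empirically determined maximum noise amplitude).
#'
#' @param roi a `roi_image` from [fit_roi()] (or a matrix).
#' @param tv row-sum threshold in raw units.
#' @return Row index `jts`.
#' @export
detect_torso_start <- function(roi, tv = torso_defaults()$tv) {
  x <- roi_values(roi)
  rs <- rowSums(x)
  j <- which(rs > tv)
  if (length(j) == 0L)
    stop("detection error: torso not found (no row sum exceeds tv)",
         call. = FALSE)
  min(j)
}

roi_values <- function(roi) {
  if (inherits(roi, "roi_image")) roi$Iroi$values
  else if (inherits(roi, "pressure_frame")) roi$values
  else roi
}

#' Mean intensity curve of the central band
#'
#' Per-row mean of the `delta_iz + 1` columns centred on the symmetry axis,
#' computed on the aligned smooth image I (not the masked ROI).
#'
#' @param I aligned image ([pressure_frame()] or matrix).
#' @param delta_iz even band width in px (31 columns for the default 30).
#' @return Numeric vector z of length `n_rows`.
#' @export
mean_intensity_curve <- function(I, delta_iz = torso_defaults()$delta_iz) {
  x <- if (inherits(I, "pressure_frame")) I$values else I
  stopifnot(delta_iz %% 2 == 0)
  nc <- ncol(x)
  centre <- floor(symmetry_axis(nc))   # 50 for 100 columns
  cols <- (centre - delta_iz / 2):(centre + delta_iz / 2)
  cols <- cols[cols >= 1 & cols <= nc]
  rowMeans(x[, cols, drop = FALSE])
}

#' Detect the profile extrema of z(j)
#'
#' Locates the thoracic maximum, lumbar minimum and sacral maximum by
#' extreme value analysis of z on rows `[jts, n_rows]`: the global maximum
#' splits the torso; the interior minimum between it and the opposite lobe's
#' maximum is the lumbar minimum. Ties break towards smaller j (cranial).
#'
#' @param z mean intensity curve.
#' @param jts torso start row.
#' @return List with `jtmax`, `jlmin`, `jsmax`.
#' @export
detect_profile_extrema <- function(z, jts) {
  n <- length(z)
  dom <- jts:n
  # local maxima of the lightly smoothed curve (plateaus count once, at
  # their cranial end -> ties break towards smaller j)
  zs <- moving_average(z, 2L)
  cand <- dom[-c(1L, length(dom))]
  is_max <- vapply(cand, function(j) {
    zs[j] >= zs[j - 1] && zs[j] >= zs[j + 1] &&
      (zs[j] > zs[j - 1] || zs[j] > zs[j + 1])
  }, logical(1))
  peaks <- cand[is_max]
  # refine each candidate to the raw-curve maximum nearby (the smoothing is
  # only for robust peak identification, not localisation)
  peaks <- unique(vapply(peaks, function(p) {
    w <- max(min(dom), p - 3L):min(max(dom), p + 3L)
    w[which.max(z[w])]
  }, numeric(1)))
  pick <- NULL
  if (length(peaks) >= 2L) {
    m1 <- peaks[which.max(z[peaks])]
    # partner: the highest remaining peak separated from m1 by a genuine
    # trough (below both peaks); edge minima of the torso boundary never
    # qualify because the trough must lie strictly between paired peaks
    others <- peaks[order(-z[peaks])]
    others <- setdiff(others, m1)
    for (p2 in others) {
      span <- min(m1, p2):max(m1, p2)
      mid <- span[which.min(z[span])]
      if (mid > min(span) && mid < max(span) &&
          z[mid] < min(z[m1], z[p2])) {
        pick <- if (m1 < p2) list(jtmax = m1, jlmin = mid, jsmax = p2)
                else list(jtmax = p2, jlmin = mid, jsmax = m1)
        break
      }
    }
  }
  if (is.null(pick))
    stop("detection error: no interior lumbar minimum in z(j) ",
         "(profile monotone or single-lobed)", call. = FALSE)
  pick
}

#' Region boundaries from crossings with the reference value
#'
#' The reference value vz is the mean of z over `[jts, jlmin]`. The thoracic
#' region start `jt` is the first up-crossing of vz at or after `jts`; the
#' thoracolumbar transition `jtl` the first down-crossing after the thoracic
#' maximum; the lumbar region end `jl` the first up-crossing after the
#' lumbar minimum. Crossings are localised at the first row on the far side
#' of the crossing point.
#'
#' @param z mean intensity curve.
#' @param jts,jtmax,jlmin landmark rows.
#' @return List with `vz`, `jt`, `jtl`, `jl`.
#' @export
region_boundaries <- function(z, jts, jtmax, jlmin) {
  vz <- mean(z[jts:jlmin])
  # crossings are strict transitions; the first row on the far side is
  # reported. A curve that merely touches vz (e.g. constant) has none.
  cross <- function(lo, hi, up, what) {
    if (up && z[lo] > vz) return(lo)
    if (!up && z[lo] < vz) return(lo)
    for (j in (lo + 1L):hi) {
      if (up && z[j - 1] < vz && z[j] >= vz) return(j)
      if (!up && z[j - 1] > vz && z[j] <= vz) return(j)
    }
    stop("detection error: missing boundary ", what,
         " (no crossing of vz)", call. = FALSE)
  }
  jt <- cross(jts, jtmax, TRUE, "jt")
  jtl <- cross(jtmax, jlmin, FALSE, "jtl")
  jl <- cross(jlmin, length(z), TRUE, "jl")
  if (!(jts <= jt && jt < jtmax && jtmax < jtl && jtl < jlmin && jlmin < jl))
    stop("detection error: landmark ordering violated", call. = FALSE)
  list(vz = vz, jt = jt, jtl = jtl, jl = jl)
}

# Extract left/right mask contour columns per row.
mask_contours <- function(mask) {
  rows <- which(rowSums(mask) > 0)
  xl <- vapply(rows, function(j) min(which(mask[j, ] > 0)), numeric(1))
  xr <- vapply(rows, function(j) max(which(mask[j, ] > 0)), numeric(1))
  list(rows = rows, left = xl, right = xr)
}

moving_average <- function(x, w) {
  # centred moving average with shrinking window at the ends
  n <- length(x)
  vapply(seq_len(n), function(k) {
    lo <- max(1, k - w); hi <- min(n, k + w)
    mean(x[lo:hi])
  }, numeric(1))
}

#' Lateral reference positions from the ROI contour
#'
#' On each side the ROI contour is traced as a column-per-row polyline; the
#' reference position (`il`, `ir`) is the column of the contour point with
#' maximum concave curvature (curving towards the torso interior), measured
#' by the three-point second difference over a +/-`window`-row arc after
#' light smoothing. A contour with no concave excursion (e.g. a rectangle)
#' raises a detection error.
#'
#' @param roi a `roi_image`.
#' @param window half-window in rows for the discrete curvature.
#' @return List with `il`, `ir` and the apex rows `jl_apex`, `jr_apex`.
#' @export
reference_positions <- function(roi,
                                window = torso_defaults()$curvature_window) {
  stopifnot(inherits(roi, "roi_image"))
  # trace the boundary of the imprint itself (non-zero ROI pixels), not of
  # the template mask, whose fixed shape would dominate the curvature
  support <- (roi$Iroi$values > 0) * 1
  ct <- mask_contours(support)
  n <- length(ct$rows)
  if (n < 2 * window + 1)
    stop("detection error: contour shorter than curvature window",
         call. = FALSE)
  curv_pick <- function(xcol, sign_in) {
    xs <- moving_average(xcol, 2L)
    idx <- (window + 1L):(n - window)
    # second difference over the +/- window arc; sign_in makes "towards the
    # torso interior" positive (left contour bulges to higher columns at the
    # waist, right contour to lower columns)
    k <- sign_in * (xs[idx - window] - 2 * xs[idx] + xs[idx + window])
    if (max(k) <= 0)
      stop("detection error: no concave curvature on contour", call. = FALSE)
    best <- idx[which.max(k)]
    # refine to the most medial raw contour point near the curvature peak
    # (the smoothing used for robust localisation blurs sharp notches)
    nb <- max(1L, best - window):min(n, best + window)
    apex <- nb[which.max(sign_in * (-xcol[nb]))]
    list(col = xcol[apex], row = ct$rows[apex])
  }
  left <- curv_pick(ct$left, -1)
  right <- curv_pick(ct$right, +1)
  list(il = left$col, ir = right$col,
       jl_apex = left$row, jr_apex = right$row)
}

#' Detect the full landmark set
#'
#' Runs torso-start detection, the central-band intensity curve, extreme
#' value analysis, boundary crossings and the lateral reference positions,
#' and validates the landmark ordering
#' jts <= jt < jtmax < jtl < jlmin < jl <= jsmax and il < isym < ir.
#'
#' @param roi a `roi_image` from [fit_roi()].
#' @param I the aligned smooth image (for z(j)).
#' @param config a [torso_config()] list.
#' @return A `landmark_set` object.
#' @export
detect_landmarks <- function(roi, I, config = torso_config()) {
  jts <- detect_torso_start(roi, config$tv)
  z <- mean_intensity_curve(I, config$delta_iz)
  ex <- detect_profile_extrema(z, jts)
  bd <- region_boundaries(z, jts, ex$jtmax, ex$jlmin)
  rp <- reference_positions(roi, config$curvature_window)
  lm <- structure(c(list(jts = jts), ex, bd, rp,
                    list(z = z, tv = config$tv,
                         isym = symmetry_axis(ncol(roi$mask)),
                         n_rows = nrow(roi$mask))),
                  class = "landmark_set")
  if (!(lm$jts <= lm$jt && lm$jt < lm$jtmax && lm$jtmax < lm$jtl &&
        lm$jtl < lm$jlmin && lm$jlmin < lm$jl && lm$jl <= lm$jsmax))
    stop("detection error: landmark ordering violated", call. = FALSE)
  if (!(lm$il < lm$isym && lm$isym < lm$ir))
    stop("detection error: reference positions do not straddle the axis",
         call. = FALSE)
  lm
}

#' @export
print.landmark_set <- function(x, ...) {
  cat(sprintf(paste0(
    "<landmark_set> jts=%d jt=%d jtmax=%d jtl=%d jlmin=%d jl=%d jsmax=%d ",
    "il=%g ir=%g vz=%.1f\n"),
    x$jts, x$jt, x$jtmax, x$jtl, x$jlmin, x$jl, x$jsmax, x$il, x$ir, x$vz))
  invisible(x)
}

#' Reference distances between landmarks
#'
#' Distances use the inclusive pixel convention (end - start + 1), the only
#' convention under which the published grand-mean distances equal the
#' differences of the corresponding landmark grand means.
#'
#' @param lm a `landmark_set` (or any list with the needed fields).
#' @param n_rows number of sensor rows (sacral region ends at the last row).
#' @param pixel_mm mm per pixel for the mm-scaled copy.
#' @return A `reference_distances` list: `dl`, `dw`, `dth`, `dlu`, `ds` in px
#'   plus `mm`, a vector of the same distances in millimetres.
#' @export
reference_distances <- function(lm, n_rows = 160,
                                pixel_mm = torso_defaults()$pixel_mm) {
  d <- list(dl = lm$jsmax - lm$jts + 1,
            dw = lm$ir - lm$il + 1,
            dth = lm$jtl - lm$jt + 1,
            dlu = lm$jl - lm$jtl + 1,
            ds = n_rows - lm$jl + 1)
  d$mm <- vapply(d, function(v) v * pixel_mm, numeric(1))
  structure(d, class = "reference_distances")
}
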