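# Frontal and sagittal spine shape. The paraspinal muscles form a concave
# intensity canal over the spinous processes; its per-row minima, smoothed by
# a fifth-degree polynomial, approximate the frontal spine curve Lfc(j). The
# central intensity profile z(j) between the thoracic start and lumbar end
# serves as a surrogate for the sagittal shape.

polyfit <- function(x, y, degree) {
  fit <- lm(y ~ poly(x, degree, raw = TRUE))
  unname(coef(fit))   # intercept first
}

polyval <- function(coefs, x) {
  out <- 0
  for (k in seq_along(coefs)) out <- out + coefs[k] * x^(k - 1)
  out
}

# slope of simple linear regression y ~ x
reg_slope <- function(x, y) {
  if (length(x) < 2L) stop("fit error: interval too short", call. = FALSE)
  sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
}

#' Extract the frontal spine curve from the canal minima
#'
#' For every row in `[jt, jl]`, local minima of the ROI row profile are
#' searched within the central band of +/- `delta_iz`/2 columns around the
#' symmetry axis; the minimum closest to the axis (ties towards smaller
#' column) marks the canal centre. A fifth-degree least-squares polynomial
#' through the detected points yields `Lfc`; a linear fit of `Lfc` gives its
#' generalised orientation `Lfc_s`.
#'
#' @param roi a `roi_image`.
#' @param lm a `landmark_set`.
#' @param config a [torso_config()] list.
#' @return A `frontal_curve` object with `rows`, `Lfc`, `Lfc_s`, `slope`
#'   (signed slope of the linear fit), `intercept`, `raw_rows`, `raw_cols`.
#' @export
extract_frontal_curve <- function(roi, lm, config = torso_config()) {
  x <- roi_values(roi)
  axis <- lm$isym
  half <- config$delta_iz / 2
  lo <- max(1L, as.integer(ceiling(axis - half)))
  hi <- min(ncol(x), as.integer(floor(axis + half)))
  rows <- lm$jt:lm$jl
  raw_rows <- c(); raw_cols <- c()
  for (j in rows) {
    v <- x[j, lo:hi]
    n <- length(v)
    if (all(v <= 0)) next
    # interior local minima (plateaus count once at their first point)
    is_min <- vapply(2:(n - 1), function(k) {
      v[k] <= v[k - 1] && v[k] <= v[k + 1] && (v[k] < v[k - 1] ||
                                               v[k] < v[k + 1])
    }, logical(1))
    cand <- (2:(n - 1))[is_min]
    if (length(cand) == 0L) next
    cols <- lo + cand - 1L
    d <- abs(cols - axis)
    best <- cols[order(d, cols)][1]   # closest to axis, ties -> smaller i
    raw_rows <- c(raw_rows, j); raw_cols <- c(raw_cols, best)
  }
  if (length(raw_rows) < 7L)
    stop("fit error: fewer than 7 rows with detectable canal minima",
         call. = FALSE)
  cf5 <- polyfit(raw_rows, raw_cols, 5L)
  Lfc <- polyval(cf5, rows)
  cf1 <- polyfit(rows, Lfc, 1L)
  structure(list(rows = rows, Lfc = Lfc,
                 Lfc_s = polyval(cf1, rows),
                 slope = cf1[2], intercept = cf1[1],
                 coef5 = cf5, raw_rows = raw_rows, raw_cols = raw_cols),
            class = "frontal_curve")
}

#' Frontal spine shape parameters FC1-FC7
#'
#' Asymmetry descriptors of the fitted frontal curve: total adjacent
#' variation (FC1, px), variance (FC2, px^2), thoracic/lumbar mean ratio
#' (FC3), upper-thoracic vs lower-lumbar lateral deviation (FC4, px, reported
#' as magnitude with the signed value as diagnostic), maximum deviation from
#' the symmetry axis (FC5, px), summed deviation from the linear trend
#' (FC6, px) and the magnitude of the linear-trend slope (FC7).
#'
#' @param fc a `frontal_curve`.
#' @param lm a `landmark_set`.
#' @return Named list FC1..FC7 plus `FC4_signed` and `warnings`.
#' @export
frontal_params <- function(fc, lm) {
  rows <- fc$rows; L <- fc$Lfc
  warns <- character(0)
  idx <- function(j) match(j, rows)
  FC1 <- sum(abs(diff(L)))
  FC2 <- var(L)
  th <- idx(lm$jt):idx(lm$jtl)
  lu <- idx(lm$jtl):idx(lm$jl)
  dth <- lm$jtl - lm$jt + 1
  dlu <- lm$jl - lm$jtl + 1
  FC3 <- (sum(L[th]) / dth) / (sum(L[lu]) / dlu)
  n10t <- min(10L, length(th)); n10l <- min(10L, length(lu))
  if (n10t < 10L || n10l < 10L) {
    warns <- c(warns, "FC4: region shorter than 10 rows; full region used")
    FC4_signed <- mean(L[th]) - mean(L[lu])
  } else {
    FC4_signed <- (sum(L[seq_len(10)]) -
                   sum(L[(length(L) - 9):length(L)])) / 10
  }
  FC4 <- abs(FC4_signed)
  FC5 <- max(abs(L - lm$isym))
  FC6 <- sum(abs(L - fc$Lfc_s))
  FC7 <- abs(fc$slope)
  list(FC1 = FC1, FC2 = FC2, FC3 = FC3, FC4 = FC4, FC5 = FC5, FC6 = FC6,
       FC7 = FC7, FC4_signed = FC4_signed, warnings = warns)
}

# angle between two regression slopes, arctan((m1 - m2) / (1 + m1 m2));
# the degenerate 1 + m1 m2 = 0 case returns +/- pi/2 by continuity.
slope_angle <- function(m1, m2) {
  den <- 1 + m1 * m2
  if (abs(den) < .Machine$double.eps^0.5) {
    warning("slope angle degenerate (1 + m1*m2 = 0); returning +/- pi/2")
    return(sign(m1 - m2) * pi / 2)
  }
  atan((m1 - m2) / den)
}

#' Sagittal spine shape parameters SC1-SC8
#'
#' Linear regressions of z(j) on the four landmark intervals give the slopes
#' entering the kyphosis- and lordosis-associated angles SC1/SC2 (radians,
#' slope-space angles, not clinical angles); SC3-SC8 are intensity ratios
#' and slopes characterising the sagittal imbalance. The thoracic and lumbar
#' sums share the transition row jtl, exactly as defined.
#'
#' @param lm a `landmark_set` (carries z and vz).
#' @return Named list SC1..SC8 plus the four regression slopes.
#' @export
sagittal_params <- function(lm) {
  z <- lm$z
  mt1 <- reg_slope(lm$jt:lm$jtmax, z[lm$jt:lm$jtmax])
  mt2 <- reg_slope(lm$jtmax:lm$jtl, z[lm$jtmax:lm$jtl])
  ml1 <- reg_slope(lm$jtl:lm$jlmin, z[lm$jtl:lm$jlmin])
  ml2 <- reg_slope(lm$jlmin:lm$jl, z[lm$jlmin:lm$jl])
  if (z[lm$jlmin] == 0 || lm$vz == 0)
    stop("undefined ratio: z(jlmin) or vz is zero", call. = FALSE)
  dth <- lm$jtl - lm$jt + 1
  dlu <- lm$jl - lm$jtl + 1
  sum_th <- sum(z[lm$jt:lm$jtl])
  sum_lu <- sum(z[lm$jtl:lm$jl])
  list(SC1 = slope_angle(mt1, mt2),
       SC2 = slope_angle(ml1, ml2),
       SC3 = z[lm$jtmax] / z[lm$jlmin],
       SC4 = sum_th / sum_lu,
       SC5 = (sum_th / dth) / (sum_lu / dlu),
       SC6 = (z[lm$jtmax] - z[lm$jlmin]) / (lm$jtmax - lm$jlmin),
       SC7 = z[lm$jtmax] / lm$vz,
       SC8 = z[lm$jlmin] / lm$vz,
       mt1 = mt1, mt2 = mt2, ml1 = ml1, ml2 = ml2)
}
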