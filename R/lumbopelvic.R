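# Lumbar and sacral structures: waist contour symmetry (W) and pelvic
# posture (P).

#' Waist contour parameters W0-W4
#'
#' Over the lumbar span `[jtl, jl]` extended by 10 rows on both ends, the
#' lateral waist boundary is traced per row as the outermost column whose
#' intensity exceeds the side's adaptive threshold (mean of the positive
#' intensities in the lateral third of that side over the span). A
#' fourth-degree polynomial smooths each boundary; its most medial excursion
#' within the lumbar rows is the waist centre. A second-degree fit provides
#' the quadratic coefficients compared by W4.
#'
#' @param roi a `roi_image`.
#' @param lm a `landmark_set`.
#' @return Named list with the centre coordinates, W1..W4 (+ signed
#'   diagnostics), quartic/quadratic coefficients per side.
#' @export
waist_params <- function(roi, lm) {
  x <- roi_values(roi)
  nr <- nrow(x); nc <- ncol(x)
  axis <- lm$isym
  rows <- max(1L, lm$jtl - 10L):min(nr, lm$jl + 10L)
  lumbar <- lm$jtl:lm$jl
  third <- max(2L, floor(nc / 3))
  side <- function(is_left) {
    lat_cols <- if (is_left) 1:third else (nc - third + 1L):nc
    reg <- x[rows, lat_cols, drop = FALSE]
    pos <- reg[reg > 0]
    if (!length(pos))
      stop("detection error: empty waist imprint", call. = FALSE)
    thr <- mean(pos)
    brow <- c(); bcol <- c()
    for (k in seq_along(rows)) {
      hit <- which(x[rows[k], ] > thr)
      hit <- if (is_left) hit[hit < axis] else hit[hit > axis]
      if (length(hit)) {
        brow <- c(brow, rows[k])
        bcol <- c(bcol, if (is_left) min(hit) else max(hit))
      }
    }
    if (length(brow) < 5L)
      stop("fit error: waist quartic underdetermined (<5 boundary rows)",
           call. = FALSE)
    cf4 <- polyfit(brow, bcol, 4L)
    cf2 <- polyfit(brow, bcol, 2L)
    fit <- polyval(cf4, lumbar)
    # waist centre: most medial excursion of the fitted contour within the
    # lumbar rows (left contour: maximum column; right: minimum column)
    k <- if (is_left) which.max(fit) else which.min(fit)
    list(jw = lumbar[k], iw = fit[k], aws = cf2[3], cf4 = cf4, cf2 = cf2,
         rows = brow, cols = bcol)
  }
  left <- side(TRUE)
  right <- side(FALSE)
  W1s <- left$jw - right$jw
  W2s <- abs(right$iw - axis) - abs(axis - left$iw)
  W3s <- atan((left$jw - right$jw) / (left$iw - right$iw)) * 180 / pi
  list(W0_vl = left$jw, W0_hl = left$iw - axis,
       W0_vr = right$jw, W0_hr = right$iw - axis,
       W1 = abs(W1s), W1_signed = W1s,
       W2 = abs(W2s), W2_signed = W2s,
       W3 = abs(W3s), W3_signed = W3s,
       W4 = max(abs(left$aws / right$aws), abs(right$aws / left$aws)),
       W4_l = abs(left$aws), W4_r = abs(right$aws),
       fit_l = left[c("cf4", "cf2", "rows", "cols")],
       fit_r = right[c("cf4", "cf2", "rows", "cols")])
}

#' Sacral slope P1
#'
#' Slope of the linear least-squares fit of z(j) over the lumbosacral
#' transition `[jl, jsmax]`, in raw units per pixel; a surrogate for the
#' sagittal pelvic alignment.
#'
#' @param lm a `landmark_set`.
#' @return Scalar P1.
#' @export
sacral_slope <- function(lm) {
  if (lm$jsmax - lm$jl < 1L)
    stop("fit error: sacral interval too short", call. = FALSE)
  reg_slope(lm$jl:lm$jsmax, lm$z[lm$jl:lm$jsmax])
}

#' Pelvic posture parameters P0/P2-P4
#'
#' The sacral span (rows `[jl, n_rows]`) is adaptively segmented at the mean
#' of its positive intensities and split at the symmetry axis. Per side the
#' first and last segmented rows give the upper and lower sacral edges; P2
#' sums the magnitudes of the edge shifts, P3/P4 are max ratios of the side
#' sums/means of the ROI intensities.
#'
#' @param roi a `roi_image`.
#' @param lm a `landmark_set`.
#' @return Named list with edges, P2, P3, P4 and side values.
#' @export
pelvic_params <- function(roi, lm) {
  x <- roi_values(roi)
  nr <- nrow(x); nc <- ncol(x)
  axis <- lm$isym
  rows <- lm$jl:nr
  reg <- x[rows, , drop = FALSE]
  pos <- reg[reg > 0]
  if (!length(pos))
    stop("detection error: empty sacral region", call. = FALSE)
  thr <- mean(pos)
  segm <- reg > thr
  lcols <- 1:floor(axis)
  rcols <- ceiling(axis):nc
  side <- function(cols, lab) {
    s <- segm[, cols, drop = FALSE]
    rr <- which(rowSums(s) > 0)
    if (!length(rr))
      stop("detection error: empty ", lab, " sacral segment", call. = FALSE)
    v <- reg[, cols, drop = FALSE]
    v <- v[v > 0]
    list(jpu = rows[min(rr)], jpl = rows[max(rr)],
         sum = sum(v), mean = mean(v))
  }
  left <- side(lcols, "left")
  right <- side(rcols, "right")
  list(P0_ul = left$jpu, P0_ur = right$jpu,
       P0_ll = left$jpl, P0_lr = right$jpl,
       P2 = abs(left$jpu - right$jpu) + abs(left$jpl - right$jpl),
       P3 = max_ratio(left$sum, right$sum),
       P3_l = left$sum, P3_r = right$sum,
       P4 = max_ratio(left$mean, right$mean),
       P4_l = left$mean, P4_r = right$mean)
}
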