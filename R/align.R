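# Mirror-symmetry alignment: the torso imprint is derotated and centred so
# that its mirror axis coincides with the vertical image centre, then shifted
# vertically so the caudal torso edge sits on the last row. All later
# left/right comparisons assume this canonical placement.

#' Mirror an image about the vertical centre axis
#'
#' Maps column i to n_cols + 1 - i, i.e. the mirror axis lies between the two
#' central columns.
#'
#' @param x numeric matrix.
#' @return Mirrored matrix.
#' @export
mirror_image <- function(x) x[, rev(seq_len(ncol(x))), drop = FALSE]

#' Rotate an image about its centre
#'
#' Bilinear interpolation about the continuous image centre
#' ((n_rows+1)/2, (n_cols+1)/2) with zero fill outside the source grid;
#' negative interpolation results are clipped to zero (pressure cannot be
#' negative).
#'
#' @param x numeric matrix.
#' @param alpha_deg rotation angle in degrees.
#' @return Rotated matrix of the same shape.
#' @export
rotate_image <- function(x, alpha_deg) {
  if (alpha_deg == 0) return(x)
  nr <- nrow(x); nc <- ncol(x)
  cj <- (nr + 1) / 2; ci <- (nc + 1) / 2
  a <- alpha_deg * pi / 180
  co <- cos(a); si <- sin(a)
  j <- matrix(seq_len(nr), nr, nc) - cj
  i <- matrix(seq_len(nc), nr, nc, byrow = TRUE) - ci
  # inverse mapping: source coords for each output pixel
  js <- co * j + si * i + cj
  is <- -si * j + co * i + ci
  j0 <- floor(js); i0 <- floor(is)
  fj <- js - j0; fi <- is - i0
  at <- function(jj, ii) {
    ok <- jj >= 1 & jj <= nr & ii >= 1 & ii <= nc
    v <- numeric(length(jj))
    v[ok] <- x[cbind(jj[ok], ii[ok])]
    v
  }
  v <- (1 - fj) * (1 - fi) * at(j0, i0) +
       (1 - fj) * fi       * at(j0, i0 + 1) +
       fj       * (1 - fi) * at(j0 + 1, i0) +
       fj       * fi       * at(j0 + 1, i0 + 1)
  out <- matrix(pmax(v, 0), nr, nc)
  out
}

#' Translate an image horizontally
#'
#' Shifts content by `t_px` columns (positive = towards the subject's right,
#' i.e. higher column indices), zero fill.
#'
#' @param x numeric matrix.
#' @param t_px integer column shift.
#' @return Translated matrix.
#' @export
translate_cols <- function(x, t_px) {
  if (t_px == 0) return(x)
  nc <- ncol(x)
  out <- matrix(0, nrow(x), nc)
  src <- seq_len(nc) - t_px
  ok <- src >= 1 & src <= nc
  out[, ok] <- x[, src[ok], drop = FALSE]
  out
}

translate_rows <- function(x, t_px) {
  if (t_px == 0) return(x)
  nr <- nrow(x)
  out <- matrix(0, nr, ncol(x))
  src <- seq_len(nr) - t_px
  ok <- src >= 1 & src <= nr
  out[ok, ] <- x[src[ok], , drop = FALSE]
  out
}

#' Symmetry cost of a rotation/translation candidate
#'
#' The sum of absolute differences (SAD) between the alpha-rotated,
#' t-translated image and the mirror (about the vertical image centre) of the
#' alpha-rotated image. Minimising this over the admissible integer grid
#' yields the derotation/centring transform.
#'
#' @param frame a [pressure_frame()] or numeric matrix.
#' @param alpha_deg integer rotation, |alpha_deg| <= 15.
#' @param t_px integer translation, |t_px| <= 30.
#' @param alpha_range,t_range admissible half-ranges.
#' @return Non-negative scalar cost.
#' @export
symmetry_cost <- function(frame, alpha_deg, t_px,
                          alpha_range = torso_defaults()$alpha_range,
                          t_range = torso_defaults()$t_range) {
  x <- if (inherits(frame, "pressure_frame")) frame$values else frame
  if (abs(alpha_deg) > alpha_range || alpha_deg != round(alpha_deg))
    stop("domain error: alpha_deg outside admissible grid", call. = FALSE)
  if (abs(t_px) > t_range || t_px != round(t_px))
    stop("domain error: t_px outside admissible grid", call. = FALSE)
  xr <- rotate_image(x, alpha_deg)
  sad_translate_cpp(xr, mirror_image(xr), as.integer(t_px),
                    as.integer(t_px))[1]
}

# Halving an odd t* leaves a half-pixel ambiguity; round towards zero so the
# imprint is only moved on evidence of at least one full pixel of offset.
round_half_to_zero <- function(x) {
  f <- floor(abs(x) + 0.5)
  adj <- ifelse(abs(x) - floor(abs(x)) == 0.5, floor(abs(x)), f)
  sign(x) * adj
}

#' Align a filtered image pair by mirror symmetry
#'
#' Exhaustively searches integer rotations alpha in \[-15, 15\] degrees and
#' translations t in \[-30, 30\] px for the minimum SAD between the
#' transformed image and its mirrored rotated counterpart. The translation
#' found this way moves the imprint onto its mirror image, which is twice the
#' centring offset, so the applied centring translation is tc = round(t*/2).
#' The identical transform is applied to both the smooth image `I` and the
#' lightly filtered `Is`, followed by a vertical shift placing the caudal-most
#' row whose row sum exceeds `tv_bottom` on the last row.
#'
#' @param I,Is the filtered pair from [filter_frames()].
#' @param config a [torso_config()] list; `tv` doubles as `tv_bottom`.
#' @return An `aligned_images` object with elements `I`, `Is`, `alpha_deg`,
#'   `tc_px`, `t_star`, `bottom_shift_px`, `cost`.
#' @export
align <- function(I, Is, config = torso_config()) {
  x <- if (inherits(I, "pressure_frame")) I$values else I
  xs <- if (inherits(Is, "pressure_frame")) Is$values else Is
  px <- if (inherits(I, "pressure_frame")) I$pixel_mm else
    torso_defaults()$pixel_mm
  if (all(x == 0))
    stop("alignment error: all-zero image (no torso imprint)", call. = FALSE)
  ar <- config$alpha_range; tr <- config$t_range
  alphas <- seq.int(-ar, ar)
  best <- list(cost = Inf, alpha = 0L, t = 0L)
  for (a in alphas) {
    xr <- rotate_image(x, a)
    costs <- sad_translate_cpp(xr, mirror_image(xr), -tr, tr)
    k <- which.min(costs)
    if (costs[k] < best$cost) {
      best <- list(cost = costs[k], alpha = a, t = as.integer(k - tr - 1L))
    }
  }
  tc <- as.integer(round_half_to_zero(best$t / 2))
  xa <- translate_cols(rotate_image(x, best$alpha), tc)
  xsa <- translate_cols(rotate_image(xs, best$alpha), tc)
  rs <- rowSums(xa)
  bottom <- which(rs > config$tv)
  if (length(bottom) == 0L)
    stop("alignment error: no row sum exceeds tv_bottom", call. = FALSE)
  shift <- nrow(xa) - max(bottom)
  xa <- translate_rows(xa, shift)
  xsa <- translate_rows(xsa, shift)
  structure(list(I = pressure_frame(xa, px), Is = pressure_frame(xsa, px),
                 alpha_deg = best$alpha, tc_px = tc, t_star = best$t,
                 bottom_shift_px = as.integer(shift), cost = best$cost),
            class = "aligned_images")
}

#' @export
print.aligned_images <- function(x, ...) {
  cat(sprintf(
    "<aligned_images> alpha=%d deg, tc=%d px (t*=%d), bottom shift=%d px\n",
    x$alpha_deg, x$tc_px, x$t_star, x$bottom_shift_px))
  invisible(x)
}
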