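# Filtering of the selected frame. Two filtered variants are carried through
# the pipeline: I, heavily smoothed for contour/landmark work, and Is,
# lightly filtered so that high-frequency structures such as the scapula
# peaks keep their intensity and position. Borders use edge replication.

gaussian_kernel <- function(size, sigma) {
  h <- (size - 1) / 2
  g <- exp(-((-h:h)^2) / (2 * sigma^2))
  k <- outer(g, g)
  k / sum(k)
}

# 2-D convolution with edge replication, small kernels only.
convolve_replicate <- function(x, kernel) {
  nr <- nrow(x); nc <- ncol(x)
  kr <- nrow(kernel); kc <- ncol(kernel)
  hr <- (kr - 1) / 2; hc <- (kc - 1) / 2
  out <- matrix(0, nr, nc)
  for (dj in -hr:hr) {
    jj <- pmin(pmax(seq_len(nr) + dj, 1L), nr)
    for (di in -hc:hc) {
      ii <- pmin(pmax(seq_len(nc) + di, 1L), nc)
      out <- out + kernel[dj + hr + 1, di + hc + 1] * x[jj, ii]
    }
  }
  out
}

#' Median filter with edge replication
#'
#' @param x numeric matrix.
#' @param kr,kc odd window dimensions (rows, columns).
#' @return Filtered matrix of the same shape.
#' @export
median_filter <- function(x, kr, kc) {
  stopifnot(is.matrix(x), kr %% 2 == 1, kc %% 2 == 1)
  median_filter_cpp(x, as.integer(kr), as.integer(kc))
}

#' Gaussian filter with edge replication
#'
#' @param x numeric matrix.
#' @param size odd kernel size.
#' @param sigma standard deviation in pixels.
#' @return Filtered matrix of the same shape.
#' @export
gaussian_filter <- function(x, size = 3, sigma = 3) {
  convolve_replicate(x, gaussian_kernel(size, sigma))
}

#' Filter a selected frame into the smooth and light variants
#'
#' Produces `I` = gaussian(median(frame, 15 x 5), 3 x 3, sigma = 3), the
#' smooth torso imprint used for alignment, masking and landmarks, and
#' `Is` = median(frame, 5 x 1), the lightly filtered image used where peak
#' intensities matter (scapulae). The 15 x 5 median removes thin fold
#' artifacts of the mat; the Gaussian smooths the resolution-induced steps.
#'
#' @param frame a [pressure_frame()].
#' @return List with `I` and `Is`, both [pressure_frame()] objects.
#' @export
filter_frames <- function(frame) {
  stopifnot(inherits(frame, "pressure_frame"))
  x <- frame$values
  I_  <- gaussian_filter(median_filter(x, 15, 5), 3, 3)
  Is_ <- median_filter(x, 5, 1)
  list(I = pressure_frame(I_, frame$pixel_mm),
       Is = pressure_frame(Is_, frame$pixel_mm))
}
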