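# Intra-observer reliability over a subjects x repetitions matrix of one
# parameter: one-way random-effects ICC(1,1) with an exact F-based 95% CI,
# mean within-subject SD and CV, and the classification bands used to rate
# them.

check_matrix <- function(m) {
  if (!is.matrix(m) || !is.numeric(m))
    stop("measurement matrix must be numeric", call. = FALSE)
  if (anyNA(m)) {
    keep <- stats::complete.cases(m)
    warning(sprintf("dropping %d subject(s) with missing repetitions",
                    sum(!keep)))
    m <- m[keep, , drop = FALSE]
  }
  if (nrow(m) < 2L || ncol(m) < 2L)
    stop("need at least 2 subjects and 2 repetitions", call. = FALSE)
  m
}

#' One-way random-effects intraclass correlation ICC(1,1)
#'
#' Single-measurement ICC from the one-way ANOVA decomposition:
#' ICC = (MSB - MSW) / (MSB + (k - 1) MSW) with n subjects (rows) and k
#' repetitions (columns). The two-sided confidence interval is the exact
#' F interval: with F = MSB/MSW on (n - 1, n(k - 1)) degrees of freedom,
#' FL = F / qF(1 - a/2), FU = F * qF(1 - a/2) with swapped df, and each bound
#' transformed through (F' - 1) / (F' + k - 1).
#'
#' @param m numeric n x k matrix (rows = subjects).
#' @param ci_level confidence level (default 0.95).
#' @return List with `icc`, `ci_low`, `ci_high`, `msb`, `msw`, `n`, `k`.
#' @export
#' @examples
#' icc_1_1(matrix(c(10, 10, 20, 21, 30, 29), 3, 2, byrow = TRUE))
icc_1_1 <- function(m, ci_level = 0.95) {
  m <- check_matrix(m)
  n <- nrow(m); k <- ncol(m)
  row_means <- rowMeans(m)
  grand <- mean(m)
  msb <- k * sum((row_means - grand)^2) / (n - 1)
  msw <- sum((m - row_means)^2) / (n * (k - 1))
  if (msb == 0 && msw == 0)
    stop("undefined ICC: all cells identical", call. = FALSE)
  icc <- (msb - msw) / (msb + (k - 1) * msw)
  a <- 1 - ci_level
  if (msw == 0) {
    ci <- c(1, 1)
  } else {
    Fobs <- msb / msw
    fl <- Fobs / qf(1 - a / 2, n - 1, n * (k - 1))
    fu <- Fobs * qf(1 - a / 2, n * (k - 1), n - 1)
    ci <- c((fl - 1) / (fl + k - 1), (fu - 1) / (fu + k - 1))
  }
  list(icc = icc, ci_low = ci[1], ci_high = ci[2],
       msb = msb, msw = msw, n = n, k = k)
}

#' Mean within-subject standard deviation
#'
#' Per-subject sample SD (k - 1 divisor) across repetitions, averaged over
#' subjects.
#'
#' @param m numeric n x k matrix.
#' @return Scalar mean SD.
#' @export
mean_sd <- function(m) {
  m <- check_matrix(m)
  mean(apply(m, 1, sd))
}

#' Mean coefficient of variation (percent)
#'
#' Per-subject SD over the magnitude of the per-subject mean, in percent,
#' averaged over subjects; subjects with zero mean are excluded with a
#' warning.
#'
#' @param m numeric n x k matrix.
#' @return Scalar mean CV in percent.
#' @export
mean_cv <- function(m) {
  m <- check_matrix(m)
  mu <- rowMeans(m)
  ok <- mu != 0
  if (!any(ok)) stop("CV undefined: all subject means are zero",
                     call. = FALSE)
  if (!all(ok)) warning("excluding subject(s) with zero mean from CV")
  mean(apply(m[ok, , drop = FALSE], 1, sd) / abs(mu[ok])) * 100
}

#' Classification bands for ICC, CV and SD
#'
#' ICC: excellent >= 0.9, good \[0.75, 0.9), moderate \[0.5, 0.75),
#' poor < 0.5. CV (%): excellent <= 10, good (10, 20\], moderate (20, 30\],
#' poor > 30. SD (px): very small <= 1, small (1, 2\], moderate (2, 3\],
#' large > 3.
#'
#' @param icc,cv,sd_px statistics to classify (any may be NA).
#' @return Named character vector with `icc_band`, `cv_band`, `sd_band`.
#' @export
classify_reliability <- function(icc = NA, cv = NA, sd_px = NA) {
  icc_band <- if (is.na(icc)) NA_character_
    else if (icc >= 0.9) "excellent" else if (icc >= 0.75) "good"
    else if (icc >= 0.5) "moderate" else "poor"
  cv_band <- if (is.na(cv)) NA_character_
    else if (cv <= 10) "excellent" else if (cv <= 20) "good"
    else if (cv <= 30) "moderate" else "poor"
  sd_band <- if (is.na(sd_px)) NA_character_
    else if (sd_px <= 1) "very small" else if (sd_px <= 2) "small"
    else if (sd_px <= 3) "moderate" else "large"
  c(icc_band = icc_band, cv_band = cv_band, sd_band = sd_band)
}

#' Reliability row for one parameter
#'
#' Computes the grand mean (mean of per-subject means), mean SD, mean CV,
#' ICC(1,1) with 95% CI and the classification bands for one
#' subjects x repetitions matrix.
#'
#' @param m numeric n x k matrix.
#' @param parameter_name label for the row.
#' @param units unit string; when `"px"`, mm-scaled copies are added.
#' @param pixel_mm mm per pixel for the mm copies.
#' @return A one-row data.frame.
#' @export
reliability_row <- function(m, parameter_name = "parameter", units = "",
                            pixel_mm = torso_defaults()$pixel_mm) {
  m <- check_matrix(m)
  ic <- icc_1_1(m)
  sdv <- mean_sd(m)
  cvv <- tryCatch(mean_cv(m), error = function(e) NA_real_)
  gm <- mean(rowMeans(m))
  px_like <- identical(units, "px")
  bands <- classify_reliability(ic$icc, cvv, if (px_like) sdv else NA)
  data.frame(parameter = parameter_name, units = units,
             mean = gm, mean_mm = if (px_like) gm * pixel_mm else NA_real_,
             sd = sdv, sd_mm = if (px_like) sdv * pixel_mm else NA_real_,
             cv_percent = cvv,
             icc = ic$icc, ci_low = ic$ci_low, ci_high = ic$ci_high,
             icc_band = bands[["icc_band"]], cv_band = bands[["cv_band"]],
             sd_band = if (px_like) bands[["sd_band"]] else NA_character_,
             stringsAsFactors = FALSE)
}
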