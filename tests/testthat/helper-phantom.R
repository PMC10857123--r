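# Shared fixtures. Heavy pipeline runs are cached per test session.

.fixtures <- new.env(parent = emptyenv())

# full analysis of the clean (noise-free) symmetric default phantom
clean_sym_analysis <- function() {
  if (is.null(.fixtures$clean_sym)) {
    g <- generate_phantom(phantom_spec(noise_sigma = 0))
    .fixtures$clean_sym <- list(g = g, ps = analyze_recording(g$frame))
  }
  .fixtures$clean_sym
}

# aligned/roi/landmark stage objects of the clean symmetric phantom
clean_sym_stages <- function() {
  if (is.null(.fixtures$stages)) {
    g <- generate_phantom(phantom_spec(noise_sigma = 0))
    f <- filter_frames(g$frame)
    al <- align(f$I, f$Is)
    roi <- fit_roi(al$I)
    lm <- detect_landmarks(roi, al$I)
    centres <- locate_scapulae(al$Is, lm)
    .fixtures$stages <- list(g = g, al = al, roi = roi, lm = lm,
                             centres = centres)
  }
  .fixtures$stages
}

# two-Gaussian sagittal profile with analytically known extrema:
# peaks at rows 52 and 130, trough near row 93
two_gaussian_z <- function(n = 160) {
  j <- seq_len(n)
  8000 + 3500 * exp(-((j - 52)^2) / (2 * 11^2)) +
    4000 * exp(-((j - 130)^2) / (2 * 9^2)) -
    900 * exp(-((j - 93)^2) / (2 * 14^2))
}

# naive O(n k) reference median filter with edge replication
naive_median_filter <- function(x, kr, kc) {
  nr <- nrow(x); nc <- ncol(x)
  hr <- (kr - 1) / 2; hc <- (kc - 1) / 2
  out <- matrix(0, nr, nc)
  for (j in seq_len(nr)) for (i in seq_len(nc)) {
    jj <- pmin(pmax((j - hr):(j + hr), 1), nr)
    ii <- pmin(pmax((i - hc):(i + hc), 1), nc)
    out[j, i] <- median(x[jj, ii])
  }
  out
}

# independent SAD evaluation by explicit double loop
naive_sad <- function(a, b) {
  s <- 0
  for (j in seq_len(nrow(a))) for (i in seq_len(ncol(a)))
    s <- s + abs(a[j, i] - b[j, i])
  s
}

naive_translate <- function(x, t) {
  out <- matrix(0, nrow(x), ncol(x))
  for (i in seq_len(ncol(x))) {
    src <- i - t
    if (src >= 1 && src <= ncol(x)) out[, i] <- x[, src]
  }
  out
}

# closed-form simple linear regression slope
oracle_slope <- function(x, y) {
  n <- length(x)
  (n * sum(x * y) - sum(x) * sum(y)) / (n * sum(x^2) - sum(x)^2)
}

# polynomial least squares by explicit normal equations
oracle_polyfit <- function(x, y, degree) {
  X <- outer(x, 0:degree, `^`)
  solve(t(X) %*% X, t(X) %*% y)[, 1]
}
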