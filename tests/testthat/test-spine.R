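# helper: build a roi_image + landmark_set with a carved canal at a known
# lateral path over a flat 9000-prv imprint
canal_fixture <- function(path_fun) {
  x <- matrix(0, 160, 100)
  x[30:160, 20:81] <- 9000
  for (j in 40:120) {
    c0 <- path_fun(j)
    prof <- 2500 * exp(-((20:81) - c0)^2 / (2 * 9))
    x[j, 20:81] <- x[j, 20:81] - prof
  }
  mask <- (x > 0) * 1
  roi <- structure(list(Iroi = pressure_frame(x), mask = mask, isym = 50.5),
                   class = "roi_image")
  lm <- structure(list(jt = 45, jl = 115, jtmax = 60, jtl = 80, jlmin = 100,
                       jts = 30, jsmax = 130, isym = 50.5,
                       z = rep(9000, 160), vz = 9000, il = 20, ir = 81,
                       n_rows = 160), class = "landmark_set")
  list(roi = roi, lm = lm)
}

test_that("a straight canal yields a straight frontal curve", {
  fx <- canal_fixture(function(j) 50)
  fc <- extract_frontal_curve(fx$roi, fx$lm)
  expect_lt(max(abs(fc$Lfc - 50)), 1e-6)
  expect_lt(abs(fc$slope), 1e-8)
  p <- frontal_params(fc, fx$lm)
  expect_equal(p$FC1, 0, tolerance = 1e-6)
  expect_equal(p$FC2, 0, tolerance = 1e-9)
  expect_equal(p$FC3, 1, tolerance = 1e-6)
  expect_equal(p$FC6, 0, tolerance = 1e-6)
  expect_equal(p$FC7, 0, tolerance = 1e-8)
  # FC5 measures against the axis between the central columns
  expect_equal(p$FC5, 0.5, tolerance = 1e-6)
})

test_that("equidistant minima resolve to the smaller column", {
  x <- matrix(9000, 1, 100)
  x[c(48, 52)] <- 1000       # two equal minima, equidistant from 50
  img <- matrix(0, 160, 100)
  img[30:160, ] <- 9000
  img[45:120, 48] <- 1000
  img[45:120, 52] <- 1000
  roi <- structure(list(Iroi = pressure_frame(img), mask = (img > 0) * 1,
                        isym = 50), class = "roi_image")
  lm <- structure(list(jt = 50, jl = 110, isym = 50), class = "landmark_set")
  fc <- extract_frontal_curve(roi, lm)
  expect_true(all(fc$raw_cols == 48))
})

test_that("a curved canal is recovered and FC values match a loop oracle", {
  path <- function(j) 50 + 2 * sin((j - 40) / 25)
  fx <- canal_fixture(path)
  fc <- extract_frontal_curve(fx$roi, fx$lm)
  expect_lt(max(abs(fc$Lfc - path(fc$rows))), 0.5)
  p <- frontal_params(fc, fx$lm)
  # independent naive re-evaluation on the same Lfc samples
  L <- fc$Lfc; rows <- fc$rows
  fc1 <- 0
  for (k in seq_len(length(L) - 1)) fc1 <- fc1 + abs(L[k] - L[k + 1])
  expect_equal(p$FC1, fc1)
  expect_equal(p$FC2, sum((L - mean(L))^2) / (length(L) - 1))
  th <- which(rows >= fx$lm$jt & rows <= fx$lm$jtl)
  lu <- which(rows >= fx$lm$jtl & rows <= fx$lm$jl)
  dth <- fx$lm$jtl - fx$lm$jt + 1
  dlu <- fx$lm$jl - fx$lm$jtl + 1
  expect_equal(p$FC3, (sum(L[th]) / dth) / (sum(L[lu]) / dlu))
  expect_equal(p$FC4, abs(sum(L[1:10]) - sum(L[(length(L) - 9):
                                                 length(L)])) / 10)
  expect_equal(p$FC5, max(abs(L - 50.5)))
  cf <- oracle_polyfit(rows, L, 1)
  expect_equal(p$FC7, abs(cf[2]), tolerance = 1e-8)
  expect_equal(p$FC6, sum(abs(L - (cf[1] + cf[2] * rows))),
               tolerance = 1e-6)
})

test_that("linear frontal curves give the closed-form FC5/FC7", {
  lm <- structure(list(jt = 40, jl = 110, jtmax = 55, jtl = 75,
                       jlmin = 95, isym = 50), class = "landmark_set")
  rows <- 40:110
  fc <- structure(list(rows = rows, Lfc = 50 + 0.1 * (rows - 40),
                       Lfc_s = 50 + 0.1 * (rows - 40),
                       slope = 0.1, intercept = 46), class = "frontal_curve")
  p <- frontal_params(fc, lm)
  expect_equal(p$FC7, 0.1)
  expect_equal(p$FC5, 0.1 * (110 - 40))
  expect_equal(p$FC6, 0, tolerance = 1e-9)
})

test_that("sagittal parameters have the stated identities and oracle", {
  lm_flat <- list(jt = 40, jtmax = 55, jtl = 75, jlmin = 95, jl = 110,
                  z = rep(500, 160), vz = 500)
  s <- sagittal_params(lm_flat)
  expect_equal(s$SC1, 0); expect_equal(s$SC2, 0)
  expect_equal(s$SC3, 1); expect_equal(s$SC4, 1); expect_equal(s$SC5, 1)
  expect_equal(s$SC6, 0); expect_equal(s$SC7, 1); expect_equal(s$SC8, 1)

  # piecewise-linear slopes (+2, -1) around jtmax: hand evaluation
  z <- rep(0, 160)
  z[40:55] <- 100 + 2 * (40:55 - 40)
  z[55:75] <- z[55] - 1 * (55:75 - 55)
  z[75:110] <- z[75]
  lm_pw <- list(jt = 40, jtmax = 55, jtl = 75, jlmin = 95, jl = 110,
                z = z, vz = 100)
  s2 <- sagittal_params(lm_pw)
  expect_equal(s2$SC1, atan((2 - (-1)) / (1 + 2 * (-1))), tolerance = 1e-9)

  # two-Gaussian fixture against independent regression/ratio oracles
  z3 <- two_gaussian_z()
  ex <- detect_profile_extrema(z3, 30)
  bd <- region_boundaries(z3, 30, ex$jtmax, ex$jlmin)
  lm3 <- c(list(jts = 30), ex, bd, list(z = z3))
  s3 <- sagittal_params(lm3)
  mt1 <- oracle_slope(lm3$jt:lm3$jtmax, z3[lm3$jt:lm3$jtmax])
  mt2 <- oracle_slope(lm3$jtmax:lm3$jtl, z3[lm3$jtmax:lm3$jtl])
  expect_equal(s3$SC1, atan((mt1 - mt2) / (1 + mt1 * mt2)), tolerance = 1e-9)
  expect_equal(s3$SC3, z3[lm3$jtmax] / z3[lm3$jlmin])
  expect_equal(s3$SC6, (z3[lm3$jtmax] - z3[lm3$jlmin]) /
                         (lm3$jtmax - lm3$jlmin))
  expect_lt(s3$SC6, 0)   # printed sign convention: cranial max -> negative
  expect_equal(s3$SC7, z3[lm3$jtmax] / lm3$vz)
  dth <- lm3$jtl - lm3$jt + 1; dlu <- lm3$jl - lm3$jtl + 1
  expect_equal(s3$SC5, (sum(z3[lm3$jt:lm3$jtl]) / dth) /
                         (sum(z3[lm3$jtl:lm3$jl]) / dlu))
})

test_that("sagittal parameters are exactly mirror invariant", {
  st <- clean_sym_stages()
  lmm <- st$lm
  # mirroring the image leaves z(j) and hence SC1-SC8 unchanged
  zm <- mean_intensity_curve(mirror_image(st$al$I$values))
  expect_equal(zm, lmm$z, tolerance = 1e-9)
})

test_that("kyphosis amplitude drives SC3, SC7 and |SC6| monotonically", {
  amps <- c(2000, 2750, 3500, 4250, 5000)
  vals <- sapply(amps, function(a) {
    g <- generate_phantom(phantom_spec(kyphosis_amp = a, noise_sigma = 0))
    ps <- analyze_recording(g$frame)
    ps$values[c("SC3", "SC7", "SC6")]
  })
  expect_true(all(diff(vals["SC3", ]) > 0))
  expect_true(all(diff(vals["SC7", ]) > 0))
  expect_true(all(diff(abs(vals["SC6", ])) > 0))
})
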