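test_that("torso start is the first row-sum crossing of tv", {
  x <- matrix(0, 160, 100)
  x[30:150, ] <- 100                    # row sums of 10000
  expect_equal(detect_torso_start(x, tv = 7000), 30)
  expect_error(detect_torso_start(matrix(0, 160, 100)), "torso not found")
  # independent cumulative-scan oracle on a noisy phantom ROI
  st <- clean_sym_stages()
  v <- st$roi$Iroi$values
  oracle <- NA
  for (j in 1:160) if (sum(v[j, ]) > 7000) { oracle <- j; break }
  expect_equal(detect_torso_start(st$roi), oracle)
})

test_that("mean intensity curve averages the 31-column central band", {
  expect_equal(mean_intensity_curve(matrix(7, 160, 100)), rep(7, 160))
  ramp <- matrix(0, 160, 100)
  ramp[, 35:65] <- matrix(1:160, 160, 31)
  expect_equal(mean_intensity_curve(ramp), as.numeric(1:160))
  # double-loop oracle on a random frame
  set.seed(21)
  x <- matrix(runif(16000, 0, 100), 160, 100)
  z <- mean_intensity_curve(x)
  for (j in c(1, 80, 160))
    expect_equal(z[j], mean(sapply(35:65, function(i) x[j, i])))
})

test_that("profile extrema are found with cranial tie-breaking", {
  z <- two_gaussian_z()
  ex <- detect_profile_extrema(z, jts = 30)
  expect_equal(ex$jtmax, 52)
  expect_equal(ex$jsmax, 130)
  expect_lte(abs(ex$jlmin - 93), 3)     # trough of the superposition
  expect_equal(ex$jlmin, (ex$jtmax:ex$jsmax)[
    which.min(z[ex$jtmax:ex$jsmax])])
  # plateau at the maximum resolves to the smaller row
  zp <- z
  zp[51] <- zp[52] <- max(z) + 100
  expect_equal(detect_profile_extrema(zp, 30)$jtmax, 51)
  expect_error(detect_profile_extrema(seq(0, 1000, length.out = 160), 10),
               "detection error")
})

test_that("region boundaries come from vz crossings", {
  z <- two_gaussian_z()
  ex <- detect_profile_extrema(z, 30)
  bd <- region_boundaries(z, 30, ex$jtmax, ex$jlmin)
  expect_equal(bd$vz, mean(z[30:ex$jlmin]))
  # independent linear-scan oracle for the three crossings
  jt_o <- jtl_o <- jl_o <- NA
  for (j in 30:ex$jtmax) if (z[j] >= bd$vz) { jt_o <- j; break }
  for (j in (ex$jtmax + 1):ex$jlmin) if (z[j] <= bd$vz) { jtl_o <- j; break }
  for (j in (ex$jlmin + 1):160) if (z[j] >= bd$vz) { jl_o <- j; break }
  expect_equal(bd$jt, jt_o)
  expect_equal(bd$jtl, jtl_o)
  expect_equal(bd$jl, jl_o)
  expect_true(bd$jt < ex$jtmax && ex$jtmax < bd$jtl &&
              bd$jtl < ex$jlmin && ex$jlmin < bd$jl)
  expect_error(region_boundaries(rep(5, 160), 30, 52, 93), "boundary")
})

test_that("reference positions find the waist notch and reject rectangles", {
  # sharp single-pixel notch per side
  mask <- matrix(0, 160, 100)
  mask[40:160, 25:76] <- 1
  mask[100, 25] <- 0; mask[100, 76] <- 0
  roi <- structure(list(Iroi = pressure_frame(mask * 100), mask = mask,
                        isym = 50.5), class = "roi_image")
  rp <- reference_positions(roi)
  expect_equal(rp$il, 26)
  expect_equal(rp$ir, 75)
  expect_equal(rp$jl_apex, 100)
  # rectangle: no concave curvature anywhere
  rect <- matrix(0, 160, 100)
  rect[40:160, 25:76] <- 1
  roi_r <- structure(list(Iroi = pressure_frame(rect), mask = rect,
                          isym = 50.5), class = "roi_image")
  expect_error(reference_positions(roi_r), "no concave curvature")
})

test_that("waist apex of the phantom is recovered", {
  st <- clean_sym_stages()
  rp <- reference_positions(st$roi)
  # apex row: waist_row_up above the anchored bottom edge
  expect_lte(abs(rp$jl_apex - (160 - st$g$spec$waist_row_up)), 4)
  expect_lte(abs(rp$jr_apex - (160 - st$g$spec$waist_row_up)), 4)
  expect_true(rp$il < st$lm$isym && st$lm$isym < rp$ir)
})

test_that("reference distances use the inclusive pixel convention", {
  lm <- list(jts = 31.7, jt = 39.9, jtmax = 51.7, jtl = 72.3, jlmin = 93.1,
             jl = 111.3, jsmax = 130.2, il = 23.9, ir = 74.5)
  d <- reference_distances(lm)
  expect_equal(d$dl, 99.5)
  expect_equal(d$dw, 51.6)
  expect_equal(d$dth, 33.4)
  expect_equal(d$dlu, 40.0)
  expect_equal(d$ds, 49.7)
  expect_equal(unname(d$mm["dw"]), 263.16, tolerance = 1e-9)
  expect_equal(unname(d$mm["dl"]), 507.45, tolerance = 1e-9)
  # exact identity linking the region lengths
  expect_equal(d$dth + d$dlu, lm$jl - lm$jt + 2)
})

test_that("landmark ordering holds and rows shift with the imprint", {
  st <- clean_sym_stages()
  lm <- st$lm
  expect_true(lm$jts <= lm$jt && lm$jt < lm$jtmax && lm$jtmax < lm$jtl &&
              lm$jtl < lm$jlmin && lm$jlmin < lm$jl && lm$jl <= lm$jsmax)
  # shifting the image caudally shifts z-derived landmarks by exactly k
  x <- st$al$I$values
  k <- 6
  xs <- translate_rows(x, -k)           # move cranially to keep in-grid
  z0 <- mean_intensity_curve(x)
  zs <- mean_intensity_curve(xs)
  e0 <- detect_profile_extrema(z0, lm$jts)
  es <- detect_profile_extrema(zs, lm$jts - k)
  expect_equal(es$jtmax, e0$jtmax - k)
  expect_equal(es$jlmin, e0$jlmin - k)
  expect_equal(es$jsmax, e0$jsmax - k)
})
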