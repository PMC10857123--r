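test_that("ICC(1,1) identities and hand-computed ANOVA fixture", {
  # zero within-subject variance -> ICC 1
  m <- matrix(rep(c(10, 20, 30), each = 3), 3, 3, byrow = TRUE)
  r <- icc_1_1(m)
  expect_equal(r$icc, 1)
  expect_equal(r$ci_low, 1)

  # 3 x 2 fixture: explicit one-way ANOVA by hand
  # rows {1,2},{3,4},{5,6}: grand mean 3.5, row means 1.5/3.5/5.5
  # SSB = 2*((1.5-3.5)^2+(3.5-3.5)^2+(5.5-3.5)^2) = 16, MSB = 16/2 = 8
  # SSW = 6*0.25 = 1.5, MSW = 1.5/3 = 0.5
  # ICC = (8-0.5)/(8+0.5) = 15/17
  m2 <- matrix(1:6, 3, 2, byrow = TRUE)
  r2 <- icc_1_1(m2)
  expect_equal(r2$msb, 8, tolerance = 1e-9)
  expect_equal(r2$msw, 0.5, tolerance = 1e-9)
  expect_equal(r2$icc, 15 / 17, tolerance = 1e-9)
  # CI transformed from the F interval with (2, 3) degrees of freedom
  Fo <- 8 / 0.5
  fl <- Fo / qf(0.975, 2, 3); fu <- Fo * qf(0.975, 3, 2)
  expect_equal(r2$ci_low, (fl - 1) / (fl + 1), tolerance = 1e-9)
  expect_equal(r2$ci_high, (fu - 1) / (fu + 1), tolerance = 1e-9)
  expect_true(r2$ci_low <= r2$icc && r2$icc <= r2$ci_high)

  expect_error(icc_1_1(matrix(5, 3, 3)), "undefined ICC")
})

test_that("iid cells give ICC near zero at n = 200, k = 10", {
  set.seed(2024)
  m <- matrix(rnorm(2000), 200, 10)
  expect_lte(abs(icc_1_1(m)$icc), 0.05)
})

test_that("ICC is affine invariant; SD scales; CV scales only", {
  set.seed(33)
  m <- matrix(rnorm(50, 100, 10), 10, 5)
  r0 <- icc_1_1(m)
  r1 <- icc_1_1(3.7 * m - 250)
  expect_equal(r1$icc, r0$icc, tolerance = 1e-12)
  expect_equal(r1$ci_low, r0$ci_low, tolerance = 1e-12)
  expect_equal(mean_sd(2 * m), 2 * mean_sd(m), tolerance = 1e-12)
  expect_equal(mean_cv(2 * m), mean_cv(m), tolerance = 1e-12)
})

test_that("ICC grows with between-subject spread at fixed noise", {
  set.seed(44)
  noise <- matrix(rnorm(200, 0, 1), 20, 10)
  spreads <- c(0.5, 1, 2, 4, 8)
  iccs <- sapply(spreads, function(s) {
    subj <- rnorm(20, 0, s)
    icc_1_1(matrix(subj, 20, 10) + noise)$icc
  })
  expect_true(all(diff(iccs) > 0))
})

test_that("the CI brackets the estimate and narrows with n", {
  set.seed(55)
  mk <- function(n) matrix(rnorm(n, 0, 2), n, 10) + matrix(rnorm(n * 10),
                                                           n, 10)
  r10 <- icc_1_1(mk(10)); r40 <- icc_1_1(mk(40))
  expect_true(r10$ci_low <= r10$icc && r10$icc <= r10$ci_high)
  expect_lt(r40$ci_high - r40$ci_low, r10$ci_high - r10$ci_low)
})

test_that("mean SD and CV follow the closed forms and a loop oracle", {
  m <- matrix(rep(c(4, 9), each = 4), 2, 4, byrow = TRUE)
  expect_equal(mean_sd(m), 0)
  expect_equal(mean_cv(m), 0)
  m2 <- matrix(c(9, 11), 1, 2)
  m2 <- rbind(m2, m2)
  expect_equal(mean_sd(m2), sqrt(2), tolerance = 1e-12)
  expect_equal(mean_cv(m2), sqrt(2) / 10 * 100, tolerance = 1e-12)
  set.seed(66)
  m3 <- matrix(runif(100, 1, 50), 10, 10)
  sds <- cvs <- numeric(10)
  for (s in 1:10) {
    mu <- sum(m3[s, ]) / 10
    sds[s] <- sqrt(sum((m3[s, ] - mu)^2) / 9)
    cvs[s] <- sds[s] / abs(mu) * 100
  }
  expect_equal(mean_sd(m3), mean(sds), tolerance = 1e-12)
  expect_equal(mean_cv(m3), mean(cvs), tolerance = 1e-12)
})

test_that("classification bands match the published conventions", {
  expect_equal(unname(classify_reliability(icc = 0.917)["icc_band"]),
               "excellent")
  expect_equal(unname(classify_reliability(icc = 0.75)["icc_band"]), "good")
  expect_equal(unname(classify_reliability(icc = 0.49)["icc_band"]), "poor")
  expect_equal(unname(classify_reliability(cv = 10)["cv_band"]),
               "excellent")   # boundary inclusive
  expect_equal(unname(classify_reliability(cv = 10.01)["cv_band"]), "good")
  expect_equal(unname(classify_reliability(sd_px = 3.3)["sd_band"]),
               "large")
  expect_equal(unname(classify_reliability(sd_px = 1)["sd_band"]),
               "very small")
})

test_that("reliability_row assembles the table row with mm scaling", {
  set.seed(77)
  m <- matrix(rnorm(40, 30, 2), 10, 4)
  row <- reliability_row(m, "jts", "px")
  expect_equal(row$mean_mm, row$mean * 5.1)
  expect_equal(row$sd_mm, row$sd * 5.1)
  expect_true(row$ci_low <= row$icc && row$icc <= row$ci_high)
  row2 <- reliability_row(m, "SC3", "nd")
  expect_true(is.na(row2$mean_mm))
})

test_that("missing cells trigger listwise subject removal", {
  m <- matrix(rnorm(20, 10), 5, 4)
  m[2, 3] <- NA
  expect_warning(r <- icc_1_1(m), "dropping 1 subject")
  expect_equal(r$n, 4)
})
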