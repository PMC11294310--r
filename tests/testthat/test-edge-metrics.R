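test_that("centered crops keep the grid centre and reject parity mismatches", {
  img <- ct_slice(matrix(seq_len(512 * 512), 512, 512))
  c128 <- crop_center(img, 128)
  expect_identical(c128$values, img$values[193:320, 193:320])
  c64 <- crop_center(c128, 64)
  expect_identical(c64$values, img$values[(192 + 33):(192 + 96),
                                          (192 + 33):(192 + 96)])
  expect_identical(crop_center(img, 512)$values, img$values)
  odd <- ct_slice(matrix(0, 9, 9))
  expect_error(crop_center(odd, 4), "parity")
  expect_error(crop_center(odd, 11), "exceeds")
})

test_that("noise estimator averages the two corner ROI SDs", {
  expect_equal(estimate_noise(ct_slice(matrix(7, 128, 128))), 0)
  # two ROIs with different spread: mean-of-SDs convention
  v <- matrix(0, 128, 128)
  rows <- 85:128
  set.seed(1)
  v[rows, 1:44] <- rnorm(44 * 44, sd = 10)
  v[rows, 85:128] <- rnorm(44 * 44, sd = 20)
  got <- estimate_noise(ct_slice(v))
  want <- (sd(v[rows, 1:44]) + sd(v[rows, 85:128])) / 2
  expect_equal(got, want)
  # seeded white field: recovers sigma within the SE of a sample SD
  set.seed(42)
  w <- ct_slice(matrix(rnorm(128 * 128, sd = 10), 128, 128))
  expect_lt(abs(estimate_noise(w) - 10), 0.5)
})

test_that("noise estimator is unbiased over repeated fields", {
  ests <- vapply(1:100, function(s) {
    set.seed(s)
    estimate_noise(ct_slice(matrix(rnorm(128 * 128, sd = 10), 128, 128)))
  }, numeric(1))
  expect_lt(abs(mean(ests) - 10) / 10, 0.01)
})

test_that("background slope noise matches white-noise propagation on white fields", {
  set.seed(11)
  w <- ct_slice(matrix(rnorm(128 * 128, sd = 10), 128, 128), spacing_mm = 0.4)
  got <- estimate_slope_noise(w)
  want <- 10 / (2 * 0.4 * sqrt(2))
  expect_lt(abs(got - want) / want, 0.1)
})

test_that("profiles are 4-row band means with centred mm positions", {
  v <- matrix(0, 64, 64)
  img <- ct_slice(v)
  p <- extract_profiles(img)
  expect_equal(nrow(p), 128)
  h <- dplyr::filter(p, direction == "horizontal")
  expect_equal(h$position_mm, ((1:64) - 32.5) * 0.4)
  # constant image -> constant profiles
  pc <- extract_profiles(ct_slice(matrix(100, 64, 64)))
  expect_true(all(pc$hu == 100))
  # band rows 31..34: set them to 0/100/100/200 -> profile constant 100
  v2 <- matrix(999, 64, 64)
  v2[31, ] <- 0; v2[32, ] <- 100; v2[33, ] <- 100; v2[34, ] <- 200
  h2 <- dplyr::filter(extract_profiles(ct_slice(v2)), direction == "horizontal")
  expect_true(all(h2$hu == 100))
  # one bright column inside the band appears at that column only
  v3 <- matrix(0, 64, 64)
  v3[31:34, 20] <- 80
  h3 <- dplyr::filter(extract_profiles(ct_slice(v3)), direction == "horizontal")
  expect_equal(h3$hu[20], 80)
  expect_true(all(h3$hu[-20] == 0))
})

test_that("amplitude is the mean of background-referenced profile maxima", {
  v <- matrix(0, 64, 64)
  v[31:34, 20] <- 800    # bump seen by the horizontal profile only
  v[40, 31:34] <- 1000   # bump seen by the vertical profile only
  p <- extract_profiles(ct_slice(v))
  expect_equal(profile_amplitude(p), 900)  # mean of the two profile maxima
  flat <- extract_profiles(ct_slice(matrix(5, 64, 64)))
  expect_equal(profile_amplitude(flat), 0)
})

test_that("three-point regression slope equals the central difference and the OLS oracle", {
  # linear ramp: exact slope everywhere
  x <- seq(0, 10, by = 0.4)
  sc <- slope_curve(x, 5 * x)
  expect_true(all(abs(sc$slope_hu_mm - 5) < 1e-12))
  # worked 3-point example
  sc3 <- slope_curve(c(0, 0.4, 0.8), c(0, 0, 6))
  expect_equal(sc3$slope_hu_mm, 7.5)
  # quadratic sampled at uniform spacing: slope at x is exactly 2x
  y <- x^2
  scq <- slope_curve(x, y)
  expect_equal(scq$slope_hu_mm, 2 * scq$position_mm, tolerance = 1e-12)
  # random profiles vs a generic least-squares fit of each triple
  set.seed(3)
  for (rep in 1:20) {
    yy <- rnorm(15)
    xx <- seq_along(yy) * 0.4
    got <- slope_curve(xx, yy)$slope_hu_mm
    want <- vapply(2:(length(yy) - 1), function(i)
      ols_slope(xx[(i - 1):(i + 1)], yy[(i - 1):(i + 1)]), numeric(1))
    expect_equal(got, want, tolerance = 1e-12)
  }
  expect_error(slope_curve(c(0, 1), c(0, 1)), "at least 3")
  expect_error(slope_curve(c(0, 1, 3), c(0, 1, 2)), "uniform")
})

test_that("transition maxima: trapezoid with a distinct shelf scores 8", {
  # synthetic noise-free profile: lumen 1900, wall shelf 500, water 0 with
  # sharp steps at the nominal radii; the 2 mm wall leaves a sampled
  # zero-slope shelf between the two transitions
  pos <- ((1:64) - 32.5) * 0.4
  ph <- phantom_spec(4, 37, wall_mm = 2)  # r_in 2, r_out 4
  hu <- vapply(pos, function(x) {
    a <- abs(x)
    if (a < 2) 1900 else if (a < 4) 500 else 0
  }, numeric(1))
  sl <- slope_curve(pos, hu)
  tr <- find_transition_maxima(sl, ph, noise_sd = 1, spacing_mm = 0.4)
  expect_equal(nrow(tr), 4)
  expect_equal(sum(tr$visible), 4)   # 4 per profile, 8 over both
  # symmetry: left and right maxima agree
  expect_equal(tr$slope_hu_mm[tr$boundary == "outer"][1],
               tr$slope_hu_mm[tr$boundary == "outer"][2], tolerance = 1e-9)
  expect_equal(tr$slope_hu_mm[tr$boundary == "inner"][1],
               tr$slope_hu_mm[tr$boundary == "inner"][2], tolerance = 1e-9)
})

test_that("iso-attenuating lumen leaves only the outer transitions visible", {
  pos <- ((1:64) - 32.5) * 0.4
  ph <- phantom_spec(4, 9.25)
  # lumen HU == wall HU: single step at the outer boundary
  hu <- vapply(pos, function(x) if (abs(x) < 3) 500 else 0, numeric(1))
  sl <- slope_curve(pos, hu)
  tr <- find_transition_maxima(sl, ph, noise_sd = 1, spacing_mm = 0.4)
  expect_equal(sum(tr$visible[tr$boundary == "outer"]), 2)
  expect_equal(sum(tr$visible[tr$boundary == "inner"]), 0)
})

test_that("zero-contrast image scores 0", {
  ph <- phantom_spec(3, 0)
  flat <- ct_slice(matrix(0, 512, 512))
  a <- analyze_image(flat, ph)
  expect_equal(a$slope_score, 0)
  expect_equal(a$amplitude, 0)
  expect_equal(a$noise_sd, 0)
})

test_that("full chain on a noise-free high-contrast slice finds every transition", {
  # ultrasharp kernel: both wall boundaries resolve at full iodine contrast
  ph <- phantom_spec(5, 37)
  a <- analyze_image(sim_noise_free(5, 37, "Qr72"), ph)
  expect_equal(a$slope_score, 8)
  expect_gt(a$mean_slope_maximum, 0)
  expect_equal(nrow(a$transitions), 8)
  # sharp kernel resolves the wall at the intermediate concentration, where
  # the lumen-wall contrast no longer drowns the water-wall transition
  ph2 <- phantom_spec(5, 18.5)
  a2 <- analyze_image(sim_noise_free(5, 18.5, "Qr60"), ph2)
  expect_equal(a2$slope_score, 8)
  # at full concentration the sharp kernel loses the outer maxima to the
  # blooming of the 8x stronger lumen edge
  a3 <- analyze_image(sim_noise_free(5, 37, "Qr60"), ph)
  expect_equal(a3$slope_score, 4)
  expect_true(all(tidy(a3)$visible[tidy(a3)$boundary == "inner"]))
  # determinism: rerun gives an identical result
  b <- analyze_image(sim_noise_free(5, 37, "Qr72"), ph)
  expect_identical(glance(a), glance(b))
})

test_that("rotating the slice by 90 degrees leaves the metrics unchanged", {
  ph <- phantom_spec(3, 37)
  img <- sim_noise_free(3, 37, "Qr60")
  rot <- ct_slice(rot90(img$values), img$spacing_mm)
  a <- analyze_image(img, ph)
  b <- analyze_image(rot, ph)
  expect_equal(a$amplitude, b$amplitude, tolerance = 1e-9)
  expect_equal(a$mean_slope_maximum, b$mean_slope_maximum, tolerance = 1e-9)
  expect_identical(a$slope_score, b$slope_score)
  # profiles swap between directions (up to reversal)
  ah <- dplyr::filter(a$profiles, direction == "horizontal")$hu
  bv <- dplyr::filter(b$profiles, direction == "vertical")$hu
  expect_true(isTRUE(all.equal(ah, bv, tolerance = 1e-9)) ||
              isTRUE(all.equal(ah, rev(bv), tolerance = 1e-9)))
})

test_that("sharpness response rises to the plateau then stays within 10%", {
  kernels <- c("Qr36", "Qr44", "Qr60", "Qr64", "Qr72", "Qr76")
  ph <- phantom_spec(5, 37)
  ms <- vapply(kernels, function(k)
    analyze_image(sim_noise_free(5, 37, k), ph)$mean_slope_maximum,
    numeric(1))
  # strictly increasing up to the plateau kernel
  expect_true(all(diff(ms[1:3]) > 0))
  hi <- ms[3:6]
  expect_lt((max(hi) - min(hi)) / max(hi), 0.10)
})

test_that("tidy and glance expose the analysis as tibbles", {
  ph <- phantom_spec(3, 37)
  a <- analyze_image(sim_noise_free(3, 37, "Qr60", n = 256), ph)
  td <- tidy(a)
  expect_s3_class(td, "tbl_df")
  expect_setequal(unique(td$boundary), c("outer", "inner"))
  g <- glance(a)
  expect_identical(nrow(g), 1L)
  expect_named(g, c("noise_sd", "slope_noise_sd", "amplitude",
                    "mean_slope_maximum", "slope_score"))
})
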