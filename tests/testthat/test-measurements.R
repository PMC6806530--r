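test_that("YII formula, bounds and error handling", {
  expect_equal(compute_yii(0.8, 0.8), 0)
  expect_equal(compute_yii(0, 1), 1)
  expect_equal(compute_yii(0.4, 0.8), 0.5)

  # bounds and monotonicity over a grid of valid (F, F'M) pairs
  FMp <- 0.9
  Fs <- seq(0, FMp, length.out = 25)
  y <- compute_yii(Fs, FMp)
  expect_true(all(y >= 0 & y <= 1))
  expect_true(all(diff(y) < 0))  # strictly decreasing in F

  expect_error(compute_yii(0.5, 0), "positive")
  expect_error(compute_yii(-0.1, 1), "non-negative")
  expect_warning(yv <- compute_yii(1.2, 1), "exceeds")
  expect_lt(yv, 0)
})

test_that("reflectance calibration identities and per-band errors", {
  bands <- seq(400, 900, length.out = 6)
  raw <- array(runif(5 * 4 * 6), dim = c(5, 4, 6))
  white <- seq(0.8, 1.3, length.out = 6)
  dark <- rep(0.05, 6)

  expect_equal(calibrate_reflectance(
    array(rep(white, each = 20), c(5, 4, 6)), white, dark, bands)$data,
    array(1, c(5, 4, 6)))
  expect_equal(calibrate_reflectance(
    array(rep(dark, each = 20), c(5, 4, 6)), white, dark, bands)$data,
    array(0, c(5, 4, 6)))
  mid <- array(rep((white + dark) / 2, each = 20), c(5, 4, 6))
  expect_equal(calibrate_reflectance(mid, white, dark, bands)$data,
               array(0.5, c(5, 4, 6)))

  # idempotence: calibrating a calibrated cube against white=1, dark=0
  cal <- calibrate_reflectance(raw, white, dark, bands)
  cal2 <- calibrate_reflectance(cal, 1, 0)
  expect_equal(cal2$data, cal$data)

  bad_white <- white; bad_white[3] <- dark[3]
  expect_error(calibrate_reflectance(raw, bad_white, dark, bands), "band 3")
})

test_that("region sampling matches the pixel-counting oracle", {
  set.seed(8)
  vals <- matrix(runif(30 * 40), 30, 40)
  cube <- spectral_cube(c(500, 600), array(c(vals, 2 * vals), c(30, 40, 2)))

  shapes <- list(region_circle(20, 15, 6.5),
                 region_circle(2, 2, 3),          # clipped at the border
                 region_line(c(5, 5), c(35, 25), 4))
  for (sh in shapes) {
    got <- sample_region_spectrum(cube, sh)
    oracle <- region_mean_oracle(vals, sh)
    expect_equal(got$n_pixels, oracle$n)
    expect_equal(got$spectrum[1], oracle$mean)
    expect_equal(got$spectrum[2], 2 * oracle$mean)
    gt <- sample_region_temperature(vals, sh)
    expect_equal(gt$mean_temp, oracle$mean)
    expect_equal(gt$n_pixels, oracle$n)
  }

  # constant field: any shape returns the constant
  ucube <- spectral_cube(c(500, 600), array(0.3, c(20, 20, 2)))
  expect_equal(sample_region_spectrum(ucube, region_circle(10, 10, 4))$spectrum,
               c(0.3, 0.3))

  # half-over-boundary with equal pixel counts averages exactly
  half <- matrix(rep(c(0.2, 0.4), each = 200), 20, 20)  # columns 1:10 = 0.2
  hcube <- spectral_cube(c(500, 600), array(half, c(20, 20, 2)))
  # circle centered between columns 10 and 11: equal pixels on both sides
  sh <- region_circle(10.5, 10, 4.4)
  got <- sample_region_spectrum(hcube, sh)
  expect_equal(got$spectrum, c(0.3, 0.3))
  t20_30 <- matrix(rep(c(20, 30), each = 200), 20, 20)
  expect_equal(sample_region_temperature(t20_30, sh)$mean_temp, 25)

  # sampling linearity: mean(region, A + B) = mean(region, A) + mean(region, B)
  cubeA <- spectral_cube(500, array(runif(400), c(20, 20, 1)))
  cubeB <- spectral_cube(500, array(runif(400), c(20, 20, 1)))
  cubeS <- spectral_cube(500, array(cubeA$data + cubeB$data, c(20, 20, 1)))
  sh2 <- region_circle(9, 9, 5.2)
  expect_equal(sample_region_spectrum(cubeS, sh2)$spectrum,
               sample_region_spectrum(cubeA, sh2)$spectrum +
                 sample_region_spectrum(cubeB, sh2)$spectrum)

  # no intersection -> error
  expect_error(sample_region_spectrum(ucube, region_circle(100, 100, 2)),
               "intersect")
  expect_error(region_circle(1, 1, 0), "positive")
  expect_error(region_line(c(1, 1), c(1, 1)), "distinct")
})

test_that("red-edge derivative: flat, ramp, logistic step", {
  bands <- seq(400, 900, length.out = 56)

  flat <- rep(0.4, 56)
  rf <- red_edge_derivative(flat, bands)
  expect_equal(rf$max_derivative, 0)
  expect_equal(rf$wavelength, bands[bands >= 690][1])  # tie -> lowest band

  ramp <- 0.002 * bands
  rr <- red_edge_derivative(ramp, bands)
  expect_equal(rr$max_derivative, 0.002, tolerance = 1e-12)
  interior <- rr$derivative[2:55]
  expect_true(all(abs(interior - 0.002) < 1e-12))

  logi <- 0.1 + 0.4 / (1 + exp(-(bands - 710) / 5))
  rl <- red_edge_derivative(logi, bands)
  spacing <- diff(bands)[1]
  expect_lt(abs(rl$wavelength - 710), spacing + 1e-9)

  expect_error(red_edge_derivative(flat, bands, c(300, 700)), "outside")
  expect_error(red_edge_derivative(flat[1:10], bands), "mismatch")
})

test_that("records round-trip through CSV and JSON; PNG renders", {
  df <- data.frame(site_index = 1:3, x = c(0.1, 0.2, 0.3),
                   y = c(0.4, 0.5, 0.6), z = c(0.3, 0.31, 0.29),
                   YII = c(0.71, 0.64, 0.58))
  fc <- tempfile(fileext = ".csv")
  export_records(df, fc, "csv")
  back <- import_records(fc, "csv")
  expect_equal(back, df, tolerance = 1e-7)
  expect_identical(names(back), c("site_index", "x", "y", "z", "YII"))

  fj <- tempfile(fileext = ".json")
  export_records(df, fj, "json")
  backj <- import_records(fj, "json")
  expect_equal(backj, df, tolerance = 1e-7)

  fp <- tempfile(fileext = ".png")
  img <- matrix(runif(400, 20, 30), 20, 20)
  export_records(data.frame(px = c(5, 10), py = c(5, 15)), fp, "png",
                 image = img, shapes = list(region_circle(10, 10, 4)))
  expect_true(file.exists(fp))
  expect_gt(file.info(fp)$size, 0)

  expect_error(export_records(df[0, ], tempfile(), "csv"), "no records")
})
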