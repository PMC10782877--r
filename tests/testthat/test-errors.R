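test_that("identity configurations are exact no-ops", {
  sp <- gauss_spectrum(146)
  expect_equal(add_gaussian_noise(sp, NULL)$intensity, sp$intensity)
  expect_equal(shift_wavelength(sp, 0)$intensity, sp$intensity)
  expect_equal(compress_spectrum(sp, 0)$intensity, sp$intensity)
  expect_equal(rotate_spectrum(sp, 0)$intensity, sp$intensity)
  expect_equal(scale_spectrum(sp, 0)$intensity, sp$intensity)
  ds <- toy_dataset()
  same <- corrupt_dataset(ds, character(0), seed = 1)
  expect_equal(same$gray, ds$gray)
})

test_that("noise hits the requested RMS signal-to-noise ratio", {
  sp <- gauss_spectrum(300)
  expect_identical(add_gaussian_noise(sp, 35, seed = 7),
                   add_gaussian_noise(sp, 35, seed = 7))
  set.seed(42)
  ratios <- replicate(1000, {
    noisy <- add_gaussian_noise(sp, 35)
    sqrt(mean(sp$intensity^2)) / sqrt(mean((noisy$intensity - sp$intensity)^2))
  })
  # harmonic-style pooled estimate of the realised SNR over 1000 draws
  snr_hat <- sqrt(1 / mean(1 / ratios^2))
  expect_gt(snr_hat, 33)
  expect_lt(snr_hat, 37)
  expect_error(add_gaussian_noise(sp, -1), "positive")
})

test_that("wavelength shifts relabel, interpolate and zero-fill as specified", {
  n <- 146L
  wl <- wavelength_grid(n)
  h <- diff(wl)[1]
  # integer-pixel shift: exact column relabelling with zero fill
  sp <- gauss_spectrum(n)
  k <- 5L
  right <- shift_wavelength(sp, k * h)
  expect_equal(right$intensity[(k + 1):n], sp$intensity[1:(n - k)], tolerance = 1e-9)
  expect_equal(right$intensity[1:k], rep(0, k))
  # piecewise-linear spectra round-trip exactly under fractional shifts
  lin <- drs_spectrum(wl, seq(2, 5, length.out = n))
  back <- shift_wavelength(shift_wavelength(lin, -4.8), 4.8)
  interior <- 30:(n - 30)
  expect_equal(back$intensity[interior], lin$intensity[interior], tolerance = 1e-9)
  # smooth fixtures round-trip within the linear-interpolation error bound
  sm <- gauss_spectrum(n, width = 40)
  back2 <- shift_wavelength(shift_wavelength(sm, -4.8), 4.8)
  curv <- max(abs(diff(sm$intensity, differences = 2)))  # ~ h^2 |f''|
  expect_lt(max(abs(back2$intensity[interior] - sm$intensity[interior])), curv)
  expect_error(shift_wavelength(sp, 1000), "span")
})

test_that("tail compression squeezes content inward and clamps the margins", {
  n <- 146L
  wl <- wavelength_grid(n)
  sp <- gauss_spectrum(n)
  expect_equal(compress_spectrum(sp, 0)$intensity, sp$intensity)
  const <- drs_spectrum(wl, rep(2, n))
  expect_equal(compress_spectrum(const, 1)$intensity, rep(2, n))
  # a peak at lambda_p relocates by the affine-map displacement
  peak_wl <- 520
  sp2 <- gauss_spectrum(n, centre = peak_wl, width = 10)
  t <- 3
  out <- compress_spectrum(sp2, t)
  span <- diff(range(wl))
  expected_peak <- (wl[1] + t) + (peak_wl - wl[1]) / span * (span - 2 * t)
  got_peak <- as.numeric(wl[which.max(out$intensity)])
  expect_lt(abs(got_peak - expected_peak), 2 * diff(wl)[1])
  expect_gt(got_peak, peak_wl)  # left-of-centre peaks move toward the centre
  expect_error(compress_spectrum(sp, 100), "span")
})

test_that("rotation ramps from (1+a) to (1-a) about an unchanged midpoint", {
  n <- 145L  # odd length, exact midpoint column
  sp <- gauss_spectrum(n)
  out <- rotate_spectrum(sp, a = 0.05)
  expect_equal(out$intensity[1], 1.05 * sp$intensity[1])
  expect_equal(out$intensity[n], 0.95 * sp$intensity[n])
  mid <- (n + 1) / 2
  expect_equal(out$intensity[mid], sp$intensity[mid])
  # the ramp has mean one: a constant spectrum keeps its band integral
  const <- drs_spectrum(wavelength_grid(n), rep(4, n))
  expect_equal(mean(rotate_spectrum(const, a = 0.05)$intensity), 4, tolerance = 1e-12)
  expect_identical(rotate_spectrum(sp, 0.05, seed = 3), rotate_spectrum(sp, 0.05, seed = 3))
})

test_that("systematic scaling draws one bounded factor per spectrum", {
  sp <- gauss_spectrum(100)
  set.seed(9)
  for (i in 1:20) {
    out <- scale_spectrum(sp, 0.05)
    f <- out$intensity / sp$intensity
    expect_lt(diff(range(f)), 1e-12)           # one factor for every column
    expect_gte(f[1], 1)
    expect_lte(f[1], 1.05)
    expect_equal(mean(out$intensity), f[1] * mean(sp$intensity))
  }
})

test_that("augmentation rows apply the marked corruptions in order", {
  rows <- augmentation_rows()
  expect_equal(dim(rows), c(14, 5))
  expect_false(any(rows[1, ]))
  expect_true(all(rows[11, ]))
  expect_equal(unname(rowSums(rows)[2:6]), rep(1, 5))
  ds <- toy_dataset()
  r1 <- apply_error_row(ds, 1, seed = 5)
  expect_equal(r1$gray, ds$gray)
  expect_equal(r1$error_tag, "row01")
  r11 <- apply_error_row(ds, 11, seed = 5)
  expect_equal(dim(r11$gray), dim(ds$gray))
  expect_equal(r11$labels, ds$labels)
  expect_equal(r11$group_id, ds$group_id)
  # row 11 compounds all five errors at the compounded SNR: identical to the
  # explicit corruption call with the same seed
  manual <- corrupt_dataset(ds, c("noise", "scale", "shift", "compress", "rotate"),
                            seed = 5, error_tag = "row11")
  expect_equal(r11$gray, manual$gray)
  expect_error(apply_error_row(ds, 15), "unknown")
})

test_that("corruption is bit-reproducible under a fixed seed", {
  ds <- toy_dataset()
  a <- corrupt_dataset(ds, c("noise", "rotate", "scale"), seed = 123)
  b <- corrupt_dataset(ds, c("noise", "rotate", "scale"), seed = 123)
  expect_identical(a, b)
  c2 <- corrupt_dataset(ds, c("noise", "rotate", "scale"), seed = 124)
  expect_false(identical(a$gray, c2$gray))
})

test_that("the augmented training set concatenates all fourteen rows", {
  small <- generate_grid_dataset(5, 2, wavelength = wavelength_grid(50))
  expect_warning(aug <- build_augmented_training_set(small, seed = 1), "expected 1520")
  expect_equal(aug$n_records, 14 * 10)
  expect_equal(length(aug$datasets), 14)
  expect_equal(aug$datasets[[1]]$gray, small$gray)  # row 1 is the base data
  tags <- vapply(aug$datasets, `[[`, "", "error_tag")
  expect_equal(tags, rownames(augmentation_rows()))
})
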