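test_that("slope series are per-column first differences", {
  expect_equal(slope_series(rep(2, 10)), rep(0, 9))
  expect_equal(slope_series(seq(1, 10, by = 0.5)), rep(0.5, 18))
  expect_length(slope_series(stats::runif(50)), 49)
  expect_error(slope_series(1), "two columns")
})

test_that("spectrum length 1 counts columns strictly above quarter-max", {
  expect_equal(spectrum_length_1(rep(7, 20)), 20)
  expect_equal(spectrum_length_1(c(0, 10, 100, 10, 0)), 1)
  expect_equal(spectrum_length_1(c(30, 10, 100, 30, 0)), 3)
  expect_equal(spectrum_length_1(rep(0, 5)), 0)
})

test_that("spectrum length 2 finds the highest non-global local maximum", {
  y <- rep(0, 300)
  y[100] <- 10; y[99] <- 5; y[101] <- 5
  y[250] <- 8; y[249] <- 4; y[251] <- 4
  expect_equal(spectrum_length_2(y), 150)
  expect_equal(spectrum_length_2(seq_len(100)), 0)     # strictly monotone
  # three local maxima: brute-force scan oracle
  set.seed(21)
  for (rep in 1:20) {
    z <- as.numeric(stats::filter(stats::runif(120), rep(1 / 5, 5), sides = 2))
    z[is.na(z)] <- 0
    locs <- which(diff(sign(diff(z))) == -2) + 1
    got <- spectrum_length_2(z)
    if (length(locs) >= 2) {
      peak <- locs[which.max(z[locs])]
      others <- locs[locs != peak]
      expect_equal(got, abs(peak - others[which.max(z[others])]))
    } else {
      expect_equal(got, 0)
    }
  }
})

test_that("skewness is the biased third standardised moment", {
  y <- c(1, 2, 9)
  m <- mean(y)
  expected <- mean((y - m)^3) / mean((y - m)^2)^1.5
  expect_equal(spectral_skewness(y), expected)
  expect_equal(spectral_skewness(c(1, 2, 3, 4, 5)), 0)       # symmetric multiset
  expect_equal(spectral_skewness(3 * y), spectral_skewness(y))
  expect_warning(s0 <- spectral_skewness(rep(1, 5)), "zero-variance")
  expect_equal(s0, 0)
})

test_that("feature vectors have the frozen 35-entry layout", {
  expect_length(wir_feature_names(), 35)
  sp <- gauss_spectrum(146)
  set <- split_to_channels(sp)
  v <- extract_features(set, probe_geometry(2L))
  expect_length(v, 35)
  expect_named(v, wir_feature_names())
  expect_true(all(is.finite(v)))
  expect_equal(unname(v["probe_id"]), 2)
  expect_identical(v, extract_features(set, probe_geometry(2L)))
})

test_that("scaling all channels moves only the scale-covariant features", {
  sp <- gauss_spectrum(146)
  set <- split_to_channels(sp)
  v1 <- extract_features(set)
  set2 <- split_to_channels(drs_spectrum(sp$wavelength, 2.5 * sp$intensity, "gray"))
  v2 <- extract_features(set2)
  covariant <- grep("^(max|mean|sd|slope)_", wir_feature_names(), value = TRUE)
  exact <- c("spectrum_length_1", "spectrum_length_2", "probe_id")
  skews <- grep("^skew_", wir_feature_names(), value = TRUE)
  expect_equal(v2[covariant], 2.5 * v1[covariant], tolerance = 1e-12)
  expect_identical(v2[exact], v1[exact])
  expect_equal(v2[skews], v1[skews], tolerance = 1e-12)
})

test_that("intensity features are robust to a 4.8 nm shift on smooth fixtures", {
  sp <- gauss_spectrum(585, centre = 540, width = 25)
  v1 <- extract_features(split_to_channels(sp))
  shifted <- shift_wavelength(sp, -4.8)
  v2 <- extract_features(split_to_channels(shifted))
  for (f in c("max_gray", "mean_gray", "sd_gray"))
    expect_lt(abs(v2[f] - v1[f]) / v1[f], 0.01)
  expect_lte(abs(v2["spectrum_length_1"] - v1["spectrum_length_1"]), 2)
})

test_that("dataset feature tables agree with single-set extraction", {
  ds <- toy_dataset()
  tab <- drs_features(ds)
  expect_equal(dim(tab), c(30, 35))
  expect_false(anyNA(tab))
  i <- 17L
  set <- split_to_channels(drs_spectrum(ds$wavelength, ds$gray[i, ], "gray"))
  v <- extract_features(set, probe_geometry(ds$probe_id))
  expect_equal(unlist(tab[i, ]), v, tolerance = 1e-12)
})

test_that("features stay finite on randomly rendered fixtures", {
  set.seed(31)
  for (i in 1:10) {
    y <- as.numeric(stats::filter(stats::runif(146, 0.1, 1), rep(1 / 7, 7), sides = 2))
    y[is.na(y)] <- 0.1
    set <- split_to_channels(drs_spectrum(wavelength_grid(146), y, "gray"))
    img <- render_image(set, m_rows = 4L)
    back <- preprocess_image(img, wavelength_grid(146), cutoff = 0L)
    expect_true(all(is.finite(extract_features(back))))
  }
})
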