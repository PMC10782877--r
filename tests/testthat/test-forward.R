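test_that("forward spectra are deterministic, positive, and ordered in the labels", {
  a <- simulate_reflectance(1.2, 8)
  b <- simulate_reflectance(1.2, 8)
  expect_identical(a, b)
  expect_true(all(a$intensity > 0))
  # strictly decreasing in mu_a at every wavelength, on a 5 x 5 label grid
  mua <- seq(0.44, 2.45, length.out = 5)
  mus <- seq(6.53, 9.58, length.out = 5)
  for (s in mus) {
    spectra <- sapply(mua, function(m) simulate_reflectance(m, s)$intensity)
    expect_true(all(apply(spectra, 1, diff) < 0))
  }
  # higher mu_s' raises intensity at every wavelength (fixed sign)
  lo <- simulate_reflectance(1.2, 6.53)$intensity
  hi <- simulate_reflectance(1.2, 9.58)$intensity
  expect_true(all(hi > lo))
  # band-integrated intensity strictly lower for the higher mu_a
  expect_lt(sum(simulate_reflectance(2.45, 8)$intensity),
            sum(simulate_reflectance(0.44, 8)$intensity))
})

test_that("chromophore shapes are positive with band mean one, so labels are band averages", {
  wl <- wavelength_grid()
  ch <- chromophore_model()
  shpA <- absorption_shape(ch, wl)
  shpS <- scattering_shape(ch, wl)
  expect_true(all(shpA > 0) && all(shpS > 0))
  expect_equal(mean(shpA), 1, tolerance = 1e-9)
  expect_equal(mean(shpS), 1, tolerance = 1e-9)
  expect_equal(mean(1.7 * shpA), 1.7, tolerance = 1e-9)
})

test_that("weak-absorption violations are warned about but computed", {
  expect_warning(simulate_reflectance(60, 7), "validity")
})

test_that("the label grid covers the configured ranges exactly", {
  ds <- toy_dataset()
  expect_equal(range(ds$labels$mu_a), c(0.44, 2.45))
  expect_equal(range(ds$labels$mu_s_prime), c(6.53, 9.58))
  small <- generate_grid_dataset(2, 2, wavelength = wavelength_grid(50))
  expect_equal(nrow(small$gray), 4)
  expect_error(generate_grid_dataset(0, 2), "at least one")
  expect_error(generate_grid_dataset(2, 2, mu_a_range = c(-1, 2)), "range")
})

test_that("the generator multiplies by the standard and groups by titration", {
  wl <- wavelength_grid(60)
  ds <- generate_grid_dataset(3, 2, wavelength = wl)
  fwd_raw <- simulate_reflectance(ds$labels$mu_a[1], ds$labels$mu_s_prime[1],
                                  wavelength = wl)
  std <- default_standard(wl)
  expect_equal(ds$gray[1, ], fwd_raw$intensity * std$intensity, tolerance = 1e-12)
  expect_equal(length(unique(ds$group_id)), 3)  # one group per mu_a level
  same_mua <- ds$labels$mu_a == ds$labels$mu_a[1]
  expect_equal(length(unique(ds$group_id[same_mua])), 1)
})

test_that("the forward closure reproduces the generator's spectra", {
  wl <- wavelength_grid(60)
  ds <- generate_grid_dataset(2, 2, wavelength = wl)
  fwd <- forward_closure(standard = attr(ds, "standard"), wavelength = wl)
  for (i in 1:4)
    expect_equal(fwd(ds$labels$mu_a[i], ds$labels$mu_s_prime[i]), ds$gray[i, ],
                 tolerance = 1e-12)
})
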