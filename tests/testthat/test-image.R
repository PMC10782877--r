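make_image <- function(px_fun, m = 4L, n = 20L, ti = 0.5, iso = 400) {
  px <- array(0L, c(m, n, 3L))
  for (c in 1:3) px[, , c] <- px_fun(c)
  drs_image(px, ti, iso)
}

test_that("thresholding zeroes sub-cutoff channels independently and is idempotent", {
  img <- make_image(function(c) c(0L, 20L, 9L)[c], m = 1L, n = 1L)
  th <- threshold_image(img)
  expect_equal(as.integer(th$pixels), c(0L, 20L, 0L))
  img2 <- make_image(function(c) 10L, m = 1L, n = 1L)
  expect_equal(as.integer(threshold_image(img2)$pixels), c(10L, 10L, 10L))
  img3 <- make_image(function(c) 9L, m = 1L, n = 1L)
  expect_equal(as.integer(threshold_image(img3)$pixels), c(0L, 0L, 0L))
  set.seed(1)
  img4 <- make_image(function(c) matrix(sample(0:255, 80, TRUE), 4, 20))
  expect_identical(threshold_image(threshold_image(img4)), threshold_image(img4))
  px <- array(0.5, c(2, 2, 3))
  expect_error(drs_image(px, 1, 100), "integers")
})

test_that("exposure normalisation follows Iraw / (Ti * ISO)", {
  img <- make_image(function(c) 120L, m = 1L, n = 1L, ti = 0.5, iso = 400)
  expect_equal(as.numeric(normalize_exposure(img)), rep(0.6, 3))
  img0 <- make_image(function(c) 0L, m = 2L, n = 3L)
  expect_true(all(normalize_exposure(img0) == 0))
  # (Ti, ISO) and (2 Ti, ISO / 2) give identical normalised arrays
  set.seed(2)
  vals <- matrix(sample(0:255, 60, TRUE), 3, 20)
  a <- make_image(function(c) vals, m = 3L, ti = 0.25, iso = 800)
  b <- make_image(function(c) vals, m = 3L, ti = 0.5, iso = 400)
  expect_identical(normalize_exposure(a), normalize_exposure(b))
  bad <- make_image(function(c) 1L)
  bad$exposure_time_s <- -1
  expect_error(normalize_exposure(bad), "calibration")
})

test_that("collapsing sums rows per channel and conserves total intensity", {
  wl <- wavelength_grid(20)
  one_row <- make_image(function(c) matrix(c * (1:20), 1, 20, byrow = TRUE), m = 1L)
  set <- collapse_to_spectra(normalize_exposure(one_row), wl)
  norm <- normalize_exposure(one_row)
  expect_equal(set$red, norm[1, , 1])
  ones <- make_image(function(c) 1L, m = 3L)
  set3 <- collapse_to_spectra(normalize_exposure(ones), wl)
  expect_equal(set3$red, rep(3 / (0.5 * 400), 20))
  set.seed(3)
  rnd <- make_image(function(c) matrix(sample(0:255, 80, TRUE), 4, 20))
  nr <- normalize_exposure(rnd)
  s <- collapse_to_spectra(nr, wl)
  expect_equal(sum(s$gray), sum(nr), tolerance = 1e-12)
  expect_error(collapse_to_spectra(nr, wavelength_grid(21)), "dimension")
})

test_that("identical image and metadata produce a bit-identical spectrum set", {
  set.seed(4)
  img <- make_image(function(c) matrix(sample(0:255, 200, TRUE), 10, 20), m = 10L)
  wl <- wavelength_grid(20)
  std <- default_standard(wl)
  a <- preprocess_image(img, wl, std, "divide")
  b <- preprocess_image(img, wl, std, "divide")
  expect_identical(a, b)
})

test_that("rendered images survive the preprocessing round trip within quantisation", {
  sp <- gauss_spectrum(146, width = 40)
  set <- split_to_channels(sp)
  img <- render_image(set, m_rows = 6L, exposure_time_s = 0.5, iso_speed = 100,
                      peak_dn = 250L)
  expect_true(all(img$pixels >= 0 & img$pixels <= 255))
  back <- preprocess_image(img, wavelength_grid(146), cutoff = 0L, smooth_window = 1L)
  # per-column relative shape error bounded by the 8-bit quantisation step
  # (columns above half-max: rounding error <= 0.5/(0.5 peak) + 0.5/peak)
  rel <- abs(back$gray / max(back$gray) - set$gray / max(set$gray))
  keep <- set$gray > 0.5 * max(set$gray)
  expect_lt(max(rel[keep] / (set$gray[keep] / max(set$gray))), 2 / 250)
})

test_that("image metadata round-trips through PNG plus sidecar", {
  sp <- gauss_spectrum(64)
  img <- render_image(split_to_channels(sp), m_rows = 3L,
                      exposure_time_s = 1 / 30, iso_speed = 200, probe_id = 2L)
  f <- tempfile(fileext = ".png")
  write_drs_image(img, f)
  back <- read_drs_image(f)
  expect_equal(back$exposure_time_s, img$exposure_time_s)
  expect_equal(back$iso_speed, img$iso_speed)
  expect_equal(back$probe_id, img$probe_id)
  expect_equal(back$pixels, img$pixels, ignore_attr = TRUE)
})
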