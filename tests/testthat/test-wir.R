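test_that("WIR fits are reproducible and respect the training label range", {
  ds <- toy_dataset()
  feats <- drs_features(ds)
  m1 <- wir(feats, ds$labels)
  m2 <- wir(feats, ds$labels)
  held <- drs_features(corrupt_dataset(ds, "noise", seed = 2))
  expect_identical(predict(m1, held), predict(m2, held))
  p <- predict(m1, held)
  expect_true(all(p$mu_a >= min(ds$labels$mu_a) & p$mu_a <= max(ds$labels$mu_a)))
  expect_true(all(p$mu_s_prime >= min(ds$labels$mu_s_prime) &
                  p$mu_s_prime <= max(ds$labels$mu_s_prime)))
})

test_that("WIR refuses mismatched feature layouts", {
  ds <- toy_dataset()
  feats <- drs_features(ds)
  bad <- feats
  names(bad)[1] <- "nonsense"
  expect_error(wir(bad, ds$labels), "layout")
  m <- wir(feats, ds$labels)
  expect_error(predict(m, bad), "layout")
  expect_error(predict(m, feats[, 1:10]), "layout")
})

test_that("feature importances are a normalised ranking", {
  m <- wir(toy_dataset())
  imp <- feature_importances(m)
  for (target in c("mu_a", "mu_s_prime")) {
    d <- imp[[target]]
    expect_equal(nrow(d), 35)
    expect_true(all(d$importance >= 0))
    expect_equal(sum(d$importance), 1, tolerance = 1e-9)
    expect_true(!is.unsorted(rev(d$importance)))
  }
  expect_output(print(summary(m)), "Top features")
})

test_that("WIR model bundles round-trip through disk", {
  ds <- toy_dataset()
  feats <- drs_features(ds)
  m <- wir(feats, ds$labels)
  dir <- tempfile("wirmodel")
  write_wir(m, dir)
  back <- read_wir(dir)
  expect_equal(predict(back, feats), predict(m, feats), tolerance = 1e-12)
  # a tampered manifest is refused
  man <- jsonlite::read_json(file.path(dir, "manifest.json"), simplifyVector = TRUE)
  man$feature_names[1] <- "nonsense"
  jsonlite::write_json(man, file.path(dir, "manifest.json"), auto_unbox = TRUE)
  expect_error(read_wir(dir), "mismatched")
})

test_that("the dense NN baseline has the stated architecture and reproduces", {
  ds <- toy_dataset()
  feats <- as.matrix(drs_features(ds))
  nn <- dense_nn(feats, ds$labels, epochs = 40, seed = 1)
  net <- nn$nets$mu_a
  expect_length(net$W, 3)                    # two hidden layers plus output
  expect_equal(dim(net$W[[1]]), c(35, 25))
  expect_equal(dim(net$W[[2]]), c(25, 25))
  expect_equal(dim(net$W[[3]]), c(25, 1))
  p1 <- predict(nn, feats)
  p2 <- predict(dense_nn(feats, ds$labels, epochs = 40, seed = 1), feats)
  expect_identical(p1, p2)
  expect_true(all(is.finite(p1$mu_a)) && all(is.finite(p1$mu_s_prime)))
  raw <- raw_spectra_matrix(ds)
  expect_equal(ncol(raw), 4 * length(ds$wavelength))
  nn_raw <- dense_nn(raw, ds$labels, input_mode = "raw_spectra", epochs = 15, seed = 1)
  expect_true(all(is.finite(predict(nn_raw, raw)$mu_a)))
  expect_error(predict(nn_raw, raw[, 1:10]), "shape")
})
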