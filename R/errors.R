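#' Use-error configuration
#'
#' Magnitudes of the six spectral corruptions that common device use-errors
#' produce. Defaults follow the simulation study conditions: detector noise
#' at a linear RMS signal-to-noise ratio of 35:1 (45:1 when all errors are
#' compounded, for inversion-convergence comparability), a silent wavelength
#' shift of 4.8 nm to the left, a 1 nm inward compression at each tail, a
#' tail rotation of up to 5 percent (left tail up, right tail down), and a
#' systematic intensity scale-up of up to 5 percent.
#'
#' @param snr_linear RMS signal-to-noise ratio for single-error noise.
#' @param snr_compounded SNR used when all errors are compounded.
#' @param shift_nm Wavelength shift (negative = leftward).
#' @param compress_nm_per_tail Inward compression per tail (nm).
#' @param rotate_max_frac Maximum tail rotation fraction.
#' @param scale_max_frac Maximum systematic scaling fraction.
#' @return List of class \code{"drs_error_config"}.
#' @export
drs_error_config <- function(snr_linear = 35, snr_compounded = 45,
                             shift_nm = -4.8, compress_nm_per_tail = 1,
                             rotate_max_frac = 0.05, scale_max_frac = 0.05) {
  structure(list(snr_linear = snr_linear, snr_compounded = snr_compounded,
                 shift_nm = shift_nm, compress_nm_per_tail = compress_nm_per_tail,
                 rotate_max_frac = rotate_max_frac, scale_max_frac = scale_max_frac),
            class = "drs_error_config")
}

## --- single-spectrum operations (vector in, vector out) ------------------

noise_vec <- function(y, snr_linear) {
  if (is.null(snr_linear) || is.na(snr_linear)) return(y)
  if (snr_linear <= 0) stop("snr must be positive", call. = FALSE)
  sigma <- sqrt(mean(y^2)) / snr_linear
  y + stats::rnorm(length(y), 0, sigma)
}

shift_vec <- function(y, wl, delta_nm) {
  if (delta_nm == 0) return(y)
  if (abs(delta_nm) >= diff(range(wl)))
    stop("shift exceeds the band span", call. = FALSE)
  out <- stats::approx(wl, y, xout = wl - delta_nm, rule = 1)$y
  out[is.na(out)] <- 0
  out
}

compress_vec <- function(y, wl, nm_per_tail) {
  if (nm_per_tail == 0) return(y)
  if (2 * nm_per_tail >= diff(range(wl)))
    stop("compression exceeds the band span", call. = FALSE)
  lo <- wl[1] + nm_per_tail
  hi <- wl[length(wl)] - nm_per_tail
  # inverse of the affine map [lo, hi] <- [wl_min, wl_max]; margins clamp
  xin <- (pmin(pmax(wl, lo), hi) - lo) / (hi - lo) * diff(range(wl)) + wl[1]
  stats::approx(wl, y, xout = xin, rule = 2)$y
}

rotate_vec <- function(y, wl, a) {
  span <- diff(range(wl))
  y * (1 + a - 2 * a * (wl - wl[1]) / span)
}

#' Add detector noise to a spectrum
#'
#' Zero-mean Gaussian noise scaled so that RMS(signal)/RMS(noise) equals the
#' target linear SNR in expectation.
#'
#' @param spec A \code{drs_spectrum}.
#' @param snr_linear Target linear SNR (> 0); \code{NULL} is the identity.
#' @param seed Optional integer seed for reproducibility.
#' @return The noisy \code{drs_spectrum}.
#' @export
add_gaussian_noise <- function(spec, snr_linear = 35, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  spec$intensity <- noise_vec(spec$intensity, snr_linear)
  spec
}

#' Shift a spectrum along the wavelength axis
#'
#' Simulates silent wavelength miscalibration: the intensities are linearly
#' interpolated onto the shifted axis while the grid labels stay unchanged.
#' Columns with no source data are set to 0 (unexposed sensor columns).
#'
#' @param spec A \code{drs_spectrum}.
#' @param delta_nm Shift in nm; negative shifts the spectrum leftward.
#' @return The shifted \code{drs_spectrum}.
#' @export
shift_wavelength <- function(spec, delta_nm = -4.8) {
  spec$intensity <- shift_vec(spec$intensity, spec$wavelength, delta_nm)
  spec
}

#' Compress a spectrum inward at the tails
#'
#' Simulates sensor/grating misalignment: the content of the band is squeezed
#' by the affine map sending [min, max] onto [min+t, max-t]; the t-wide
#' margins hold the edge values.
#'
#' @param spec A \code{drs_spectrum}.
#' @param nm_per_tail Compression per tail in nm (default 1).
#' @return The compressed \code{drs_spectrum}.
#' @export
compress_spectrum <- function(spec, nm_per_tail = 1) {
  spec$intensity <- compress_vec(spec$intensity, spec$wavelength, nm_per_tail)
  spec
}

#' Rotate (tilt) a spectrum
#'
#' Wavelength-dependent intensity fluctuation from an unstable light source:
#' multiply by a linear ramp running from (1+a) at the left tail to (1-a) at
#' the right tail, midpoint unchanged. The magnitude a is drawn uniformly
#' from [0, max_frac] per spectrum (left tail up, right tail down).
#'
#' @param spec A \code{drs_spectrum}.
#' @param max_frac Maximum tail fraction (default 0.05).
#' @param seed Optional seed.
#' @param a Fix the ramp magnitude instead of drawing it (testing hook).
#' @return The tilted \code{drs_spectrum}.
#' @export
rotate_spectrum <- function(spec, max_frac = 0.05, seed = NULL, a = NULL) {
  if (max_frac < 0 || max_frac >= 1) stop("max_frac must be in [0, 1)", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(a)) a <- stats::runif(1, 0, max_frac)
  spec$intensity <- rotate_vec(spec$intensity, spec$wavelength, a)
  spec
}

#' Systematically scale a spectrum
#'
#' Simulates improper light-source warm-up: every column is multiplied by one
#' factor drawn uniformly from [1, 1 + max_frac] per spectrum.
#'
#' @param spec A \code{drs_spectrum}.
#' @param max_frac Maximum scaling fraction (default 0.05).
#' @param seed Optional seed.
#' @return The scaled \code{drs_spectrum}.
#' @export
scale_spectrum <- function(spec, max_frac = 0.05, seed = NULL) {
  if (max_frac < 0 || max_frac >= 1) stop("max_frac must be in [0, 1)", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  spec$intensity <- spec$intensity * stats::runif(1, 1, 1 + max_frac)
  spec
}

#' The fourteen training-augmentation corruption rows
#'
#' Which corruptions each augmentation dataset applies: rows 2-6 carry one
#' error each, rows 7-14 compound several, row 11 carries all five.
#'
#' @return Logical 14 x 5 matrix with columns noise, scale, shift, compress,
#'   rotate.
#' @export
augmentation_rows <- function() {
  m <- matrix(FALSE, 14, 5,
              dimnames = list(paste0("row", sprintf("%02d", 1:14)),
                              c("noise", "scale", "shift", "compress", "rotate")))
  mark <- function(i, ...) m[i, c(...)] <<- TRUE
  mark(2, "noise")
  mark(3, "shift")
  mark(4, "scale")
  mark(5, "compress")
  mark(6, "rotate")
  mark(7, "noise", "compress")
  mark(8, "noise", "shift")
  mark(9, "noise", "scale", "shift")
  mark(10, "noise", "scale", "shift", "compress")
  mark(11, "noise", "scale", "shift", "compress", "rotate")
  mark(12, "scale", "compress")
  mark(13, "scale", "shift")
  mark(14, "shift", "compress")
  m
}

#' Corrupt every record of a dataset
#'
#' Applies the requested corruptions to each gray spectrum in the fixed order
#' scale, rotate, shift, compress, noise (detection noise enters after all
#' optical and calibration distortions). Labels, group ids and record count
#' are preserved; the error tag is replaced.
#'
#' @param dataset A \code{drs_dataset}.
#' @param errors Character subset of
#'   \code{c("noise","scale","shift","compress","rotate")}.
#' @param config A \code{\link{drs_error_config}}.
#' @param seed Integer seed driving all random draws.
#' @param error_tag Tag for the output dataset; defaults to the joined error
#'   names.
#' @param snr Override the SNR (otherwise \code{snr_linear}, or
#'   \code{snr_compounded} when all five errors are requested).
#' @return The corrupted \code{drs_dataset}.
#' @export
corrupt_dataset <- function(dataset, errors, config = drs_error_config(),
                            seed = 0L, error_tag = NULL, snr = NULL) {
  stopifnot(inherits(dataset, "drs_dataset"))
  bad <- setdiff(errors, c("noise", "scale", "shift", "compress", "rotate"))
  if (length(bad)) stop("unknown corruption: ", paste(bad, collapse = ", "), call. = FALSE)
  if (is.null(snr))
    snr <- if (length(errors) == 5L) config$snr_compounded else config$snr_linear
  wl <- dataset$wavelength
  set.seed(seed)
  out <- dataset$gray
  for (i in seq_len(nrow(out))) {
    y <- out[i, ]
    if ("scale" %in% errors) y <- y * stats::runif(1, 1, 1 + config$scale_max_frac)
    if ("rotate" %in% errors) y <- rotate_vec(y, wl, stats::runif(1, 0, config$rotate_max_frac))
    if ("shift" %in% errors) y <- shift_vec(y, wl, config$shift_nm)
    if ("compress" %in% errors) y <- compress_vec(y, wl, config$compress_nm_per_tail)
    if ("noise" %in% errors) y <- noise_vec(y, snr)
    out[i, ] <- y
  }
  dataset$gray <- out
  dataset$error_tag <- if (is.null(error_tag)) {
    if (length(errors)) paste(sort(errors), collapse = "+") else "none"
  } else error_tag
  dataset
}

#' Apply one augmentation row to a dataset
#'
#' @param dataset A \code{drs_dataset}.
#' @param row Row number 1-14 (see \code{\link{augmentation_rows}}).
#' @param config A \code{\link{drs_error_config}}.
#' @param seed Integer seed.
#' @return The corrupted \code{drs_dataset} tagged \code{"rowNN"}.
#' @export
apply_error_row <- function(dataset, row, config = drs_error_config(), seed = 0L) {
  rows <- augmentation_rows()
  if (!row %in% seq_len(nrow(rows))) stop("unknown augmentation row: ", row, call. = FALSE)
  on <- colnames(rows)[rows[row, ]]
  corrupt_dataset(dataset, on, config, seed, error_tag = rownames(rows)[row])
}

#' Build the augmented training set
#'
#' Concatenates all fourteen augmentation rows applied to the base dataset
#' (14 x 1520 = 21,280 records under the default grid). Error tags
#' distinguish the rows; labels and group ids are carried through.
#'
#' @param base A \code{drs_dataset} (expected 1520 records; a different size
#'   triggers a warning and proceeds with 14 x nrow).
#' @param config A \code{\link{drs_error_config}}.
#' @param seed Master seed; row k uses \code{seed + k}.
#' @return List of class \code{"drs_augmented"}: fields \code{datasets}
#'   (14 \code{drs_dataset}s), \code{n_records}.
#' @export
build_augmented_training_set <- function(base, config = drs_error_config(), seed = 0L) {
  stopifnot(inherits(base, "drs_dataset"))
  if (nrow(base$gray) != 1520L)
    warning("base dataset has ", nrow(base$gray), " records (expected 1520); proceeding")
  sets <- lapply(seq_len(14L), function(k) apply_error_row(base, k, config, seed + k))
  structure(list(datasets = sets, n_records = 14L * nrow(base$gray)),
            class = "drs_augmented")
}

#' @export
print.drs_augmented <- function(x, ...) {
  cat(sprintf("<drs_augmented> 14 corruption rows, %d records total\n", x$n_records))
  invisible(x)
}

#' The seven evaluation conditions
#'
#' Builds the evaluation suite: the perfect dataset plus the six single- or
#' compounded-error variants (noise, shifted, intensity-scaled, compressed,
#' rotated, all errors compounded). Noise uses the single-error SNR except in
#' the compounded condition.
#'
#' @param base A perfect \code{drs_dataset}.
#' @param config A \code{\link{drs_error_config}}.
#' @param seed Master seed; condition k uses \code{seed + k}.
#' @return Named list of seven \code{drs_dataset}s.
#' @export
condition_suite <- function(base, config = drs_error_config(), seed = 0L) {
  specs <- list(perfect = character(0), noise = "noise", shifted = "shift",
                scaled = "scale", compressed = "compress", rotated = "rotate",
                all = c("noise", "scale", "shift", "compress", "rotate"))
  out <- vector("list", length(specs))
  names(out) <- names(specs)
  for (k in seq_along(specs))
    out[[k]] <- corrupt_dataset(base, specs[[k]], config, seed + k,
                                error_tag = names(specs)[k])
  out
}
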