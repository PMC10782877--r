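#' Names of the 35 wavelength-independent features, in fixed order
#'
#' Twelve intensity statistics (max, mean, sd for R, G, B, gray), sixteen
#' slope statistics (max, min, mean, sd of the per-column first differences
#' for R, G, B, gray), two spectrum lengths computed on the gray spectrum,
#' four skewnesses, and the categorical probe id. None references a specific
#' wavelength, which is what makes the downstream regressor robust to
#' wavelength miscalibration.
#'
#' @return Character vector of length 35.
#' @export
wir_feature_names <- function() {
  ch <- c("red", "green", "blue", "gray")
  c(paste0("max_", ch), paste0("mean_", ch), paste0("sd_", ch),
    paste0("slope_max_", ch), paste0("slope_min_", ch),
    paste0("slope_mean_", ch), paste0("slope_sd_", ch),
    "spectrum_length_1", "spectrum_length_2",
    paste0("skew_", ch), "probe_id")
}

#' First-difference slope series of a spectrum
#'
#' Per-pixel-column slope: simple first differences of the intensities
#' (deliberately per column, not per nm, so the series never references the
#' wavelength axis).
#'
#' @param spec A \code{drs_spectrum} or numeric vector of length >= 2.
#' @return Numeric vector of length N-1.
#' @export
slope_series <- function(spec) {
  y <- if (inherits(spec, "drs_spectrum")) spec$intensity else spec
  if (length(y) < 2L) stop("need at least two columns for slopes", call. = FALSE)
  diff(y)
}

#' Spectrum length 1: columns above quarter-maximum
#'
#' Number of pixel columns whose intensity is strictly greater than
#' 0.25 times the maximum intensity. An all-zero spectrum has length 0.
#'
#' @param spec A \code{drs_spectrum} or numeric vector.
#' @return Integer count.
#' @export
spectrum_length_1 <- function(spec) {
  y <- if (inherits(spec, "drs_spectrum")) spec$intensity else spec
  sum(y > 0.25 * max(y))
}

#' Spectrum length 2: distance between the two highest local maxima
#'
#' Pixel distance between the absolute maximum and the highest other local
#' maximum of the (smoothed) gray spectrum. A local maximum is a column
#' strictly greater than both neighbours; ties break to the leftmost
#' position. Returns 0 when no second local maximum exists (e.g. a strictly
#' monotone spectrum).
#'
#' @param spec A \code{drs_spectrum} or numeric vector (already smoothed).
#' @return Integer pixel distance.
#' @export
spectrum_length_2 <- function(spec) {
  y <- if (inherits(spec, "drs_spectrum")) spec$intensity else spec
  n <- length(y)
  if (n < 3L) return(0L)
  core <- y[2:(n - 1L)]
  locs <- which(core > y[1:(n - 2L)] & core > y[3:n]) + 1L
  if (length(locs) < 2L) return(0L)
  peak <- locs[which.max(y[locs])]           # global among local maxima, leftmost tie
  others <- locs[locs != peak]
  second <- others[which.max(y[others])]
  abs(peak - second)
}

#' Sample skewness of a spectrum's intensities
#'
#' Third standardised moment in the biased form m3 / m2^1.5 of the intensity
#' values treated as a sample. Zero-variance input is defined as skewness 0
#' (with a warning).
#'
#' @param spec A \code{drs_spectrum} or numeric vector.
#' @return Numeric skewness.
#' @export
spectral_skewness <- function(spec) {
  y <- if (inherits(spec, "drs_spectrum")) spec$intensity else spec
  m <- mean(y)
  m2 <- mean((y - m)^2)
  if (m2 == 0) {
    warning("zero-variance spectrum: skewness defined as 0")
    return(0)
  }
  mean((y - m)^3) / m2^1.5
}

feat_from_channels <- function(red, green, blue, gray, probe_id) {
  chans <- list(red, green, blue, gray)
  stat <- function(f) vapply(chans, f, numeric(1))
  slopes <- lapply(chans, diff)
  sstat <- function(f) vapply(slopes, f, numeric(1))
  v <- c(stat(max), stat(mean), stat(stats::sd),
         sstat(max), sstat(min), sstat(mean), sstat(stats::sd),
         spectrum_length_1(gray), spectrum_length_2(gray),
         stat(spectral_skewness), probe_id)
  stats::setNames(v, wir_feature_names())
}

#' Extract the 35 wavelength-independent features from one spectrum set
#'
#' Channel intensities are clamped at zero (preprocessed spectra are
#' nonnegative; corrupted spectra can carry unphysical negative noise
#' excursions in their dim tails) and smoothed with a six-column moving
#' average before any statistic is computed, then the intensity, slope,
#' length and skewness features are assembled in the frozen order of
#' \code{\link{wir_feature_names}}. A degenerate all-zero channel yields 0
#' for its statistics (with a warning from the skewness).
#'
#' @param set A \code{drs_rgbset}.
#' @param probe A \code{\link{probe_geometry}} or probe id.
#' @param smooth_window Moving-average window (default 6); 1 disables.
#' @return Named numeric vector of length 35.
#' @export
extract_features <- function(set, probe = probe_geometry(1L), smooth_window = 6L) {
  stopifnot(inherits(set, "drs_rgbset"))
  pid <- if (is.list(probe)) probe$probe_id else as.integer(probe)
  feat_from_channels(smooth_vec(pmax(set$red, 0), smooth_window),
                     smooth_vec(pmax(set$green, 0), smooth_window),
                     smooth_vec(pmax(set$blue, 0), smooth_window),
                     smooth_vec(pmax(set$gray, 0), smooth_window), pid)
}

#' Feature table of a labelled dataset
#'
#' Vectorised feature extraction over every record: derives the channel
#' matrices from the gray matrix, smooths each spectrum and assembles the
#' 35-column feature table.
#'
#' @param dataset A \code{drs_dataset}.
#' @param smooth_window Moving-average window (default 6).
#' @return Data frame with 35 columns named per
#'   \code{\link{wir_feature_names}}, one row per record.
#' @export
drs_features <- function(dataset, smooth_window = 6L) {
  stopifnot(inherits(dataset, "drs_dataset"))
  fr <- channel_fractions(dataset$wavelength)
  n <- nrow(dataset$gray)
  out <- matrix(0, n, 35L, dimnames = list(NULL, wir_feature_names()))
  for (i in seq_len(n)) {
    y <- pmax(dataset$gray[i, ], 0)
    out[i, ] <- feat_from_channels(smooth_vec(y * fr[, 1], smooth_window),
                                   smooth_vec(y * fr[, 2], smooth_window),
                                   smooth_vec(y * fr[, 3], smooth_window),
                                   smooth_vec(y, smooth_window),
                                   dataset$probe_id)
  }
  as.data.frame(out)
}
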