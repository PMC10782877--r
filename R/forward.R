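#' Chromophore model: spectral shapes behind the scalar labels
#'
#' The synthetic phantoms are an aqueous suspension of hemoglobin (absorber)
#' and polystyrene microspheres (scatterer). A scalar label pair
#' (mu_a, mu_s') scales two fixed spectral shapes:
#' \itemize{
#'   \item an oxyhemoglobin-like extinction curve (log-spline through anchor
#'     values approximating the published oxyhemoglobin spectrum: Soret tail
#'     at 450 nm, Q bands at 542/576 nm, near-transparency beyond 600 nm),
#'   \item a Mie-like scattering power law \eqn{(\lambda/\lambda_{ref})^{-b}}.
#' }
#' Both shapes are normalised to band mean 1 on the evaluation grid, so the
#' scalar labels are exactly the band-average mu_a and mu_s' in cm^-1.
#'
#' @param scattering_exponent Power-law slope b (default 0.37, a typical
#'   polystyrene-sphere slope in the visible).
#' @param reference_wavelength_nm Reference wavelength for the power law.
#' @return Object of class \code{"chromophore_model"}.
#' @export
chromophore_model <- function(scattering_exponent = 0.37,
                              reference_wavelength_nm = 540) {
  structure(list(
    absorption_anchors = data.frame(
      # synthetic anchor table, oxyhemoglobin-like molar extinction (a.u.)
      wl = c(450, 460, 470, 480, 490, 500, 510, 520, 530, 540, 542, 550,
             560, 570, 576, 580, 590, 600, 610, 620, 630),
      e  = c(62816, 44480, 33209, 26629, 23684, 20932, 20035, 24202, 39956,
             53236, 57080, 43016, 32613, 44496, 63960, 50104, 11050, 3200,
             1506, 942, 610)),
    scattering_exponent = scattering_exponent,
    reference_wavelength_nm = reference_wavelength_nm),
    class = "chromophore_model")
}

#' Absorption shape of a chromophore model on a grid
#'
#' @param chromo A \code{chromophore_model}.
#' @param wavelength Wavelength grid.
#' @return Strictly positive numeric vector with band mean 1.
#' @export
absorption_shape <- function(chromo, wavelength) {
  a <- chromo$absorption_anchors
  s <- exp(stats::spline(a$wl, log(a$e), xout = as.numeric(wavelength))$y)
  s / mean(s)
}

#' Scattering shape of a chromophore model on a grid
#'
#' @param chromo A \code{chromophore_model}.
#' @param wavelength Wavelength grid.
#' @return Strictly positive numeric vector with band mean 1.
#' @export
scattering_shape <- function(chromo, wavelength) {
  s <- (as.numeric(wavelength) / chromo$reference_wavelength_nm)^(-chromo$scattering_exponent)
  s / mean(s)
}

#' Default reflectance standard: cool-white LED through the device
#'
#' Smooth synthetic instrument-response curve: a narrow blue LED peak near
#' 455 nm, the characteristic "cyan gap" near 480 nm, a broad phosphor hump
#' near 560 nm declining gradually into the red, and a soft roll-on at the
#' blue edge of the band. Strictly positive on [450, 630] nm.
#'
#' @param wavelength Wavelength grid.
#' @return A \code{reflectance_standard}.
#' @export
default_standard <- function(wavelength) {
  wl <- as.numeric(wavelength)
  g <- function(mu, s) exp(-0.5 * ((wl - mu) / s)^2)
  core <- 0.5 * g(455, 10) + g(560, 42)
  taper <- 1 / (1 + exp(-(wl - 452) / 4))
  reflectance_standard(wavelength, 0.003 + core * taper)
}

#' Closed-form forward reflectance at short source-detector separation
#'
#' Stand-in for a photon-transport simulation: at sub-millimetre SDS the
#' detected photons travel short, weakly dispersed paths, so the collected
#' reflectance factorises into a scattering amplitude and a Beer-Lambert
#' absorption term along a mean partial pathlength,
#' \deqn{R(\lambda) = k \, \mu_s'(\lambda)^{1.5} \exp(-\mu_a(\lambda) L(\mu_s'))}
#' with \eqn{L = 0.22 (8/\mu_s')^{0.35}} cm. Scattering thus sets the overall
#' intensity scale while absorption carves the spectral shape, matching the
#' qualitative behaviour of Monte-Carlo reflectance at these distances.
#' Deterministic; strictly positive.
#'
#' @param mu_a,mu_s_prime Wavelength-resolved coefficients (cm^-1), vectors.
#' @param sds_um Source-detector separation in micrometres (geometry record;
#'   the default pathlength constants are calibrated for the 650-750 um range).
#' @return Reflectance (arbitrary units), same length as the inputs.
#' @keywords internal
reflectance_model <- function(mu_a, mu_s_prime, sds_um = 750) {
  L <- 0.22 * (8 / mu_s_prime)^0.35
  0.05 * mu_s_prime^1.5 * exp(-mu_a * L)
}

#' Simulate a gray diffuse reflectance spectrum
#'
#' Evaluates the closed-form forward model with
#' \eqn{\mu_a(\lambda) = \mu_a \cdot shape_A(\lambda)} and
#' \eqn{\mu_s'(\lambda) = \mu_s' \cdot shape_S(\lambda)}. If absorption
#' reaches or exceeds reduced scattering anywhere on the band (outside the
#' weak-absorption regime the closed form assumes) a warning is recorded and
#' the computation proceeds.
#'
#' @param mu_a,mu_s_prime Scalar band-average labels (cm^-1, > 0).
#' @param probe A \code{\link{probe_geometry}}.
#' @param chromo A \code{\link{chromophore_model}}.
#' @param wavelength Wavelength grid.
#' @return A gray \code{drs_spectrum} (not yet standard-calibrated).
#' @export
simulate_reflectance <- function(mu_a, mu_s_prime, probe = probe_geometry(1L),
                                 chromo = chromophore_model(),
                                 wavelength = wavelength_grid()) {
  if (!isTRUE(mu_a > 0) || !isTRUE(mu_s_prime > 0))
    stop("optical properties must be positive", call. = FALSE)
  mua <- mu_a * absorption_shape(chromo, wavelength)
  mus <- mu_s_prime * scattering_shape(chromo, wavelength)
  if (any(mua >= mus))
    warning("weak-absorption validity violated: mu_a(lambda) >= mu_s'(lambda) at ",
            sum(mua >= mus), " columns", call. = FALSE)
  drs_spectrum(wavelength, reflectance_model(mua, mus, probe$sds_um), "gray")
}

#' Labelled dataset of simulated spectra
#'
#' Container for n simulated records on one shared grid: the gray
#' (standard-multiplied) spectra as an n x N matrix, the label pairs, a group
#' id per record (synthetic "titration" groups, one per mu_a level), and an
#' error tag naming the corruption applied. Channel spectra are derived from
#' the gray matrix through the fixed per-column RGB fractions (see
#' \code{\link{dataset_channels}}), which keeps gray = R+G+B exact under
#' every corruption.
#'
#' @param wavelength Shared grid.
#' @param gray n x N matrix of gray intensities.
#' @param labels Data frame with columns mu_a, mu_s_prime.
#' @param group_id Character vector of group labels (length n).
#' @param error_tag Single string naming the corruption ("none" for perfect).
#' @param probe_id Probe used (1 or 2).
#' @return Object of class \code{"drs_dataset"}.
#' @export
drs_dataset <- function(wavelength, gray, labels, group_id,
                        error_tag = "none", probe_id = 1L) {
  assert_grid(wavelength)
  gray <- as.matrix(gray)
  n <- nrow(gray)
  if (ncol(gray) != length(wavelength)) stop("gray matrix does not match the grid", call. = FALSE)
  if (nrow(labels) != n || !all(c("mu_a", "mu_s_prime") %in% names(labels)))
    stop("labels must have one row per record with columns mu_a, mu_s_prime", call. = FALSE)
  if (length(group_id) != n || any(!nzchar(group_id)))
    stop("each record needs a non-empty group_id", call. = FALSE)
  structure(list(wavelength = as.numeric(wavelength), gray = gray,
                 labels = as.data.frame(labels), group_id = as.character(group_id),
                 error_tag = error_tag, probe_id = as.integer(probe_id)),
            class = "drs_dataset")
}

#' @export
print.drs_dataset <- function(x, ...) {
  cat(sprintf("<drs_dataset> %d spectra x %d columns, error '%s', %d groups\n",
              nrow(x$gray), ncol(x$gray), x$error_tag, length(unique(x$group_id))))
  cat(sprintf("  mu_a  [%.3f, %.3f] cm^-1   mu_s' [%.3f, %.3f] cm^-1\n",
              min(x$labels$mu_a), max(x$labels$mu_a),
              min(x$labels$mu_s_prime), max(x$labels$mu_s_prime)))
  invisible(x)
}

#' @export
dim.drs_dataset <- function(x) dim(x$gray)

#' Channel spectra of a dataset
#'
#' @param dataset A \code{drs_dataset}.
#' @return List with matrices \code{red}, \code{green}, \code{blue} (same
#'   shape as \code{dataset$gray}).
#' @export
dataset_channels <- function(dataset) {
  fr <- channel_fractions(dataset$wavelength)
  list(red = sweep(dataset$gray, 2, fr[, 1], `*`),
       green = sweep(dataset$gray, 2, fr[, 2], `*`),
       blue = sweep(dataset$gray, 2, fr[, 3], `*`))
}

#' Generate the labelled simulation grid
#'
#' Cartesian grid of equally spaced label pairs (default 40 mu_a levels x
#' 38 mu_s' levels = 1520 spectra spanning mu_a 0.44-2.45 cm^-1 and mu_s'
#' 6.53-9.58 cm^-1). Each gray forward spectrum is multiplied column-by-column
#' by the reflectance standard so the instrument response is part of the
#' training distribution. Records are grouped into synthetic titrations, one
#' group per mu_a level.
#'
#' @param n_mu_a,n_mu_s Number of levels per label.
#' @param mu_a_range,mu_s_range Label ranges (cm^-1).
#' @param probe A \code{\link{probe_geometry}}.
#' @param chromo A \code{\link{chromophore_model}}.
#' @param standard A \code{reflectance_standard}; defaults to
#'   \code{\link{default_standard}} on the grid.
#' @param wavelength Wavelength grid.
#' @return A \code{drs_dataset} with error tag \code{"none"}.
#' @export
generate_grid_dataset <- function(n_mu_a = 40L, n_mu_s = 38L,
                                  mu_a_range = c(0.44, 2.45),
                                  mu_s_range = c(6.53, 9.58),
                                  probe = probe_geometry(1L),
                                  chromo = chromophore_model(),
                                  standard = NULL,
                                  wavelength = wavelength_grid()) {
  if (n_mu_a < 1L || n_mu_s < 1L) stop("need at least one level per label", call. = FALSE)
  if (diff(mu_a_range) < 0 || diff(mu_s_range) < 0 || min(mu_a_range, mu_s_range) <= 0)
    stop("invalid label ranges", call. = FALSE)
  if (is.null(standard)) standard <- default_standard(wavelength)
  mua_levels <- if (n_mu_a == 1L) mu_a_range[1] else seq(mu_a_range[1], mu_a_range[2], length.out = n_mu_a)
  mus_levels <- if (n_mu_s == 1L) mu_s_range[1] else seq(mu_s_range[1], mu_s_range[2], length.out = n_mu_s)
  labels <- expand.grid(mu_a = mua_levels, mu_s_prime = mus_levels,
                        KEEP.OUT.ATTRS = FALSE)
  shpA <- absorption_shape(chromo, wavelength)
  shpS <- scattering_shape(chromo, wavelength)
  # R(lambda) per record, times the standard (vectorised over the grid)
  gray <- t(mapply(function(a, s)
    reflectance_model(a * shpA, s * shpS, probe$sds_um) * standard$intensity,
    labels$mu_a, labels$mu_s_prime))
  group <- sprintf("titration%02d", match(labels$mu_a, mua_levels))
  ds <- drs_dataset(wavelength, gray, labels, group, "none", probe$probe_id)
  attr(ds, "standard") <- standard
  ds
}

#' Forward closure for inversion
#'
#' Builds the deterministic map (mu_a, mu_s') -> standard-multiplied gray
#' spectrum used both by the dataset generator and by the spectral-matching
#' inversion baseline, so the inversion is run against exactly the model that
#' generated the data.
#'
#' @inheritParams generate_grid_dataset
#' @return Function of \code{(mu_a, mu_s_prime)} returning an intensity vector.
#' @export
forward_closure <- function(probe = probe_geometry(1L), chromo = chromophore_model(),
                            standard = NULL, wavelength = wavelength_grid()) {
  if (is.null(standard)) standard <- default_standard(wavelength)
  shpA <- absorption_shape(chromo, wavelength)
  shpS <- scattering_shape(chromo, wavelength)
  sds <- probe$sds_um
  std <- standard$intensity
  function(mu_a, mu_s_prime)
    reflectance_model(mu_a * shpA, mu_s_prime * shpS, sds) * std
}
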