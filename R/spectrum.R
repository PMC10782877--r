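#' Wavelength grid for a spectral image
#'
#' The spectrometer disperses the 450-630 nm band across the pixel columns of
#' the camera sensor. The pixel-to-wavelength map is linear:
#' \eqn{\lambda(j) = 450 + j (630 - 450)/(N - 1)} for 0-based column j, so the
#' default 585 columns give a spacing of about 0.308 nm per pixel.
#'
#' @param n Number of pixel columns (wavelength samples).
#' @param range Band limits in nm; must lie within \code{[450, 630]}.
#' @return Numeric vector of wavelengths (nm), class \code{"wavelength_grid"}.
#' @export
#' @examples
#' wl <- wavelength_grid()
#' length(wl)       # 585
#' diff(wl)[1]      # ~0.308 nm per pixel column
wavelength_grid <- function(n = 585L, range = c(450, 630)) {
  if (n < 2L) stop("a wavelength grid needs at least 2 columns", call. = FALSE)
  if (range[1] < 450 - 1e-9 || range[2] > 630 + 1e-9 || range[1] >= range[2])
    stop("grid span must be contained in [450, 630] nm", call. = FALSE)
  wl <- seq(range[1], range[2], length.out = n)
  structure(wl, class = c("wavelength_grid", "numeric"))
}

assert_grid <- function(wl) {
  if (length(wl) < 2L || anyNA(wl)) stop("invalid wavelength grid", call. = FALSE)
  d <- diff(wl)
  if (any(d <= 0) || diff(range(d)) > 1e-9)
    stop("wavelength grid must be strictly increasing and uniformly spaced", call. = FALSE)
  invisible(wl)
}

#' Single-channel spectrum
#'
#' A spectrum is an intensity value per pixel column of the dispersed image,
#' in arbitrary counts, for one of the channels R, G, B or gray
#' (gray = R + G + B elementwise).
#'
#' @param wavelength Wavelength grid (nm), uniformly spaced.
#' @param intensity Numeric intensities, same length as \code{wavelength}.
#' @param channel One of \code{"R"}, \code{"G"}, \code{"B"}, \code{"gray"}.
#' @return Object of class \code{"drs_spectrum"}: a list with fields
#'   \code{wavelength}, \code{intensity}, \code{channel}.
#' @export
drs_spectrum <- function(wavelength, intensity, channel = "gray") {
  assert_grid(wavelength)
  channel <- match.arg(channel, c("R", "G", "B", "gray"))
  if (length(intensity) != length(wavelength))
    stop("intensity length must match the wavelength grid", call. = FALSE)
  if (!all(is.finite(intensity))) stop("intensities must be finite", call. = FALSE)
  structure(list(wavelength = as.numeric(wavelength),
                 intensity = as.numeric(intensity),
                 channel = channel),
            class = "drs_spectrum")
}

#' @export
print.drs_spectrum <- function(x, ...) {
  cat(sprintf("<drs_spectrum> channel %s, %d columns, %.1f-%.1f nm, intensity [%.4g, %.4g]\n",
              x$channel, length(x$wavelength), min(x$wavelength), max(x$wavelength),
              min(x$intensity), max(x$intensity)))
  invisible(x)
}

#' Aligned R, G, B and gray spectra on one grid
#'
#' @param wavelength Shared wavelength grid.
#' @param red,green,blue Channel intensity vectors.
#' @param gray Optional gray intensities; defaults to \code{red+green+blue},
#'   and is checked against that sum when supplied.
#' @return Object of class \code{"drs_rgbset"}.
#' @export
drs_rgbset <- function(wavelength, red, green, blue, gray = NULL) {
  assert_grid(wavelength)
  n <- length(wavelength)
  for (v in list(red, green, blue))
    if (length(v) != n) stop("channel length must match the grid", call. = FALSE)
  s <- red + green + blue
  if (is.null(gray)) gray <- s
  else if (max(abs(gray - s)) > 1e-9 * max(1, max(abs(s))))
    stop("gray channel must equal red + green + blue elementwise", call. = FALSE)
  structure(list(wavelength = as.numeric(wavelength),
                 red = as.numeric(red), green = as.numeric(green),
                 blue = as.numeric(blue), gray = as.numeric(gray)),
            class = "drs_rgbset")
}

#' @export
print.drs_rgbset <- function(x, ...) {
  cat(sprintf("<drs_rgbset> %d columns, %.1f-%.1f nm, gray intensity [%.4g, %.4g]\n",
              length(x$wavelength), min(x$wavelength), max(x$wavelength),
              min(x$gray), max(x$gray)))
  invisible(x)
}

#' Probe geometry
#'
#' Two fiber-optic probes are supported: probe 1 with a source-detector
#' separation (SDS) of 750 um and probe 2 with 650 um. All fibers are
#' 200 um core diameter. The SDS controls the optical probing depth and is
#' the geometric input to the forward reflectance model.
#'
#' @param probe_id 1 or 2.
#' @return List with \code{probe_id}, \code{sds_um}, \code{fiber_diameter_um}.
#' @export
probe_geometry <- function(probe_id = 1L) {
  probe_id <- as.integer(probe_id)
  if (!probe_id %in% c(1L, 2L)) stop("probe_id must be 1 or 2", call. = FALSE)
  list(probe_id = probe_id,
       sds_um = if (probe_id == 1L) 750 else 650,
       fiber_diameter_um = 200)
}

#' Moving-average smoothing of a spectrum
#'
#' Centred moving average with reflected edges. For the default even window of
#' six pixels the window is centred by taking three columns to the left and
#' two to the right of the index. Length is preserved.
#'
#' @param spec A \code{drs_spectrum}, or a bare numeric intensity vector.
#' @param window Window size in pixel columns (>= 1, <= number of columns).
#' @return Same type as the input, smoothed.
#' @export
smooth_spectrum <- function(spec, window = 6L) {
  if (inherits(spec, "drs_spectrum")) {
    out <- spec
    out$intensity <- smooth_vec(spec$intensity, window)
    return(out)
  }
  smooth_vec(spec, window)
}

smooth_vec <- function(y, window = 6L) {
  window <- as.integer(window)
  n <- length(y)
  if (window < 1L) stop("window must be >= 1", call. = FALSE)
  if (window > n) stop("window larger than the spectrum", call. = FALSE)
  if (window == 1L) return(y)
  left <- ceiling((window - 1L) / 2L)   # 3 for window 6
  right <- window - 1L - left           # 2 for window 6
  z <- c(rev(y[seq_len(left)]), y, rev(y[seq.int(n - right + 1L, n)]))
  cs <- cumsum(c(0, z))
  (cs[(window + 1L):(n + window)] - cs[seq_len(n)]) / window
}

#' Reflectance standard
#'
#' A diffusely reflecting calibration target. Its spectrum, measured through
#' the device, captures the combined spectral response of the light source,
#' optics and camera. Simulated spectra are multiplied by it (so the training
#' set carries the instrument response); measured spectra are divided by it.
#'
#' @param wavelength Wavelength grid.
#' @param intensity Strictly positive intensities.
#' @return A \code{drs_spectrum} of class \code{c("drs_standard","drs_spectrum")}.
#' @export
reflectance_standard <- function(wavelength, intensity) {
  if (any(intensity <= 0)) stop("a reflectance standard must be strictly positive", call. = FALSE)
  out <- drs_spectrum(wavelength, intensity, "gray")
  class(out) <- c("drs_standard", class(out))
  out
}

#' Apply a reflectance standard to a spectrum
#'
#' @param spec A \code{drs_spectrum}.
#' @param std A \code{reflectance_standard} on the same grid.
#' @param mode \code{"multiply"} (simulated path: imprint the instrument
#'   response) or \code{"divide"} (measured path: remove it).
#' @return The calibrated \code{drs_spectrum}.
#' @export
apply_standard <- function(spec, std, mode = c("multiply", "divide")) {
  mode <- match.arg(mode)
  if (length(spec$wavelength) != length(std$wavelength) ||
      max(abs(spec$wavelength - std$wavelength)) > 1e-9)
    stop("spectrum and standard must share one wavelength grid", call. = FALSE)
  if (mode == "divide" && any(std$intensity <= 0))
    stop("cannot divide by a standard with non-positive values", call. = FALSE)
  out <- spec
  out$intensity <- if (mode == "multiply") spec$intensity * std$intensity
                   else spec$intensity / std$intensity
  out
}

#' Write aligned channel spectra to CSV
#'
#' Long format with columns \code{wavelength_nm}, \code{intensity},
#' \code{channel}.
#'
#' @param x A \code{drs_rgbset} or \code{drs_spectrum}.
#' @param file Output path.
#' @export
write_spectra <- function(x, file) {
  if (inherits(x, "drs_rgbset")) {
    df <- rbind(
      data.frame(wavelength_nm = x$wavelength, intensity = x$red, channel = "R"),
      data.frame(wavelength_nm = x$wavelength, intensity = x$green, channel = "G"),
      data.frame(wavelength_nm = x$wavelength, intensity = x$blue, channel = "B"),
      data.frame(wavelength_nm = x$wavelength, intensity = x$gray, channel = "gray"))
  } else {
    df <- data.frame(wavelength_nm = x$wavelength, intensity = x$intensity,
                     channel = x$channel)
  }
  utils::write.csv(df, file, row.names = FALSE)
  invisible(file)
}

#' Read spectra from CSV
#'
#' Reads the long format written by \code{\link{write_spectra}}. If all four
#' channels are present a \code{drs_rgbset} is returned, otherwise a single
#' \code{drs_spectrum}.
#'
#' @param file CSV path with columns wavelength_nm, intensity, channel.
#' @return A \code{drs_rgbset} or \code{drs_spectrum}.
#' @export
read_spectra <- function(file) {
  df <- utils::read.csv(file, stringsAsFactors = FALSE)
  need <- c("wavelength_nm", "intensity", "channel")
  if (!all(need %in% names(df)))
    stop("spectrum CSV needs columns wavelength_nm, intensity, channel", call. = FALSE)
  chans <- split(df, df$channel)
  if (all(c("R", "G", "B") %in% names(chans))) {
    wl <- chans$R$wavelength_nm
    drs_rgbset(wl, chans$R$intensity, chans$G$intensity, chans$B$intensity)
  } else {
    ch <- names(chans)[1]
    drs_spectrum(chans[[ch]]$wavelength_nm, chans[[ch]]$intensity, ch)
  }
}
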