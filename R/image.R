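#' 8-bit RGB spectral image with acquisition metadata
#'
#' The raw output of the device is an 8-bit RGB photograph of the dispersed
#' spectrum: M pixel rows by N pixel columns (columns map to wavelength) by
#' 3 channels. Exposure time and ISO speed are needed to normalise intensities
#' across camera settings; the probe id records which fiber probe was used.
#'
#' @param pixels Integer-valued M x N x 3 array, values in \code{[0, 255]}.
#' @param exposure_time_s Exposure time in seconds (> 0).
#' @param iso_speed ISO speed (> 0).
#' @param probe_id 1 or 2.
#' @return Object of class \code{"drs_image"}.
#' @export
drs_image <- function(pixels, exposure_time_s, iso_speed, probe_id = 1L) {
  d <- dim(pixels)
  if (length(d) != 3L || d[3] != 3L) stop("pixels must be an M x N x 3 array", call. = FALSE)
  if (any(pixels != round(pixels)))
    stop("pixel values must be integers (8-bit image)", call. = FALSE)
  if (min(pixels) < 0 || max(pixels) > 255)
    stop("pixel values must lie in [0, 255]", call. = FALSE)
  if (!is.numeric(exposure_time_s) || exposure_time_s <= 0)
    stop("exposure_time_s must be a positive number", call. = FALSE)
  if (!is.numeric(iso_speed) || iso_speed <= 0)
    stop("iso_speed must be a positive number", call. = FALSE)
  structure(list(pixels = pixels,
                 exposure_time_s = as.numeric(exposure_time_s),
                 iso_speed = as.numeric(iso_speed),
                 probe_id = as.integer(probe_id)),
            class = "drs_image")
}

#' @export
print.drs_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<drs_image> %d x %d x 3, Ti = %g s, ISO = %g, probe %d\n",
              d[1], d[2], x$exposure_time_s, x$iso_speed, x$probe_id))
  invisible(x)
}

#' Background thresholding of a raw image
#'
#' Removes background noise: any channel value strictly below the cutoff is
#' set to 0 for that channel, independently per channel. A pixel (0, 20, 9)
#' with the default cutoff of 10 becomes (0, 20, 0).
#'
#' @param img A \code{drs_image}.
#' @param cutoff Intensity cutoff (default 10); values \code{< cutoff} are zeroed.
#' @return The thresholded \code{drs_image}; shape and metadata unchanged.
#' @export
threshold_image <- function(img, cutoff = 10L) {
  stopifnot(inherits(img, "drs_image"))
  px <- img$pixels
  px[px < cutoff] <- 0L
  img$pixels <- px
  img
}

#' Exposure normalisation
#'
#' Normalises raw pixel intensities for camera settings on a pixel-by-pixel
#' basis: \eqn{I_{norm} = I_{raw} / (T_i \cdot ISO)} where \eqn{T_i} is the
#' exposure time in seconds and ISO the ISO speed. The same scene captured at
#' (c Ti, ISO/c) therefore yields identical normalised values.
#'
#' @param img A \code{drs_image}.
#' @return Real-valued M x N x 3 array of normalised intensities.
#' @export
normalize_exposure <- function(img) {
  stopifnot(inherits(img, "drs_image"))
  if (is.null(img$exposure_time_s) || is.null(img$iso_speed) ||
      !isTRUE(img$exposure_time_s > 0) || !isTRUE(img$iso_speed > 0))
    stop("calibration error: exposure time and ISO speed must be positive", call. = FALSE)
  img$pixels / (img$exposure_time_s * img$iso_speed)
}

#' Collapse a normalised image to channel spectra
#'
#' The spectral intensity at pixel column j is the sum of the normalised
#' intensities over all M pixel rows, per channel; the gray spectrum is the
#' elementwise sum of R, G and B.
#'
#' @param norm_img Real M x N x 3 array (output of \code{\link{normalize_exposure}}).
#' @param wavelength Wavelength grid with N entries.
#' @return A \code{drs_rgbset}.
#' @export
collapse_to_spectra <- function(norm_img, wavelength) {
  d <- dim(norm_img)
  if (length(d) != 3L || d[3] != 3L) stop("expected an M x N x 3 array", call. = FALSE)
  if (d[2] != length(wavelength))
    stop("dimension error: image has ", d[2], " columns but the grid has ",
         length(wavelength), call. = FALSE)
  chan <- function(c) {
    m <- norm_img[, , c, drop = FALSE]
    dim(m) <- d[1:2]
    colSums(m)
  }
  drs_rgbset(wavelength, red = chan(1), green = chan(2), blue = chan(3))
}

#' Full image-to-spectra preprocessing chain
#'
#' Runs the measured-data pipeline: background threshold, exposure
#' normalisation, row collapse to spectra, moving-average smoothing, and
#' (optionally) calibration against a reflectance standard.
#'
#' @param img A \code{drs_image}.
#' @param wavelength Wavelength grid matching the image columns.
#' @param standard Optional \code{reflectance_standard}.
#' @param mode Standard mode, \code{"divide"} (measured data) or
#'   \code{"multiply"}; only used when \code{standard} is given.
#' @param cutoff Threshold cutoff (default 10).
#' @param smooth_window Moving-average window (default 6); 1 disables smoothing.
#' @return A \code{drs_rgbset} of preprocessed spectra.
#' @export
preprocess_image <- function(img, wavelength, standard = NULL,
                             mode = c("divide", "multiply"),
                             cutoff = 10L, smooth_window = 6L) {
  mode <- match.arg(mode)
  set <- collapse_to_spectra(normalize_exposure(threshold_image(img, cutoff)),
                             wavelength)
  r <- smooth_vec(set$red, smooth_window)
  g <- smooth_vec(set$green, smooth_window)
  b <- smooth_vec(set$blue, smooth_window)
  if (!is.null(standard)) {
    if (mode == "divide" && any(standard$intensity <= 0))
      stop("cannot divide by a standard with non-positive values", call. = FALSE)
    f <- if (mode == "divide") 1 / standard$intensity else standard$intensity
    r <- r * f; g <- g * f; b <- b * f
  }
  drs_rgbset(wavelength, r, g, b)
}

#' Render channel spectra as a synthetic 8-bit spectral image
#'
#' Fixture generator for end-to-end tests: spreads each channel spectrum
#' uniformly over \code{m_rows} pixel rows, scales the brightest pixel to
#' \code{peak_dn} and quantises to 8 bits. Values that would exceed 255 are
#' clipped with a warning.
#'
#' @param spec_set A \code{drs_rgbset}.
#' @param m_rows Number of pixel rows.
#' @param exposure_time_s,iso_speed,probe_id Metadata to attach.
#' @param peak_dn Digital number of the brightest pixel (<= 255).
#' @return A \code{drs_image}.
#' @export
render_image <- function(spec_set, m_rows = 8L, exposure_time_s = 1, iso_speed = 100,
                         probe_id = 1L, peak_dn = 250L) {
  stopifnot(inherits(spec_set, "drs_rgbset"))
  if (peak_dn > 255L) stop("peak_dn must be <= 255", call. = FALSE)
  chan <- cbind(spec_set$red, spec_set$green, spec_set$blue)
  top <- max(chan)
  if (top <= 0) stop("cannot render an all-zero spectrum set", call. = FALSE)
  dn <- round(chan * (peak_dn / top))
  if (max(dn) > 255L) {
    warning("rendered intensities clipped to 255")
    dn[dn > 255L] <- 255L
  }
  n <- length(spec_set$wavelength)
  px <- array(0L, dim = c(m_rows, n, 3L))
  for (c in 1:3) px[, , c] <- matrix(dn[, c], nrow = m_rows, ncol = n, byrow = TRUE)
  drs_image(px, exposure_time_s, iso_speed, probe_id)
}

#' Read a spectral image and its metadata sidecar
#'
#' Images are 8-bit RGB PNG; acquisition metadata travels in a sidecar JSON
#' file \code{{"exposure_time_s": ..., "iso_speed": ..., "probe_id": ...}}
#' keyed to the image file (no EXIF parsing).
#'
#' @param image_file PNG path.
#' @param meta_file JSON sidecar path; defaults to \code{image_file} with a
#'   \code{.json} extension.
#' @return A \code{drs_image}.
#' @export
read_drs_image <- function(image_file, meta_file = NULL) {
  if (is.null(meta_file)) meta_file <- paste0(sub("\\.png$", "", image_file), ".json")
  arr <- png::readPNG(image_file)
  if (length(dim(arr)) != 3L || dim(arr)[3] < 3L)
    stop("expected an RGB PNG", call. = FALSE)
  px <- round(arr[, , 1:3] * 255)
  meta <- jsonlite::read_json(meta_file, simplifyVector = TRUE)
  need <- c("exposure_time_s", "iso_speed", "probe_id")
  if (!all(need %in% names(meta)))
    stop("metadata sidecar must contain exposure_time_s, iso_speed, probe_id", call. = FALSE)
  drs_image(px, meta$exposure_time_s, meta$iso_speed, meta$probe_id)
}

#' Write a spectral image as PNG plus metadata sidecar
#'
#' @param img A \code{drs_image}.
#' @param image_file PNG output path; the sidecar is written next to it.
#' @export
write_drs_image <- function(img, image_file) {
  stopifnot(inherits(img, "drs_image"))
  png::writePNG(img$pixels / 255, image_file)
  meta_file <- paste0(sub("\\.png$", "", image_file), ".json")
  jsonlite::write_json(list(exposure_time_s = img$exposure_time_s,
                            iso_speed = img$iso_speed,
                            probe_id = img$probe_id),
                       meta_file, auto_unbox = TRUE, digits = NA)
  invisible(image_file)
}
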