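#' Map a wavelength to an 8-bit RGB triple
#'
#' Piecewise-linear approximation of the visible spectrum's apparent colour,
#' used to decompose a simulated grayscale spectrum into R, G and B channel
#' spectra. Breakpoints (nm): blue falls 490-510, red rises 510-580, green
#' falls 580-620; beyond 620 nm the colour is pure red. The intensity
#' falloff that such maps usually apply near 380 and 780 nm is disabled so
#' that the triple sum is nonzero everywhere on the 450-630 nm working band.
#'
#' @param lambda_nm Wavelength(s) in nm; must lie in \code{[380, 780]}.
#' @return Integer matrix with columns \code{r}, \code{g}, \code{b} in
#'   \code{[0, 255]} (one row per wavelength).
#' @export
#' @examples
#' wavelength_to_rgb(500)
wavelength_to_rgb <- function(lambda_nm) {
  l <- as.numeric(lambda_nm)
  if (any(l < 380 | l > 780))
    stop("wavelength outside the visible range [380, 780] nm", call. = FALSE)
  r <- ifelse(l < 440, (440 - l) / 60,
       ifelse(l < 510, 0,
       ifelse(l < 580, (l - 510) / 70, 1)))
  g <- ifelse(l < 440, 0,
       ifelse(l < 490, (l - 440) / 50,
       ifelse(l < 580, 1,
       ifelse(l < 620, (620 - l) / 40, 0))))
  b <- ifelse(l < 490, 1,
       ifelse(l < 510, (510 - l) / 20, 0))
  out <- cbind(r = round(255 * pmin(1, pmax(0, r))),
               g = round(255 * pmin(1, pmax(0, g))),
               b = round(255 * pmin(1, pmax(0, b))))
  storage.mode(out) <- "integer"
  out
}

#' Convert an RGB triple to channel fractions
#'
#' Each channel's share of the overall signal: fraction = channel / (r+g+b).
#' The fractions sum to one. For the triple (0, 255, 146) this gives
#' (0, 0.64, 0.36) after rounding to two decimals.
#'
#' @param triple Length-3 nonnegative vector (r, g, b), not all zero.
#' @return Named numeric vector \code{c(f_red, f_green, f_blue)}.
#' @export
#' @examples
#' round(to_fractions(c(0, 255, 146)), 2)  # 0.00 0.64 0.36
to_fractions <- function(triple) {
  if (length(triple) != 3L || any(triple < 0))
    stop("expected a nonnegative RGB triple", call. = FALSE)
  s <- sum(triple)
  if (s == 0) stop("undefined fractions: all-zero RGB triple", call. = FALSE)
  stats::setNames(as.numeric(triple) / s, c("f_red", "f_green", "f_blue"))
}

.fraction_cache <- new.env(parent = emptyenv())

#' Channel fractions for every column of a wavelength grid
#'
#' Evaluates \code{\link{wavelength_to_rgb}} and \code{\link{to_fractions}}
#' per column, cached per grid.
#'
#' @param wavelength Wavelength grid.
#' @return N x 3 matrix of fractions with columns f_red, f_green, f_blue;
#'   rows sum to 1.
#' @export
channel_fractions <- function(wavelength) {
  key <- paste0(length(wavelength), ":", wavelength[1], ":", wavelength[length(wavelength)])
  hit <- .fraction_cache[[key]]
  if (!is.null(hit)) return(hit)
  tri <- wavelength_to_rgb(wavelength)
  s <- rowSums(tri)
  if (any(s == 0))
    stop("fraction error: the RGB map is all-zero at some grid wavelength", call. = FALSE)
  fr <- tri / s
  colnames(fr) <- c("f_red", "f_green", "f_blue")
  .fraction_cache[[key]] <- fr
  fr
}

#' Split a grayscale spectrum into R, G, B channel spectra
#'
#' Per column, the channel intensity is the gray intensity times that
#' wavelength's channel fraction, so the three channel spectra sum back to
#' the gray spectrum exactly.
#'
#' @param gray A gray \code{drs_spectrum}.
#' @return A \code{drs_rgbset}.
#' @export
split_to_channels <- function(gray) {
  stopifnot(inherits(gray, "drs_spectrum"))
  fr <- channel_fractions(gray$wavelength)
  drs_rgbset(gray$wavelength,
             red = gray$intensity * fr[, 1],
             green = gray$intensity * fr[, 2],
             blue = gray$intensity * fr[, 3])
}

#' Export the wavelength-to-fraction map as a data frame
#'
#' @param wavelength Wavelength grid.
#' @return Data frame with wavelength_nm, f_red, f_green, f_blue.
#' @export
fraction_table <- function(wavelength) {
  fr <- channel_fractions(wavelength)
  data.frame(wavelength_nm = as.numeric(wavelength),
             f_red = fr[, 1], f_green = fr[, 2], f_blue = fr[, 3])
}
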