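# Shared fixtures, built in code. Cached per session to keep the suite fast.
.fixture_env <- new.env()

toy_dataset <- function(n_mu_a = 6L, n_mu_s = 5L, n_wl = 146L) {
  key <- paste(n_mu_a, n_mu_s, n_wl, sep = "-")
  hit <- .fixture_env[[key]]
  if (!is.null(hit)) return(hit)
  ds <- generate_grid_dataset(n_mu_a, n_mu_s, wavelength = wavelength_grid(n_wl))
  .fixture_env[[key]] <- ds
  ds
}

# smooth band-limited fixture: Gaussian hump well inside the band
gauss_spectrum <- function(n = 585L, centre = 540, width = 30, amp = 100) {
  wl <- wavelength_grid(n)
  drs_spectrum(wl, amp * exp(-0.5 * ((as.numeric(wl) - centre) / width)^2), "gray")
}

# direct windowed-mean oracle for the moving average (3 left, 2 right,
# reflected edges), written independently of smooth_spectrum()
smooth_oracle <- function(y, window = 6L) {
  n <- length(y)
  left <- ceiling((window - 1) / 2)
  right <- window - 1 - left
  idx_reflect <- function(i) {
    i <- ifelse(i < 1L, 1L - i, i)          # reflect including the edge
    ifelse(i > n, 2L * n + 1L - i, i)
  }
  vapply(seq_len(n), function(i) {
    mean(y[idx_reflect((i - left):(i + right))])
  }, numeric(1))
}
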