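#' Canonical frequency bands
#'
#' The six bands used throughout: delta 2-4, theta 4-8, alpha 8-14,
#' beta 14-30, gamma_low 30-50, gamma_high 50-80 Hz. Band membership of a
#' grid frequency is half-open `[low, high)`, with the upper edge of the
#' highest band included, so the bands partition the 2-80 Hz analysis range.
#'
#' @return named list of `c(low, high)` pairs in Hz.
#' @export
canonical_bands <- function() {
  list(delta = c(2, 4), theta = c(4, 8), alpha = c(8, 14),
       beta = c(14, 30), gamma_low = c(30, 50), gamma_high = c(50, 80))
}

#' Logarithmic analysis frequency grid
#'
#' @param n number of frequencies (default 100).
#' @param lo,hi grid bounds in Hz (default 2 and 80).
#' @return strictly increasing numeric vector of length `n`.
#' @export
frequency_grid <- function(n = 100, lo = 2, hi = 80) {
  10^seq(log10(lo), log10(hi), length.out = n)
}

## indices of grid frequencies belonging to each band (partition of the grid)
band_membership <- function(grid, bands = canonical_bands()) {
  hi_top <- max(vapply(bands, `[`, numeric(1), 2))
  lapply(bands, function(b) {
    if (b[2] >= hi_top) which(grid >= b[1] & grid <= b[2])
    else which(grid >= b[1] & grid < b[2])
  })
}

#' Epoched EEG container
#'
#' @param data numeric array `samples x channels x epochs`, in microvolts.
#' @param sfreq sampling rate in Hz.
#' @param layout a [channel_layout()] with one row per data channel.
#' @param participant_id identifier string.
#' @return an `epoched_eeg` object.
#' @export
epoched_eeg <- function(data, sfreq, layout, participant_id = "unknown") {
  stopifnot(is.array(data), length(dim(data)) == 3)
  if (dim(data)[2] != nrow(layout))
    stop("channel count does not match layout")
  if (dim(data)[3] < 1L) stop("need at least one epoch")
  if (!all(is.finite(data))) stop("non-finite amplitudes")
  structure(list(data = data, sfreq = sfreq, layout = layout,
                 participant_id = participant_id),
            class = "epoched_eeg")
}

#' @export
print.epoched_eeg <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<epoched_eeg> %s: %d epochs x %d channels x %d samples @ %g Hz\n",
              x$participant_id, d[3], d[2], d[1], x$sfreq))
  invisible(x)
}

n_epochs <- function(eeg) dim(eeg$data)[3]
n_channels <- function(eeg) dim(eeg$data)[2]
n_samples <- function(eeg) dim(eeg$data)[1]

## Gaussian frequency-domain weights for an FFT of length n at rate sfreq,
## centred at f0 with the given FWHM, applied to positive frequencies only
## (one-sided, doubled: the analytic-signal convention).
gauss_weights <- function(n, sfreq, f0, fwhm) {
  f <- (0:(n - 1)) * sfreq / n
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  w <- numeric(n)
  pos <- 2:ceiling(n / 2)                     # positive, non-DC frequencies
  w[pos] <- 2 * exp(-(f[pos] - f0)^2 / (2 * sigma^2))
  w
}

## analytic signal after Gaussian band-pass, per channel.
## x: samples x channels matrix. Returns complex matrix of the same shape.
band_analytic <- function(x, sfreq, f0, fwhm) {
  n <- nrow(x)
  w <- gauss_weights(n, sfreq, f0, fwhm)
  X <- stats::mvfft(x)
  stats::mvfft(X * w, inverse = TRUE) / n
}
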