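#' Inter-site phase clustering
#'
#' For each channel pair: Gaussian band-pass both channels, take the phase
#' difference time series per epoch, and compute the mean resultant length
#' `|mean(exp(i dphi))|` over time, averaged over epochs. Conventionally
#' computed on surface-Laplacian data (see [surface_laplacian()]); this
#' function uses whatever data it is given.
#'
#' @param eeg an [epoched_eeg()].
#' @param band band name or `c(low, high)` Hz pair.
#' @param pairs two-column matrix of channel names (default: all pairs).
#' @return data frame with columns `chan_a`, `chan_b`, `ispc` in `[0, 1]`.
#' @export
ispc <- function(eeg, band, pairs = NULL) {
  band <- resolve_band(band)
  chans <- eeg$layout$channel
  if (is.null(pairs)) {
    pairs <- t(utils::combn(chans, 2))
  }
  ia <- match(pairs[, 1], chans); ib <- match(pairs[, 2], chans)
  if (anyNA(ia) || anyNA(ib)) stop("pair references unknown channel")
  M <- ispc_matrix(eeg, band)
  data.frame(chan_a = pairs[, 1], chan_b = pairs[, 2],
             ispc = M[cbind(ia, ib)], stringsAsFactors = FALSE)
}

## full channels x channels ISPC matrix for one band (epoch-averaged)
ispc_matrix <- function(eeg, band) {
  band <- resolve_band(band)
  f0 <- mean(band); fwhm <- diff(band)
  nch <- n_channels(eeg); n <- n_samples(eeg)
  acc <- matrix(0, nch, nch)
  for (e in seq_len(n_epochs(eeg))) {
    z <- band_analytic(eeg$data[, , e, drop = FALSE][, , 1], eeg$sfreq, f0, fwhm)
    mod <- Mod(z)
    u <- z / ifelse(mod > 0, mod, 1)        # unit phasors; zero stays zero
    M <- Conj(t(u)) %*% u / n
    acc <- acc + Mod(M)
  }
  M <- acc / n_epochs(eeg)
  dimnames(M) <- list(eeg$layout$channel, eeg$layout$channel)
  M
}
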