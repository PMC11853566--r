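#' Tort modulation index
#'
#' Bins an amplitude series by the phase of a slower rhythm, normalises the
#' per-bin mean amplitudes to a distribution p, and measures the divergence
#' of p from uniformity: `MI = (log N - H(p)) / log N` with N phase bins.
#'
#' @param phase numeric vector of instantaneous phase, radians in (-pi, pi].
#' @param amplitude numeric vector of instantaneous amplitude, same length.
#' @param n_bins number of phase bins (default 18).
#' @return MI in `[0, 1]`; NA when the total binned amplitude is zero.
#' @export
tort_mi <- function(phase, amplitude, n_bins = 18) {
  if (length(phase) != length(amplitude)) stop("length mismatch")
  if (n_bins < 2) stop("n_bins must be >= 2")
  edges <- seq(-pi, pi, length.out = n_bins + 1)
  idx <- findInterval(phase, edges, rightmost.closed = TRUE, all.inside = TRUE)
  s <- vapply(seq_len(n_bins), function(b) {
    m <- idx == b
    if (any(m)) mean(amplitude[m]) else 0
  }, numeric(1))
  tot <- sum(s)
  if (tot <= 0) return(NA_real_)
  p <- s / tot
  h <- -sum(ifelse(p > 0, p * log(p), 0))
  (log(n_bins) - h) / log(n_bins)
}

#' Default phase/amplitude band pairs for PAC
#'
#' Twelve pairs: phase bands delta/theta/alpha/beta crossed with amplitude
#' bands beta/gamma_low/gamma_high.
#'
#' @return data frame with columns `phase_band`, `amp_band`.
#' @export
pac_band_pairs <- function() {
  expand.grid(phase_band = c("delta", "theta", "alpha", "beta"),
              amp_band = c("beta", "gamma_low", "gamma_high"),
              KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
}

#' Phase-amplitude coupling for one band pair
#'
#' Per channel: Gaussian band-pass at the phase band's centre for
#' instantaneous phase, at the amplitude band's centre for instantaneous
#' amplitude, epochs filtered independently then concatenated, then
#' [tort_mi()].
#'
#' @param eeg an [epoched_eeg()].
#' @param phase_band,amp_band band names (see [canonical_bands()]) or
#'   `c(low, high)` Hz pairs; phase band centre must not exceed the amplitude
#'   band centre.
#' @param n_bins phase bins for [tort_mi()].
#' @return named numeric vector of MI per channel.
#' @export
pac_band_pair <- function(eeg, phase_band, amp_band, n_bins = 18) {
  pb <- resolve_band(phase_band); ab <- resolve_band(amp_band)
  if (mean(pb) > mean(ab))
    stop("phase band centre must not exceed amplitude band centre")
  ph <- band_phase_amp(eeg, pb)$phase
  am <- band_phase_amp(eeg, ab)$amplitude
  mi <- vapply(seq_len(n_channels(eeg)),
               function(ch) tort_mi(ph[, ch], am[, ch], n_bins), numeric(1))
  names(mi) <- eeg$layout$channel
  mi
}

resolve_band <- function(band) {
  if (is.character(band)) {
    bands <- canonical_bands()
    if (!band %in% names(bands)) stop("unknown band: ", band)
    bands[[band]]
  } else {
    stopifnot(is.numeric(band), length(band) == 2, band[1] < band[2])
    band
  }
}

## instantaneous phase and amplitude per channel, epochs concatenated.
## Returns list(phase, amplitude): (samples*epochs) x channels matrices.
band_phase_amp <- function(eeg, band) {
  band <- resolve_band(band)
  f0 <- mean(band); fwhm <- diff(band)
  nep <- n_epochs(eeg)
  ph <- vector("list", nep); am <- vector("list", nep)
  for (e in seq_len(nep)) {
    z <- band_analytic(eeg$data[, , e, drop = FALSE][, , 1], eeg$sfreq, f0, fwhm)
    ph[[e]] <- Arg(z)
    am[[e]] <- Mod(z)
  }
  list(phase = do.call(rbind, ph), amplitude = do.call(rbind, am))
}
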