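#' Sample entropy
#'
#' `SampEn(m, r) = -log(A / B)` where B counts pairs of length-`m` templates
#' within Chebyshev tolerance `r` and A counts pairs that still match when
#' extended by one sample. Self-matches are excluded.
#'
#' @param x numeric series.
#' @param m embedding dimension (default 2).
#' @param r tolerance, in the units of `x` (absolute, not a fraction of SD).
#' @return non-negative entropy; NA when no template pairs match (undefined).
#' @export
sample_entropy <- function(x, m = 2, r) {
  if (length(x) < m + 2) return(NA_real_)
  cnt <- sampen_counts(as.numeric(x), as.integer(m), as.numeric(r))
  if (cnt[2] == 0 || cnt[1] == 0) return(NA_real_)   # undefined-sentinel
  -log(cnt[1] / cnt[2])
}

#' Multiscale sample entropy of an epoched recording
#'
#' For each scale `tau` the signal is coarse-grained by averaging
#' non-overlapping blocks of `tau` samples, then sample entropy is computed
#' with tolerance `r` times the SD of the original (scale-1) signal.
#' Template and match counts are pooled across epochs before taking
#' `-log(A/B)` (identical to [sample_entropy()] for a single epoch); this
#' keeps high scales defined for short epochs. A scale whose pooled
#' coarse-grained length falls below `10 * (m + 1)` points is NA.
#'
#' @param eeg an [epoched_eeg()].
#' @param scales integer vector of coarse-graining factors (default 1:20).
#' @param m embedding dimension.
#' @param r tolerance as a fraction of the scale-1 SD (default 0.2).
#' @return `channels x scales` matrix of entropies.
#' @export
multiscale_entropy <- function(eeg, scales = 1:20, m = 2, r = 0.2) {
  nch <- n_channels(eeg); nep <- n_epochs(eeg); n <- n_samples(eeg)
  out <- matrix(NA_real_, nch, length(scales),
                dimnames = list(eeg$layout$channel, paste0("scale", scales)))
  for (ch in seq_len(nch)) {
    series <- matrix(eeg$data[, ch, ], n, nep)  # samples x epochs
    tol <- r * stats::sd(as.numeric(series))
    for (si in seq_along(scales)) {
      tau <- scales[si]
      len <- floor(n / tau)
      if (len < m + 2 || len * nep < 10 * (m + 1)) next
      A <- 0; B <- 0
      for (e in seq_len(nep)) {
        cg <- coarse_grain(series[, e], tau)
        cnt <- sampen_counts(cg, as.integer(m), tol)
        A <- A + cnt[1]; B <- B + cnt[2]
      }
      if (B > 0 && A > 0) out[ch, si] <- -log(A / B)
      else if (B > 0 && A == 0) out[ch, si] <- NA_real_
    }
  }
  out
}

#' Coarse-grain a series by non-overlapping block means
#'
#' @param x numeric series.
#' @param tau block length; `tau = 1` returns `x` unchanged.
#' @return series of length `floor(length(x) / tau)`.
#' @export
coarse_grain <- function(x, tau) {
  if (tau == 1) return(as.numeric(x))
  len <- floor(length(x) / tau)
  colMeans(matrix(x[seq_len(len * tau)], nrow = tau))
}
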