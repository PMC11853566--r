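#' Narrowband power spectra by Gaussian frequency-domain convolution
#'
#' For each grid frequency, each epoch's spectrum is multiplied by a Gaussian
#' centred at that frequency, the analytic signal implied, and the squared
#' magnitude averaged over time and epochs. The time average of the squared
#' analytic signal is evaluated through Parseval's identity on the weighted
#' spectrum, which is algebraically identical to reconstructing the analytic
#' signal and averaging |.|^2.
#'
#' @param eeg an [epoched_eeg()].
#' @param grid analysis frequencies in Hz (default [frequency_grid()]).
#' @param fwhm filter full width at half maximum per grid frequency in Hz;
#'   default `max(0.25 f, 1)`.
#' @return a `spectrum_set`: list with `freq`, and `channels x frequencies`
#'   matrices `power` (absolute, uV^2), `relative` (fraction of total grid
#'   power per channel; NA when total power is zero) and `log_power`
#'   (log10 absolute; -Inf guarded to NA).
#' @export
gaussian_narrowband_power <- function(eeg, grid = frequency_grid(),
                                      fwhm = pmax(0.25 * grid, 1)) {
  nyq <- eeg$sfreq / 2
  if (any(grid <= 0) || any(grid >= nyq)) stop("grid frequency outside (0, Nyquist)")
  if (any(fwhm <= 0)) stop("fwhm must be positive")
  if (length(fwhm) == 1L) fwhm <- rep(fwhm, length(grid))
  n <- n_samples(eeg); nch <- n_channels(eeg); nep <- n_epochs(eeg)
  ## weight matrix: grid x fft bins, squared Gaussian (one-sided) weights
  W2 <- t(vapply(seq_along(grid),
                 function(i) gauss_weights(n, eeg$sfreq, grid[i], fwhm[i])^2,
                 numeric(n)))
  acc <- matrix(0, length(grid), nch)
  for (e in seq_len(nep)) {
    X2 <- Mod(stats::mvfft(eeg$data[, , e, drop = FALSE][, , 1]))^2  # n x nch
    acc <- acc + (W2 %*% X2) / n^2
  }
  power <- t(acc / nep)                      # channels x frequencies
  tot <- rowSums(power)
  rel <- power / tot
  rel[tot == 0, ] <- NA_real_
  lp <- suppressWarnings(log10(power))
  lp[!is.finite(lp)] <- NA_real_
  structure(list(freq = grid, power = power, relative = rel, log_power = lp,
                 channels = eeg$layout$channel),
            class = "spectrum_set")
}

#' Aperiodic (1/f) fit of a power spectrum
#'
#' Fits `log10 P = offset - exponent * log10 f` with iterative masking of
#' oscillatory peaks: points whose residual from the current line exceeds a
#' positive threshold are excluded and the line refit (a knee-free spectral
#' parameterisation).
#'
#' @param power numeric vector of power values (one channel).
#' @param freq frequencies in Hz matching `power`.
#' @param fit_range fit bounds in Hz, default `c(2, 40)`.
#' @param n_iter masking iterations.
#' @param z_thresh residual threshold in SD units for peak masking.
#' @return list with `exponent`, `offset` (log10 power at 1 Hz), `r_squared`
#'   (on the final non-peak points), `fit_range`.
#' @export
fit_aperiodic <- function(power, freq, fit_range = c(2, 40), n_iter = 4,
                          z_thresh = 2) {
  sel <- freq >= fit_range[1] & freq <= fit_range[2]
  if (sum(sel) < 10) stop("need at least 10 grid points in fit_range")
  p <- power[sel]; f <- freq[sel]
  if (any(p <= 0)) stop("non-positive power in fit range")
  lx <- log10(f); ly <- log10(p)
  keep <- rep(TRUE, length(lx))
  for (i in seq_len(n_iter)) {
    ft <- stats::lm.fit(cbind(1, lx[keep]), ly[keep])
    pred <- ft$coefficients[1] + ft$coefficients[2] * lx
    res <- ly - pred
    s <- stats::sd(res[keep])
    if (!is.finite(s) || s < 1e-12) break
    new_keep <- res <= z_thresh * s        # mask positive (peak) outliers only
    if (identical(new_keep, keep)) break
    keep <- new_keep
    if (sum(keep) < 10) { keep <- rep(TRUE, length(lx)); break }
  }
  ft <- stats::lm.fit(cbind(1, lx[keep]), ly[keep])
  pred <- ft$coefficients[1] + ft$coefficients[2] * lx
  ss_res <- sum((ly[keep] - pred[keep])^2)
  ss_tot <- sum((ly[keep] - mean(ly[keep]))^2)
  r2 <- if (ss_tot < 1e-24) 1 else max(0, min(1, 1 - ss_res / ss_tot))
  list(exponent = unname(-ft$coefficients[2]),
       offset = unname(ft$coefficients[1]),
       r_squared = r2, fit_range = fit_range)
}

#' Peak alpha frequency
#'
#' Fits a single Gaussian to the power above the aperiodic fit within the
#' 6-14 Hz candidate range (least-squares over a mean/width grid with a
#' closed-form height) and returns the Gaussian's mean and height. A peak is
#' reported only when the fitted height exceeds `floor_frac` of the local
#' aperiodic level, otherwise both fields are NA.
#'
#' @param power,freq one channel's spectrum.
#' @param candidate_range Hz, default `c(6, 14)`.
#' @param floor_frac minimum peak height as a fraction of the aperiodic level.
#' @param aperiodic optional precomputed [fit_aperiodic()] result.
#' @return list with `frequency` (Hz) and `amplitude` (power units), NA when
#'   no acceptable peak.
#' @export
peak_alpha <- function(power, freq, candidate_range = c(6, 14),
                       floor_frac = 0.05, aperiodic = NULL) {
  if (min(freq) > candidate_range[1] || max(freq) < candidate_range[2])
    stop("spectrum does not cover the candidate range")
  if (is.null(aperiodic)) aperiodic <- fit_aperiodic(power, freq)
  sel <- freq >= candidate_range[1] & freq <= candidate_range[2]
  f <- freq[sel]
  ap <- 10^(aperiodic$offset - aperiodic$exponent * log10(f))
  r <- power[sel] - ap
  means <- seq(candidate_range[1], candidate_range[2], by = 0.05)
  sds <- c(0.5, 0.75, 1, 1.5, 2, 3)
  best <- list(sse = Inf, mu = NA_real_, h = NA_real_)
  for (mu in means) for (s in sds) {
    g <- exp(-(f - mu)^2 / (2 * s^2))
    h <- sum(r * g) / sum(g * g)
    if (!is.finite(h) || h < 0) h <- 0
    sse <- sum((r - h * g)^2)
    if (sse < best$sse - 1e-15) best <- list(sse = sse, mu = mu, h = h)
  }
  ap_at <- 10^(aperiodic$offset - aperiodic$exponent * log10(best$mu))
  if (!is.finite(best$h) || best$h <= floor_frac * ap_at)
    return(list(frequency = NA_real_, amplitude = NA_real_))
  list(frequency = best$mu, amplitude = best$h)
}
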