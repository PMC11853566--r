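## Independent brute-force oracles and small fixtures, used to cross-check
## the implementation. Oracles deliberately avoid the package's code paths.

## --- fixtures -------------------------------------------------------------

## minimal valid layout: n channels on two rings, alternating hemispheres,
## all five regions represented
## Regions cycle through all five and hemispheres alternate left/right, so
## n >= 10 covers every region x hemisphere combination (valid for the full
## grouping scheme); n >= 8 is enough for the Laplacian.
toy_layout <- function(n = 8) {
  stopifnot(n >= 8, n <= 12)
  i <- seq_len(n)
  hemi <- ifelse(i %% 2 == 1, "left", "right")
  az <- ifelse(hemi == "left", -1, 1) * (20 + 12 * i)
  incl <- 40 + (i * 13) %% 55
  regions <- rep(c("frontal", "central", "parietal", "occipital", "lateral"),
                 length.out = n)
  x <- sin(incl * pi / 180) * sin(az * pi / 180)
  y <- sin(incl * pi / 180) * cos(az * pi / 180)
  z <- cos(incl * pi / 180)
  channel_layout(paste0("ch", i), x, y, z, regions, hemi)
}

## wrap a samples x channels x epochs array for a given layout
toy_eeg <- function(data, layout, sfreq = 250, id = "toy") {
  epoched_eeg(data, sfreq, layout, id)
}

## sinusoid recording: one frequency on every channel, random phase per
## epoch/channel under seed
sine_eeg <- function(layout, freq = 10, amp = 1, n = 500, epochs = 3,
                     sfreq = 250, seed = 1, noise = 0) {
  set.seed(seed)
  nch <- nrow(layout)
  tvec <- (seq_len(n) - 1) / sfreq
  dat <- array(0, c(n, nch, epochs))
  for (e in seq_len(epochs)) for (ch in seq_len(nch))
    dat[, ch, e] <- amp * sin(2 * pi * freq * tvec + runif(1, 0, 2 * pi)) +
      if (noise > 0) rnorm(n, 0, noise) else 0
  toy_eeg(dat, layout, sfreq)
}

demo_toy <- function(n_ad = 12, n_asd = 12, n_con = 24, seed = 7) {
  set.seed(seed)
  n <- n_ad + n_asd + n_con
  data.frame(participant_id = sprintf("S%03d", 1:n),
             age_months = runif(n, 3, 248),
             sex = sample(c("F", "M"), n, replace = TRUE),
             iq = rnorm(n, 100, 15),
             diagnosis = c(rep("AD", n_ad), rep("ASD", n_asd), rep("CON", n_con)),
             dataset = "toy", stringsAsFactors = FALSE)
}

## --- oracles --------------------------------------------------------------

## FFT periodogram band fraction: share of one-sided spectral power in [lo, hi]
periodogram_band_fraction <- function(x, sfreq, lo, hi) {
  n <- length(x)
  p <- Mod(fft(x))^2
  f <- (0:(n - 1)) * sfreq / n
  half <- f > 0 & f <= sfreq / 2
  sum(p[half & f >= lo & f <= hi]) / sum(p[half])
}

## O(n^2) sample-entropy template counter
sampen_oracle <- function(x, m, r) {
  n <- length(x)
  nm <- n - m
  A <- 0; B <- 0
  for (i in 1:(nm - 1)) for (j in (i + 1):nm) {
    if (max(abs(x[i:(i + m - 1)] - x[j:(j + m - 1)])) <= r) {
      B <- B + 1
      if (abs(x[i + m] - x[j + m]) <= r) A <- A + 1
    }
  }
  if (B == 0 || A == 0) NA_real_ else -log(A / B)
}

## direct Tort MI from binned means (independent binning code)
tort_mi_oracle <- function(phase, amplitude, n_bins = 18) {
  b <- floor((phase + pi) / (2 * pi) * n_bins) + 1
  b[b > n_bins] <- n_bins; b[b < 1] <- 1
  means <- sapply(1:n_bins, function(k) if (any(b == k)) mean(amplitude[b == k]) else 0)
  p <- means / sum(means)
  h <- -sum(p[p > 0] * log(p[p > 0]))
  (log(n_bins) - h) / log(n_bins)
}

## resultant length of the phase-angle difference of two analytic series
ispc_oracle <- function(phi_a, phi_b) {
  Mod(mean(exp(1i * (phi_a - phi_b))))
}

## type-III eta^2 by explicit RSS difference with plain qr.solve fits
eta2_oracle <- function(y, X_full, drop_cols) {
  rss <- function(X) {
    beta <- qr.solve(X, y)
    sum((y - X %*% beta)^2)
  }
  rf <- rss(X_full)
  rr <- rss(X_full[, -drop_cols, drop = FALSE])
  (rr - rf) / ((rr - rf) + rf)
}

## NMI from an explicit contingency table (natural logs, sum normalisation)
nmi_oracle <- function(a, b) {
  ta <- table(a); tb <- table(b); tj <- table(a, b); n <- length(a)
  h <- function(tt) { p <- tt / n; -sum(p[p > 0] * log(p[p > 0])) }
  ha <- h(ta); hb <- h(tb)
  if (ha == 0 && hb == 0) return(1)
  if (ha == 0 || hb == 0) return(0)
  mi <- 0
  for (i in rownames(tj)) for (j in colnames(tj)) {
    pij <- tj[i, j] / n
    if (pij > 0) mi <- mi + pij * log(pij / (ta[[i]] / n * tb[[j]] / n))
  }
  2 * mi / (ha + hb)
}

## Legendre polynomial by explicit sum formula (independent of the
## package's recursion): P_n(x) = 2^-n sum_k choose(n,k)^2 (x-1)^(n-k) (x+1)^k
legendre_oracle <- function(n, x) {
  s <- 0
  for (k in 0:n) s <- s + choose(n, k)^2 * (x - 1)^(n - k) * (x + 1)^k
  s / 2^n
}

## spherical-spline Laplacian assembled from the oracle Legendre sums
laplacian_oracle <- function(V, pos, m = 4, n_leg = 10, lambda = 1e-5) {
  cosang <- tcrossprod(pos)
  cosang[cosang > 1] <- 1; cosang[cosang < -1] <- -1
  series <- function(x, mm) {
    acc <- 0
    for (n in 1:n_leg)
      acc <- acc + (2 * n + 1) / (n * (n + 1))^mm * legendre_oracle(n, x)
    acc / (4 * pi)
  }
  G <- series(cosang, m); H <- series(cosang, m - 1)
  Gi <- solve(G + diag(lambda, nrow(G)))
  sgi <- rowSums(Gi)
  d <- Gi %*% V
  c0 <- colSums(d) / sum(sgi)
  H %*% (d - outer(sgi, c0))
}
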