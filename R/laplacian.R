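#' Spherical-spline surface Laplacian
#'
#' Perrin-style current-source-density estimate: scalp potentials are
#' interpolated with spherical splines of order `m` and the surface Laplacian
#' of the spline evaluated at the electrodes. The output is reference-free
#' (adding a constant to all channels leaves it unchanged) and a spatially
#' uniform potential maps to zero.
#'
#' @param eeg an [epoched_eeg()] with at least 8 channels.
#' @param m spline order (default 4).
#' @param n_legendre number of Legendre terms in the g/h series (default 10).
#' @param lambda Tikhonov regularisation added to the G matrix diagonal.
#' @return an [epoched_eeg()] of Laplacian-transformed data.
#' @export
surface_laplacian <- function(eeg, m = 4, n_legendre = 10, lambda = 1e-5) {
  lay <- eeg$layout
  if (nrow(lay) < 8) stop("surface Laplacian needs at least 8 channels")
  pos <- as.matrix(lay[, c("x", "y", "z")])
  cosang <- tcrossprod(pos)
  cosang[cosang > 1] <- 1; cosang[cosang < -1] <- -1
  d <- cosang; diag(d) <- -Inf
  if (any(d > 1 - 1e-10)) stop("duplicate channel positions")
  G <- gh_series(cosang, m, n_legendre)
  H <- gh_series(cosang, m - 1, n_legendre)
  Gs <- G + diag(lambda, nrow(G))
  Gi <- solve(Gs)
  sgi <- rowSums(Gi)
  ssgi <- sum(sgi)
  out <- eeg$data
  for (e in seq_len(n_epochs(eeg))) {
    V <- t(eeg$data[, , e, drop = FALSE][, , 1])   # channels x samples
    dmat <- Gi %*% V
    c0 <- colSums(dmat) / ssgi
    Cw <- dmat - outer(sgi, c0)
    out[, , e] <- t(H %*% Cw)
  }
  epoched_eeg(out, eeg$sfreq, lay, eeg$participant_id)
}

## Legendre-series kernel: sum_{n=1..N} (2n+1) / (n(n+1))^m * P_n(x) / (4 pi)
gh_series <- function(x, m, n_legendre) {
  acc <- array(0, dim = dim(as.matrix(x)))
  P_prev <- array(1, dim = dim(acc))   # P_0
  P_cur <- x                            # P_1
  for (n in seq_len(n_legendre)) {
    acc <- acc + (2 * n + 1) / (n * (n + 1))^m * P_cur
    P_next <- ((2 * n + 1) * x * P_cur - n * P_prev) / (n + 1)
    P_prev <- P_cur; P_cur <- P_next
  }
  acc / (4 * pi)
}
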