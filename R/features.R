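#' Per-channel metric battery for one recording
#'
#' Computes everything the registry aggregates: narrowband spectra, the
#' aperiodic fit and alpha-peak parameters per channel, Tort MI per PAC band
#' pair per channel, multiscale entropy per channel, and the ISPC matrix per
#' band on surface-Laplacian data.
#'
#' @param eeg an [epoched_eeg()].
#' @param registry a [build_registry()] result for the recording's layout.
#' @param grid analysis frequency grid.
#' @param n_bins Tort MI phase bins.
#' @param mse_m,mse_r multiscale-entropy embedding and tolerance fraction.
#' @return list of per-channel metric blocks (used by [aggregate_features()]).
#' @export
channel_metrics <- function(eeg, registry, grid = frequency_grid(),
                            n_bins = 18, mse_m = 2, mse_r = 0.2) {
  bands <- attr(registry, "bands")
  pac_pairs <- attr(registry, "pac_pairs")
  spec <- gaussian_narrowband_power(eeg, grid)
  nch <- n_channels(eeg)
  slope <- matrix(NA_real_, nch, 2, dimnames = list(spec$channels, c("exponent", "offset")))
  paf <- matrix(NA_real_, nch, 2, dimnames = list(spec$channels, c("frequency", "amplitude")))
  for (ch in seq_len(nch)) {
    ap <- tryCatch(fit_aperiodic(spec$power[ch, ], spec$freq), error = function(e) NULL)
    if (!is.null(ap)) {
      slope[ch, ] <- c(ap$exponent, ap$offset)
      pk <- peak_alpha(spec$power[ch, ], spec$freq, aperiodic = ap)
      paf[ch, ] <- c(pk$frequency, pk$amplitude)
    }
  }
  pac <- matrix(NA_real_, nch, nrow(pac_pairs),
                dimnames = list(spec$channels,
                                paste(pac_pairs$phase_band, pac_pairs$amp_band, sep = "_")))
  ## cache phase/amplitude per distinct band
  ph_cache <- list(); am_cache <- list()
  for (i in seq_len(nrow(pac_pairs))) {
    pb <- pac_pairs$phase_band[i]; ab <- pac_pairs$amp_band[i]
    if (is.null(ph_cache[[pb]])) ph_cache[[pb]] <- band_phase_amp(eeg, bands[[pb]])$phase
    if (is.null(am_cache[[ab]])) am_cache[[ab]] <- band_phase_amp(eeg, bands[[ab]])$amplitude
    for (ch in seq_len(nch))
      pac[ch, i] <- tort_mi(ph_cache[[pb]][, ch], am_cache[[ab]][, ch], n_bins)
  }
  mse <- multiscale_entropy(eeg, attr(registry, "mse_scales"), mse_m, mse_r)
  lap <- surface_laplacian(eeg)
  ispc_mats <- lapply(bands, function(b) ispc_matrix(lap, b))
  list(spectrum = spec, slope = slope, paf = paf, pac = pac, mse = mse,
       ispc = ispc_mats, channels = spec$channels)
}

#' Aggregate per-channel metrics into one registry row
#'
#' Regional values are means over member channels (and over band frequencies
#' or scale-bin members); asymmetry values are differences of the two
#' constituent regional means; ISPC contrasts are means over the designated
#' channel-pair sets. Relative power is summed over the band's grid
#' frequencies (fraction of total power in the band) so that the six bands,
#' which partition the grid, sum to one per grouping. Peak-alpha values
#' average the channels where a peak was found; all other families propagate
#' NA from missing channel metrics.
#'
#' @param metrics a [channel_metrics()] result.
#' @param registry a [build_registry()] result.
#' @return named numeric vector over all registry keys.
#' @export
aggregate_features <- function(metrics, registry) {
  grp <- attr(registry, "groupings")
  con <- attr(registry, "ispc_contrasts")
  bands <- attr(registry, "bands")
  mse_bins <- attr(registry, "mse_bins")
  mse_scales <- attr(registry, "mse_scales")
  chans <- metrics$channels
  bidx <- band_membership(metrics$spectrum$freq, bands)

  ## per-channel value for (family, qualifier): channels-length vector
  chan_value <- function(family, qualifier) {
    switch(family,
      power_abs = rowMeans(metrics$spectrum$power[, bidx[[qualifier]], drop = FALSE]),
      power_rel = rowSums(metrics$spectrum$relative[, bidx[[qualifier]], drop = FALSE]),
      power_log = rowMeans(metrics$spectrum$log_power[, bidx[[qualifier]], drop = FALSE]),
      slope = metrics$slope[, qualifier],
      paf = metrics$paf[, qualifier],
      pac = metrics$pac[, qualifier],
      mse = {
        sc <- match(mse_bins[[qualifier]], mse_scales)
        rowMeans(metrics$mse[, sc, drop = FALSE], na.rm = TRUE)
      },
      stop("unknown family ", family))
  }

  group_mean <- function(vals, members, na_ok) {
    v <- vals[match(members, chans)]
    if (na_ok) { if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE) }
    else mean(v)
  }

  out <- stats::setNames(rep(NA_real_, nrow(registry)), registry$key)
  cache <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(registry))) {
    fam <- registry$family[i]; g <- registry$grouping[i]; q <- registry$qualifier[i]
    if (fam == "ispc") {
      M <- metrics$ispc[[q]]
      prs <- con[[g]]
      out[i] <- mean(M[cbind(match(prs[, 1], chans), match(prs[, 2], chans))])
      next
    }
    ck <- paste(fam, q, sep = "\r")
    vals <- get0(ck, envir = cache, inherits = FALSE)
    if (is.null(vals)) vals <- (cache[[ck]] <- chan_value(fam, q))
    na_ok <- fam == "paf"
    if (g %in% names(grp$regional)) {
      out[i] <- group_mean(vals, grp$regional[[g]], na_ok)
    } else {
      a <- grp$asymmetry[[g]]
      out[i] <- group_mean(vals, a$pos, na_ok) - group_mean(vals, a$neg, na_ok)
    }
  }
  out
}

#' Compute one participant's full feature row
#'
#' @inheritParams channel_metrics
#' @return named numeric vector over the registry keys.
#' @export
compute_features <- function(eeg, registry, grid = frequency_grid(), ...) {
  aggregate_features(channel_metrics(eeg, registry, grid, ...), registry)
}

#' Feature table for a cohort of recordings
#'
#' @param recordings list of [epoched_eeg()] objects.
#' @param registry a [build_registry()] result.
#' @param ... passed to [channel_metrics()].
#' @param verbose print progress.
#' @return data frame: `participant_id` plus one column per registry key.
#' @export
feature_table <- function(recordings, registry, ..., verbose = FALSE) {
  rows <- lapply(seq_along(recordings), function(i) {
    if (verbose) message("features: ", recordings[[i]]$participant_id)
    compute_features(recordings[[i]], registry, ...)
  })
  out <- as.data.frame(do.call(rbind, rows))
  data.frame(participant_id = vapply(recordings, `[[`, "", "participant_id"),
             out, check.names = FALSE, stringsAsFactors = FALSE)
}
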