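#' Regional channel groupings and asymmetry contrasts
#'
#' Derives from a layout's region/hemisphere tags the 13 regional channel
#' groups (right/left frontal, right/left centroparietal, right/left
#' occipito-parietal, frontal, occipital, central, left/right lateral,
#' right/left hemisphere) and the 5 asymmetry-sensitive contrasts
#' (interhemispheric, rostrocaudal within each hemisphere, mediolateral
#' within each hemisphere), 18 groupings in total.
#'
#' @param layout a [channel_layout()].
#' @return list with `regional` (named list of channel vectors) and
#'   `asymmetry` (named list of `list(pos=, neg=)` channel-vector pairs).
#' @export
channel_groupings <- function(layout) {
  ch <- function(cond) layout$channel[cond]
  hemi <- layout$hemisphere; reg <- layout$region
  regional <- list(
    frontal_left        = ch(reg == "frontal" & hemi == "left"),
    frontal_right       = ch(reg == "frontal" & hemi == "right"),
    centroparietal_left = ch(reg %in% c("central", "parietal") & hemi == "left"),
    centroparietal_right = ch(reg %in% c("central", "parietal") & hemi == "right"),
    occipitoparietal_left = ch(reg %in% c("occipital", "parietal") & hemi == "left"),
    occipitoparietal_right = ch(reg %in% c("occipital", "parietal") & hemi == "right"),
    frontal             = ch(reg == "frontal"),
    occipital           = ch(reg == "occipital"),
    central             = ch(reg == "central"),
    lateral_left        = ch(reg == "lateral" & hemi == "left"),
    lateral_right       = ch(reg == "lateral" & hemi == "right"),
    hemisphere_left     = ch(hemi == "left"),
    hemisphere_right    = ch(hemi == "right"))
  asymmetry <- list(
    asym_interhemispheric = list(pos = regional$hemisphere_left,
                                 neg = regional$hemisphere_right),
    asym_rostrocaudal_left = list(pos = regional$frontal_left,
                                  neg = regional$occipitoparietal_left),
    asym_rostrocaudal_right = list(pos = regional$frontal_right,
                                   neg = regional$occipitoparietal_right),
    asym_mediolateral_left = list(pos = ch(hemi == "left" & reg != "lateral"),
                                  neg = regional$lateral_left),
    asym_mediolateral_right = list(pos = ch(hemi == "right" & reg != "lateral"),
                                   neg = regional$lateral_right))
  empt <- c(names(regional)[vapply(regional, length, 1L) == 0L],
            names(asymmetry)[vapply(asymmetry, function(a)
              length(a$pos) == 0L || length(a$neg) == 0L, TRUE)])
  if (length(empt)) stop("grouping resolves to zero channels: ",
                         paste(empt, collapse = ", "))
  list(regional = regional, asymmetry = asymmetry)
}

#' ISPC pair-set contrasts
#'
#' Seven channel-pair sets: long-range (frontal to parieto-occipital),
#' interhemispheric homologous pairs, intra-left, intra-right, frontal-local,
#' posterior-local, and the global mean over all pairs.
#'
#' @param layout a [channel_layout()].
#' @return named list of two-column channel-name matrices.
#' @export
ispc_contrasts <- function(layout) {
  reg <- layout$region; hemi <- layout$hemisphere; chn <- layout$channel
  cross_pairs <- function(a, b) {
    g <- expand.grid(a = a, b = b, stringsAsFactors = FALSE)
    g <- g[g$a != g$b, , drop = FALSE]
    ## unordered: canonicalise and dedupe
    lo <- pmin(g$a, g$b); hi <- pmax(g$a, g$b)
    unique(cbind(lo, hi))
  }
  within_pairs <- function(a) {
    if (length(a) < 2) return(matrix(character(0), ncol = 2))
    t(utils::combn(a, 2))
  }
  frontal <- chn[reg == "frontal"]
  posterior <- chn[reg %in% c("parietal", "occipital")]
  left <- chn[hemi == "left"]; right <- chn[hemi == "right"]
  out <- list(
    longrange = cross_pairs(frontal, posterior),
    interhemispheric = homologous_pairs(layout),
    intra_left = within_pairs(left),
    intra_right = within_pairs(right),
    frontal_local = within_pairs(frontal),
    posterior_local = within_pairs(posterior),
    global = within_pairs(chn))
  empt <- names(out)[vapply(out, nrow, 1L) == 0L]
  if (length(empt)) stop("ISPC contrast resolves to zero pairs: ",
                         paste(empt, collapse = ", "))
  out
}

#' Build the canonical dependent-variable registry
#'
#' Enumerates the full battery of dependent variables: power (3 forms x 18
#' groupings x 6 bands = 324), aperiodic slope (exponent + offset x 18 = 36),
#' peak alpha (frequency + amplitude x 18 = 36), PAC (12 band pairs x 18 =
#' 216), MSE (4 scale bins x 18 = 72) and ISPC (7 contrasts x 6 bands = 42),
#' 726 variables in total. Keys depend only on grouping/band names, not on
#' specific channels, so two layouts with complete tags yield identical keys.
#'
#' @param layout a [channel_layout()].
#' @param bands band definitions (default [canonical_bands()]).
#' @param mse_scales scales computed for MSE (default 1:20).
#' @param mse_bins list of scale vectors averaged into each MSE bin.
#' @param pac_pairs data frame of phase/amplitude band pairs
#'   (default [pac_band_pairs()]).
#' @return a `variable_registry`: data frame with columns `key`, `family`,
#'   `grouping`, `qualifier`, carrying the grouping maps, ISPC contrasts,
#'   band and MSE definitions as attributes.
#' @export
build_registry <- function(layout, bands = canonical_bands(),
                           mse_scales = 1:20,
                           mse_bins = list(scales_01_05 = 1:5,
                                           scales_06_10 = 6:10,
                                           scales_11_15 = 11:15,
                                           scales_16_20 = 16:20),
                           pac_pairs = pac_band_pairs()) {
  grp <- channel_groupings(layout)
  con <- ispc_contrasts(layout)
  gnames <- c(names(grp$regional), names(grp$asymmetry))
  bnames <- names(bands)
  rows <- list()
  add <- function(family, grouping, qualifier)
    rows[[length(rows) + 1L]] <<- data.frame(
      key = paste(family, grouping, qualifier, sep = "."),
      family = family, grouping = grouping, qualifier = qualifier,
      stringsAsFactors = FALSE)
  for (form in c("power_abs", "power_rel", "power_log"))
    for (g in gnames) for (b in bnames) add(form, g, b)
  for (q in c("exponent", "offset")) for (g in gnames) add("slope", g, q)
  for (q in c("frequency", "amplitude")) for (g in gnames) add("paf", g, q)
  for (i in seq_len(nrow(pac_pairs)))
    for (g in gnames)
      add("pac", g, paste(pac_pairs$phase_band[i], pac_pairs$amp_band[i], sep = "_"))
  for (q in names(mse_bins)) for (g in gnames) add("mse", g, q)
  for (cn in names(con)) for (b in bnames) add("ispc", cn, b)
  reg <- do.call(rbind, rows)
  if (anyDuplicated(reg$key)) stop("duplicate registry keys")
  structure(reg,
            groupings = grp, ispc_contrasts = con, bands = bands,
            mse_scales = mse_scales, mse_bins = mse_bins,
            pac_pairs = pac_pairs,
            class = c("variable_registry", "data.frame"))
}

#' Serialise a registry manifest
#'
#' @param registry a [build_registry()] result.
#' @param path TSV output path.
#' @export
write_registry <- function(registry, path) {
  utils::write.table(as.data.frame(registry)[, c("key", "family", "grouping", "qualifier")],
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
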