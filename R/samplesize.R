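#' Proportion-preserving subsample of a cohort
#'
#' Samples without replacement so that the proportion of participants in
#' each (diagnosis x sex) cell matches the source cohort: cell quotas are
#' `fraction * cell size`, floored, with the remaining places distributed by
#' largest remainder until the rounded total is reached.
#'
#' @param demographics demographics rows (typically one age group).
#' @param fraction sampling fraction in (0, 1].
#' @param seed integer seed.
#' @return character vector of selected participant ids.
#' @export
subsample_ids <- function(demographics, fraction, seed) {
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  set.seed(as.integer(seed))
  n <- nrow(demographics)
  target <- round(fraction * n)
  cell <- interaction(demographics$diagnosis, demographics$sex, drop = TRUE)
  sizes <- table(cell)
  exact <- fraction * as.numeric(sizes)
  quota <- floor(exact)
  short <- target - sum(quota)
  if (short > 0) {
    ord <- order(exact - quota, decreasing = TRUE)
    quota[ord[seq_len(short)]] <- quota[ord[seq_len(short)]] + 1
  } else if (short < 0) {
    ord <- order(exact - quota)
    take <- ord[quota[ord] > 0][seq_len(-short)]
    quota[take] <- quota[take] - 1
  }
  quota <- pmin(quota, as.numeric(sizes))
  ids <- character(0)
  for (i in seq_along(sizes)) {
    members <- demographics$participant_id[cell == names(sizes)[i]]
    if (quota[i] == 0) {
      if (length(members) > 0)
        warning("cell ", names(sizes)[i], " received quota 0")
      next
    }
    ids <- c(ids, members[sample.int(length(members), quota[i])])
  }
  ids
}

#' Binary supra-threshold pattern of an effect table
#'
#' One binary label per (variable, term) record: 1 when
#' `eta2 > threshold`. Failed fits (NA eta2) are labelled sub-threshold.
#'
#' @param effects an [effect_table()] result (or subset).
#' @param threshold eta-squared threshold.
#' @return named integer vector over `variable:term` cells.
#' @export
supra_threshold_pattern <- function(effects, threshold = 0.035) {
  v <- as.integer(!is.na(effects$eta2) & effects$eta2 > threshold)
  names(v) <- paste(effects$variable, effects$term, sep = "|")
  v
}

#' Normalised mutual information between two binary patterns
#'
#' Each pattern is a two-class partition of the cells; NMI is computed from
#' the contingency table, normalised as `2 I / (H1 + H2)` by default
#' (`sqrt` and `max` normalisations selectable). Degenerate cases: both
#' partitions single-class yield 1; exactly one single-class yields 0.
#'
#' @param a,b equal-length label vectors.
#' @param normalization `"sum"`, `"sqrt"` or `"max"`.
#' @return NMI in `[0, 1]`.
#' @export
nmi_partition <- function(a, b, normalization = c("sum", "sqrt", "max")) {
  normalization <- match.arg(normalization)
  if (length(a) != length(b)) stop("length mismatch")
  tab <- table(a, b)
  n <- sum(tab)
  pa <- rowSums(tab) / n; pb <- colSums(tab) / n
  h <- function(p) -sum(ifelse(p > 0, p * log(p), 0))
  ha <- h(pa); hb <- h(pb)
  if (ha == 0 && hb == 0) return(1)
  if (ha == 0 || hb == 0) return(0)
  pj <- tab / n
  mi <- 0
  for (i in seq_along(pa)) for (j in seq_along(pb))
    if (pj[i, j] > 0) mi <- mi + pj[i, j] * log(pj[i, j] / (pa[i] * pb[j]))
  val <- switch(normalization,
                sum = 2 * mi / (ha + hb),
                sqrt = mi / sqrt(ha * hb),
                max = mi / max(ha, hb))
  min(1, max(0, val))
}

#' Sample-size bootstrap of supra-threshold prevalence and NMI
#'
#' For each age group, sampling fraction and repetition: draw a
#' proportion-preserving subsample, rerun the full effect-size sweep on it,
#' record the per-term proportion of supra-threshold effects, and compute
#' pairwise NMI of the supra-threshold patterns between repetitions of the
#' same fraction and age group, per term.
#'
#' @param features,demographics cohort feature table and demographics.
#' @param grouping an [assign_age_tertiles()] result (computed if NULL).
#' @param fractions sampling fractions (paper design: `seq(0.1, 0.7, 0.1)`).
#' @param reps repetitions per fraction (paper design: 100).
#' @param seed master seed.
#' @param threshold eta-squared threshold.
#' @return list with `runs` (age_group, fraction, rep, term, n, prop_supra)
#'   and `nmi` (age_group, fraction, term, rep_a, rep_b, nmi).
#' @export
bootstrap_curve <- function(features, demographics, grouping = NULL,
                            fractions = seq(0.1, 0.7, 0.1), reps = 100,
                            seed = 1, threshold = 0.035) {
  if (is.null(grouping)) grouping <- assign_age_tertiles(demographics)
  runs <- list(); nmis <- list()
  w <- 0L
  for (g in levels(grouping$labels)) {
    in_g <- grouping$labels == g
    dem_g <- demographics[in_g, , drop = FALSE]
    feat_g <- features[in_g, , drop = FALSE]
    for (fr in fractions) {
      pats <- list()
      for (r in seq_len(reps)) {
        w <- w + 1L
        ids <- subsample_ids(dem_g, fr, derive_seed(seed, w))
        sel <- dem_g$participant_id %in% ids
        sub_grouping <- list(labels = factor(rep(g, sum(sel)),
                                             levels = levels(grouping$labels)))
        class(sub_grouping) <- "age_grouping"
        eff <- effect_table(feat_g[sel, , drop = FALSE],
                            dem_g[sel, , drop = FALSE], sub_grouping)
        pat <- supra_threshold_pattern(eff, threshold)
        term_of <- effects_terms(eff)
        pats[[r]] <- split(pat, term_of)
        for (term in names(pats[[r]]))
          runs[[length(runs) + 1L]] <- data.frame(
            age_group = g, fraction = fr, rep = r, term = term,
            n = length(ids), prop_supra = mean(pats[[r]][[term]]),
            stringsAsFactors = FALSE)
      }
      if (reps >= 2) {
        for (i in 1:(reps - 1)) for (j in (i + 1):reps)
          for (term in names(pats[[i]]))
            nmis[[length(nmis) + 1L]] <- data.frame(
              age_group = g, fraction = fr, term = term, rep_a = i, rep_b = j,
              nmi = nmi_partition(pats[[i]][[term]], pats[[j]][[term]]),
              stringsAsFactors = FALSE)
      }
    }
  }
  list(runs = do.call(rbind, runs), nmi = do.call(rbind, nmis))
}

effects_terms <- function(effects) effects$term

#' Demographically matched case-control sample
#'
#' Iterates autistic (AD or ASD) participants in ascending age order and
#' greedily assigns each the unused CON participant of the same sex with
#' `|age difference| <= 5` months and `|IQ difference| <= 10` points,
#' minimising the age difference (ties: smaller IQ difference, then id
#' order). Unmatched cases and unused controls are discarded.
#'
#' @param demographics demographics data frame.
#' @param age_tol,iq_tol matching tolerances (months, IQ points).
#' @return data frame of matched pairs (`case_id`, `control_id`,
#'   `age_diff`, `iq_diff`) plus attribute `ids` with all selected ids.
#' @export
matched_sample <- function(demographics, age_tol = 5, iq_tol = 10) {
  cases <- demographics[demographics$diagnosis %in% c("AD", "ASD"), , drop = FALSE]
  cons <- demographics[demographics$diagnosis == "CON", , drop = FALSE]
  cases <- cases[order(cases$age_months, cases$participant_id), , drop = FALSE]
  used <- rep(FALSE, nrow(cons))
  out <- list()
  for (i in seq_len(nrow(cases))) {
    dage <- abs(cons$age_months - cases$age_months[i])
    diq <- abs(cons$iq - cases$iq[i])
    elig <- !used & cons$sex == cases$sex[i] & dage <= age_tol & diq <= iq_tol
    if (!any(elig)) next
    cand <- which(elig)
    cand <- cand[order(dage[cand], diq[cand], cons$participant_id[cand])]
    pick <- cand[1]
    used[pick] <- TRUE
    out[[length(out) + 1L]] <- data.frame(
      case_id = cases$participant_id[i],
      control_id = cons$participant_id[pick],
      age_diff = cases$age_months[i] - cons$age_months[pick],
      iq_diff = cases$iq[i] - cons$iq[pick], stringsAsFactors = FALSE)
  }
  pairs <- if (length(out)) do.call(rbind, out)
  else data.frame(case_id = character(0), control_id = character(0),
                  age_diff = numeric(0), iq_diff = numeric(0))
  attr(pairs, "ids") <- c(pairs$case_id, pairs$control_id)
  pairs
}
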