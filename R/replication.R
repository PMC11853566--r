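#' Stratified random half-split of a cohort
#'
#' Within each (diagnosis x sex x age-decile) cell, members are shuffled
#' under the seed and assigned alternately to the two halves, so diagnosis,
#' sex and age-distribution proportions differ between halves by at most one
#' participant per cell. The half receiving the surplus member of odd cells
#' alternates across cells.
#'
#' @param demographics demographics rows of one age group.
#' @param seed integer seed.
#' @return `split_plan` list: `half_a`, `half_b` (participant ids), `seed`.
#' @export
stratified_split <- function(demographics, seed) {
  set.seed(as.integer(seed))
  dec <- age_decile(demographics$age_months)
  cell <- interaction(demographics$diagnosis, demographics$sex, dec, drop = TRUE)
  half_a <- character(0); half_b <- character(0)
  flip <- FALSE
  for (cl in levels(cell)) {
    ids <- demographics$participant_id[cell == cl]
    ids <- ids[sample.int(length(ids))]
    pick_a <- seq_along(ids) %% 2 == if (flip) 0 else 1
    if (length(ids) %% 2 == 1) flip <- !flip
    half_a <- c(half_a, ids[pick_a])
    half_b <- c(half_b, ids[!pick_a])
  }
  structure(list(half_a = half_a, half_b = half_b, seed = seed),
            class = "split_plan")
}

age_decile <- function(age) {
  qs <- unique(stats::quantile(age, probs = seq(0, 1, 0.1), names = FALSE))
  if (length(qs) < 2) return(factor(rep(1, length(age))))
  cut(age, qs, include.lowest = TRUE, labels = FALSE)
}

#' Split-half replication rate of one effect
#'
#' For each of `n_splits` stratified half-splits of the age group, the
#' designated model is refit on each half (full-data outlier mask and
#' quadratic-age decision held fixed) and the type-III partial eta-squared
#' recomputed; the replication rate is the proportion of splits in which
#' both halves exceed the threshold. A failed half-fit counts as
#' non-replication.
#'
#' @param features,demographics cohort feature table and demographics.
#' @param grouping an [assign_age_tertiles()] result.
#' @param variable registry key; `age_group` one of youngest/middle/oldest.
#' @param model,term designated model (M1-M4) and term.
#' @param n_splits number of random splits (default 150).
#' @param threshold eta-squared threshold (default 0.035).
#' @param seed master seed; split s uses a seed derived from it.
#' @param use_age2 quadratic-age decision; if NULL, re-decided on full data.
#' @param outlier_threshold robust-z cut.
#' @return `replication_summary` data frame row: variable, age_group, model,
#'   term, full-data eta2, rate, n_splits, threshold, n_failed.
#' @export
replication_rate <- function(features, demographics, grouping, variable,
                             age_group, model, term, n_splits = 150,
                             threshold = 0.035, seed = 1, use_age2 = NULL,
                             outlier_threshold = 3.5) {
  in_g <- grouping$labels == age_group
  dem_g <- demographics[in_g, , drop = FALSE]
  vals <- features[[variable]][in_g]
  or <- remove_outliers(vals, dem_g$diagnosis, outlier_threshold)
  v <- vals[or$keep]; d <- dem_g[or$keep, , drop = FALSE]
  if (is.null(use_age2))
    use_age2 <- tryCatch(lrt_age_quadratic(v, d$age_months)$use_age2,
                         error = function(e) FALSE,
                         warning = function(w) FALSE)
  full_eta2 <- half_eta2(v, d, model, term, use_age2)
  ok <- 0L; failed <- 0L
  for (s in seq_len(n_splits)) {
    plan <- stratified_split(d, derive_seed(seed, s))
    e_a <- half_eta2(v[d$participant_id %in% plan$half_a],
                     d[d$participant_id %in% plan$half_a, , drop = FALSE],
                     model, term, use_age2)
    e_b <- half_eta2(v[d$participant_id %in% plan$half_b],
                     d[d$participant_id %in% plan$half_b, , drop = FALSE],
                     model, term, use_age2)
    if (is.na(e_a) || is.na(e_b)) failed <- failed + 1L
    else if (e_a > threshold && e_b > threshold) ok <- ok + 1L
  }
  structure(data.frame(variable = variable, age_group = age_group,
                       model = model, term = term, eta2 = full_eta2,
                       rate = ok / n_splits, n_splits = n_splits,
                       threshold = threshold, n_failed = failed,
                       stringsAsFactors = FALSE),
            class = c("replication_summary", "data.frame"))
}

half_eta2 <- function(v, d, model, term, use_age2) {
  tryCatch({
    df <- model_frame(v, d)
    f <- model_formulas(use_age2)[[model]]
    tt <- stats::terms(f, data = df)
    mm <- stats::model.matrix(tt, stats::model.frame(tt, df),
                              contrasts.arg = list(Sex = "contr.sum",
                                                   Diagnosis = "contr.sum"))
    idx <- match_term(term, attr(tt, "term.labels"))
    eta2_from_matrices(df$y, mm, attr(mm, "assign"), idx)$eta2
  }, error = function(e) NA_real_)
}

#' Replication summaries for all supra-threshold effects
#'
#' Runs [replication_rate()] for every effect-table record with
#' `eta2 > threshold`.
#'
#' @param effects an [effect_table()] result.
#' @inheritParams replication_rate
#' @return stacked `replication_summary` data frame (zero rows if nothing is
#'   supra-threshold).
#' @export
replication_summaries <- function(effects, features, demographics, grouping,
                                  n_splits = 150, threshold = 0.035, seed = 1) {
  sel <- which(!is.na(effects$eta2) & effects$eta2 > threshold)
  rows <- lapply(sel, function(i)
    replication_rate(features, demographics, grouping,
                     variable = effects$variable[i],
                     age_group = effects$age_group[i],
                     model = effects$model[i], term = effects$term[i],
                     n_splits = n_splits, threshold = threshold,
                     seed = derive_seed(seed, i),
                     use_age2 = effects$use_age2[i]))
  if (!length(rows))
    return(data.frame(variable = character(0), age_group = character(0),
                      model = character(0), term = character(0),
                      eta2 = numeric(0), rate = numeric(0),
                      n_splits = integer(0), threshold = numeric(0),
                      n_failed = integer(0)))
  do.call(rbind, rows)
}

#' Select replicable effects
#'
#' Effects with `eta2 > eta2_threshold` and replication rate at least
#' `rate_threshold` (boundary included), sorted by age group then rate.
#'
#' @param summaries a [replication_summaries()] result.
#' @param eta2_threshold,rate_threshold selection thresholds (defaults 0.035
#'   and 0.64, the square of the 0.80 power convention).
#' @return filtered, sorted data frame.
#' @export
select_replicable <- function(summaries, eta2_threshold = 0.035,
                              rate_threshold = 0.64) {
  sel <- !is.na(summaries$eta2) & summaries$eta2 > eta2_threshold &
    summaries$rate >= rate_threshold
  out <- summaries[sel, , drop = FALSE]
  out[order(out$age_group, -out$rate), , drop = FALSE]
}
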