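#' Assign age tertiles balancing autistic subgroup counts
#'
#' Sorts participants by age (ties broken by participant id) and chooses two
#' boundary ages so that AD counts and ASD counts are each split as evenly
#' as possible across the three groups (minimising the larger of the two
#' max-min count imbalances, earliest cuts on ties). CON participants are
#' assigned by the same boundaries.
#'
#' @param demographics demographics data frame.
#' @return an `age_grouping`: list with `labels` (factor youngest/middle/
#'   oldest aligned to `demographics` rows), `boundaries` (two cut ages in
#'   months, midpoints between adjacent autistic ages), and `counts`.
#' @export
assign_age_tertiles <- function(demographics) {
  aut <- demographics$diagnosis %in% c("AD", "ASD")
  if (sum(demographics$diagnosis == "AD") < 3 ||
      sum(demographics$diagnosis == "ASD") < 3)
    stop("need at least 3 AD and 3 ASD participants")
  a <- demographics[aut, , drop = FALSE]
  ord <- order(a$age_months, a$participant_id)
  a <- a[ord, , drop = FALSE]
  n <- nrow(a)
  cum_ad <- cumsum(a$diagnosis == "AD")
  cum_asd <- cumsum(a$diagnosis == "ASD")
  imbalance <- function(cum, k1, k2) {
    cnt <- c(cum[k1], cum[k2] - cum[k1], cum[n] - cum[k2])
    max(cnt) - min(cnt)
  }
  best <- NULL; best_val <- Inf
  for (k1 in 1:(n - 2)) {
    for (k2 in (k1 + 1):(n - 1)) {
      v <- max(imbalance(cum_ad, k1, k2), imbalance(cum_asd, k1, k2))
      if (v < best_val) { best_val <- v; best <- c(k1, k2) }
    }
  }
  b1 <- mean(a$age_months[best[1] + 0:1])
  b2 <- mean(a$age_months[best[2] + 0:1])
  labels <- cut(demographics$age_months, c(-Inf, b1, b2, Inf),
                labels = c("youngest", "middle", "oldest"))
  structure(list(labels = labels, boundaries = c(b1, b2),
                 counts = table(labels, demographics$diagnosis)),
            class = "age_grouping")
}

#' Remove extreme outliers by a robust z rule
#'
#' Flags values with `|x - median| > threshold * 1.4826 * MAD` (raw median
#' absolute deviation); zero MAD removes nothing. Removal counts are
#' reported for autistic (AD or ASD) versus neurotypical participants.
#'
#' @param values numeric vector (one variable, one age group).
#' @param diagnosis matching diagnosis labels.
#' @param threshold robust-z cut (default 3.5).
#' @return list with `keep` (logical), `removed_autistic`,
#'   `removed_neurotypical`.
#' @export
remove_outliers <- function(values, diagnosis, threshold = 3.5) {
  ok <- !is.na(values)
  med <- stats::median(values[ok])
  mad_raw <- stats::median(abs(values[ok] - med))
  keep <- ok
  if (is.finite(mad_raw) && mad_raw > 0)
    keep <- ok & abs(values - med) <= threshold * 1.4826 * mad_raw
  removed <- ok & !keep
  list(keep = keep,
       removed_autistic = sum(removed & diagnosis %in% c("AD", "ASD")),
       removed_neurotypical = sum(removed & diagnosis == "CON"))
}

#' Likelihood-ratio test for a quadratic age term
#'
#' Compares `value ~ age` against `value ~ age + age^2` with the Gaussian
#' likelihood-ratio statistic `LR = n * log(RSS0 / RSS1)`, p from chi-square
#' with 1 df.
#'
#' @param values,age complete numeric vectors (NA pairs dropped).
#' @param alpha significance level for including the quadratic term.
#' @return list with `use_age2`, `lr`, `p`.
#' @export
lrt_age_quadratic <- function(values, age, alpha = 0.05) {
  cc <- stats::complete.cases(values, age)
  v <- values[cc]; a <- age[cc]
  n <- length(v)
  if (n < 10) stop("need at least 10 complete cases")
  rss <- function(X) {
    ft <- stats::lm.fit(X, v)
    sum(ft$residuals^2)
  }
  rss0 <- rss(cbind(1, a))
  rss1 <- rss(cbind(1, a, a^2))
  ss_tot <- sum((v - mean(v))^2)
  if (rss0 <= 1e-12 * max(ss_tot, 1e-12))     # linear fit already perfect
    return(list(use_age2 = FALSE, lr = 0, p = 1))
  if (rss1 <= 0 || !is.finite(rss0 / rss1)) {
    warning("singular fit in age LRT; keeping linear age")
    return(list(use_age2 = FALSE, lr = NA_real_, p = NA_real_))
  }
  lr <- n * log(rss0 / rss1)
  p <- stats::pchisq(lr, df = 1, lower.tail = FALSE)
  list(use_age2 = p < alpha, lr = lr, p = p)
}

## covariate frame with the coding the models assume: sum-to-zero contrasts
## for Diagnosis (AD/ASD/CON) and Sex (F/M), mean-centred Age and IQ.
model_frame <- function(values, demographics) {
  data.frame(
    y = values,
    Age = demographics$age_months - mean(demographics$age_months),
    Sex = factor(demographics$sex, levels = c("F", "M")),
    IQ = demographics$iq - mean(demographics$iq),
    Diagnosis = factor(demographics$diagnosis, levels = c("AD", "ASD", "CON")))
}

model_formulas <- function(use_age2) {
  base <- if (use_age2) "Age + I(Age^2)" else "Age"
  list(
    M1 = stats::as.formula(paste("y ~", base, "+ Sex + IQ + Diagnosis")),
    M2 = stats::as.formula(paste("y ~", base, "+ Sex + IQ + Diagnosis + Diagnosis:Sex")),
    M3 = stats::as.formula(paste("y ~", base, "+ Sex + IQ + Diagnosis + Diagnosis:Age")),
    M4 = stats::as.formula(paste("y ~ Age * Sex * Diagnosis + IQ",
                                 if (use_age2) "+ I(Age^2)" else "")))
}

## terms whose type-III partial eta^2 is extracted from each model
designated_terms <- list(M1 = c("Age", "Sex", "IQ", "Diagnosis"),
                         M2 = "Diagnosis:Sex", M3 = "Diagnosis:Age",
                         M4 = "Age:Sex:Diagnosis")

## match a term label ignoring the order of interaction components
## (R canonicalises "Diagnosis:Sex" to "Sex:Diagnosis")
match_term <- function(term, labs) {
  canon <- function(x) paste(sort(strsplit(x, ":", fixed = TRUE)[[1]]),
                             collapse = ":")
  match(canon(term), vapply(labs, canon, ""))
}

#' Fit the four group-difference models
#'
#' M1: main effects of Age, Sex, IQ and Diagnosis; M2 adds Diagnosis x Sex;
#' M3 adds Diagnosis x Age; M4 is the full Age x Sex x Diagnosis factorial
#' plus IQ. Diagnosis and Sex use sum-to-zero contrasts; Age and IQ are
#' mean-centred; `I(Age^2)` is appended as a main-effect covariate when
#' `use_age2`.
#'
#' @param values numeric outcome vector.
#' @param demographics matching demographics rows.
#' @param use_age2 include the quadratic age covariate.
#' @return named list of `lm` fits (M1-M4).
#' @export
fit_models <- function(values, demographics, use_age2 = FALSE) {
  df <- model_frame(values, demographics)
  ctr <- list(Sex = "contr.sum", Diagnosis = "contr.sum")
  lapply(model_formulas(use_age2), function(f)
    stats::lm(f, data = df, contrasts = ctr))
}

#' Type-III partial eta-squared for a model term
#'
#' `SS_term = RSS(model without the term, all other terms retained) -
#' RSS(full)`; `eta2 = SS_term / (SS_term + RSS(full))`. With sum-to-zero
#' contrasts this is the classical type-III decomposition.
#'
#' @param fit an `lm` fit.
#' @param term a term label of the fit (e.g. `"Diagnosis"`,
#'   `"Diagnosis:Sex"`).
#' @return list with `eta2`, `p`, `f`, `df`, `df_res`, `ss_term`, `rss_full`.
#' @export
partial_eta2_type3 <- function(fit, term) {
  mm <- stats::model.matrix(fit)
  asgn <- attr(mm, "assign")
  labs <- attr(stats::terms(fit), "term.labels")
  idx <- match_term(term, labs)
  if (is.na(idx)) stop("term not in model: ", term)
  y <- stats::model.response(stats::model.frame(fit))
  eta2_from_matrices(y, mm, asgn, idx)
}

eta2_from_matrices <- function(y, mm, asgn, idx) {
  full <- stats::lm.fit(mm, y)
  if (full$rank < ncol(mm)) return(list(eta2 = NA_real_, p = NA_real_,
                                        f = NA_real_, df = NA_integer_,
                                        df_res = NA_integer_,
                                        ss_term = NA_real_, rss_full = NA_real_))
  rss_full <- sum(full$residuals^2)
  keep <- asgn != idx
  red <- stats::lm.fit(mm[, keep, drop = FALSE], y)
  ss_term <- max(0, sum(red$residuals^2) - rss_full)
  df_term <- sum(!keep)
  df_res <- length(y) - ncol(mm)
  eta2 <- if (ss_term + rss_full > 0) ss_term / (ss_term + rss_full) else 0
  fstat <- (ss_term / df_term) / (rss_full / df_res)
  p <- stats::pf(fstat, df_term, df_res, lower.tail = FALSE)
  list(eta2 = eta2, p = p, f = fstat, df = df_term, df_res = df_res,
       ss_term = ss_term, rss_full = rss_full)
}

#' Generalised variance inflation factors
#'
#' Fox-Monette GVIF per model term on the correlation matrix of the
#' intercept-free model matrix: `GVIF = det(R_t) det(R_-t) / det(R)`;
#' the adjusted form is `GVIF^(1 / (2 df))`.
#'
#' @param fit an `lm` fit (or a model matrix with an `assign` attribute).
#' @return data frame with `term`, `df`, `gvif`, `adj_gvif`.
#' @export
compute_gvif <- function(fit) {
  if (inherits(fit, "lm")) {
    mm <- stats::model.matrix(fit)
    labs <- attr(stats::terms(fit), "term.labels")
  } else {
    mm <- fit
    labs <- attr(mm, "term.labels")
  }
  asgn <- attr(mm, "assign")
  keep <- asgn != 0
  X <- mm[, keep, drop = FALSE]
  asgn <- asgn[keep]
  dec <- qr(X)
  if (dec$rank < ncol(X)) {
    dropped <- dec$pivot[(dec$rank + 1):ncol(X)]
    stop("aliased columns in design; term(s): ",
         paste(unique(labs[asgn[dropped]]), collapse = ", "))
  }
  R <- stats::cor(X)
  detR <- det(R)
  out <- lapply(sort(unique(asgn)), function(t) {
    sel <- asgn == t
    g <- det(R[sel, sel, drop = FALSE]) * det(R[!sel, !sel, drop = FALSE]) / detR
    data.frame(term = labs[t], df = sum(sel), gvif = g,
               adj_gvif = g^(1 / (2 * sum(sel))), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Effect-size sweep over a feature table
#'
#' For every variable and age group: remove extreme outliers, decide the
#' quadratic age term by likelihood-ratio test, fit M1-M4, and extract
#' type-III partial eta-squared for the designated terms (Age, Sex, IQ and
#' Diagnosis from M1; Diagnosis:Sex from M2; Diagnosis:Age from M3;
#' Age:Sex:Diagnosis from M4). Per-variable failures are recorded, never
#' abort the sweep.
#'
#' @param features feature-table data frame (`participant_id` + variables).
#' @param demographics demographics data frame.
#' @param grouping an [assign_age_tertiles()] result (computed if NULL).
#' @param outlier_threshold robust-z cut for [remove_outliers()].
#' @param lrt_alpha level for the quadratic-age decision.
#' @return `effect_table` data frame with one row per (variable, age group,
#'   model, term): `variable`, `family`, `age_group`, `model`, `term`,
#'   `eta2`, `p`, `n_used`, `removed_autistic`, `removed_neurotypical`,
#'   `use_age2`; attribute `n_fits` counts distinct model fits.
#' @export
effect_table <- function(features, demographics, grouping = NULL,
                         outlier_threshold = 3.5, lrt_alpha = 0.05) {
  stopifnot(identical(features$participant_id, demographics$participant_id))
  if (is.null(grouping)) grouping <- assign_age_tertiles(demographics)
  vars <- setdiff(names(features), "participant_id")
  fam <- sub("\\..*$", "", vars)
  res <- vector("list", 3L * length(vars))
  k <- 0L
  for (g in levels(grouping$labels)) {
    in_g <- grouping$labels == g
    if (!any(in_g)) next
    dem_g <- demographics[in_g, , drop = FALSE]
    for (vi in seq_along(vars)) {
      v <- vars[vi]
      vals <- features[[v]][in_g]
      rec <- sweep_one(vals, dem_g, outlier_threshold, lrt_alpha)
      rec$variable <- v; rec$family <- fam[vi]; rec$age_group <- g
      k <- k + 1L
      res[[k]] <- rec
    }
  }
  out <- data.table::rbindlist(res[seq_len(k)])
  data.table::setcolorder(out, c("variable", "family", "age_group", "model",
                                 "term", "eta2", "p", "n_used",
                                 "removed_autistic", "removed_neurotypical",
                                 "use_age2"))
  out <- as.data.frame(out)
  attr(out, "n_fits") <- nrow(unique(out[, c("variable", "age_group", "model")]))
  class(out) <- c("effect_table", "data.frame")
  out
}

## one (variable, age group): outliers -> LRT -> M1-M4 -> designated eta^2
sweep_one <- function(vals, dem_g, outlier_threshold, lrt_alpha) {
  or <- remove_outliers(vals, dem_g$diagnosis, outlier_threshold)
  keep <- or$keep
  empty <- data.table::data.table(model = rep(names(designated_terms),
                                              lengths(designated_terms)),
                                  term = unlist(designated_terms),
                                  eta2 = NA_real_, p = NA_real_,
                                  n_used = sum(keep),
                                  removed_autistic = or$removed_autistic,
                                  removed_neurotypical = or$removed_neurotypical,
                                  use_age2 = NA)
  if (sum(keep) < 10) return(empty)
  v <- vals[keep]; d <- dem_g[keep, , drop = FALSE]
  lrt <- tryCatch(lrt_age_quadratic(v, d$age_months),
                  warning = function(w) list(use_age2 = FALSE),
                  error = function(e) list(use_age2 = FALSE))
  use_age2 <- isTRUE(lrt$use_age2)
  df <- model_frame(v, d)
  ctr <- list(Sex = "contr.sum", Diagnosis = "contr.sum")
  rows <- list()
  for (m in names(designated_terms)) {
    f <- model_formulas(use_age2)[[m]]
    rec <- tryCatch({
      tt <- stats::terms(f, data = df)
      mf <- stats::model.frame(tt, df)
      mm <- stats::model.matrix(tt, mf, contrasts.arg = ctr)
      asgn <- attr(mm, "assign")
      labs <- attr(tt, "term.labels")
      lapply(designated_terms[[m]], function(term) {
        idx <- match_term(term, labs)
        e <- eta2_from_matrices(df$y, mm, asgn, idx)
        data.table::data.table(model = m, term = term, eta2 = e$eta2, p = e$p)
      })
    }, error = function(e) {
      lapply(designated_terms[[m]], function(term)
        data.table::data.table(model = m, term = term,
                               eta2 = NA_real_, p = NA_real_))
    })
    rows <- c(rows, rec)
  }
  out <- data.table::rbindlist(rows)
  out$n_used <- sum(keep)
  out$removed_autistic <- or$removed_autistic
  out$removed_neurotypical <- or$removed_neurotypical
  out$use_age2 <- use_age2
  out
}
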