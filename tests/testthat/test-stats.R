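test_that("age tertiles balance AD and ASD counts", {
  ## interleaved ages: an exact 3/3/3 split of both subgroups exists
  dem <- demo_toy(9, 9, 12, seed = 21)
  dem$age_months[dem$diagnosis == "AD"] <- seq(10, 90, by = 10)
  dem$age_months[dem$diagnosis == "ASD"] <- seq(11, 91, by = 10)
  g <- assign_age_tertiles(dem)
  tab <- table(g$labels, dem$diagnosis)
  expect_equal(as.integer(tab[, "AD"]), rep(3L, 3))
  expect_equal(as.integer(tab[, "ASD"]), rep(3L, 3))
  ## CON counts follow the boundaries, unconstrained
  expect_equal(sum(tab[, "CON"]), 12L)
  ## deterministic
  expect_identical(g$labels, assign_age_tertiles(dem)$labels)
  expect_error(assign_age_tertiles(demo_toy(2, 9, 5)), "at least 3")
})

test_that("tertile boundaries achieve the enumerated optimum imbalance", {
  ## random interleavings: compare against brute-force enumeration of cuts
  for (seed in 22:24) {
    dem <- demo_toy(10, 9, 5, seed = seed)
    g <- assign_age_tertiles(dem)
    tab <- table(g$labels, dem$diagnosis)
    got <- max(max(tab[, "AD"]) - min(tab[, "AD"]),
               max(tab[, "ASD"]) - min(tab[, "ASD"]))
    aut <- dem[dem$diagnosis != "CON", ]
    aut <- aut[order(aut$age_months, aut$participant_id), ]
    is_ad <- cumsum(aut$diagnosis == "AD"); is_as <- cumsum(aut$diagnosis == "ASD")
    n <- nrow(aut)
    best <- Inf
    for (k1 in 1:(n - 2)) for (k2 in (k1 + 1):(n - 1)) {
      ad <- c(is_ad[k1], is_ad[k2] - is_ad[k1], is_ad[n] - is_ad[k2])
      as <- c(is_as[k1], is_as[k2] - is_as[k1], is_as[n] - is_as[k2])
      best <- min(best, max(max(ad) - min(ad), max(as) - min(as)))
    }
    expect_equal(got, best)
    expect_equal(sum(tab[, "AD"]), 10L)
  }
})

test_that("outlier removal reproduces the robust-z rule", {
  diag <- rep(c("AD", "CON"), 50)
  const <- remove_outliers(rep(1, 100), diag)
  expect_true(all(const$keep))
  v <- c(rnorm(99), 1e6)
  r <- remove_outliers(v, diag)
  expect_identical(which(!r$keep), 100L)
  ## brute-force recomputation on a mixed toy vector
  set.seed(23)
  v2 <- c(rnorm(40), 8, -7.5, 3.2)
  d2 <- sample(c("AD", "ASD", "CON"), 43, replace = TRUE)
  r2 <- remove_outliers(v2, d2)
  med <- median(v2); madr <- median(abs(v2 - med))
  manual <- abs(v2 - med) <= 3.5 * 1.4826 * madr
  expect_identical(r2$keep, manual)
  expect_equal(r2$removed_autistic, sum(!manual & d2 %in% c("AD", "ASD")))
  expect_equal(r2$removed_neurotypical, sum(!manual & d2 == "CON"))
})

test_that("age-quadratic LRT matches the RSS-ratio formula", {
  age <- seq(10, 200, length.out = 50)
  lin <- lrt_age_quadratic(3 + 0.1 * age + rnorm(50, 0, 1e-8), age)
  expect_false(lin$use_age2)
  quad <- lrt_age_quadratic(3 + 0.002 * (age - 100)^2, age)
  expect_true(quad$use_age2)
  expect_lt(quad$p, 1e-10)
  set.seed(24)
  y <- 1 + 0.05 * age + 1e-4 * age^2 + rnorm(50)
  got <- lrt_age_quadratic(y, age)
  rss0 <- sum(lm(y ~ age)$residuals^2)
  rss1 <- sum(lm(y ~ age + I(age^2))$residuals^2)
  expect_equal(got$lr, 50 * log(rss0 / rss1), tolerance = 1e-10)
  expect_equal(got$p, pchisq(50 * log(rss0 / rss1), 1, lower.tail = FALSE))
  expect_error(lrt_age_quadratic(y[1:5], age[1:5]), "10 complete")
})

test_that("a pure diagnosis shift yields eta2 = 1 and type III matches the oracle", {
  dem <- demo_toy(12, 12, 12, seed = 25)
  shift <- c(AD = 1, ASD = 0, CON = -1)[dem$diagnosis]
  fits <- fit_models(unname(shift), dem, use_age2 = FALSE)
  e <- partial_eta2_type3(fits$M1, "Diagnosis")
  expect_equal(e$eta2, 1, tolerance = 1e-9)
  ## arbitrary data: matrix-free oracle via explicit drop-column refits
  set.seed(26)
  y <- rnorm(36) + 0.5 * (dem$diagnosis == "AD")
  fits2 <- fit_models(y, dem, use_age2 = FALSE)
  mm <- model.matrix(fits2$M1)
  asgn <- attr(mm, "assign")
  dcols <- which(asgn == match("Diagnosis", attr(terms(fits2$M1), "term.labels")))
  expect_equal(partial_eta2_type3(fits2$M1, "Diagnosis")$eta2,
               eta2_oracle(y, mm, dcols), tolerance = 1e-10)
  ## 1-df term identity: eta2 = t^2 / (t^2 + df_res)
  tval <- summary(fits2$M1)$coefficients["IQ", "t value"]
  df_res <- fits2$M1$df.residual
  expect_equal(partial_eta2_type3(fits2$M1, "IQ")$eta2,
               tval^2 / (tval^2 + df_res), tolerance = 1e-10)
})

test_that("one-way three-group toy equals the hand-computed decomposition", {
  y <- c(4.1, 3.9, 4.0, 5.2, 5.1, 4.8, 6.3, 6.1, 6.0)
  g <- factor(rep(c("AD", "ASD", "CON"), each = 3))
  fit <- lm(y ~ g, contrasts = list(g = "contr.sum"))
  e <- partial_eta2_type3(fit, "g")
  ss_b <- sum(3 * (tapply(y, g, mean) - mean(y))^2)
  ss_w <- sum((y - ave(y, g))^2)
  expect_equal(e$eta2, ss_b / (ss_b + ss_w), tolerance = 1e-12)
})

test_that("balanced orthogonal design: type III equals sequential SS", {
  dem <- expand.grid(sex = c("F", "M"), diagnosis = c("AD", "ASD", "CON"),
                     rep = 1:6, stringsAsFactors = FALSE)
  dem$participant_id <- sprintf("B%02d", seq_len(nrow(dem)))
  dem$age_months <- 100; dem$iq <- 100; dem$dataset <- "toy"
  set.seed(27)
  y <- rnorm(nrow(dem)) + (dem$diagnosis == "AD")
  df <- data.frame(y = y, Sex = factor(dem$sex),
                   Diagnosis = factor(dem$diagnosis))
  fit <- lm(y ~ Sex + Diagnosis, data = df,
            contrasts = list(Sex = "contr.sum", Diagnosis = "contr.sum"))
  t3 <- partial_eta2_type3(fit, "Diagnosis")
  seq_ss <- anova(fit)["Diagnosis", "Sum Sq"]
  expect_equal(t3$ss_term, seq_ss, tolerance = 1e-9)
})

test_that("GVIF: orthogonal designs, the 1/(1-r^2) closed form, aliasing", {
  set.seed(28)
  n <- 4000
  x1 <- rnorm(n); x2 <- rnorm(n)
  ## exactly orthogonalise x2 against x1
  x2 <- residuals(lm(x2 ~ x1))
  y <- rnorm(n)
  f <- lm(y ~ x1 + x2)
  g <- compute_gvif(f)
  expect_equal(g$gvif, c(1, 1), tolerance = 1e-10)
  ## exact correlation 0.6 by construction
  x2c <- 0.6 * scale(x1)[, 1] + sqrt(1 - 0.36) * scale(x2)[, 1]
  f2 <- lm(y ~ x1 + x2c)
  g2 <- compute_gvif(f2)
  r2 <- cor(x1, x2c)^2
  expect_equal(g2$gvif, rep(1 / (1 - r2), 2), tolerance = 1e-10)
  expect_equal(g2$adj_gvif, sqrt(g2$gvif), tolerance = 1e-12)
  expect_equal(1 / (1 - 0.6^2), 1.5625)
  ## duplicated predictor
  f3 <- lm(y ~ x1 + I(2 * x1))
  expect_error(compute_gvif(f3), "aliased")
})

test_that("effect_table sweeps all variables, groups, models and terms", {
  dem <- demo_toy(15, 15, 30, seed = 29)
  keys <- c("power_abs.frontal.delta", "slope.central.exponent",
            "mse.occipital.scales_01_05")
  ft <- simulate_features(dem, keys, seed = 30)
  eff <- effect_table(ft, dem)
  expect_equal(attr(eff, "n_fits"), length(keys) * 3 * 4)
  expect_equal(nrow(eff), length(keys) * 3 * 7)
  expect_setequal(unique(eff$term),
                  c("Age", "Sex", "IQ", "Diagnosis", "Diagnosis:Sex",
                    "Diagnosis:Age", "Age:Sex:Diagnosis"))
  expect_true(all(eff$eta2 >= 0 & eff$eta2 <= 1, na.rm = TRUE))
  expect_true(all(eff$n_used <= 60))
  ## deterministic: no randomness in the sweep
  expect_identical(eff$eta2, effect_table(ft, dem)$eta2)
})

test_that("null simulation: supra-threshold rate tracks the F-tail", {
  ## P(eta2 > c) for the 2-df Diagnosis term equals
  ## P(F(2, df2) > c/(1-c) * df2/2); Monte-Carlo at n = 120 per fit
  set.seed(31)
  n <- 120
  dem <- demo_toy(30, 30, 60, seed = 31)
  nrep <- 400
  hits <- 0
  for (i in 1:nrep) {
    y <- rnorm(n)
    df <- data.frame(y = y, Diagnosis = factor(dem$diagnosis))
    mm <- model.matrix(~ Diagnosis, df,
                       contrasts.arg = list(Diagnosis = "contr.sum"))
    e <- eegstability:::eta2_from_matrices(y, mm, attr(mm, "assign"), 1L)
    if (e$eta2 > 0.035) hits <- hits + 1
  }
  df2 <- n - 3
  expected <- pf(0.035 / (1 - 0.035) * df2 / 2, 2, df2, lower.tail = FALSE)
  expect_lt(abs(hits / nrep - expected), 3 * sqrt(expected * (1 - expected) / nrep) + 0.01)
})
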