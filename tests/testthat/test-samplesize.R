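test_that("subsampling preserves diagnosis x sex proportions", {
  dem <- demo_toy(25, 25, 50, seed = 51)
  all_ids <- subsample_ids(dem, 1.0, seed = 1)
  expect_setequal(all_ids, dem$participant_id)
  cell <- interaction(dem$diagnosis, dem$sex, drop = TRUE)
  for (s in 1:100) {
    ids <- subsample_ids(dem, 0.5, seed = s)
    expect_equal(length(ids), 50)
    expect_false(anyDuplicated(ids) > 0)
    sel <- dem$participant_id %in% ids
    expect_true(all(abs(table(cell[sel]) - 0.5 * table(cell)) <= 1))
  }
  expect_identical(subsample_ids(dem, 0.3, seed = 4),
                   subsample_ids(dem, 0.3, seed = 4))
  expect_error(subsample_ids(dem, 0, seed = 1), "fraction")
})

test_that("supra-threshold patterns label cells correctly", {
  eff <- data.frame(variable = c("a", "b", "c"), term = "Diagnosis",
                    eta2 = c(0.1, 0.01, NA))
  p <- supra_threshold_pattern(eff)
  expect_equal(unname(p), c(1L, 0L, 0L))
  expect_equal(unname(supra_threshold_pattern(transform(eff, eta2 = 0))),
               rep(0L, 3))
  expect_equal(unname(supra_threshold_pattern(
    transform(eff, eta2 = c(1, 2, 3)), threshold = 0)), rep(1L, 3))
})

test_that("NMI matches hand-computed and degenerate cases", {
  ## identical non-degenerate patterns
  expect_equal(nmi_partition(c(1, 1, 0, 0), c(1, 1, 0, 0)), 1)
  ## independent 2x2: all cells equal -> MI = 0
  expect_equal(nmi_partition(c(1, 1, 0, 0), c(1, 0, 1, 0)), 0)
  ## degenerate: both single-class -> 1; exactly one -> 0
  expect_equal(nmi_partition(c(1, 1, 1), c(1, 1, 1)), 1)
  expect_equal(nmi_partition(c(0, 0, 0), c(0, 0, 0)), 1)
  expect_equal(nmi_partition(c(1, 1, 1), c(1, 0, 1)), 0)
  ## symmetry and oracle agreement on random patterns
  set.seed(52)
  for (i in 1:20) {
    a <- rbinom(60, 1, 0.4); b <- rbinom(60, 1, 0.6)
    if (length(unique(a)) < 2 || length(unique(b)) < 2) next
    expect_equal(nmi_partition(a, b), nmi_oracle(a, b), tolerance = 1e-10)
    expect_equal(nmi_partition(a, b), nmi_partition(b, a), tolerance = 1e-12)
  }
  ## long independent patterns: near zero
  a <- rbinom(1e4, 1, 0.5); b <- rbinom(1e4, 1, 0.5)
  expect_lt(nmi_partition(a, b), 0.01)
  expect_error(nmi_partition(1:3, 1:4), "length mismatch")
})

test_that("bootstrap_curve emits the expected record structure", {
  dem <- demo_toy(20, 12, 40, seed = 53)
  keys <- c("power_abs.frontal.delta", "power_abs.frontal.alpha",
            "slope.central.exponent")
  grouping <- assign_age_tertiles(dem)
  ft <- simulate_features(dem, keys, seed = 54, strata = grouping$labels,
                          age_slope = c("delta" = 1))
  bc <- bootstrap_curve(ft, dem, grouping, fractions = 0.8, reps = 2, seed = 5)
  ## 3 age groups x 1 fraction x 2 reps x 7 terms
  expect_equal(nrow(bc$runs), 3 * 2 * 7)
  ## C(2,2) = 1 NMI pair per term per age group
  expect_equal(nrow(bc$nmi), 3 * 7)
  expect_true(all(bc$nmi$nmi >= 0 & bc$nmi$nmi <= 1))
  expect_true(all(bc$runs$prop_supra >= 0 & bc$runs$prop_supra <= 1))
})

test_that("matched samples satisfy every pairwise constraint", {
  dem <- demo_toy(20, 10, 40, seed = 55)
  pairs <- matched_sample(dem)
  expect_true(all(abs(pairs$age_diff) <= 5))
  expect_true(all(abs(pairs$iq_diff) <= 10))
  idx_case <- match(pairs$case_id, dem$participant_id)
  idx_con <- match(pairs$control_id, dem$participant_id)
  expect_identical(dem$sex[idx_case], dem$sex[idx_con])
  expect_true(all(dem$diagnosis[idx_case] %in% c("AD", "ASD")))
  expect_true(all(dem$diagnosis[idx_con] == "CON"))
  expect_false(anyDuplicated(pairs$control_id) > 0)
  ## a case with no eligible control is dropped
  lone <- data.frame(participant_id = c("x1", "c1"),
                     age_months = c(50, 200), sex = c("F", "F"),
                     iq = c(100, 100), diagnosis = c("AD", "CON"),
                     dataset = "toy", stringsAsFactors = FALSE)
  expect_equal(nrow(matched_sample(lone)), 0)
  ## greedy trace oracle: independent re-implementation
  oracle <- local({
    cases <- dem[dem$diagnosis != "CON", ]
    cases <- cases[order(cases$age_months, cases$participant_id), ]
    cons <- dem[dem$diagnosis == "CON", ]
    taken <- character(0); res <- character(0)
    for (i in seq_len(nrow(cases))) {
      ok <- cons[!(cons$participant_id %in% taken) &
                   cons$sex == cases$sex[i] &
                   abs(cons$age_months - cases$age_months[i]) <= 5 &
                   abs(cons$iq - cases$iq[i]) <= 10, ]
      if (!nrow(ok)) next
      ok <- ok[order(abs(ok$age_months - cases$age_months[i]),
                     abs(ok$iq - cases$iq[i]), ok$participant_id), ]
      taken <- c(taken, ok$participant_id[1])
      res <- c(res, cases$participant_id[i])
    }
    list(cases = res, controls = taken)
  })
  expect_identical(pairs$case_id, oracle$cases)
  expect_identical(pairs$control_id, oracle$controls)
})
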