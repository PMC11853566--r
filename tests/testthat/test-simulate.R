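test_that("generate_demographics honours counts, strata and determinism", {
  cfg <- cohort_config(n_per_stratum = c(AD = 10, ASD = 10, CON = 10))
  d1 <- generate_demographics(cfg, seed = 1)
  expect_equal(nrow(d1), 90)
  expect_equal(as.integer(table(d1$diagnosis)), rep(30L, 3))
  expect_true(all(d1$age_months >= 3 & d1$age_months <= 248))
  expect_identical(d1, generate_demographics(cfg, seed = 1))
  expect_false(identical(d1, generate_demographics(cfg, seed = 2)))
})

test_that("impossible configurations are rejected", {
  expect_error(cohort_config(n_per_stratum = c(AD = 0, ASD = 0, CON = 0)),
               "non-positive total")
  expect_error(cohort_config(female_prop = c(AD = 1.4, ASD = 0.5, CON = 0.5)),
               "sex ratio")
  expect_error(generate_demographics(cohort_config()), "seed")
})

test_that("IQ distribution matches its specification at large n", {
  cfg <- cohort_config(n_per_stratum = c(AD = 0, ASD = 0, CON = 3334))
  d <- generate_demographics(cfg, seed = 5)
  expect_gt(nrow(d), 10000 - 3)
  expect_lt(abs(mean(d$iq) - 100), 1)
  expect_lt(abs(sd(d$iq) - 15), 1)
})

test_that("all-zero effect spec yields an all-zero recording", {
  lay <- toy_layout(8)
  rec <- generate_recording(list(participant_id = "z", age_months = 50,
                                 sex = "M", iq = 100, diagnosis = "CON"),
                            effect_spec(), lay, n_epochs = 2, seed = 1)
  expect_true(all(rec$data == 0))
})

test_that("a pure alpha oscillation concentrates spectral power in band", {
  lay <- toy_layout(8)
  eff <- effect_spec(osc_base = c(alpha = 1))
  rec <- generate_recording(list(participant_id = "a", age_months = 50,
                                 sex = "M", iq = 100, diagnosis = "CON"),
                            eff, lay, n_epochs = 3, seed = 2)
  for (ch in 1:4) {
    fr <- periodogram_band_fraction(rec$data[, ch, 1], rec$sfreq, 8, 14)
    expect_gt(fr, 0.95)
  }
})

test_that("recording generation is deterministic and errors on bad input", {
  lay <- toy_layout(8)
  rec_args <- list(record = list(participant_id = "d", age_months = 50,
                                 sex = "F", iq = 100, diagnosis = "AD"),
                   effects = default_effects(), layout = lay,
                   n_epochs = 2, seed = 9)
  r1 <- do.call(generate_recording, rec_args)
  r2 <- do.call(generate_recording, rec_args)
  expect_identical(r1$data, r2$data)
  expect_error(do.call(generate_recording, modifyList(rec_args, list(epoch_length = 100))),
               "2 cycles")
  expect_error(do.call(generate_recording, modifyList(rec_args, list(sampling_rate = 100))),
               "sampling rate")
})

test_that("PAC injection raises Tort MI for the injected pair only", {
  lay <- toy_layout(8)
  ## theta oscillation present so the control pair has genuine theta phase
  ## (otherwise alpha leakage through the wide theta filter dominates)
  eff <- effect_spec(osc_base = c(theta = 1, alpha = 1, gamma_low = 1),
                     pac = data.frame(phase_band = "alpha",
                                      amp_band = "gamma_low", depth = 1),
                     noise_sd = 0.05)
  rec <- generate_recording(list(participant_id = "p", age_months = 50,
                                 sex = "M", iq = 100, diagnosis = "CON"),
                            eff, lay, n_epochs = 8, seed = 4)
  mi_inj <- mean(pac_band_pair(rec, "alpha", "gamma_low"))
  mi_ctrl <- mean(pac_band_pair(rec, "theta", "gamma_low"))
  expect_gt(mi_inj, 5 * mi_ctrl)
})

test_that("shared-source injection raises ISPC in the injected band", {
  lay <- toy_layout(8)
  eff <- effect_spec(osc_base = c(alpha = 0.2), ispc = c(alpha = 1),
                     noise_sd = 0.3)
  rec <- generate_recording(list(participant_id = "i", age_months = 50,
                                 sex = "M", iq = 100, diagnosis = "CON"),
                            eff, lay, n_epochs = 6, seed = 5)
  null_eff <- effect_spec(osc_base = c(alpha = 0.2), noise_sd = 0.3)
  rec0 <- generate_recording(list(participant_id = "i0", age_months = 50,
                                  sex = "M", iq = 100, diagnosis = "CON"),
                             null_eff, lay, n_epochs = 6, seed = 5)
  pair <- cbind("ch1", "ch2")
  expect_gt(ispc(rec, "alpha", pair)$ispc, ispc(rec0, "alpha", pair)$ispc)
})

test_that("generate_cohort yields one recording per row, reproducibly", {
  cfg <- cohort_config(n_per_stratum = c(AD = 2, ASD = 1, CON = 1))
  coh <- generate_cohort(cfg, effect_spec(osc_base = c(alpha = 1), noise_sd = 0.1),
                         toy_layout(8), seed = 6, n_epochs = 2)
  expect_equal(length(coh$recordings), nrow(coh$demographics))
  expect_identical(names(coh$recordings), coh$demographics$participant_id)
  coh2 <- generate_cohort(cfg, effect_spec(osc_base = c(alpha = 1), noise_sd = 0.1),
                          toy_layout(8), seed = 6, n_epochs = 2)
  expect_identical(coh$recordings[[3]]$data, coh2$recordings[[3]]$data)
})

test_that("feature-level simulator injects effects on matched keys only", {
  dem <- demo_toy(20, 20, 40)
  keys <- c("power_abs.frontal.delta", "power_abs.frontal.alpha", "mse.central.scales_01_05")
  ft <- simulate_features(dem, keys, seed = 3,
                          diag_shift = list("delta" = c(AD = 3, ASD = 3, CON = 0)))
  expect_identical(names(ft), c("participant_id", keys))
  d_delta <- mean(ft[[2]][dem$diagnosis != "CON"]) - mean(ft[[2]][dem$diagnosis == "CON"])
  d_alpha <- mean(ft[[3]][dem$diagnosis != "CON"]) - mean(ft[[3]][dem$diagnosis == "CON"])
  expect_gt(d_delta, 2)
  expect_lt(abs(d_alpha), 1)
  expect_identical(ft, simulate_features(dem, keys, seed = 3,
                                         diag_shift = list("delta" = c(AD = 3, ASD = 3, CON = 0))))
})
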