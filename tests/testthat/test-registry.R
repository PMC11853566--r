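test_that("layout validation catches malformed montages", {
  expect_error(channel_layout(c("a", "a"), 1:2, 1:2, 1:2,
                              c("frontal", "frontal"), c("left", "right")),
               "duplicate channel names")
  expect_error(channel_layout(c("a", "b"), c(1, 1), c(0, 0), c(0, 0),
                              c("frontal", "frontal"), c("left", "right")),
               "duplicate channel positions")
  lay <- default_layout()
  expect_true(all(abs(lay$x^2 + lay$y^2 + lay$z^2 - 1) < 1e-12))
  expect_true(all(lay$hemisphere %in% c("left", "right", "midline")))
})

test_that("default registry has the canonical size and family subcounts", {
  reg <- build_registry(default_layout())
  expect_equal(nrow(reg), 726)
  counts <- table(reg$family)
  expect_equal(unname(counts["power_abs"] + counts["power_rel"] +
                        counts["power_log"]), 324)
  expect_equal(unname(counts["slope"]), 36L)
  expect_equal(unname(counts["paf"]), 36L)
  expect_equal(unname(counts["pac"]), 216L)
  expect_equal(unname(counts["mse"]), 72L)
  expect_equal(unname(counts["ispc"]), 42L)
  grp <- attr(reg, "groupings")
  expect_length(grp$regional, 13)
  expect_length(grp$asymmetry, 5)
  expect_length(attr(reg, "ispc_contrasts"), 7)
})

test_that("registry keys depend on groupings, not on specific channels", {
  k1 <- build_registry(default_layout())$key
  k2 <- build_registry(toy_layout(10))$key
  expect_identical(k1, k2)
})

test_that("a grouping resolving to zero channels is an error", {
  lay <- toy_layout(10)
  lay$region[lay$region == "occipital"] <- "parietal"
  expect_error(channel_groupings(lay), "zero channels")
})

test_that("aggregation: constant input, asymmetry arithmetic, linearity", {
  lay <- default_layout()
  reg <- build_registry(lay)
  grp <- attr(reg, "groupings")

  fake_metrics <- function(chan_vals) {
    nch <- length(chan_vals)
    grid <- frequency_grid()
    power <- matrix(rep(chan_vals, length(grid)), nch)
    rel <- power / rowSums(power)
    list(spectrum = list(freq = grid, power = power, relative = rel,
                         log_power = suppressWarnings(log10(power))),
         slope = cbind(exponent = chan_vals, offset = chan_vals),
         paf = cbind(frequency = chan_vals, amplitude = chan_vals),
         pac = matrix(chan_vals, nch, 12,
                      dimnames = list(NULL, paste(pac_band_pairs()$phase_band,
                                                  pac_band_pairs()$amp_band,
                                                  sep = "_"))),
         mse = matrix(chan_vals, nch, 20,
                      dimnames = list(NULL, paste0("scale", 1:20))),
         ispc = lapply(canonical_bands(), function(b) {
           M <- matrix(0.5, nch, nch,
                       dimnames = list(lay$channel, lay$channel)); M
         }),
         channels = lay$channel)
  }

  v <- fake_metrics(rep(2, nrow(lay)))
  row <- aggregate_features(v, reg)
  expect_true(all(abs(row[grepl("^slope\\.(?!asym)", names(row), perl = TRUE)] - 2) < 1e-12))
  ## every asymmetry contrast of a constant field is zero
  asym <- row[grepl("^(power_abs|slope|paf|pac|mse)\\.asym_", names(row))]
  expect_true(all(abs(asym) < 1e-12))

  ## interhemispheric contrast: left = 2, right = 1 -> L - R = 1
  cv <- ifelse(lay$hemisphere == "left", 2,
               ifelse(lay$hemisphere == "right", 1, 0))
  row2 <- aggregate_features(fake_metrics(cv), reg)
  expect_equal(unname(row2["slope.asym_interhemispheric.exponent"]), 1)

  ## regional mean equals the hand-computed mean of member channels
  set.seed(11)
  rv <- rnorm(nrow(lay))
  row3 <- aggregate_features(fake_metrics(rv), reg)
  for (g in c("frontal", "central", "hemisphere_left")) {
    manual <- mean(rv[match(grp$regional[[g]], lay$channel)])
    expect_equal(unname(row3[paste0("slope.", g, ".exponent")]), manual)
  }

  ## linearity of mean-type aggregation
  rv2 <- rnorm(nrow(lay))
  ra <- aggregate_features(fake_metrics(rv), reg)
  rb <- aggregate_features(fake_metrics(rv2), reg)
  rab <- aggregate_features(fake_metrics(2 * rv + 3 * rv2), reg)
  sl <- grepl("^slope\\.", names(ra))
  expect_equal(rab[sl], 2 * ra[sl] + 3 * rb[sl], tolerance = 1e-10)
})

test_that("relative-power regional values sum to 1 across the six bands", {
  lay <- default_layout()
  reg <- build_registry(lay)
  eeg <- sine_eeg(lay, freq = 10, epochs = 2, noise = 0.5, seed = 3)
  row <- compute_features(eeg, reg)
  grp <- attr(reg, "groupings")
  for (g in names(grp$regional)) {
    s <- sum(row[paste0("power_rel.", g, ".", names(canonical_bands()))])
    expect_equal(s, 1, tolerance = 1e-6)
  }
})
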