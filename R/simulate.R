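#' Ground-truth effect specification for the EEG generator
#'
#' Describes how band-limited oscillation amplitudes depend on participant
#' covariates, the aperiodic background, and optional cross-frequency /
#' inter-channel coupling. Setting every effect entry to zero yields
#' exchangeable groups (a null generator). Units: amplitudes and noise in
#' microvolts; age slopes in microvolts per SD of age; sex/diagnosis offsets
#' in microvolts; PAC depth and ISPC weight dimensionless.
#'
#' @param osc_base named per-band oscillation base amplitudes (uV).
#' @param age_slope named per-band change in amplitude per SD of age.
#' @param sex_offset named per-band amplitude offset for female participants.
#' @param diag_offset named list: band -> c(AD=, ASD=, CON=) offsets.
#' @param aperiodic_amp background (1/f) process SD in uV.
#' @param aperiodic_exponent,aperiodic_exponent_sd mean/SD of the per-subject
#'   1/f exponent (truncated below at 0.5).
#' @param pac data frame with columns `phase_band`, `amp_band`, `depth`
#'   (modulation depth in `[0, 1+]`); NULL for none.
#' @param ispc named per-band weight of a shared source mixed into every
#'   channel; NULL/0 for none.
#' @param noise_sd white measurement noise SD in uV.
#' @param age_center,age_scale months; standardisation used for age slopes.
#' @return an `effect_spec` list.
#' @export
effect_spec <- function(osc_base = c(delta = 0, theta = 0, alpha = 0,
                                     beta = 0, gamma_low = 0, gamma_high = 0),
                        age_slope = NULL, sex_offset = NULL, diag_offset = NULL,
                        aperiodic_amp = 0,
                        aperiodic_exponent = 1.5, aperiodic_exponent_sd = 0.2,
                        pac = NULL, ispc = NULL, noise_sd = 0,
                        age_center = 125, age_scale = 60) {
  if (any(osc_base < 0)) stop("oscillation amplitudes must be non-negative")
  if (aperiodic_amp < 0 || noise_sd < 0) stop("amplitudes must be non-negative")
  structure(list(osc_base = osc_base, age_slope = age_slope,
                 sex_offset = sex_offset, diag_offset = diag_offset,
                 aperiodic_amp = aperiodic_amp,
                 aperiodic_exponent = aperiodic_exponent,
                 aperiodic_exponent_sd = aperiodic_exponent_sd,
                 pac = pac, ispc = ispc, noise_sd = noise_sd,
                 age_center = age_center, age_scale = age_scale),
            class = "effect_spec")
}

#' Default realistic cohort effects
#'
#' Maturational effects the analysis is expected to recover on synthetic
#' data: delta/theta amplitude decreasing and alpha increasing with age, a
#' modest female alpha offset, a 1/f background, and measurement noise.
#' Diagnosis effects are zero (the null world) unless supplied.
#'
#' @param diag_offset optional diagnosis offsets, see [effect_spec()].
#' @return an `effect_spec`.
#' @export
default_effects <- function(diag_offset = NULL) {
  effect_spec(
    osc_base = c(delta = 2, theta = 1.5, alpha = 1.5, beta = 0.8,
                 gamma_low = 0.4, gamma_high = 0.2),
    age_slope = c(delta = -0.6, theta = -0.4, alpha = 0.4),
    sex_offset = c(alpha = 0.2),
    diag_offset = diag_offset,
    aperiodic_amp = 3, aperiodic_exponent = 1.5, aperiodic_exponent_sd = 0.2,
    noise_sd = 1)
}

#' Default demographic configuration
#'
#' Three age strata mirroring the tertile structure of a developmental
#' cohort (3-96, 98-126, 128-248 months) with per-diagnosis counts per
#' stratum, per-diagnosis female proportions, and an IQ distribution of
#' mean 100, SD 15 (truncated to 40-160).
#'
#' @param n_per_stratum named counts `c(AD=, ASD=, CON=)` used for every
#'   stratum, or a 3x3 matrix (strata rows, diagnosis columns).
#' @param female_prop named per-diagnosis female proportions.
#' @param iq_mean,iq_sd IQ distribution parameters.
#' @param age_breaks stratum bounds in months (4 values).
#' @param dataset dataset label column value.
#' @return a `cohort_config` list.
#' @export
cohort_config <- function(n_per_stratum = c(AD = 20, ASD = 10, CON = 30),
                          female_prop = c(AD = 0.25, ASD = 0.47, CON = 0.45),
                          iq_mean = 100, iq_sd = 15,
                          age_breaks = c(3, 96, 126, 248),
                          dataset = "synthetic") {
  if (is.matrix(n_per_stratum)) {
    counts <- n_per_stratum
  } else {
    counts <- matrix(rep(n_per_stratum, each = 3), nrow = 3,
                     dimnames = list(NULL, names(n_per_stratum)))
  }
  if (is.null(colnames(counts)) ||
      !setequal(colnames(counts), c("AD", "ASD", "CON")))
    stop("counts must be named AD/ASD/CON")
  if (any(counts < 0) || sum(counts) <= 0) stop("non-positive total cohort")
  if (any(female_prop < 0 | female_prop > 1)) stop("impossible sex ratio")
  structure(list(counts = counts[, c("AD", "ASD", "CON")],
                 female_prop = female_prop, iq_mean = iq_mean, iq_sd = iq_sd,
                 age_breaks = age_breaks, dataset = dataset),
            class = "cohort_config")
}

#' Generate a demographics table
#'
#' @param config a [cohort_config()].
#' @param seed integer seed; generation is deterministic given the seed.
#' @return data frame with columns `participant_id`, `age_months`, `sex`
#'   (F/M), `iq`, `diagnosis` (AD/ASD/CON), `dataset`.
#' @export
generate_demographics <- function(config = cohort_config(), seed) {
  if (missing(seed)) stop("seed is required")
  set.seed(as.integer(seed))
  rows <- list()
  brk <- config$age_breaks
  for (s in 1:3) for (dg in c("AD", "ASD", "CON")) {
    n <- config$counts[s, dg]
    if (n == 0) next
    age <- stats::runif(n, brk[s] + (s > 1) * 1e-6, brk[s + 1])
    n_f <- round(config$female_prop[[dg]] * n)
    sex <- sample(c(rep("F", n_f), rep("M", n - n_f)))
    iq <- pmin(160, pmax(40, stats::rnorm(n, config$iq_mean, config$iq_sd)))
    rows[[length(rows) + 1L]] <- data.frame(
      age_months = age, sex = sex, iq = iq, diagnosis = dg,
      dataset = config$dataset, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out <- data.frame(participant_id = sprintf("P%04d", seq_len(nrow(out))), out,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

## deterministic per-participant sub-seed below 2^31
derive_seed <- function(master, i) {
  (as.numeric(master) * 48271 + i * 7919) %% 2147483647
}

#' Generate one participant's epoched recording
#'
#' Each epoch and channel receives: a 1/f^chi background (spectrally shaped
#' white noise), one sinusoidal oscillation per band whose amplitude is the
#' effect spec evaluated at the participant's covariates (clamped at zero),
#' optional amplitude modulation of a high band by a low band's phase
#' (`a(t) = 1 + depth * cos(phi_low(t))`), an optional band-limited source
#' shared across channels, and white noise.
#'
#' @param record one demographics row.
#' @param effects an [effect_spec()].
#' @param layout a [channel_layout()].
#' @param n_epochs,sampling_rate,epoch_length epochs, Hz, samples per epoch.
#' @param seed integer seed.
#' @return an [epoched_eeg()].
#' @export
generate_recording <- function(record, effects, layout, n_epochs = 60,
                               sampling_rate = 250, epoch_length = 500, seed) {
  if (missing(seed)) stop("seed is required")
  if (n_epochs < 1) stop("need at least one epoch")
  if (sampling_rate < 160) stop("sampling rate must be at least 2 x 80 Hz")
  if (epoch_length / sampling_rate < 1) stop("epoch shorter than 2 cycles of 2 Hz")
  set.seed(as.integer(seed))
  bands <- canonical_bands()
  z_age <- (record$age_months - effects$age_center) / effects$age_scale
  getv <- function(v, b) if (!is.null(v) && b %in% names(v)) v[[b]] else 0
  amp <- vapply(names(bands), function(b) {
    a <- getv(effects$osc_base, b) + getv(effects$age_slope, b) * z_age
    if (identical(record$sex, "F")) a <- a + getv(effects$sex_offset, b)
    dof <- effects$diag_offset[[b]]
    if (!is.null(dof)) a <- a + getv(dof, record$diagnosis)
    max(a, 0)
  }, numeric(1))
  chi <- max(0.5, stats::rnorm(1, effects$aperiodic_exponent,
                               effects$aperiodic_exponent_sd))
  n <- epoch_length; nch <- nrow(layout)
  tvec <- (seq_len(n) - 1) / sampling_rate
  fc <- vapply(bands, mean, numeric(1))
  pac <- effects$pac
  dat <- array(0, dim = c(n, nch, n_epochs))
  for (e in seq_len(n_epochs)) {
    shared <- list()
    if (!is.null(effects$ispc)) {
      for (b in names(effects$ispc)) {
        if (effects$ispc[[b]] > 0)
          shared[[b]] <- sin(2 * pi * fc[[b]] * tvec + stats::runif(1, 0, 2 * pi))
      }
    }
    for (ch in seq_len(nch)) {
      x <- numeric(n)
      if (effects$aperiodic_amp > 0)
        x <- x + effects$aperiodic_amp * shaped_noise(n, sampling_rate, chi)
      phases <- stats::runif(length(fc), 0, 2 * pi)
      names(phases) <- names(fc)
      osc <- lapply(names(fc), function(b) {
        if (amp[[b]] <= 0) return(numeric(n))
        amp[[b]] * sin(2 * pi * fc[[b]] * tvec + phases[[b]])
      })
      names(osc) <- names(fc)
      if (!is.null(pac)) for (i in seq_len(nrow(pac))) {
        pb <- pac$phase_band[i]; ab <- pac$amp_band[i]; d <- pac$depth[i]
        if (d > 0 && amp[[ab]] > 0) {
          phi_low <- 2 * pi * fc[[pb]] * tvec + phases[[pb]]
          osc[[ab]] <- osc[[ab]] * (1 + d * cos(phi_low)) / (1 + d)
        }
      }
      x <- x + Reduce(`+`, osc)
      for (b in names(shared))
        x <- x + effects$ispc[[b]] * shared[[b]]
      if (effects$noise_sd > 0)
        x <- x + stats::rnorm(n, 0, effects$noise_sd)
      dat[, ch, e] <- x
    }
  }
  epoched_eeg(dat, sampling_rate, layout, record$participant_id)
}

## 1/f^chi background: unit-SD spectrally shaped white noise
shaped_noise <- function(n, sfreq, chi) {
  w <- stats::rnorm(n)
  X <- stats::fft(w)
  f <- (0:(n - 1)) * sfreq / n
  f[f > sfreq / 2] <- sfreq - f[f > sfreq / 2]   # fold to physical frequency
  shape <- c(0, 1 / f[-1]^(chi / 2))
  x <- Re(stats::fft(X * shape, inverse = TRUE)) / n
  s <- stats::sd(x)
  if (s > 0) x / s else x
}

#' Generate a full synthetic cohort
#'
#' One recording per demographics row, with per-participant seeds derived
#' deterministically from the master seed.
#'
#' @param config a [cohort_config()] or an existing demographics data frame.
#' @param effects an [effect_spec()].
#' @param layout a [channel_layout()].
#' @param seed master integer seed.
#' @param ... passed to [generate_recording()].
#' @return list with `demographics` and `recordings` (named by participant).
#' @export
generate_cohort <- function(config = cohort_config(), effects = default_effects(),
                            layout = default_layout(), seed, ...) {
  if (missing(seed)) stop("seed is required")
  dem <- if (is.data.frame(config)) config else generate_demographics(config, seed)
  recs <- lapply(seq_len(nrow(dem)), function(i)
    generate_recording(dem[i, ], effects, layout,
                       seed = derive_seed(seed, i), ...))
  names(recs) <- dem$participant_id
  list(demographics = dem, recordings = recs)
}

#' Simulate a feature table directly (no signal synthesis)
#'
#' Draws standard-normal feature values and injects linear covariate effects
#' in SD units on selected variables. This feature-level generator serves
#' the statistics, replication and sample-size modules at cohort scales
#' where full signal synthesis plus feature extraction would be intractable;
#' the signal-level generator ([generate_cohort()]) validates the feature
#' extractors themselves.
#'
#' @param demographics a demographics data frame.
#' @param registry a [build_registry()] result (or character vector of keys).
#' @param seed integer seed.
#' @param age_slope named vector: regex on registry keys -> slope per SD age.
#' @param sex_shift named vector: regex -> shift (F minus M) in SD units.
#' @param diag_shift named list: regex -> c(AD=, ASD=, CON=) shifts in SD.
#' @param noise_sd residual SD.
#' @param strata optional factor (e.g. age-tertile labels): age is then
#'   standardised within stratum, so `age_slope` is the slope per SD of
#'   within-group age -- the scale on which the age-group-wise models see
#'   the effect.
#' @return feature-table data frame (`participant_id` + one column per key).
#' @export
simulate_features <- function(demographics, registry, seed,
                              age_slope = NULL, sex_shift = NULL,
                              diag_shift = NULL, noise_sd = 1, strata = NULL) {
  if (missing(seed)) stop("seed is required")
  set.seed(as.integer(seed))
  keys <- if (is.data.frame(registry)) registry$key else as.character(registry)
  n <- nrow(demographics)
  vals <- matrix(stats::rnorm(n * length(keys), 0, noise_sd), n,
                 dimnames = list(NULL, keys))
  z_age <- if (is.null(strata)) as.numeric(scale(demographics$age_months))
  else stats::ave(demographics$age_months, strata,
                  FUN = function(a) as.numeric(scale(a)))
  for (pat in names(age_slope)) {
    hit <- grepl(pat, keys)
    vals[, hit] <- vals[, hit] + outer(z_age * age_slope[[pat]], rep(1, sum(hit)))
  }
  for (pat in names(sex_shift)) {
    hit <- grepl(pat, keys)
    vals[, hit] <- vals[, hit] +
      outer((demographics$sex == "F") * sex_shift[[pat]], rep(1, sum(hit)))
  }
  for (pat in names(diag_shift)) {
    hit <- grepl(pat, keys)
    sh <- diag_shift[[pat]][demographics$diagnosis]
    vals[, hit] <- vals[, hit] + outer(unname(sh), rep(1, sum(hit)))
  }
  data.frame(participant_id = demographics$participant_id, vals,
             check.names = FALSE, stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
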