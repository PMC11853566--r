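---
title: "Methods: simulating, measuring and stress-testing resting-state EEG group differences"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating, measuring and stress-testing resting-state EEG group differences}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem this package addresses

Resting-state EEG (rsEEG) studies of autism have reported group differences
in almost every spectral and dynamical quantity ever measured, and almost
none of those differences replicate across laboratories. A credible way to
probe this situation is to compute a very large, standardised battery of
rsEEG variables in one cohort, measure group effects with a single
transparent model family, and then attack one's own findings with
resampling: split-half replication and sample-size bootstraps. This package
implements that full workflow as reusable, tested code, driven by a
synthetic-cohort generator, because the motivating cohorts (five NIMH Data
Archive datasets) are access-restricted and cannot ship with software.

Every stage is therefore testable end-to-end: the generator injects known
effects (or none), and the analysis stack either recovers them or does not.

## The variable battery

A cleaned recording is an `epoched_eeg`: epochs x channels x samples, in
microvolts, with a montage (`channel_layout`) whose region and hemisphere
tags drive the channel groupings. Six metric families are computed per
channel and then averaged into 18 channel groupings -- 13 regional groups
(left/right frontal, left/right centroparietal, left/right
occipito-parietal, frontal, occipital, central, left/right lateral,
left/right hemisphere) and 5 asymmetry difference scores (interhemispheric,
rostrocaudal within each hemisphere, mediolateral within each hemisphere) --
and 6 canonical bands: delta 2-4, theta 4-8, alpha 8-14, beta 14-30, low
gamma 30-50, high gamma 50-80 Hz. The registry enumerates

* power, 3 forms x 18 groupings x 6 bands = 324,
* aperiodic (1/f) exponent and offset x 18 = 36,
* alpha-peak frequency and amplitude x 18 = 36,
* phase-amplitude coupling, 12 band pairs x 18 = 216,
* multiscale entropy, 4 scale bins x 18 = 72,
* inter-site phase clustering, 7 pair-set contrasts x 6 bands = 42,

726 variables in total. Two counting conventions deserve a note. First, the
12 PAC pairs are phase {delta, theta, alpha, beta} x amplitude {beta, low
gamma, high gamma}; the beta-on-beta pair has coincident band centres, so
the operation accepts phase centre less than *or equal to* the amplitude
centre -- the registry's printed decomposition (216 = 18 x 12) takes
precedence over a strict inequality. Second, relative power is aggregated
as the *sum* of per-frequency relative power over the band's grid
frequencies (the fraction of total 2-80 Hz power in the band), so the six
bands, which partition the grid, sum to exactly 1 per grouping; absolute
and log power use the band mean. A per-band mean of relative power could
not satisfy that partition identity on a log-spaced grid.

### Signal metrics and their numerical choices

**Narrowband power.** Each epoch's FFT is multiplied by a Gaussian centred
at each of 100 log-spaced frequencies (2-80 Hz), FWHM `max(0.25 f, 1)` Hz,
one-sided (analytic-signal convention). The time-averaged squared magnitude
of the analytic signal is evaluated via Parseval's identity on the weighted
spectrum -- algebraically identical to materialising the analytic signal,
and an explicit inverse-FFT oracle in the test suite confirms agreement to
1e-10.

**Aperiodic fit.** `log10 P = offset - exponent * log10 f` on 2-40 Hz, with
iterative masking of positive residual outliers (the oscillatory peaks),
i.e. a knee-free spectral parameterisation. Pure power laws are recovered
exactly; a 10x alpha peak perturbs the recovered exponent by less than 0.1.

**Peak alpha.** A single Gaussian is fit by least squares (mean/width grid,
closed-form height) to the power above the aperiodic fit within 6-14 Hz.
A peak must exceed 5% of the local aperiodic level, otherwise both PAF
variables are NA; grouping averages then use the channels where a peak
exists. The floor and the single-Gaussian choice are conventions -- the
battery needs *a* deterministic rule, and both are configurable arguments.

**PAC.** Tort's modulation index with 18 phase bins: bin amplitude by
phase, normalise bin means to a distribution, MI = (log N - H)/log N.
Epochs are filtered independently and concatenated before binning.
Closed-form cases (all-one-bin, two-bin: (ln 18 - ln 2)/ln 18 = 0.7602) are
asserted exactly.

**Multiscale entropy.** Coarse-grain by non-overlapping block means at
scales 1-20, sample entropy with m = 2 and tolerance 0.2 x the SD of the
scale-1 signal, held fixed across scales. One deviation from the obvious
per-epoch design: with 2 s epochs at 250 Hz, scales above 16 leave fewer
than the conventional 10(m+1) points per epoch, so template and match
counts are *pooled across epochs* before taking -log(A/B). This is the
standard epoched-EEG practice, reduces to plain SampEn for one epoch, and
keeps the 16-20 scale bin defined.

**Surface Laplacian and ISPC.** A Perrin-style spherical-spline current
source density (spline order 4, 10 Legendre terms, ridge 1e-5) precedes
connectivity: volume conduction inflates phase locking, the Laplacian
suppresses it. ISPC is the mean resultant length of the band-limited phase
difference per pair, epoch-averaged, summarised over 7 pair sets
(long-range fronto-posterior, homologous interhemispheric, intra-left,
intra-right, frontal-local, posterior-local, global). Only the long-range
set is dictated by the analysis design; the other six are declared
conventions, replaceable via the layout-driven contrast builder.

## The statistical engine

Participants are split into age **tertiles** with boundaries chosen (by
exhaustive search over cut pairs in the age-sorted autistic subsample) so
that AD and ASD counts are each as balanced as possible; controls follow
the same boundaries. Models are fit per variable within each tertile:

1. extreme outliers removed by a robust-z rule (|x - median| >
   3.5 x 1.4826 x MAD), with removal counts logged by autistic versus
   neurotypical status;
2. a Gaussian likelihood-ratio test (`LR = n log(RSS0/RSS1)`,
   chi-square(1), alpha = 0.05) decides whether `Age^2` joins the
   covariates;
3. four OLS models: M1 `~ Age + Sex + IQ + Diagnosis`; M2 adds
   `Diagnosis:Sex`; M3 adds `Diagnosis:Age`; M4 is
   `Age * Sex * Diagnosis + IQ`. Diagnosis (AD/ASD/CON) and Sex use
   sum-to-zero contrasts, Age and IQ are mean-centred within the fitted
   subset, and when selected `Age^2` enters as a main-effect covariate
   only;
4. type-III partial eta-squared per designated term --
   `SS_term = RSS(model minus term) - RSS(full)`,
   `eta2 = SS_term/(SS_term + RSS)` -- for Age, Sex, IQ and Diagnosis from
   M1 and the three interactions from M2-M4.

726 variables x 3 age groups x 4 models = 8712 fits. (The motivating study
prints N = 2,184 diagnosis coefficients where 726 x 3 = 2,178; the registry
count is used here and the 6-coefficient discrepancy remains unexplained.)
Fox-Monette generalised VIFs (adjusted form `GVIF^(1/(2 df))`) are exposed
as a multicollinearity diagnostic.

**Replication rate.** For each supra-threshold effect (eta2 > 0.035, the
boundary between small and moderate effects), 150 stratified half-splits
are drawn -- shuffle-and-alternate within diagnosis x sex x age-decile
cells, so halves differ by at most one participant per cell -- the model is
refit on each half with the full-data outlier mask and `Age^2` decision
frozen, and the replication rate is the fraction of splits with eta2 >
0.035 in *both* halves. Effects with rate >= 0.64 (the square of the 0.80
power convention) are deemed replicable. Splits are drawn without
replacement: "split the data into two halves" is taken literally. Freezing
the quadratic-age decision keeps the model space constant across splits;
re-deciding per half would conflate model-selection noise with effect
instability.

**Sample-size bootstrap.** For each age group and fraction (design: 10-70%
in steps of 10, 100 repetitions), a diagnosis x sex proportion-preserving
subsample (largest-remainder quotas) is drawn, the entire sweep is rerun,
and two statistics recorded: the proportion of supra-threshold effects per
term, and the normalised mutual information between the binary
supra-threshold patterns of every repetition pair, per term
(`2I/(H1+H2)`; sqrt and max normalisations selectable, sum is the default
since the reference implementation's normalisation is not documented).
Degenerate partitions follow the convention: two single-class patterns
agree perfectly (NMI 1), one single-class pattern carries no information
(NMI 0).

**Matched sample.** Autistic participants in ascending age order are
greedily paired with the unused control of the same sex within 5 months of
age and 10 IQ points, minimising the age gap (ties: IQ gap, then id). This
removes diagnosis-covariate collinearity entirely at the cost of n; the
package's null-world tests verify that matching does not systematically
inflate diagnosis effect sizes.

## The synthetic cohort: what it emulates and what it does not

`generate_demographics()` draws a cohort over three age strata (3-96,
98-126, 128-248 months -- the tertile structure of the motivating cohort),
with per-diagnosis female proportions (defaults 0.25/0.47/0.45 for
AD/ASD/CON, approximating the real cohort's composition) and IQ ~
N(100, 15) truncated to [40, 160]. `generate_recording()` builds each
epoch from: spectrally shaped 1/f^chi noise (chi ~ N(1.5, 0.2) truncated at
0.5 -- a generator convention; the motivating work measured exponents, it
did not simulate them); one sinusoid per band whose amplitude is the effect
specification evaluated at the participant's covariates, clamped at zero;
optional amplitude modulation `a(t) = 1 + d cos(phi_low)` of a high band by
a low band's phase (detectable by Tort MI by construction); an optional
shared band-limited source mixed into all channels (detectable by ISPC);
and white noise. Defaults: 250 Hz, 2 s epochs, 60 epochs, an idealised
32-channel extended 10-20 montage -- chosen to support 2-80 Hz analysis at
modest compute; epoch/channel counts in the motivating datasets ranged
10-160 and 51-125.

The default effect world (`default_effects()`) encodes the maturational
signals any credible rsEEG dataset shows -- delta/theta amplitude falling
and alpha rising with age, a small female alpha offset -- and **no**
diagnosis effect: the null world is the reference condition, and diagnosis
effects are opt-in.

Two honest limitations. The generator produces stationary sinusoids plus
1/f noise: no artifacts, no montage heterogeneity, no non-sinusoidal
waveform shape, no dataset batch effects (injectable in principle, not by
default). A green end-to-end test therefore establishes that the *analysis
machinery* is correct and calibrated, not that real autism cohorts behave
like the simulation. Second, full signal synthesis plus feature extraction
for hundreds of participants is not tractable in a test budget, so the
statistics, replication and bootstrap layers are exercised at scale through
`simulate_features()`, which draws the 726-column table directly with
injected covariate effects in SD units; the signal-level generator
validates the feature extractors themselves on small cohorts. One
consequence of the age-tertile design matters when injecting age effects:
a slope expressed per SD of *whole-cohort* age is diluted roughly threefold
within a tertile, so `simulate_features(strata = )` standardises age within
stratum -- "a 0.5-SD injected slope" then means 0.5 SD on the scale the
age-group-wise models actually see.

## Degenerate inputs and tie-breaking

Zero-amplitude recordings yield zero power and NA relative power; zero MAD
disables outlier removal; zero binned amplitude makes MI undefined (NA), as
does an absent template match in sample entropy; duplicate electrode
positions are an error for the Laplacian; rank-deficient model matrices
yield NA effect records (and failed half-fits count as non-replication);
age ties at tertile boundaries are resolved by participant id; odd
stratification cells alternate their surplus member across cells.

## Scale and reproducibility

All randomness flows from explicit seeds; per-participant, per-split and
per-subsample seeds are derived deterministically from the master seed, so
results are independent of execution order and bit-reproducible within a
BLAS configuration. The full 7 x 100 bootstrap and 150-split sweep over
all supra-threshold effects are production settings; the test suite runs
reduced designs (stated in each test) that exercise identical code paths.
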