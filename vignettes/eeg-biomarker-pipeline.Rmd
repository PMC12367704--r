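---
title: "Multiband EEG biomarkers for two-group studies: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiband EEG biomarkers for two-group studies: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# Scope

`eegmarkers` implements a complete resting-state EEG biomarker pipeline
for two-group (case/control) studies: multiband feature extraction from
windowed multichannel recordings, ensemble classification under k-fold
cross-validation, recursive feature elimination (RFE), and
spatio-spectral group-difference reporting. A synthetic cohort generator
with controllable, known group effects makes every stage testable
without clinical data. The reference configuration is a 16-channel
10--20 montage sampled at 128 Hz, with the group labels called HC
(healthy control) and SCZ (schizophrenia), the application that
motivated the pipeline; nothing in the code is specific to that
disorder.

# Signal model and preprocessing

Recordings are processed in a fixed order: broadband bandpass to
0.5--45 Hz, average re-referencing (the across-channel mean is
subtracted at every sample), decomposition into the five canonical
bands — Delta 0.5--4, Theta 4--8, Alpha 8--13, Beta 13--30, Gamma
30--45 Hz — and segmentation into non-overlapping windows, contiguous
from the first sample, with any trailing remainder dropped.

All filters are 4th-order Butterworth bandpasses applied
forward-backward (`signal::filtfilt`), i.e. zero net phase at an
effective 8th order. Zero-phase filtering matters because the
connectivity feature below is a pure phase statistic: a causal filter
would add frequency-dependent phase shifts that masquerade as lags.
Decomposition happens **before** windowing so that no per-window filter
transients are created; windows then index all band signals
identically.

Band edges shared by adjacent bands (4, 8, 13, 30 Hz) are disambiguated
at the spectral-integration stage by half-open intervals $[f_{lo},
f_{hi})$, with the band touching the 45-Hz analysis bound closed, so no
frequency bin is counted twice.

# Feature families

Each (window, channel) or (window, channel-pair) contributes one value
per band to three families. With 16 channels and 5 bands the canonical
feature space is $16 \times 5 = 80$ relative-power features, $80$
fuzzy-entropy features and $(16 \cdot 15/2) \times 5 = 600$ phase-lag
features: 760 in total, in a fixed family-major, band-major,
channel-ordered layout (`feature_keys()`).

## Relative power (RP)

For a broadband window signal $x(t)$ with one-sided periodogram
$P_x(f)$, the relative power of band $h$ with edges $(f_l, f_h)$ inside
the analysis range $(f_n, f_m) = (0.5, 45)$ Hz is

$$
RP(h) = \frac{\int_{f_l}^{f_h} P_x(f)\,df}{\int_{f_n}^{f_m} P_x(f)\,df}
        \times \frac{f_m - f_n}{f_h - f_l},
$$

a band-power fraction rescaled by the bandwidth ratio, so a flat
spectrum scores exactly 1 in every band. The integrals are discrete bin
sums on the DFT grid $k \cdot f_s/N$, and the bandwidth factors are
measured on the same grid (bin count × bin width). This choice makes
two identities exact to 1e-9 on *any* window length: flat spectrum ⇒
$RP = 1$ per band, and $\sum_h RP(h)\,(f_h - f_l)/(f_m - f_n) = 1$. The
printed bandwidths are not integer multiples of the bin width for every
window length, so using them verbatim would break those identities at
the 0.5--1% level. The cost is a matching sub-percent shift in extreme
cases (a pure alpha tone scores 8.95 rather than the continuous-limit
$44.5/5 = 8.9$).

RP is computed from the **broadband** window periodogram (one spectrum,
one shared denominator), not from the band-filtered time series; the
formula above is defined on a single spectrum, and summing filtered
time-domain energies would double-count filter rolloff.

## Fuzzy entropy (FuzEn)

FuzEn measures signal irregularity by comparing the similarity of
embedded subsequences at dimensions $m$ and $m+1$. Length-$m$
subsequences are baseline-corrected by their own mean; the distance
between two subsequences is the Chebyshev distance $d_{ij}$; pair
similarity is the fuzzy membership $\exp(-\ln 2 \, (d_{ij}/r)^2)$; the
similarity degree $O_m(r)$ averages memberships over all ordered pairs
$i \ne j$, with $i, j$ ranging over the first $N - m$ subsequences at
*both* dimensions so the pair counts match; and

$$
FuzEn(m, r, N) = \ln O_m(r) - \ln O_{m+1}(r) \ge 0 .
$$

Defaults are $m = 2$ and $r = k\,\delta$ with $k = 0.2$ and $\delta$
the per-window, per-channel standard deviation, which makes the value
exactly invariant to positive rescaling. The per-subsequence-mean
baseline is applied identically at both dimensions (the common FuzEn
convention). FuzEn is computed per band-filtered channel. The $O(N^2)$
pair loop is compiled (Rcpp); memberships below $3 \times 10^{-20}$ are
skipped, ~9 orders of magnitude below the $10^{-10}$ agreement the
brute-force oracle test enforces. A constant channel makes $r = 0$;
such windows are dropped from the feature table (with a message) rather
than imputed.

## Phase lag index (PLI)

For two band-filtered window signals with instantaneous phases
$\phi_k(t), \phi_l(t)$ from the FFT analytic signal,

$$
PLI(k, l) = \left| \frac{1}{N} \sum_t
  \mathrm{sign}\bigl(\phi_k(t) - \phi_l(t)\bigr) \right| \in [0, 1],
$$

with the phase difference wrapped to $(-\pi, \pi]$ and
$\mathrm{sign}(0)$ contributing exactly 0 (no epsilon perturbation), so
identical signals give $PLI = 0$ exactly and a constant nonzero lag
gives 1. PLI is insensitive to zero-lag (volume-conduction-like)
coupling and to amplitude scaling. Because the finite-window analytic
signal distorts phases near the edges, 5% of samples at each end are
excluded from the sign average by default (`trim = 0.05`,
configurable); the analytic extreme cases pass with trimming on and
off. Per band and window the 120 channel pairs fill a symmetric,
zero-diagonal matrix whose lower triangle, read in canonical pair
order, supplies the feature columns.

# Classification and validation

The feature table (one row per window, 760 columns) is classified by
ensemble learners behind a uniform adapter interface
(fit/predict/importance): bundled adapters wrap random forests
(`ranger`) and gradient-boosted trees (`xgboost`), with
`register_learner()` accepting further engines without touching fold or
metric code. Library-default hyperparameters are used with fixed seeds;
no tuning is performed.

Validation is stratified 10-fold cross-validation. Accuracy, precision,
recall and F1 are reported per fold and as mean ± sd on the percent
scale, with SCZ as the positive class (a convention this package fixes;
precision/recall are undefined without one). Two fold units are
exposed:

* `unit = "window"` (default) splits windows independently, mirroring
  the common practice of randomly dividing the pooled window set. **All
  windows of a subject then can appear in both training and test
  folds**; on real data, where windows of one subject share
  subject-level idiosyncrasies, this inflates accuracy. Use it to
  compare against window-level literature, not to estimate
  subject-level generalization.
* `unit = "subject"` keeps every window of a subject in one fold — the
  leakage-safe alternative.

The synthetic generator draws windows i.i.d. within a group (no
subject-level random effects), so this leakage mechanism is absent from
synthetic benchmarks by construction; a chance-level null result on
synthetic data therefore does not certify window-level CV on real
recordings.

# Feature selection

RFE ranks all features by model importance and evaluates nested
prefixes of the ranking by cross-validated accuracy under identical
folds and seeds; the optimal size is the accuracy argmax with ties
broken toward the smaller subset. Two rankings are offered:

* default — one ranking from the cross-validated full model (per-fold
  importances averaged, ties broken by canonical column order), then
  the subset-size curve by adding one feature per cycle. Tractable at
  760 features.
* `rescoring = TRUE` — classical RFE: refit after every single-feature
  elimination and re-rank the remainder. $O(K^2)$ model fits; intended
  for small tables.

A `stride` parameter evaluates every s-th subset size; the full size is
always evaluated, and the contract that the size-$K$ accuracy equals
the full-feature CV accuracy under the same folds/seeds is enforced by
test. Subset columns are always presented to learners in canonical
table order, so results are invariant to the order a subset was
supplied in (tree learners are column-order-sensitive; this was found
by the contract test). `subset_distribution()` cross-tabulates any
subset by family × band with totals.

# Synthetic cohorts: what is emulated, and how

`simulate_cohort()` draws two groups of 16-channel recordings (defaults:
39 HC + 45 SCZ, 60 s at 128 Hz — 60 s is chosen so that 4-s
non-overlapping segmentation yields 15 windows per subject, i.e. 585 HC
+ 675 SCZ = 1,260 windows in the default design). Per-subject sub-seeds
derive deterministically from the master seed; identical (config, seed)
reproduces the cohort bit for bit.

Each channel is a sum over bands of unit-variance band-limited noise
(white noise passed through the *same* Butterworth filters the analysis
uses, avoiding filter-mismatch artifacts in recovery tests), weighted
by eyes-closed-like base amplitudes (Delta 2.0, Theta 1.5, Alpha 2.5,
Beta 1.0, Gamma 0.6, arbitrary units — alpha-dominant, 1/f-ish), plus
independent broadband sensor noise (sd 0.3). Amplitudes are
uncalibrated because every downstream feature is scale-invariant or
ratio-based. Group effects enter three ways:

* **Band power** — the SCZ group's band amplitudes are multiplied by
  per-band factors (defaults: Delta/Theta/Beta 1.3, Alpha 0.7, Gamma
  0.75, the direction pattern reported for pediatric SCZ).
* **Phase coupling** — per edge $(i, j, band)$, a shared band-limited
  source is blended into channel $i$ and a delayed copy into channel
  $j$ with group-specific weight $\gamma$ (variance-preserving blend
  $\sqrt{1-\gamma^2}\,\text{own} + \gamma\,\text{shared}$). The delay
  is the integer sample count closest to the requested phase lag at the
  band's center frequency — exact, and detectable by PLI as long as the
  lag is neither 0 nor $\pi$ (both are invisible to the sign statistic,
  so `effect_spec()` rejects such edges). Default edges follow the
  reported directions: theta/beta/gamma coupling raised in SCZ on
  fronto-central-parietal edges, alpha coupling lowered on right-sided
  fronto-parieto-occipital edges. Default alpha down-edges are
  channel-disjoint because blending two shared sources into one channel
  dilutes the first edge.
* **Regularity** (lowers FuzEn) — in the SCZ group a per-band gain
  $g$ re-filters the band signal to the lower $(1-g)^2$ fraction of the
  band (re-filtering, not regenerating, so planted coupling inside the
  retained sub-band survives) and replaces a capped variance share
  ($0.3g$) with a deterministic tone whose frequency is drawn per
  channel from the retained sub-band. Two deliberate design points
  here. First, simply replacing band variance with a tone does *not*
  lower fuzzy entropy at $m = 2$: within an already narrow band, a tone
  is indistinguishable from the band noise unless the residual
  stochastic fraction is near zero (measured: 80% tone variance changes
  FuzEn by under 1%). What sample-scale entropy actually responds to in
  band-limited signals is the dominant-frequency content, so the
  implemented mechanism concentrates the stochastic energy toward the
  lower band edge — slower, hence more regular and predictable — which
  lowers FuzEn monotonically in $g$ in every band while leaving the
  band's total power (hence RP) untouched. Second, the tone share is
  capped because near-frequency tones on different channels phase-lock
  spuriously and would contaminate planted PLI directions.

With a neutral effect specification the group label never touches the
random draws: HC and SCZ recordings with the same seed are bit-identical,
which is the strongest available statement of the null.

What the generator does **not** emulate: artifacts (blinks, EMG, line
noise), volume conduction and reference-field spread, subject-level
random effects, 1/f slope variation, age/sex covariates, and
non-stationarity. Consequently, passing recovery tests demonstrates the
pipeline's correctness and sensitivity, not clinical performance; real
preprocessed data should be supplied as cleaned text matrices or via
`eeg_recording()`.

# Reporting

`summarize_groups()` tabulates per-feature HC/SCZ means (window-level
and a subject-level mean-of-means variant — both, since either unit is
defensible and they differ under unequal window counts), direction
labels (`SCZ>HC`/`SCZ<HC`, anti-symmetric under label swap), and pooled
standardized effect sizes; aggregations cover family × band counts, the
PLI edge list with 10--20 region endpoints (frontal F, central C,
temporal T, parietal P, occipital O — letter-code assignment, since
region vocabularies rarely come with a printed membership), and
per-band region proportions where each edge contributes both endpoints
(proportions per band sum to 1). `window_sweep()` re-runs extraction
and CV per window length. `render_reports()` writes all tables as CSV
plus a run log, with no timestamps so identical inputs give
byte-identical outputs. Statistical tests on group differences are
intentionally not included: the reported quantity is selection-based
discriminativeness, and mixing it with p-values invites double dipping.

# Numerical choices and degenerate inputs

* Periodogram normalized so bins sum to the window mean square
  (Parseval, tested to 1e-9).
* FuzEn needs $N > m + 1$ and a non-constant signal; violations raise
  errors, and degenerate windows drop the whole feature-table row.
* PLI trim default 0.05 per end; `trim = 0` is exact for on-bin tones.
* Ties: argmax ties in RFE go to the smaller subset; importance ties
  keep canonical column order; fold assignment is a seeded
  stratified deal.
* All stochastic steps (generator, folds, learners) are seeded;
  cross-validation results reproduce bit for bit.

# Problem sizes used by the test suite

The suite exercises the full design bookkeeping (39+45 subjects, 60 s)
for shape checks with the fast RP family only, and full three-family
recovery runs at 20+20 subjects × 24 s (240 windows × 760 features),
with strong planted effects for sensitivity and a neutral cohort for
the chance-level null. These sizes were chosen as the smallest at which
the planted-direction and chance-level statements are statistically
stable; all thresholds were fixed before the cohorts were drawn.

# Known limitations

* CatBoost and LightGBM, often used in the window-level EEG
  classification literature, have no R engines here; the adapter
  registry accepts user-supplied wrappers should they become available.
* Window-level CV optimism on real data (see above) is a property of
  the validation design, not of any implementation; the subject-level
  unit is one switch away and should be preferred for claims about new
  subjects.
* The RP bandwidth convention trades sub-percent agreement with
  continuous-limit constants for exact discrete identities.
* EDF input is not implemented; recordings arrive as plain-text
  matrices (samples × channels) or programmatically.
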