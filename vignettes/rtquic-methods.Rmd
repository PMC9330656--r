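---
title: "Methods: RT-QuIC positivity calling and diagnostic accuracy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: RT-QuIC positivity calling and diagnostic accuracy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rtquic)
```

## The assay and the analysis problem

Real-time quaking-induced conversion (RT-QuIC) is a seed-amplification
assay: misfolded protein aggregates in a clinical specimen (here,
α-synuclein from nasal-swab olfactory mucosa or cerebrospinal fluid)
template the conversion of recombinant substrate into amyloid fibrils,
which bind Thioflavin T and raise its fluorescence. A plate reader records
relative fluorescence units (rfu) for each well every 45 minutes over
several days. Seeded wells show a characteristic lag phase followed by a
sigmoidal rise to a plateau; unseeded wells stay at a noisy baseline, with
occasional spontaneous substrate conversion.

The analysis problem is to turn these raw kinetic traces into a binary
per-sample result and then into diagnostic-accuracy statistics. `rtquic`
implements this as a pipeline: trace I/O and validation → baseline
adjustment and normalization → threshold computation → replicate- and
sample-level calling → accuracy and agreement statistics, with a
deterministic synthetic-cohort generator for validation.

## The calling procedure

For each sample (a set of replicate wells of one specimen):

1. **Baseline.** The mean trace across the sample's replicates is scanned
   with a sliding window of duration `baseline_window_h` (default 10 h);
   the window with the lowest mean rfu defines the baseline value, with
   ties broken to the earliest window. The window is a *duration*, so on
   the 45-min grid it covers the readings with
   $t \in [t_\text{start}, t_\text{start} + 10]$.
2. **Adjustment and normalization.** The baseline value is subtracted from
   every replicate reading; negative values are floored at 0. Adjusted
   values are expressed as percent of the normalization maximum
   $M$: the largest adjusted reading in the whole run (default) or in the
   sample.
3. **Thresholds.** Two positivity thresholds are in common use and both
   are implemented: a fixed line at `percent_threshold` (default 20% of
   $M$), and a run-specific noise floor equal to the mean of all
   normalized readings with $t \in [15, 17]$ h plus
   `noise_sd_multiplier` (default 3) sample standard deviations. The
   default `threshold_mode = "max_of_both"` requires a replicate to
   exceed both; `percent_only` and `noise_only` select either alone.
4. **Replicate call and lag.** A replicate is positive if any reading at
   $t \le$ `cutoff_time_h` (default 80 h) reaches the effective
   threshold; its lag time is the time of the *first* such reading. No
   interpolation is performed: lag resolution is the 45-min reading
   interval, and interpolating would fabricate sub-reading precision.
5. **Sample call.** A sample with $k$ replicates is positive when at
   least $\min(2, k)$ replicates crossed (the 2-of-4 rule, generalized);
   $k < 2$ is an error, and $k < 4$ is flagged in the output. The
   endpoint summary is the mean across replicates of the last reading at
   or before the cutoff.

### Normalization scope

Protocols describe normalizing "per set of replicate reactions", yet a
20%-of-maximum criterion is only discriminative against a *run-wide*
maximum — a self-normalized trace always reaches 100%, so every sample
with any fluorescence drift would eventually cross 20% of its own
maximum. The package therefore defaults to `normalization_scope = "run"`
and offers `"sample"` scope for figure-style plots where each positive
trace is drawn relative to its own maximum. This was a genuinely open
design choice; the run-wide default is the one under which the 20% rule
separates seeded from unseeded wells.

### Boundary conventions

Readings exactly at $t = 15$, $17$ or $80$ h are included (closed
intervals), and the noise window pools readings from *all* samples on the
run, including strongly positive ones — whose in-window values are near
zero during the lag phase. These conventions are stated once and applied
deterministically; tests pin them.

## The statistics layer

Calls feed standard diagnostic-accuracy statistics, computed from call
tables or directly from printed count tables:

- **Sensitivity / specificity / positivity** as binomial proportions with
  exact 95% Clopper–Pearson intervals (via `stats::binom.test`), plus the
  integer percent rounded half-up as results tables print it.
- **Fisher's exact test** (two-sided) for unpaired 2×2 tables, by
  hypergeometric enumeration under fixed margins with the
  point-probability convention: the p-value sums the probabilities of all
  tables no more likely than the observed one, with a $1 + 10^{-7}$
  relative guard against floating-point tie loss. Tests verify exact
  agreement with an independent binomial-coefficient enumeration for
  every margin combination with $n \le 60$, and with `stats::fisher.test`.
- **Cramér's V** ($\phi_c$), which for 2×2 tables is
  $|ad - bc| / \sqrt{r_1 r_2 c_1 c_2}$.
- **Exact McNemar test** on paired calls:
  $p = \min(1,\, 2\,P(X \le \min(b,c)))$, $X \sim \mathrm{Bin}(b+c, 1/2)$
  over the discordant pairs, with $p = 1$ when $b + c = 0$.
- **Cohen's kappa** with the Fleiss–Cohen–Everitt (1969) asymptotic
  standard error and a Wald 95% CI clipped to $[-1, 1]$. Published kappa
  CIs do not always state their method; this package reports the standard
  asymptotic interval and treats the point estimate, not the interval, as
  the reproducible quantity.
- **Either-positive combination** of two tests per subject (e.g. CSF plus
  olfactory mucosa), excluding subjects missing either call with a
  warning.

## The synthetic-cohort generator

The generator exists so every pipeline stage can be validated without raw
assay exports, which are rarely published. It emulates:

- **Converting replicates**: logistic kinetics
  $\mathrm{rfu}(t) = \text{baseline} + P / (1 + e^{-k(t - t_{50})})$ with
  Gaussian reader noise, the plateau $P$ drawn per replicate as a
  fraction of the nominal run maximum (clipped to $[0.25, 1]$ so the 20%
  line is always crossable). The lag is parameterized directly as the
  analytic time of crossing 20% of the nominal run maximum — $t_{50}$ is
  back-computed — so generator truth and pipeline lag estimates are
  directly comparable.
- **Non-converting replicates**: baseline plus noise, floored at 0.
- **Replicate heterogeneity**: each replicate of a seeding sample
  converts independently with probability `conversion_prob`; replicates
  of non-seeding samples convert with a small `spontaneous_prob`. This is
  deliberate: a generator in which all replicates of a positive sample
  convert would never exercise the 2-of-4 decision boundary.

`calibrated_cohort_config()` packages group parameters whose *expected*
sample-level call rates equal published first-round rates (agger nasi PD
84%, middle turbinate PD 45%, non-PD 10%), with mean lags of 41 h and
47 h and plateau fractions of 0.80 and 0.57 for the two swab sites.
Per-replicate conversion probabilities are back-solved from the
sample-level targets through the $\ge 2$-of-4 binomial tail
(`replicate_conversion_prob()`); sample-level rates under-determine the
replicate-level probability, and this is the unique solution under the
independent-replicates model. Non-seeding groups use a lag distribution
centred at 55 h (SD 8 h) — spontaneous conversions are late, as observed
in practice — and the same back-solving for the 10% target. The group
mean endpoint of a calibrated cohort falls below the per-replicate
plateau fraction because non-converting replicates of positive samples
contribute near-zero endpoints to the sample mean; this matches how
replicate averaging dilutes endpoint summaries in real data.

All randomness flows from one Mersenne–Twister stream seeded once per
cohort; kinetic quantities are drawn for every replicate whether or not
it converts, so the stream — and the entire cohort — is reproducible from
the seed alone.

What the generator does **not** model: plate-position effects,
evaporation, substrate lot variability, drifting baselines, cross-seeding
between aggregate strains, or non-sigmoid kinetics. Passing recovery
tests on synthetic plates therefore demonstrates the correctness of the
calling logic under the stated model, not robustness to every artifact of
real plates.

## Numerical choices

- Baseline window scan uses cumulative sums over reading windows defined
  by duration; ties in mean rfu break to the earliest window.
- Negative baseline-adjusted values are floored at 0 before
  normalization, keeping percent values in $[0, 100]$.
- The lag is the first grid reading at/above threshold; on a 45-min grid
  this upper-bounds the continuous crossing time by at most one interval.
- Fisher enumeration works on `dhyper` densities in double precision with
  the $1 + 10^{-7}$ guard; exact rational arithmetic is unnecessary at
  the table sizes involved (verified exhaustively to $n \le 60$).
- An all-flat run (normalization maximum $\le 0$) is an error, not a
  silently all-negative plate.

## Validation problem sizes

The test suite validates the pipeline at sizes chosen to give tight
statistical resolution while keeping the suite quick to run: noiseless
truth recovery on 90-sample plates (exact equality of calls and lag
times), calibration recovery at 2000 subjects per group (observed
positivity within 2.5 binomial standard errors of the 84% / 45% / 10%
targets), threshold-monotonicity and scale-invariance properties over
1000 randomly generated traces, and exhaustive oracle comparisons for the
baseline finder (traces up to 200 points) and Fisher p-values (all
margins with $n \le 60$).

## Limitations

- The calling procedure assumes a common reading grid within each
  sample's replicates; plates with per-well grids must be resampled
  upstream.
- The noise threshold requires at least two readings in the 15–17 h
  window; runs shorter than 17 h can only use `percent_only` mode.
- Kappa's asymptotic CI is unreliable at very small $n$ or extreme
  marginals; the point estimate and exact McNemar p-value are the robust
  outputs there.
- No kinetic curve fitting (growth rates, $t_{50}$ estimation) is
  performed; the assay readout is binary by design and the package stops
  at threshold crossing.
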