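# rtquic

Analysis pipeline for **RT-QuIC** (real-time quaking-induced conversion)
seed-amplification assays, written for assay developers and clinical
researchers who need to turn raw plate-reader Thioflavin T (ThT)
fluorescence kinetics into reproducible positivity calls and
diagnostic-accuracy statistics — for example when comparing α-synuclein
seeding activity across specimen types (nasal-swab olfactory mucosa
sampled at the *agger nasi* or middle turbinate, versus cerebrospinal
fluid) in Parkinson's disease.

## What it computes

**Positivity calling.** For each sample (four replicate wells by
convention), the mean-of-replicates trace is scanned for the 10-h window
with the lowest mean rfu; that baseline is subtracted from every
replicate reading (floored at 0), and adjusted values are normalized to
percent of the run's maximal baseline-adjusted fluorescence *M*. A
replicate is positive when it reaches the effective threshold — the
larger of 20% of *M* and the run's noise floor, mean + 3 SD of all
readings between 15 and 17 h — at or before the 80-h cutoff; its **lag
time** is the first reading at/above threshold. A sample is positive when
at least 2 of its replicates crossed.

**Diagnostic accuracy.** Sensitivity/specificity with exact 95%
Clopper–Pearson intervals; two-sided Fisher's exact test by
hypergeometric enumeration (point-probability convention); Cramér's V
(φ*c* = |ad − bc| / √(r₁r₂c₁c₂) for 2×2); exact McNemar test on
discordant pairs (p = min(1, 2·P(X ≤ min(b, c))), X ~ Bin(b + c, ½));
Cohen's κ = (p₀ − pₑ)/(1 − pₑ) with the Fleiss–Cohen–Everitt asymptotic
SE; and either-positive combination of two tests per subject.

**Synthetic cohorts.** A deterministic generator of plate-reader-style
cohorts — sigmoidal converting replicates with group-specific lag and
plateau distributions, flat noisy negatives, independent per-replicate
conversion, spontaneous conversions — so the full pipeline can be
validated against known truth without access to raw exports.

## Worked example

Simulate a cohort calibrated to published first-round rates, run the
calling pipeline, and summarize:

```r
library(rtquic)

cfg    <- calibrated_cohort_config()        # 32 AN-PD, 11 MT-PD, 29 non-PD
cohort <- simulate_cohort(cfg, seed = 42)
report <- run_calling(cohort$traces, cohort$plate_map)
report
#> RT-QuIC run report
#>   threshold: 20.000% (mode max_of_both; noise component 0.476%)
#>   samples: 72 (32 positive)

run_stats(calls = report$calls)
#> Positivity by group:
#>   NS_AN/PD: 23/32 (72%), 95% CI [0.53, 0.86]
#>   NS_AN/NON_PD: 1/14 (7%), 95% CI [0.00, 0.34]
#>   NS_MT/PD: 4/11 (36%), 95% CI [0.11, 0.69]
#>   NS_MT/NON_PD: 4/15 (27%), 95% CI [0.08, 0.55]
#> ...
```

The effective threshold was the 20% line (the noise floor sat at 0.48%),
32 of 72 samples were called positive, and at this cohort size the
per-group positivity rates scatter around their generative targets (84% /
45% / 10%) within binomial noise. The mean lag of the AN-PD group's
crossing replicates recovers the generative 41 h:

```r
an  <- report$calls$sample[report$calls$specimen == "NS_AN" &
                           report$calls$diagnosis == "PD"]
kin <- summarize_group_kinetics(report$calls, report$normalized, an)
#> AN-PD positives: 23/32; mean lag 41.4 h
```

Statistics straight from printed count tables, no traces needed:

```r
run_stats(counts = tibble::tibble(group    = c("NS_AN", "NS_MT"),
                                  positive = c(27, 5),
                                  total    = c(32, 11)))
#> Positivity by group:
#>   NS_AN: 27/32 (84%), 95% CI [0.67, 0.95]
#>   NS_MT: 5/11 (45%), 95% CI [0.17, 0.77]
#> Fisher exact p = 0.01838, Cramer's V = 0.389 (NS_AN vs NS_MT)

cohens_kappa(table2x2(9, 9, 1, 4, layout = "paired"))
#> Cohen's kappa 0.190 (SE 0.151, 95% CI [-0.10, 0.49]);
#> exact McNemar p = 0.02148 (10 discordant of 23)
```

A thin command-line wrapper with `simulate`, `call` and `stats`
subcommands is installed at `inst/scripts/rtquic-cli.R`.

## Package layout

- `R/trace_io.R` — trace/plate-map CSV readers and writers, validation
- `R/kinetics.R` — baseline window, normalization, thresholds, calling
- `R/diagnostics.R` — 2×2 tables, exact tests, agreement, combination
- `R/synthetic.R` — cohort generator and calibration helpers
- `R/pipeline.R` — end-to-end orchestration and JSON reports
- `vignettes/rtquic-methods.Rmd` — the model, conventions, and design
  decisions in detail
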