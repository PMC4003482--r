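# metaboaging

Analysis pipeline for untargeted LC-MS metabolomics of aging cohorts under
two dietary regimens — a standard diet and a lifespan-extending
(dietary-restriction-like) defined diet — as in *Drosophila* lifespan
studies. The package is for researchers who have a feature-by-sample
intensity table (features in rows, samples in columns, intensity 0 =
non-detected) with diet / age / replicate metadata and survivorship
curves, and want to quantify how the metabolome remodels with age and how
diet shifts that remodeling.

## What it computes

**Metabolite diversity and mortality.** The number of detected features
per sample (a proxy for the accumulation of new, mostly low-abundance
molecular species), its cubic trend over age, and the *plateau age* — the
smallest root of the fitted derivative with negative curvature — which
sits near the ages where the survivorship curve bends. Survival utilities:
mean lifespan, per-interval deaths, log-rank test.

**Age-association screen.** Per feature and diet, a one-way
repeated-measures ANOVA with age as the within factor and the replicate
series as subject,

    SS_total = SS_age + SS_subject + SS_residual,
    F = (SS_age/(a-1)) / (SS_residual/((a-1)(s-1))),

applied to log10 intensities of features detected in all samples
(zero-containing features are routed to the diversity analysis instead).
Significance at p < 0.0014 by default, with an error-rate-knee threshold
calibrator and the plug-in FDR `alpha * m / #{p <= alpha}`.

**Cross-diet trajectory analysis.** For features significant in both
diets: per-feature Pearson correlation of the two diets' age trajectories;
a permutation test of the median matched-pair correlation against random
re-pairings; correlation of trajectories with the survivorship curve
(|r| > 0.75 flag); orientation-free intra- and inter-diet fold changes
with a twofold flag.

**Trajectory clusters and dietary dependence.** Complete-linkage
hierarchical clustering of scaled trajectories cut into k = 12 clusters;
per-cluster inter-diet t-tests at each age classifying clusters as
diet-independent / progressive (all ages) / intermittent (some ages);
sample-space PCA under within-diet and across-diet scaling; and
remodeling-delay curves measuring the age at which each diet attains half
of the short-lived diet's total change.

**Synthetic studies.** `generate_study()` builds feature tables with
planted trajectory classes, detection-limit censoring, onset-age "damage"
features, inter-diet delays and offsets, plus Gompertz survivorship
calibrated to target mean lifespans (50.8 / 64.4 days by default) — with
ground-truth labels, so every stage above is testable against known truth.

## Worked example

```r
library(metaboaging)

cfg <- run_config(generator = generator_config(seed = 1), seed = 1)
bundle <- run_full_analysis(cfg)
#> [metaboaging] data: 2003 features x 42 samples, diets: standard, defined
#> [metaboaging] normalize: 3 standards, 2000 assayed features
#> [metaboaging] diversity: plateau estimates standard=53.7, defined=NA
#> [metaboaging] screen: defined 281/2000 significant; standard 281/2000 significant
#> [metaboaging] trajectories: 279 overlapping features, median r = 0.966 (p = 0.0005), 73% below twofold
#> [metaboaging] clusters: k = 12; dependence fractions independent=0.67, progressive=0.24, intermittent=0.09

bundle
#> <report_bundle> seed 1, config 0031f442
#>   screen: defined 281 sig (14.1%); standard 281 sig (14.1%)
#>   concordance: median r = 0.966, p = 0.0005
#>   dependence: independent 67%, progressive 24%, intermittent 9%
```

Reading the log: the screen declares 14.1% of features age-associated in
each diet (the generator planted 14%); 279 features overlap between diets
and their trajectories are highly concordant (median matched-pair r =
0.966 against a re-pairing null p = 0.0005); 73% change less than twofold
between diets; two thirds of the overlapping features sit in
diet-independent clusters. The standard diet's diversity plateau is
estimated at 53.7 d (planted 50 d); the defined diet returns `NA` because
its detection curve is still rising at the last sampled age — the
long-lived cohort levels off later than the sampling window.

```r
bundle$survival_stats
#> # A tibble: 2 x 4
#>   diet     mean_lifespan log_rank_chisq log_rank_p
#> 1 standard          50.3           160.   1.36e-36
#> 2 defined           63.7           160.   1.36e-36

bundle$delay$metrics[bundle$delay$metrics$scope == "progressive", ]
#> # A tibble: 2 x 6
#>   direction  scope       half_age_short half_age_long delay_days delay_ratio
#> 1 increasing progressive           23.8          29.2       5.41       0.814
#> 2 decreasing progressive           32.5          40.3       7.82       0.806
```

The delay ratios (~0.81) recover the planted time-compression factor
50.8/64.4 = 0.789: rising and falling signals reach half of their total
change about 5–8 days later on the lifespan-extending diet.

`write_report_bundle(bundle, "out/")` writes every table as a stamped TSV
with the resolved configuration; `plot_diversity()`, `autoplot()` methods
and `plot_cluster_trajectories()` draw the standard figures. A thin shell
entry point is included:

```sh
Rscript inst/cli/remodel.R generate --outdir out --seed 1
Rscript inst/cli/remodel.R run --config cfg.yaml --outdir out
```

Own data enter through `read_feature_table(matrix.tsv, metadata.tsv)`
(TSV, first column feature id, header = sample names; metadata columns
`sample, diet, age_days, replicate`) and `read_survivorship()`
(`diet, day, fraction_alive`).

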