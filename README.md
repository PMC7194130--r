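# summitveg

Analysis of alpine summit vegetation resurveys and soil microclimate in
the GLORIA multi-summit design (four summits on an elevation gradient,
four aspect clusters per summit, permanent 1-m² corner quadrats, a
baseline survey and a resurvey a few years later), for community
ecologists running or re-analysing such monitoring programmes.

## What it computes

**β-diversity partitioning.** Pairwise Sørensen dissimilarity between
sites with `a` shared species and `b`, `c` one-sided uniques is split
into species turnover and nestedness-resultant components:

```
βsor = (b + c) / (2a + b + c)
βsim = min(b, c) / (a + min(b, c))
βsne = βsor − βsim
```

with the Sørensen-family multiple-site generalization (sums of one-sided
unique counts over all site pairs), site-through-time ("temporal")
partitions between the two survey years, per-component dissimilarity
matrices, and UPGMA clustering with Newick export.

**Thermophilization.** The thermic vegetation indicator of a quadrat is
the cover-weighted mean elevational rank, `S = Σ rankᵢ·coverᵢ / Σ coverᵢ`
(higher ranks = warm-adapted, lower-elevation species), and its change
`D = S_resurvey − S_baseline` is tested against zero with a Wilcoxon
signed-rank test (exact for ≤ 25 untied non-zero differences).

**Soil microclimate.** Hourly logger series at 10 cm depth are reduced to
daily statistics with the half-range daily average
`Tavg = 0.5 (Tmin + Tmax)`, growing degree days above a 5 °C threshold,
seasonal-analogue multiple imputation of logger gaps from the previous
year's record, and linear temperature trends.

**Variation partitioning.** Per-quadrat richness or total cover is
decomposed into pure and shared adjusted-R² fractions of elevation (E),
aspect (A), and survey year (Y) via the seven nested OLS models and
inclusion–exclusion, with reduced-model residual permutation tests for
the pure fractions.

**Summit statistics.** Group means ± SE, per-species cover-change tables,
fixed-effects ANOVA (aspect nested within summit; summit × year), Tukey
post-hoc comparisons, and Shapiro–Wilk / Brown–Forsythe Levene gates.

**Synthetic data.** A seeded generator (`survey_design()`,
`generate_survey()`, `generate_logger_series()`) emulates the
four-summit design — richness declining with elevation, warmer/richer
S/E aspects, nested summit floras, aspect-specific between-year
replacement and loss, and a controlled thermophilization shift — with a
truth record for parameter-recovery tests.

## Worked example

```r
library(summitveg)

design <- survey_design(seed = 7)        # 4 summits x 4 aspects x 4 quadrats
sv <- generate_survey(design)

# multi-site Sorensen partition across summits, baseline year
m14 <- build_matrix(sv$observations, "summit", year = 2014,
                    mode = "incidence")
multisite_partition(m14)
#> beta partition: bsor = 0.3248 = bsim 0.1232 + bsne 0.2016

# thermophilization change per quadrat and its test
ch <- thermophilization_change(
  thermic_indicators(sv$observations, sv$attributes))
mean(ch$D)
#> [1] 0.5480327
wilcoxon_signed_rank(ch$D)$p_value
#> [1] 3.78531e-12
```

The partition says dissimilarity among summits is dominated by richness
difference (nestedness, 0.20) rather than species replacement (turnover,
0.12), and the mean indicator shift of +0.55 rank units (p ≈ 4e-12)
recovers the +0.5 thermophilization signal the design imposes.

The full pipeline (simulate → microclimate → summaries → β → varpart →
thermophilization) runs from one configuration:

```r
run_pipeline(list(simulation = list(), analysis = list(seed = 1)),
             out_dir = "run1")
```

writing delimited-text tables (with `#` metadata headers carrying the
seed and a config fingerprint) and Newick dendrograms.

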