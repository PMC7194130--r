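---
title: "Methods: resurvey analysis of alpine summit vegetation"
author: "summitveg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: resurvey analysis of alpine summit vegetation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(summitveg)
```

summitveg analyses GLORIA-style alpine summit resurveys: permanent 1-m²
corner quadrats in four aspect clusters on each of several summits along
an elevation gradient, recorded in a baseline year and a resurvey year,
together with hourly soil-temperature loggers at 10 cm depth. This
vignette states the models and conventions the package commits to, why
its defaults are what they are, and what its simulation-based tests do
and do not demonstrate.

## Survey records and community matrices

The atomic record is one species' percent cover in one quadrat in one
year. Absence is encoded by record absence; a zero cover is a validation
error, because field protocols never write zero rows and a silent zero
would corrupt incidence matrices. Aspect labels are the closed set
N, S, E, W — anything else is rejected rather than guessed. Species and
summit identifiers are opaque strings; synonymy resolution is out of
scope.

`build_matrix()` aggregates records to quadrat, aspect, or summit
resolution. Cover aggregation *sums* percent covers and deliberately does
not cap sums at 100: at aspect or summit level the quantity is
area-weighted layered cover, which can exceed 100 and loses meaning if
truncated. Incidence aggregation is a logical OR, so quadrat→aspect→summit
and quadrat→summit give identical incidence. Summit-area section records
use a five-class ordinal abundance scale; the class→percent map defaults
to midpoints 0.5, 3, 15, 37.5, 87.5 of an approximately geometric cover
scale. The five-class convention fixes no numeric bounds, so this map is
a declared, user-replaceable convention, not an inference.

## β-diversity partitioning

For two sites with `a` shared species and `b`, `c` one-sided uniques:

$$\beta_{sor} = \frac{b + c}{2a + b + c}, \qquad
  \beta_{sim} = \frac{\min(b, c)}{a + \min(b, c)}, \qquad
  \beta_{sne} = \beta_{sor} - \beta_{sim}.$$

Turnover (`bsim`) measures species replacement independent of richness
difference; the nestedness-resultant component (`bsne`) is the remainder.
Two conventions matter:

* all β computations are incidence-based; cover matrices are thresholded
  at > 0 first, since the formulas are defined on presences;
* a comparison involving an empty community is an error, not β = 1 — an
  empty site has no defined Sørensen dissimilarity.

The multiple-site forms use the pairwise sums: with $S_i$ the site
richnesses, $S_T$ the pooled richness, and $b_{ij}$ the one-sided unique
counts,

$$\beta_{SIM} = \frac{\sum \min(b_{ij}, b_{ji})}
  {\sum_i S_i - S_T + \sum \min(b_{ij}, b_{ji})}, \qquad
  \beta_{SOR} = \frac{\sum\min + \sum\max}
  {2(\sum_i S_i - S_T) + \sum\min + \sum\max},$$

and $\beta_{SNE} = \beta_{SOR} - \beta_{SIM}$. For $n = 2$ these reduce
exactly to the pairwise forms. Correctness rests on two independent
oracles in the test suite: a brute-force set-arithmetic implementation
evaluated exhaustively on all small incidence matrices (all pairs on up
to 10 species via their realizable $(a,b,c)$ triples; all matrices up to
4 sites × 4 and 3 × 5 species, plus large random samples of 4 × 6), and
vegan's independent multi-site implementation.

Temporal partitions compare each site with itself across the two survey
years: pure loss (no gains) gives `bsim = 0` — richness-difference
dissimilarity only — while an equal swap gives `bsne = 0`. Dissimilarity
matrices of a chosen component feed UPGMA (average-linkage) clustering;
sites are sorted lexicographically before agglomeration so ties break
deterministically, and dendrograms export as Newick with merge heights
as branch lengths.

## Thermophilization

Each species carries a positive integer elevational rank. The package
follows the convention that **higher ranks denote warm-adapted,
lower-elevation species**; ranks are consumed as given and never
interpolated to metres, because rank assignment in the field (from
species' positions on the summits and local floras) is not an algorithm
the package can reproduce. The thermic indicator of a quadrat is the
cover-weighted mean rank

$$S = \frac{\sum_i \mathrm{rank}_i \cdot \mathrm{cover}_i}
  {\sum_i \mathrm{cover}_i},$$

bounded by the ranks present, invariant to rescaling all covers, and
strictly increasing when cover moves from a lower- to a higher-ranked
species. The change $D = S_{\mathrm{resurvey}} - S_{\mathrm{baseline}}$
is computed by simple subtraction for quadrats vegetated in both years;
quadrats vegetated in exactly one year cannot carry a D and are listed in
a side attribute rather than silently dropped.

D is tested against zero with a Wilcoxon signed-rank test: zeros dropped,
mid-ranks for ties, the exact distribution for up to 25 untied non-zero
values, and the tie- and continuity-corrected normal approximation
otherwise (`stats::wilcox.test` supplies both regimes).

## Soil microclimate

Daily statistics use the half-range daily average
$T_{avg} = 0.5\,(T_{min} + T_{max})$ — a deliberate convention that
differs from the arithmetic mean of the 24 hourly values (a day of 23
hours at 0 °C and one at 12 °C has $T_{avg} = 6$, not 0.5). Days with
fewer than 18 of 24 valid hours are emitted as missing; the threshold is
configurable because no standard exists for partial logger days.

Growing degree days accumulate $T_{avg} - 5$ over days with
$T_{avg}$ **strictly above** 5 °C (the biologically motivated alpine
threshold). "Above" is read strictly; an `inclusive` flag exposes the ≥
variant, which changes only the qualifying-day count since a boundary day
contributes zero degree-days.

Logger gaps are filled by a seasonal-analogue multiple imputation: each
missing hour takes the same month-day-hour value of the previous year's
window plus the mean of 30 residuals resampled from the empirical
current-minus-previous-year differences of the same calendar month
(falling back to all months if a month has no overlap). The residual
spread is returned as a per-hour imputation SD, draws are seeded, and
observed values are never altered. This scheme is fully specified and
testable by masking experiments: hide 480 hours of a synthetic series and
the mean absolute reconstruction error stays below the diurnal amplitude.
Timestamps are taken as local standard time; DST and time zones are
ignored. Trends are ordinary least-squares slopes of period means on the
period index; an exactly constant series is reported as slope 0 with
p = 1 rather than a 0/0 statistic.

## Variation partitioning

Per-quadrat responses (richness, summed cover) are univariate, so the
partition uses linear-model adjusted R² rather than a multivariate
ordination. The seven nested OLS models on elevation (numeric metres by
default; a flag switches to summit identity as a factor), aspect, and
year give pure fractions as differences against the model omitting the
variable, shared fractions by inclusion–exclusion, and a residual of
1 − adjR²(full). Negative fractions are reported as computed — truncating
them would break the exact fraction-sum identity, which the package
asserts to 1e−10.

One algebraic consequence worth knowing: a *noiseless* response that
depends only on elevation does not give `pure_E` exactly equal to
`total`, because the reduced aspect+year model has R² = 0 and therefore
an adjusted R² of exactly $-p/(n-p-1)$ (−4/123 ≈ −0.033 with four
aspects, two years, n = 128). This is the textbook adjustment penalty,
not an implementation artifact; the unit suite asserts its exact value.

Pure fractions are tested by permuting residuals of the reduced model
(the model omitting the tested variable) and adding them back to its
fitted values, with $p = (1 + \#\{perm \ge obs\})/(n_{perm}+1)$; shared
fractions are subtraction artifacts and cannot be tested. Permutations
are ranked by the partial pseudo-F of full versus reduced model rather
than by the raw adjusted-R² fraction: the fraction's denominator (the
permuted response's total sum of squares) varies across permutations,
making it non-pivotal and its null p-value distribution measurably
conservative at the study's sample size, while the pseudo-F ranking —
which shares the fraction's numerator and is the standard statistic in
partial-model permutation tests — is uniform, as the suite's
500-replicate Kolmogorov–Smirnov calibration check asserts. The reported
observed value is still the pure fraction.

## ANOVA machinery

"Aspect nested within summit" is a fixed-effects summit main effect plus
an aspect-within-summit term; the summit × year model adds their
interaction. Sums of squares are sequential — the synthetic designs are
balanced, where sequential and marginal coincide, and the convention is
recorded in the output's metadata. Terms with zero sum of squares
(constant responses) are reported as F = 0, p = 1 instead of 0/0. Levene's
test uses Brown–Forsythe median centering, the robust variant; Shapiro–
Wilk runs on group-centered residuals. Per-species cover-change p-values
are unadjusted by default (a Holm flag exists), and a species absent in
one year contributes its change from or to zero cover — the only
convention under which "simple subtraction" is defined.

## The synthetic-data generator

The generator is first-class, tested code: it defines the study
conditions under which every recovery and calibration claim is made. The
default design is four summits at 3530–3740 m, four aspects × four corner
quadrats (64 quadrats), surveys in 2014 and 2018, a regional pool of 150
species, expected per-quadrat richness 15 at the base falling by 3
species per 100 m, aspect offsets +2 (S), +1.5 (E), −2 (N), −1.5 (W),
nestedness strength 0.9, a +0.5 rank-unit thermophilization shift, 15%
between-year replacement on warm (S/E) aspects, and 15% loss with 5% gain
on cold (N/W) aspects. Covers are log-normal (meanlog log 5, sdlog 0.8),
the standard community-abundance default.

Structural choices that matter:

* **Ranks from optima.** Each species gets a uniform elevation optimum
  over the gradient (±35 m margins); its rank is the summit band of that
  optimum, reversed so the warmest (lowest) band carries the highest
  rank. Ranks are therefore integers 1–4 tied to the simulated thermal
  gradient, exactly what a field rank assignment approximates.
* **Summit pools are realized floras.** A summit's pool (six times its
  expected quadrat richness) is treated as the species actually present
  on the summit, and the quadrat layer is a constrained allocation: every
  flora member lands in at least one of the 16 quadrats (a complete
  inventory, which is what a multi-quadrat GLORIA survey records), with
  remaining quadrat slots filled by draws weighted by a shared log-normal
  "commonness". Without the coverage constraint, independent quadrat
  sampling makes different summits miss different species, and that
  sampling discordance masquerades as species turnover — contradicting
  the nested structure the pools are built to have.
* **Nestedness and colonization from below.** Each higher summit's pool
  member is inherited from the summit below with probability
  `nestedness_strength`; non-inherited members are drawn with elevation
  affinity centred 150 m downslope, reflecting that novel species on a
  high summit are overwhelmingly colonizers from lower elevations. At
  strength 1 the floras are perfectly nested by construction.
* **The shift is exact in expectation.** Between years, covers of each
  shifted quadrat are tilted multiplicatively along the rank gradient,
  `cover · exp(γ(rank − mean rank))`, with γ solved per quadrat so the
  indicator S rises by exactly `shift_magnitude` (capped near the maximum
  attainable rank). Multiplicative tilting keeps covers positive, so S
  stays defined. With the shift, replacement, loss, and gain rates all
  zero, the resurvey is bit-identical to the baseline — the generator has
  no hidden change process. An optional log-normal resurvey cover noise
  exists but defaults to 0.
* **Loggers.** One logger per summit × aspect, hourly over two 12-month
  August–July windows (matching the survey periods and avoiding leap
  days, so window means are exactly comparable). The signal is annual
  sinusoid (amplitude 8 °C, peak near day 200) + diurnal sinusoid
  (2 °C, peak 14:00) + lapse term (1.2 °C per 100 m) + aspect offsets
  (+0.8 S, +0.5 E, −0.8 N, −0.5 W) + a 1.5 °C second-window warming
  increment + Gaussian noise (SD 1 °C). With noise off, annual-mean
  differences between summits and windows equal the lapse and warming
  parameters exactly, which the tests exploit as closed-form oracles.

What the generator does *not* emulate: spatial autocorrelation within
quadrat clusters, species interactions, snow-cover dynamics, immigration
of species from outside a summit's flora, and observer error. Passing
recovery tests therefore demonstrates that the estimators extract the
signals the generator encodes at the study's scale — not that real
Himalayan summit data meet these assumptions.

## Problem sizes and numerical conventions

The test suite runs the exhaustive β oracles on all matrices up to
4 × 4 and 3 × 5 (with 2000 random 4 × 6 matrices beyond), 200 replicate
surveys for each recovery/calibration claim, 500 replicates × 199
permutations for permutation-test calibration, and 1e5 random pairs for
the additivity/bounds sweep; these sizes keep every statistical check at
meaningful power while the whole suite completes in a few minutes.
Additivity is asserted to 1e−12, the varpart fraction sum to 1e−10.
Degenerate inputs fail loudly by design: empty communities, constant
factors, single-replicate cells, all-zero difference vectors, and
overlapping logger gaps are errors with named offenders, never silent
results.

The pipeline (`run_pipeline()`) executes simulate/load → microclimate →
summaries → β → variation partitioning → thermophilization in a fixed
order, writes only delimited text (plus Newick), stamps every table with
the package version, seed, and a configuration fingerprint, and is
byte-identical under a fixed seed. The package's functions and this
pipeline are the interface; there is no separate shell executable.
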