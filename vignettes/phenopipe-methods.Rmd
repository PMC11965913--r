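---
title: "Methods: from raw phenotyping scans to letter displays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from raw phenotyping scans to letter displays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenopipe)
```

This vignette is the package's own account of its methods: what each stage
assumes, which tunables matter, what the synthetic-data generator does and
does not emulate, and where genuinely open design choices were made.

## The data and its problems

A table-scanning phenotyping platform measures every pot on a table in one
pass. Three consequences shape everything downstream:

* **Timestamps are smeared.** A scan that nominally happens at 14:00 yields
  per-plant timestamps spread over the few minutes the scanner needs to
  traverse the table. Treating raw timestamps as a factor would give almost
  every plant its own level.
* **Technical replication is implicit.** Back-to-back passes over the same
  table produce repeated measurements of each plant minutes apart; these are
  replicates of one observation, not new time points.
* **Gross errors happen.** A person walking through the scanning area, a
  re-arranged pot, or a glossy leaf produces isolated absurd values that
  would wreck means and variances.

## Time clustering

Timestamps are clustered with one-dimensional DBSCAN on the time axis,
distance being the absolute time difference. Two tunables:

* `eps_hours` (default **1 h**): the reachability radius. One hour cleanly
  separates designs whose consecutive scans are at least an hour apart from
  within-scan smear plus back-to-back replicate passes, which live inside a
  few minutes.
* `min_pts` (default **1**): the core-point threshold. The default makes
  every point a core point, so there is no DBSCAN "noise" and no
  measurement is ever silently discarded; the clustering then reduces to
  splitting the sorted timestamps at gaps larger than `eps` — exactly the
  behaviour the pipeline's tests verify against an independent gap-split
  oracle. Values above 1 are supported (with classical core/border/noise
  semantics and deterministic border assignment to the nearest core point,
  earlier on ties) for users who want sparse stray scans labelled as noise.

Clustering is computed over the pooled timestamps of all plants, not per
plant: one scan pass is one physical event, and pooling is what lets a
cluster's **median** time stand in for the design time point. For
even-sized clusters the median is the interpolated midpoint of the two
central order statistics, the standard convention of `stats::median()`.
Cluster ids are assigned in chronological order of cluster start, so
displays are stable. Rows sharing a plant id and a cluster are technical
replicates.

## Preprocessing

The preparation chain runs in a fixed order: proportion transform →
outlier filter → replicate aggregation → factor cleanup. Outliers are thus
judged on the analysis-ready (logit) scale, and medians are computed from
surviving values only.

**Proportions.** Percentage traits (spectral-index bins that sum to 100%
per scan) are rescaled to the unit interval and logit-transformed,
`logit(p) = ln(p/(1-p))`, which maps (0,1) onto the real line and
stabilises variance for linear models. The logit is undefined at the
boundaries, so exact 0/1 values are first replaced by the nearest observed
interior value of that column over the whole experiment — a minimal-impact
substitution that preserves rank order. A column consisting entirely of
boundary values is an error: no substitute exists. Transformed columns are
renamed with a `_logit` suffix so every downstream table is
self-describing. Proportion columns can be declared explicitly or
auto-detected (name contains `"bin"`, ≥99% of values in [0, 100]).

**Outlier filtering.** Within each (trait × time cluster) group, pooled
over all plants, the z-score rule drops values more than `z_threshold`
(default **3**) sample standard deviations from the group mean; the IQR
rule drops values outside `[Q1 − m·IQR, Q3 + m·IQR]` with `m = 1.5` and
type-7 (linearly interpolated) quantiles. Degenerate groups — fewer than 3
values, or zero spread — pass through untouched. The 3σ rule assumes
approximate within-group normality; the IQR rule is the robust alternative
for heavy-tailed traits, and on heavy-tailed data it removes at least as
much (a property the acceptance suite checks on t₃ samples).

Two genuinely open choices here:

* *Grouping scope.* The filter pools each cluster across all plants rather
  than filtering within a plant's replicates: gross errors stand out
  against the population of a scan, and per-plant groups of 2–3 values are
  too small for any variance estimate. A config switch can add treatment or
  cultivar to the grouping key when treatment effects are so large that the
  pooled spread would mask errors.
* *Blanking, not deleting.* A removed value blanks that trait's cell only;
  the row survives for its other traits, which were measured independently
  and are usually fine.

**Aggregation and cleanup.** Technical replicates collapse to per-trait
medians (missing-safe; an all-missing group stays missing), one row per
(plant, cluster). Factor columns with a single observed level are dropped —
they carry no contrast and would make model terms inestimable.

## Statistics

The model for a chosen trait is built from the user's ordered factors as
all main effects plus **all two-way interactions and nothing higher**:
`trait ~ F1 + F2 + F1:F2`. Sums of squares are **sequential (Type I)**, the
classical `aov()` decomposition: each term is charged with the variance it
explains after the terms before it. For unbalanced data the factor order
therefore matters and is part of the model specification — this is
deliberate and documented rather than hidden behind a Type-II/III scheme.
Mean squares are `SS/df`, `F = MS_term / MS_residual`, p-values are
upper-tail F probabilities, and the usual significance ladder is attached
(`***` < 0.001, `**` < 0.01, `*` < 0.05, `.` < 0.1). The full-precision
p-values are kept; rounding is left to display.

Shapiro–Wilk (Royston's AS R94 approximation, 3 ≤ n ≤ 5000) is applied to
the **model residuals**, not to raw groups: it is the residual normality
that underwrites the F tests. A zero-variance sample is reported as
not-computable rather than an error.

Tukey HSD contrasts cover all level pairs of a chosen term (for a two-way
interaction, the colon-joined level combinations). Standard errors use the
model's residual mean square with the Tukey–Kramer correction for unequal
group sizes; adjusted p-values and simultaneous 1−α intervals come from the
studentized range distribution with (k, df_residual). Factor levels are
restricted to `[A-Za-z0-9_]` (violations are auto-sanitized on ingest, with
a logged mapping) precisely so that `-` and `:` remain unambiguous
separators in contrast labels; cluster times used as factor levels are
formatted compactly (`20240501T140243`) for the same reason.

**Compact letter display.** Letters are assigned by insert-and-absorb:
start with one letter column holding all levels; for each significant pair
still sharing a column, duplicate the column and delete one member from
each copy; absorb columns whose level set is contained in another's.
Letters are emitted in first-use order, columns ordered by earliest member.
The defining contract — *two levels share a letter if and only if their
comparison is not significant at α* — holds by construction and is verified
by brute force on random significance matrices in the test suite. The
unambiguous level-by-column membership matrix is attached as an attribute;
the concatenated letter string is display sugar.

## The synthetic generator

`design_spec()` describes a factorial experiment the way the platform
records one; its defaults emulate a cereal nitrate-response screen: 35
cultivars × 3 treatments × 2 replicate plants (210 plants), scanned three
times daily (8 h spacing) in 2 technical passes, each pass smearing
timestamps over a 5.5-minute window (330 s). Morphological traits follow
logistic growth — sigmoidal trajectories are what biomass curves look like,
and only group contrasts matter for the statistics — with a multiplicative
log-normal cultivar effect (σ = 0.05), an additive treatment shift
expressed in residual-sd units (default 2σ per level step), and Normal
measurement noise with σ = 5% of the trait's asymptote. Six NDVI bins are
drawn from a Dirichlet whose lowest-bin concentration shifts with
treatment, so the bins sum to exactly 100% and the logit pathway has a
recoverable signal. Plants are laid out on tables of 12 pots.

Planted gross outliers flip a cell by `outlier_magnitude_sigma` (default 8)
standard deviations **of that trait's within-scan spread** — the spread the
per-cluster filter actually judges against, and the scale on which a real
scanner error stands out from the population. Outlier cells, plant
assignments, time-point indices and effect sizes are returned as ground
truth. Everything is deterministic given the seed, down to the archive
bytes (file mtimes are pinned before zipping).

What the generator does **not** emulate: growth-curve autocorrelation
within a plant (noise is independent across scans), spatial pot-position
effects, missing scans, drifting calibration, or non-normal measurement
noise. Passing tests therefore demonstrate that the machinery is correct
under its stated assumptions — not that real phenotyping data meet those
assumptions; the Shapiro–Wilk diagnostic and the IQR option exist exactly
because they often do not.

## Problem sizes used in the checks

The property-based checks run at sizes chosen to make their statistics
meaningful: DBSCAN-versus-oracle on 1000 random instances of up to 200
timestamps; sum-of-squares conservation on 500 random fits with up to 4
factors; F = t² and the Tukey/t identity on 200 seeds each; the letter
contract on 1000 random matrices with up to 8 levels; clean-data retention
on 10 × 10,000 Normal cells; outlier sensitivity on 200 seeded fixtures of
36 plants (72 values per cluster group — large enough that one spike cannot
hide another by inflating the group variance, which is what happens in toy
12-plant fixtures); effect recovery on 200 fixtures with 10 plants per
treatment observed over 3 time clusters. The Tukey/t identity is asserted
to 10⁻⁶: `ptukey()` is evaluated by numerical quadrature and agrees with
the algebraic identity only to about that accuracy.

## Interfaces and formats

Everything the pipeline reads and writes is plain text: CSV tables, YAML
configs and reports, and a results "workbook" that is a directory of CSV
sheets plus `model.txt` — a deliberate portability choice so headless runs
need no spreadsheet library and exports diff cleanly under version control
(a `.xlsx` groups file is rejected with a pointer to CSV export). The one
exception is the intermediate cache, `processed.parquet`, a self-describing
columnar file that round-trips column types exactly; a `processed.csv`
twin is written alongside for human eyes. Re-running `cmd_prepare()` on
unchanged inputs and settings reuses the cache (fingerprint of config plus
input sizes and mtimes).

## Known limitations

* Type-I sums of squares make term order meaningful for unbalanced data;
  users comparing factor importance should fit the orders they care about.
* No mixed-effects or repeated-measures modelling: plants measured across
  time clusters enter the ANOVA as independent observations, which
  overstates residual degrees of freedom when within-plant correlation is
  strong. The letter displays are descriptive in that regime.
* No imputation, growth-curve smoothing, or spatial correction.
* p-values are not adjusted across multiple traits; the Tukey adjustment
  is within one term of one model.
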