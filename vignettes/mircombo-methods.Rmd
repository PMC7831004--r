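---
title: "miRCombo: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{miRCombo: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(miRCombo)
```

miRCombo implements the computational backbone of a combination-miRNA
study design: three tumor-suppressor miRNAs (by default miR-124-3p,
miR-128-3p and miR-137-3p, which are jointly downregulated in glioma and
neuroblastoma) are delivered together as mimics, and the analysis asks
(i) whether the combination acts synergistically on cell growth,
(ii) whether the genes it silences are enriched for predicted targets of
the transfected miRNAs, (iii) whether silencing depth scales with the
number of targeting miRNAs and binding sites, (iv) which miRNA families
form clusters of shared targets, (v) which lncRNAs carry seed sites for
all three miRNAs, and (vi) whether joint expression of the three miRNAs
stratifies patient survival. Every stage consumes plain tables or FASTA,
and a synthetic-data generator with planted ground truth stands in for
the experimental and sequencing data, so the whole pipeline is testable
end to end.

## Synergy: effects and combination indices

**Effect definition.** For a treatment arm $X$ with replicate signals
(confluence or viability) observed over time, the endpoint effect is the
fractional inhibition relative to control,

$$E_X = 1 - \frac{\overline{s}_X(t^\ast)}{\overline{s}_{\mathrm{ctrl}}(t^\ast)},$$

where $\overline{s}$ are replicate means at the recorded timepoint
$t^\ast$ nearest the requested endpoint (default 120 h; live-cell
imaging intervals are irregular, so the endpoint snaps to the nearest
sample). How to reduce a growth curve to a scalar effect is a genuine
design choice — endpoint signal, area under the curve, and growth rate
are all defensible. We use the endpoint signal: it is the standard
readout for confluence assays, and it makes the combination index
formulas below exact statements about observable quantities. Negative
effects (signal above control) are retained and flagged as growth
promotion. Standard errors come from the delta method on the ratio of
replicate means.

**Combination indices.** With single-agent effects $E_A, E_B, E_C$ and
combination effect $E_{ABC}$:

- *linear interaction (response additivity)*:
  $\mathrm{CI} = (E_A + E_B + E_C) / E_{ABC}$;
- *Bliss independence, triple-product form*:
  $\mathrm{CI} = \big((E_A + E_B + E_C) - E_A E_B E_C\big) / E_{ABC}$;
- *Bliss independence, canonical form*:
  $\mathrm{CI} = \big(1 - (1-E_A)(1-E_B)(1-E_C)\big) / E_{ABC}$.

CI < 1 is synergy, CI > 1 antagonism, and values within a configurable
tolerance of 1 (default 0.05) are reported as additivity. The
triple-product form is reported as the default because it is the
three-agent expression used in the combination-miRNA literature this
package models; note it omits the pairwise products of the canonical
Bliss expansion, so the two variants disagree unless effects are small.
Both are always available side by side (`blissCI(..., variant =)`), and
we make no attempt to guess which was "meant" — the discrepancy is
documented, not resolved.

Endpoint groups are compared with one-way ANOVA plus Tukey HSD
(`endpointComparison()`); CI uncertainty comes from a seeded
nonparametric bootstrap over replicates (`bootstrapCI()`, default 1000
resamples).

### Precision of a three-replicate CI

A point worth stating analytically: with $R$ replicates and
multiplicative measurement noise of CV $c$ on each well, delta-method
propagation through the linear CI gives a sampling SD of roughly
$3\,c/\sqrt{R}$ near the defaults (the dominant term is the shared
control mean, which enters all four effects). At $c = 0.05$ and $R = 3$
this is about 0.09–0.10: a single three-replicate experiment determines
the CI only to roughly ±0.2 at 95% confidence. The package's recovery
tests measure exactly this spread on simulated experiments; claims of
synergy from CI values near 1 with few replicates should be treated
accordingly, while strong synergy (CI well below 0.5) is comfortably
resolvable.

## Multi-study overlap and target enrichment

Per study, genes are `up` if adjusted $p < 0.05$ and
$\log_2\mathrm{FC} \ge 0.5$, `down` if adjusted $p < 0.05$ and
$\log_2\mathrm{FC} \le -0.5$ (fold-change boundary inclusive, p boundary
strict), else `ns`. The consensus set of a direction holds genes with
that call in at least two studies, minus genes with conflicting
direction calls in any study, restricted to protein-coding genes;
lncRNAs passing the same rule are kept in a side channel feeding the
seed-site scanner. Venn region counts are computed on the conflict-free
per-study sets, so regions always sum to the union.

Enrichment of miRNA targets in a consensus set is tested two ways:

- an exact hypergeometric test on the count of set members targeted by
  at least `minMirnas` distinct miRNAs, against the chosen universe;
- a permutation null: `iters` seeded draws of equally sized subsets of
  the universe, with empirical p
  $(1 + \#\{\text{null} \ge \text{obs}\})/(\text{iters}+1)$.

The pseudo-count keeps the empirical p away from zero — 10,000 draws can
never support a p of $10^{-66}$ — so the z-score against the null mean
and SD, and the corresponding one-sided normal-approximation p, are
reported alongside and labelled as such. The default universe is the
union of all genes called up or down in any study; this is configurable,
and the target map is always supplied at run time rather than baked in.

## Silencing versus targeting count and site burden

Within each study, downregulated and not-DE genes (upregulated genes
excluded) are stratified by the number of distinct targeting miRNAs
(0–3); the package reports per-stratum median $\log_2$FC, a two-sided
Wilcoxon rank-sum test of 0 versus ≥ 1 miRNAs, and a monotonicity flag.
For consensus-down genes, the total binding-site count is summed
indiscriminately over the three miRNAs; genes whose between-study SD of
$\log_2$FC exceeds 0.5 are excluded (inconsistent measurements), and the
quartiles of the mean $\log_2$FC on the filtered set define *high*
silencing (≤ Q1, i.e. most negative — silencing means downregulation)
and *low* silencing (≥ Q3), ties included in the extreme class.
Quartiles use linear interpolation of the order statistics at positions
$(n+1)p$ (quantile type 6). The high/low classes are then tested for
association with single- versus multiple-site status by a chi-squared
test without continuity correction (flagged unreliable if any expected
cell is below 1) and for a shift in total sites by a Wilcoxon test.
Small-sample Wilcoxon tests (both groups ≤ 6) use the exact null
distribution; larger ones the normal approximation with tie correction.

## Clustering miRNA families on shared targets

Families with at least a configurable number of predicted targets are
retained and embedded as binary membership vectors over the genes shared
by at least two retained families — the clustering is driven by shared-
target structure, not by private targets. Pairwise overlap is summarized
as counts and as a percentage normalized by the smaller set (a single
percentage per pair even when set sizes differ; Jaccard and mean-size
normalizations are options). Trees use Ward's criterion on Euclidean
distances (`hclust`, `method = "ward.D2"`, which implements Ward's
method on distances); families are sorted by label first so the tree is
independent of input order, and merge heights are non-decreasing by
construction. Optional bootstrap support (off by default) resamples the
gene features with replacement and reports per-pair co-clustering
frequency. The embedding and normalization are declared defaults, not
claims of equivalence with any particular published dendrogram.

## Canonical seed-site scanning

Sites are the canonical seed-match types: with the miRNA written
5'→3', the target-side match to positions 2–8 is a **7mer-m8**; with a
downstream `A` on the target it is an **8mer**; a match to positions 2–7
followed by `A` is a **7mer-A1**; the bare 6mer core is reported only on
request (high false-positive rate). Each occurrence is classified by its
most specific type, overlapping occurrences are all reported, U/T are
interchangeable, coordinates are 0-based half-open, and only the
provided sense strand is scanned. There is no wobble pairing, 3'
supplementary pairing, or free-energy scoring: the canonical types are
the conservative, exactly testable core of site prediction, and
`tripleTargeted()` intersects per-miRNA hits to find transcripts (e.g.
lncRNAs) carrying sites for all three miRNAs.

## Survival stratification

Each miRNA expression column is standardized across patients (sample
SD), and the per-patient average z-score is split at its median (ties to
the low group; the quantile is configurable — the median is a declared
default, not an inference about any particular published cut).
Kaplan–Meier curves are estimated per group and compared with the
two-group log-rank test (`survival::survdiff`); at tied times the
standard convention applies (events before censorings). Pairwise Pearson
correlations of the markers, with t-transform p-values, accompany the
stratification. Cox regression is deliberately out of scope.

## The synthetic-data generator

`synthConfig()` fixes the study conditions; every generator expands one
master seed into fixed per-stream child seeds, so identical
configurations give byte-identical artifacts and adding a generator
never perturbs existing streams.

- **Growth curves** (`simulateGrowthCurves`): logistic trajectories
  (plateau 100, midpoint 60 h) over 0–120 h; arm $X$'s fractional effect
  ramps linearly in time to $E_X$ at the endpoint, and the combination
  effect is $\sum E_X / \mathrm{CI}^\ast$ for the planted index
  $\mathrm{CI}^\ast$, so noiseless curves recover $\mathrm{CI}^\ast$
  exactly. Noise is independent multiplicative log-normal (mean 1, CV
  `noiseCV`) per observation — signals stay positive at any CV, and
  wells are treated as independent because seeding and transfection vary
  well to well. Defaults: three single effects of 0.10 (low doses that
  individually do little), planted CI 0.35 (strong synergy on the scale
  seen in glioma lines), CV 0.05, 3 replicates, 21 timepoints.
- **DE studies** (`simulateDEStudies`): 5000 genes; each is a target of
  each miRNA independently with probability 0.25, with 1–3 sites per
  targeting miRNA; $\log_2$FC = −0.3 per targeting miRNA − 0.4 per extra
  site, plus a shared gene effect and per-study noise (total baseline SD
  0.5, 60% shared between studies, mimicking three related cell-line
  transfections). Adjusted p-values are a monotone transform of
  |$\log_2$FC| with multiplicative jitter — downstream stages only
  threshold them, so no DE model is fitted. Biotypes are 90%
  protein-coding, 8% lncRNA, 2% other.
- **Families** (`simulateFamilyTargets`): a global core (fraction
  `betweenOverlap` of each family), a per-group core (bringing
  within-group sharing to `withinOverlap`) and private genes; defaults
  two groups of three families, 200 targets each, 0.8/0.1 sharing —
  a scaled-down version of genome-wide target predictions.
- **Sequences** (`simulateTargetSequences`): random backgrounds are
  rejection-sampled to contain no seed-core match for any of the three
  miRNAs, then sites (random types, 1–2 per chosen miRNA) are spliced in
  with guard bases and the finished sequence is re-scanned until the
  scan equals the plan — so scanner false positives and negatives are
  exactly zero *by construction*, and tests can assert exact equality.
  Half of the sequences carry sites for all three miRNAs.
- **Survival** (`simulateSurvivalCohort`): three equicorrelated
  expression markers (ρ = 0.6, matching the strong co-expression of the
  three miRNAs in patient cohorts); event times are exponential with
  rate $\lambda_0 e^{\beta \bar z}$, default $\beta = \log 2$ (hazard
  ratio 2 per unit average z-score), $n = 300$, independent exponential
  censoring calibrated to ≈ 20%.

**What the generator does not emulate.** Count-level RNA-seq noise and
DE model fitting (it emits finished DE tables); realistic 3'UTR length
and site-context distributions; non-canonical and context-scored sites;
non-exponential hazards and informative censoring; batch structure
across studies beyond a shared gene effect. Passing tests therefore
demonstrate that the statistical machinery is correct and calibrated
under a faithful null and recovers planted effects — not that any
particular biological dataset will show those effects.

## Numerical and degenerate-input conventions

Effects are undefined when the control mean is zero (error); CIs are
undefined at $E_{ABC} = 0$ (error with diagnostic). All-constant
endpoint groups report F = 0, p = 1. Degenerate quartiles (Q1 = Q3)
classify everything as `mid` with a warning. Identical family membership
vectors produce a zero-height merge chain with a warning. Identical
miRNA seeds in `tripleTargeted()` warn but compute. A split group with
zero events is flagged low-information rather than suppressed. Empirical
permutation p-values are never 0 by the pseudo-count. All stochastic
routines take explicit seeds and restore the caller's RNG state.

## Problem sizes in the shipped tests

The test suite simulates at sizes chosen to make Monte-Carlo assertions
stable while keeping a full run in a few minutes on one CPU: 100-seed
recovery runs for the combination index and the site scanner, 200
synthetic datasets for null calibration of the permutation and log-rank
tests (Kolmogorov–Smirnov uniformity), 50-seed power runs for the
site-burden test, and a 10,000-permutation oracle for the log-rank test
on a 40-patient cohort. `runPipeline()` writes every stage's tables, a
log, and a summary JSON with file hashes; rerunning with the same
configuration reproduces identical hashes.

## Known limitations

- The endpoint-signal effect definition discards curve-shape
  information; with three replicates the CI carries the sampling SD
  derived above, and the package reports bootstrap intervals rather than
  pretending point precision.
- The triple-product Bliss variant is reported for comparability, not
  because it is the better-founded reference model; the canonical
  variant is the statistically standard one.
- Seed matching is sequence-only; it neither reproduces nor approximates
  context-scored or energy-based site predictors.
- The clustering embedding (shared-target membership vectors) is one
  reasonable choice among several; dendrogram shape can depend on it.
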