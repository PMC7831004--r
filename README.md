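# miRCombo

Combination therapy with tumor-suppressor miRNA mimics — delivering, say,
miR-124-3p, miR-128-3p and miR-137-3p together instead of one at a time —
promises stronger repression of shared oncogenic targets at lower doses.
Evaluating such a design takes a chain of analyses that usually live in
ad-hoc scripts: synergy quantification from growth curves, consensus
differential-expression sets across transfection studies, target-enrichment
tests, binding-site-burden analyses, shared-target clustering of miRNA
families, seed-site scanning of lncRNAs, and expression-based survival
stratification. miRCombo packages that chain as tested, seedable R
functions for computational biologists working on miRNA combination
studies in glioma, neuroblastoma and related settings, together with a
synthetic-data generator (planted ground truth) that makes every stage
verifiable without any external download.

## Models at the core

With single-agent endpoint effects `E_A, E_B, E_C` (fractional inhibition
relative to control) and combination effect `E_ABC`:

* linear interaction (response additivity): `CI = (E_A + E_B + E_C) / E_ABC`
* Bliss independence, triple-product form:
  `CI = ((E_A + E_B + E_C) − E_A·E_B·E_C) / E_ABC`
* Bliss independence, canonical form:
  `CI = (1 − (1−E_A)(1−E_B)(1−E_C)) / E_ABC`

CI < 1 indicates synergy, CI ≈ 1 additivity, CI > 1 antagonism. Target
enrichment in a multi-study consensus set is tested by an exact
hypergeometric test and by a seeded permutation null (fraction of the set
targeted by ≥ k miRNAs versus equally sized random subsets of the DE
universe), with a z-score/normal-approximation p reported alongside the
pseudo-counted empirical p. Silencing depth is related to targeting-miRNA
count (Wilcoxon) and total binding-site burden (quartile classes,
chi-squared). miRNA families are Ward-clustered on binary shared-target
membership vectors. Canonical seed sites (8mer, 7mer-m8, 7mer-A1) are
scanned on the sense strand. Survival is stratified by the median of the
per-patient average expression z-score (Kaplan–Meier + log-rank). The
methods vignette (`vignettes/mircombo-methods.Rmd`) derives and motivates
each choice.

## Worked example

```r
library(miRCombo)

cfg    <- synthConfig(seed = 1)            # default study conditions
curves <- simulateGrowthCurves(cfg)        # control, A, B, C, ABC arms
es     <- computeEffectSet(curves, endpointH = 120)
es
#> EffectSet at 120 h (3 replicates)
#>   E_A = 0.0945 (se 0.0510)
#>   E_B = 0.1309 (se 0.0509)
#>   E_C = 0.1329 (se 0.0465)
#>   E_ABC = 0.8609 (se 0.0085)
linearCI(es)
#> CombinationIndex [linear]: CI = 0.4162 (synergy)
blissCI(es, "paper")
#> CombinationIndex [bliss_paper]: CI = 0.4143 (synergy)
```

The three agents individually inhibit ~10–13% of endpoint confluence, the
combination 86%; the expected additive effect is only 0.36, so the linear
CI of 0.42 signals strong synergy (the generator planted CI = 0.35; with
three replicates at 5% noise the estimate carries a sampling SD of about
0.1 — see the vignette).

```r
de <- simulateDEStudies(cfg)               # three correlated DE studies
ov <- buildOverlap(de$studies, direction = "down")
ov
#> OverlapSets (down, >= 2 studies, protein-coding)
#>   consensus: 2121 genes; conflicts removed: 28; lncRNA side channel: 188

universe <- unique(c(unlist(lapply(de$studies, function(t) {
  t <- classifyDE(t); t$gene_id[t$label != "ns"]
})), removedConflicts(ov)))
permutationEnrichment(consensusGenes(ov), universe, de$targetMap,
                      minMirnas = 2, iters = 10000, seed = 1)
#> EnrichmentResult (>= 2 miRNAs): observed 0.294 (n=2121), null 0.193 +/- 0.006
#>   empirical p = 0.0001 (iters 10000), z = 17.93, normal-approx p = 3.54e-72
#>   hypergeometric p(over) = 7.95e-77, fold = 1.520
```

29% of the consensus-down genes are targeted by at least two of the three
miRNAs versus 19% expected by chance — a 1.5-fold enrichment that no
permutation reaches (empirical p at the 1/10001 floor; the z-based p
quantifies how far beyond the floor it lies).

`runPipeline(cfg, "out/")` (or a YAML config) runs all seven stages —
simulate, synergy, overlap, dose, cluster, sites, survival — writes every
table, a log and a hash-stamped `summary.json`, and is byte-reproducible
for a fixed seed.

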