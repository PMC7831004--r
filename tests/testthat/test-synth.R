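test_that("identical config and seed reproduce byte-identical artifacts", {
  cfg <- synthConfig(seed = 11, nGenes = 400L, nSequences = 10L,
                     nPatients = 60L)
  expect_identical(curveData(simulateGrowthCurves(cfg)),
                   curveData(simulateGrowthCurves(cfg)))
  expect_identical(simulateDEStudies(cfg), simulateDEStudies(cfg))
  s1 <- simulateTargetSequences(cfg)
  s2 <- simulateTargetSequences(cfg)
  expect_identical(as.character(s1$sequences), as.character(s2$sequences))
  expect_identical(s1$sites, s2$sites)
  expect_identical(cohortTable(simulateSurvivalCohort(cfg)),
                   cohortTable(simulateSurvivalCohort(cfg)))
})

test_that("generator streams are independent of unrelated parameters", {
  a <- synthConfig(seed = 5, nGenes = 300L)
  b <- synthConfig(seed = 5, nGenes = 300L, nSequences = 15L,
                   nPatients = 77L)
  expect_identical(curveData(simulateGrowthCurves(a)),
                   curveData(simulateGrowthCurves(b)))
  expect_identical(simulateDEStudies(a), simulateDEStudies(b))
})

test_that("invalid configurations fail naming the violated bound", {
  expect_error(synthConfig(plantedCI = 0), "plantedCI")
  expect_error(synthConfig(plantedCI = -1), "plantedCI")
  expect_error(synthConfig(singleEffects = c(0.5, 0.5, 0.5),
                           plantedCI = 1), "valid fraction")
  expect_error(synthConfig(singleEffects = c(0.1, 1, 0.1)), "\\[0, 1\\)")
  expect_error(synthConfig(fracTargeted = 0), "fracTargeted")
  expect_error(synthConfig(withinOverlap = 0.1, betweenOverlap = 0.3),
               "withinOverlap")
  expect_error(synthConfig(censorRate = 1), "censorRate")
  expect_error(synthConfig(familyGroupSizes = c(2, 2)), "sum to nFamilies")
})

test_that("noiseless curves obey the planting arithmetic exactly", {
  snap <- function(cfg) {
    df <- curveData(simulateGrowthCurves(cfg))
    at <- df[df$time_h == max(df$time_h) & df$replicate == 1, ]
    setNames(at$signal, at$arm)
  }
  # additive planting: combination endpoint = (1 - 0.3) x control
  s <- snap(synthConfig(noiseCV = 0, plantedCI = 1,
                        singleEffects = c(0.1, 0.1, 0.1)))
  expect_equal(s[["ABC"]], 0.7 * s[["control"]], tolerance = 1e-12)
  expect_equal(s[["A"]], 0.9 * s[["control"]], tolerance = 1e-12)
  # synergy planting: combination effect 0.3/0.5 = 0.6, endpoint 0.4 x control
  s <- snap(synthConfig(noiseCV = 0, plantedCI = 0.5,
                        singleEffects = c(0.1, 0.1, 0.1)))
  expect_equal(s[["ABC"]], 0.4 * s[["control"]], tolerance = 1e-12)
})

test_that("DE generator plants the targeting shift and keeps genes unique", {
  cfg <- synthConfig(seed = 3, nGenes = 20000L, deltaPerMirna = -0.3,
                     deltaPerSite = 0)
  de <- simulateDEStudies(cfg)
  for (tab in de$studies) expect_false(anyDuplicated(tab$gene_id) > 0)
  # law of large numbers on the planting rule: 3-miRNA minus 0-miRNA mean
  lfc <- de$studies$study1$log2fc
  n3 <- de$truth$n_mirnas == 3
  n0 <- de$truth$n_mirnas == 0
  expect_equal(mean(lfc[n3]) - mean(lfc[n0]), -0.9, tolerance = 0.05)
  # padj is (up to jitter) small where |log2fc| is large
  tab <- de$studies$study1
  expect_lt(median(tab$padj[abs(tab$log2fc) > 1]),
            median(tab$padj[abs(tab$log2fc) < 0.2]))
})

test_that("a null DE configuration plants no targeting effect", {
  cfg <- synthConfig(seed = 9, nGenes = 20000L, deltaPerMirna = 0,
                     deltaPerSite = 0)
  de <- simulateDEStudies(cfg)
  lfc <- de$studies$study2$log2fc
  tgt <- de$truth$n_mirnas > 0
  expect_lt(abs(mean(lfc[tgt]) - mean(lfc[!tgt])), 0.02)
  expect_gt(t.test(lfc[tgt], lfc[!tgt])$p.value, 0.001)
})

test_that("family planting yields the requested overlap block structure", {
  # degenerate planting: identical sets within a group, disjoint across
  cfg <- synthConfig(withinOverlap = 1, betweenOverlap = 0,
                     nFamilies = 4L, familyGroupSizes = c(2L, 2L),
                     targetsPerFamily = 50L)
  fam <- simulateFamilyTargets(cfg)$families
  expect_setequal(fam$fam01, fam$fam02)
  expect_length(intersect(fam$fam01, fam$fam03), 0)
  # graded planting: pairwise overlap percentages are block-structured
  cfg <- synthConfig(seed = 2, withinOverlap = 0.8, betweenOverlap = 0.1,
                     nFamilies = 6L, familyGroupSizes = c(3L, 3L),
                     targetsPerFamily = 100L)
  pct <- overlapPct(sharedTargetMatrix(simulateFamilyTargets(cfg)$families))
  within <- pct[1:3, 1:3][upper.tri(matrix(0, 3, 3))]
  between <- pct[1:3, 4:6]
  expect_true(all(within == 80))
  expect_true(all(between == 10))
})

test_that("a single family is generated without clustering structure", {
  cfg <- synthConfig(nFamilies = 1L, familyGroupSizes = 1L,
                     withinOverlap = 0.8, betweenOverlap = 0.1,
                     targetsPerFamily = 30L)
  fam <- simulateFamilyTargets(cfg)
  expect_length(fam$families, 1)
  expect_length(fam$families[[1]], 30)
})

test_that("site-free background sequences contain no canonical site", {
  cfg <- synthConfig(seed = 21, nSequences = 15L, seqLength = 300L)
  sq <- simulateTargetSequences(cfg, plantSites = FALSE)
  expect_identical(nrow(sq$sites), 0L)
  for (m in names(comboMirnaSequences())) {
    hits <- scanSeedSites(comboMirnaSequences()[[m]], sq$sequences,
                          mirna = m)
    expect_identical(nrow(hits), 0L)
  }
})

test_that("planted sites are recorded where the scanner finds them", {
  cfg <- synthConfig(seed = 8, nSequences = 20L, fracTriple = 0.5)
  sq <- simulateTargetSequences(cfg)
  expect_length(sq$tripleIds, 10)
  # every planted site interval matches the recorded type and position
  seqs <- as.character(sq$sequences)
  for (i in seq_len(nrow(sq$sites))) {
    row <- sq$sites[i, ]
    slice <- substr(seqs[[row$sequence_id]], row$start + 1, row$end)
    found <- scanSeedSites(comboMirnaSequences()[[row$mirna]],
                           setNames(seqs[row$sequence_id], row$sequence_id),
                           mirna = row$mirna)
    hit <- found[found$start == row$start, ]
    expect_identical(hit$site_type, row$site_type)
    expect_identical(hit$matched_subsequence, slice)
  }
})

test_that("survival generator honors censoring and effect sign", {
  cfg <- synthConfig(seed = 4, nPatients = 200L, censorRate = 0)
  coh <- simulateSurvivalCohort(cfg)
  expect_true(all(cohortTable(coh)$event == 1))
  # strongly protective score: high-score group survives longer
  cfg <- synthConfig(seed = 4, nPatients = 400L, hazardBeta = -2,
                     censorRate = 0.1)
  km <- kmLogrank(simulateSurvivalCohort(cfg))
  expect_gt(km$medianSurvival[["high"]], km$medianSurvival[["low"]])
})
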