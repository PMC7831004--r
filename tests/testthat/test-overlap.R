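test_that("DE classification uses inclusive fold-change and strict padj bounds", {
  tab <- deTable(c("g1", "g2", "g3", "g4"),
                 log2fc = c(0.5, -3, 0.49, -0.5),
                 padj = c(0.049, 0.05, 1e-10, 0.01))
  lab <- classifyDE(tab)$label
  expect_identical(lab, c("up", "ns", "ns", "down"))
  expect_error(classifyDE(tab, lfcThresh = 0), "thresholds")
  expect_error(classifyDE(data.frame(gene_id = "g")), "schema error")
})

test_that("consensus keeps >=2-study genes, drops conflicts and non-coding", {
  s1 <- deTable(c("gA", "gB", "gC", "gL"), c(-1, -1, -1, -1),
                c(0.01, 0.01, 0.01, 0.01),
                biotype = c("protein_coding", "protein_coding",
                            "protein_coding", "lncRNA"))
  s2 <- deTable(c("gA", "gB", "gC", "gL"), c(-1, 1, 0.1, -1),
                c(0.01, 0.01, 0.9, 0.01),
                biotype = c("protein_coding", "protein_coding",
                            "protein_coding", "lncRNA"))
  s3 <- deTable(c("gA", "gB", "gC", "gL"), c(0.1, -1, -0.2, 0.2),
                c(0.5, 0.01, 0.5, 0.4),
                biotype = c("protein_coding", "protein_coding",
                            "protein_coding", "lncRNA"))
  ov <- buildOverlap(list(s1, s2, s3), "down")
  # gA: down in studies 1,2, ns in 3 -> consensus
  expect_true("gA" %in% consensusGenes(ov))
  # gB: down in 1 and 3 but up in 2 -> conflict, in no set
  expect_identical(removedConflicts(ov), "gB")
  expect_false("gB" %in% unlist(ov@perStudy))
  # gC: down in one study only -> not consensus
  expect_false("gC" %in% consensusGenes(ov))
  # gL: lncRNA down in >=2 studies -> side channel, not coding consensus
  expect_false("gL" %in% consensusGenes(ov))
  expect_identical(lncRNAGenes(ov), "gL")
  # with codingOnly = FALSE the lncRNA joins the consensus
  ov2 <- buildOverlap(list(s1, s2, s3), "down", codingOnly = FALSE)
  expect_true(all(c("gA", "gL") %in% consensusGenes(ov2)))
  # duplicated gene within a study is an input error
  bad <- rbind(s1, s1[1, ])
  expect_error(buildOverlap(list(bad, s2), "down"), "duplicated gene_id")
})

test_that("Venn region counts sum to the union for both directions", {
  cfg <- synthConfig(seed = 17, nGenes = 1200L)
  de <- simulateDEStudies(cfg)
  for (dir in c("down", "up")) {
    ov <- buildOverlap(de$studies, dir)
    expect_identical(sum(regionCounts(ov)),
                     length(unique(unlist(ov@perStudy))))
  }
})

test_that("target fraction counts genes hit by at least k distinct miRNAs", {
  tm <- data.frame(gene_id = c("g1", "g1", "g3"),
                   mirna = c("m1", "m2", "m1"), site_count = 1)
  expect_equal(targetFraction(c("g1", "g2"), tm)$fraction, 0.5)
  expect_equal(targetFraction(c("g1", "g2"), tm, minMirnas = 3)$fraction, 0)
  expect_equal(targetFraction(c("g1", "g3"), tm)$fraction, 1.0)
  expect_error(targetFraction(character(), tm), "empty gene set")
})

test_that("hypergeometric tails match combinatorial enumeration", {
  res <- hypergeomEnrichment(4, 4, 5, 10)
  expect_equal(res$p_over, 5 / 210, tolerance = 1e-12)
  # fold = 1 exactly at the expected count
  expect_equal(hypergeomEnrichment(2, 4, 5, 10)$fold, 1)
  expect_error(hypergeomEnrichment(0, 4, 10, 10), "impossible counts")
  expect_error(hypergeomEnrichment(5, 4, 5, 10), "impossible counts")
  set.seed(33)
  for (i in 1:25) {
    N <- sample(3:14, 1); K <- sample(0:N, 1); n <- sample(1:N, 1)
    kRange <- max(0, n - (N - K)):min(n, K)
    k <- kRange[sample.int(length(kRange), 1)]
    got <- hypergeomEnrichment(k, n, K, N)
    want <- combnHyperP(k, n, K, N)
    expect_equal(got$p_over, want$p_over, tolerance = 1e-12)
    expect_equal(got$p_under, want$p_under, tolerance = 1e-12)
  }
})

test_that("permutation enrichment handles floor and degenerate cases", {
  universe <- sprintf("g%03d", 1:200)
  tm <- data.frame(gene_id = rep(universe[1:20], each = 2),
                   mirna = rep(c("m1", "m2"), 20), site_count = 1)
  # observed set is exactly the targeted genes: above every null draw
  res <- permutationEnrichment(universe[1:20], universe, tm,
                               minMirnas = 2, iters = 500, seed = 2)
  expect_equal(res@observedFraction, 1)
  expect_equal(res@empiricalP, 1 / 501)
  expect_gt(res@z, 5)
  # universe entirely targeted: observed = null = 1, p = 1
  tmAll <- data.frame(gene_id = rep(universe, each = 3),
                      mirna = rep(c("m1", "m2", "m3"), 200), site_count = 1)
  resAll <- permutationEnrichment(universe[1:20], universe, tmAll,
                                  minMirnas = 3, iters = 200, seed = 2)
  expect_equal(resAll@observedFraction, 1)
  expect_equal(resAll@nullMean, 1)
  expect_equal(resAll@empiricalP, 1)
  expect_error(permutationEnrichment(c("zz", universe[1]), universe, tm),
               "subset of the universe")
  expect_error(permutationEnrichment(universe[1:5], universe, tm,
                                     iters = 10), "iters")
})

test_that("permutation draws are seed-reproducible", {
  universe <- sprintf("g%03d", 1:300)
  tm <- data.frame(gene_id = universe[1:90], mirna = "m1", site_count = 1)
  r1 <- permutationEnrichment(universe[1:40], universe, tm, minMirnas = 1,
                              iters = 300, seed = 9, returnNull = TRUE)
  r2 <- permutationEnrichment(universe[1:40], universe, tm, minMirnas = 1,
                              iters = 300, seed = 9, returnNull = TRUE)
  expect_identical(attr(r1, "null"), attr(r2, "null"))
})

test_that("empirical and normal-approximation p agree at large iteration counts", {
  cfg <- synthConfig(seed = 23, nGenes = 2000L, deltaPerMirna = 0,
                     deltaPerSite = 0)
  de <- simulateDEStudies(cfg)
  ov <- buildOverlap(de$studies, "down")
  universe <- unique(unlist(lapply(de$studies, function(t) {
    t <- classifyDE(t); t$gene_id[t$label != "ns"]
  })))
  universe <- unique(c(universe, consensusGenes(ov)))
  # a null configuration keeps the p away from the pseudo-count floor
  res <- permutationEnrichment(consensusGenes(ov), universe, de$targetMap,
                               minMirnas = 2, iters = 8000, seed = 1)
  if (res@empiricalP > 2 / 8001 && res@empiricalP < 1) {
    # the null of a bounded discrete fraction is only approximately normal
    expect_lt(abs(res@empiricalP - res@normalApproxP), 0.05)
  }
  expect_equal(res@z, (res@observedFraction - res@nullMean) / res@nullSD)
})
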