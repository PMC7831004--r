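makeCurves <- function(values, times = c(0, 60, 120)) {
  # values: named list arm -> endpoint replicate signals
  rows <- lapply(names(values), function(arm) {
    do.call(rbind, lapply(seq_along(values[[arm]]), function(r) {
      data.frame(arm = arm, replicate = r, time_h = times,
                 signal = seq(1, values[[arm]][r], length.out = length(times)))
    }))
  })
  new("TreatmentCurveSet", curves = do.call(rbind, rows),
      controlArm = "control")
}

test_that("endpoint effect is the fractional inhibition relative to control", {
  cur <- makeCurves(list(control = c(100, 100), T = c(70, 70)))
  expect_equal(computeEffect(cur, "T")$effect, 0.30, tolerance = 1e-12)
  cur <- makeCurves(list(control = c(100, 100), T = c(100, 100)))
  expect_equal(computeEffect(cur, "T")$effect, 0)
  # signal above control: negative effect, growth-promotion flag
  cur <- makeCurves(list(control = c(100, 100), T = c(120, 120)))
  res <- computeEffect(cur, "T")
  expect_equal(res$effect, -0.20, tolerance = 1e-12)
  expect_true(res$growth_promotion)
  expect_error(computeEffect(cur, "missing"), "lookup error")
  cur0 <- makeCurves(list(control = c(0, 0), T = c(1, 1)))
  expect_error(computeEffect(cur0, "T"), "control mean")
})

test_that("linear CI follows (E_A+E_B+E_C)/E_ABC with the <1/=1/>1 rule", {
  ci <- linearCI(makeEffectSet(0.1, 0.1, 0.1, 0.3))
  expect_equal(ciValue(ci), 1)
  expect_identical(ciInterpretation(ci), "additivity")
  ci <- linearCI(makeEffectSet(0.1, 0.1, 0.1, 0.6))
  expect_equal(ciValue(ci), 0.5)
  expect_identical(ciInterpretation(ci), "synergy")
  ci <- linearCI(makeEffectSet(0.05, 0.10, 0.15, 0.9))
  expect_equal(ciValue(ci), 0.3 / 0.9, tolerance = 1e-12)
  ci <- linearCI(makeEffectSet(0.2, 0.2, 0.2, 0.5))
  expect_identical(ciInterpretation(ci), "antagonism")
  expect_error(linearCI(makeEffectSet(0.1, 0.1, 0.1, 0)),
               "division-by-zero")
})

test_that("both Bliss variants follow their printed formulas", {
  expect_equal(ciValue(blissCI(makeEffectSet(0, 0, 0, 0.5), "paper")), 0)
  expect_equal(ciValue(blissCI(makeEffectSet(0.5, 0.5, 0.5, 1.5), "paper")),
               (1.5 - 0.125) / 1.5, tolerance = 1e-12)
  # the two variants document the formula discrepancy at small effects
  es <- makeEffectSet(0.1, 0.1, 0.1, 0.3)
  expect_equal(ciValue(blissCI(es, "paper")), 0.299 / 0.3,
               tolerance = 1e-12)
  expect_equal(ciValue(blissCI(es, "canonical")), (1 - 0.9^3) / 0.3,
               tolerance = 1e-12)
})

test_that("CI formulas match brute-force re-evaluation on random tuples", {
  set.seed(71)
  for (i in 1:100) {
    e <- runif(3, -0.2, 0.9)
    abc <- runif(1, 0.05, 1.5) * sample(c(-1, 1), 1)
    es <- makeEffectSet(e[1], e[2], e[3], abc)
    expect_equal(ciValue(linearCI(es)), sum(e) / abc, tolerance = 1e-12)
    expect_equal(ciValue(blissCI(es, "paper")), (sum(e) - prod(e)) / abc,
                 tolerance = 1e-12)
    expect_equal(ciValue(blissCI(es, "canonical")),
                 (1 - prod(1 - e)) / abc, tolerance = 1e-12)
  }
})

test_that("effects and CIs are invariant to rescaling all signals", {
  cfg <- synthConfig(seed = 31, noiseCV = 0.05)
  cur <- simulateGrowthCurves(cfg)
  df <- curveData(cur)
  df$signal <- df$signal * 37.5
  scaled <- new("TreatmentCurveSet", curves = df, controlArm = "control")
  e1 <- computeEffectSet(cur); e2 <- computeEffectSet(scaled)
  expect_equal(effectValues(e1), effectValues(e2), tolerance = 1e-12)
  expect_equal(ciValue(linearCI(e1)), ciValue(linearCI(e2)),
               tolerance = 1e-12)
})

test_that("exact additivity with zero noise gives linear CI exactly 1", {
  cfg <- synthConfig(noiseCV = 0, plantedCI = 1,
                     singleEffects = c(0.08, 0.1, 0.12))
  ci <- linearCI(computeEffectSet(simulateGrowthCurves(cfg)))
  expect_equal(ciValue(ci), 1, tolerance = 1e-12)
  expect_identical(ciInterpretation(ci), "additivity")
})

test_that("bootstrap CI brackets the point estimate deterministically", {
  cfg <- synthConfig(seed = 13)
  cur <- simulateGrowthCurves(cfg)
  b1 <- bootstrapCI(cur, nBoot = 200, seed = 7)
  b2 <- bootstrapCI(cur, nBoot = 200, seed = 7)
  expect_identical(b1$boot, b2$boot)
  expect_lte(b1$lower, b1$ci)
  expect_gte(b1$upper, b1$ci)
})

test_that("endpoint comparison handles signal, no-signal and degenerate input", {
  # flat constant groups carry no signal
  res <- endpointComparison(list(a = c(5, 5, 5), b = c(5, 5, 5)))
  expect_equal(res$f, 0)
  expect_equal(res$p, 1)
  expect_true(all(res$pairs$p_adj > 0.99))
  # two clearly separated groups: agrees with a permutation oracle
  set.seed(42)
  g <- list(ctrl = rnorm(5, 0, 1), combo = rnorm(5, 10, 1))
  res <- endpointComparison(g)
  expect_lt(res$p, 1e-4)
  # the permutation oracle is floored by choose(10, 5) distinct splits
  expect_lt(permMeanDiffP(g$ctrl, g$combo, iters = 5000), 0.02)
  # order invariance
  res2 <- endpointComparison(rev(g))
  expect_equal(res$p, res2$p)
  expect_equal(sort(res$pairs$p_adj), sort(res2$pairs$p_adj))
})

test_that("Tukey in the two-group case agrees with the two-sample t-test", {
  set.seed(5)
  x <- rnorm(6, 0, 1); y <- rnorm(6, 1.2, 1)
  res <- endpointComparison(list(x = x, y = y))
  pT <- t.test(x, y, var.equal = TRUE)$p.value
  expect_equal(res$pairs$p_adj, pT, tolerance = 1e-6)
})
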