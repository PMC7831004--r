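#' @include AllClasses.R utils.R
NULL

# Snap a requested endpoint to the nearest recorded timepoint (imaging
# intervals are irregular, 4-8 h in live-cell runs).
.snapEndpoint <- function(times, endpointH) {
  u <- sort(unique(times))
  u[which.min(abs(u - endpointH))]
}

# replicate endpoint signals of one arm
.endpointSignals <- function(df, arm, tSnap) {
  sub <- df[df$arm == arm & df$time_h == tSnap, ]
  sub$signal[order(sub$replicate)]
}

#' Fractional inhibition of one treatment arm at an endpoint
#'
#' Computes `E = 1 - mean(signal_arm) / mean(signal_control)` over replicate
#' signals at the recorded timepoint nearest `endpointH`, with a delta-method
#' standard error over replicate means. Negative effects (signal above
#' control) are returned with a growth-promotion flag.
#'
#' @param curves A [TreatmentCurveSet-class].
#' @param arm Arm label to evaluate.
#' @param endpointH Requested endpoint hour (snapped to the nearest recorded
#'   timepoint).
#' @return List with `effect`, `se`, `endpoint_h` (the snapped time),
#'   `n` (replicates) and `growth_promotion` (logical).
#' @examples
#' cfg <- synthConfig(noiseCV = 0)
#' computeEffect(simulateGrowthCurves(cfg), "ABC")$effect
#' @export
computeEffect <- function(curves, arm, endpointH = 120) {
  stopifnot(is(curves, "TreatmentCurveSet"))
  df <- curves@curves
  if (!arm %in% df$arm) {
    stop("lookup error: arm '", arm, "' not present in curve set",
         call. = FALSE)
  }
  tSnap <- .snapEndpoint(df$time_h, endpointH)
  sArm <- .endpointSignals(df, arm, tSnap)
  sCtl <- .endpointSignals(df, curves@controlArm, tSnap)
  mCtl <- mean(sCtl)
  if (mCtl == 0) {
    stop("undefined-effect error: control mean signal is zero at ",
         tSnap, " h", call. = FALSE)
  }
  mArm <- mean(sArm)
  e <- 1 - mArm / mCtl
  # delta method on the ratio of replicate means
  vArm <- if (length(sArm) > 1) stats::var(sArm) / length(sArm) else 0
  vCtl <- if (length(sCtl) > 1) stats::var(sCtl) / length(sCtl) else 0
  se <- sqrt(vArm / mCtl^2 + (mArm^2 / mCtl^4) * vCtl)
  list(effect = e, se = se, endpoint_h = tSnap,
       n = length(sArm), growth_promotion = e < 0)
}

#' Endpoint effects of the single agents and the combination
#'
#' Applies [computeEffect()] to the three single-agent arms and the
#' combination arm of a five-arm curve set.
#'
#' @param curves A [TreatmentCurveSet-class].
#' @param endpointH Requested endpoint hour.
#' @param singleArms Labels of the three single-agent arms.
#' @param comboArm Label of the combination arm.
#' @return An [EffectSet-class].
#' @export
computeEffectSet <- function(curves, endpointH = 120,
                             singleArms = c("A", "B", "C"),
                             comboArm = "ABC") {
  arms <- c(singleArms, comboArm)
  res <- lapply(arms, computeEffect, curves = curves, endpointH = endpointH)
  effects <- vapply(res, `[[`, numeric(1), "effect")
  se <- vapply(res, `[[`, numeric(1), "se")
  names(effects) <- names(se) <- arms
  new("EffectSet", effects = effects, se = se,
      endpointH = res[[1]]$endpoint_h,
      nReplicates = as.integer(res[[1]]$n),
      growthPromotion = effects < 0,
      comboArm = comboArm)
}

.ciInterpret <- function(ci, tolerance) {
  if (abs(ci - 1) <= tolerance) "additivity"
  else if (ci < 1) "synergy"
  else "antagonism"
}

.comboEffect <- function(effects) {
  stopifnot(is(effects, "EffectSet"))
  eAll <- effects@effects
  eABC <- eAll[[effects@comboArm]]
  if (eABC == 0) {
    stop("division-by-zero error: combination effect E_ABC is 0; ",
         "the combination index is undefined", call. = FALSE)
  }
  list(single = eAll[setdiff(names(eAll), effects@comboArm)], combo = eABC)
}

#' Linear-interaction (response additivity) combination index
#'
#' `CI = (E_A + E_B + E_C) / E_ABC`: the ratio of the additively expected
#' combination effect to the observed one. CI < 1 indicates synergy, CI = 1
#' (within `tolerance`) additivity, CI > 1 antagonism.
#'
#' @param effects An [EffectSet-class].
#' @param tolerance Half-width of the additivity band around CI = 1.
#' @return A [CombinationIndex-class].
#' @examples
#' es <- new("EffectSet", effects = c(A = .1, B = .1, C = .1, ABC = .6),
#'           se = rep(0, 4), endpointH = 120, nReplicates = 3L,
#'           growthPromotion = rep(FALSE, 4), comboArm = "ABC")
#' ciValue(linearCI(es))  # 0.5
#' @export
linearCI <- function(effects, tolerance = 0.05) {
  p <- .comboEffect(effects)
  ci <- sum(p$single) / p$combo
  new("CombinationIndex", model = "linear", ci = ci,
      interpretation = .ciInterpret(ci, tolerance), tolerance = tolerance)
}

#' Bliss-independence combination index (three agents)
#'
#' Two variants are computed exactly as their formulas. The `"paper"`
#' variant, `CI = ((E_A + E_B + E_C) - E_A*E_B*E_C) / E_ABC`, subtracts only
#' the triple product; the `"canonical"` Bliss expansion for three
#' independent agents is
#' `CI = (1 - (1 - E_A)(1 - E_B)(1 - E_C)) / E_ABC`, which also carries the
#' pairwise products. Both are offered side by side because the two agree
#' only when effects are small; the `"paper"` variant is the default report.
#'
#' @inheritParams linearCI
#' @param variant `"paper"` or `"canonical"`.
#' @return A [CombinationIndex-class] with model `"bliss_paper"` or
#'   `"bliss_canonical"`.
#' @export
blissCI <- function(effects, variant = c("paper", "canonical"),
                    tolerance = 0.05) {
  variant <- match.arg(variant)
  p <- .comboEffect(effects)
  e <- p$single
  expected <- if (variant == "paper") {
    sum(e) - prod(e)
  } else {
    1 - prod(1 - e)
  }
  ci <- expected / p$combo
  new("CombinationIndex", model = paste0("bliss_", variant), ci = ci,
      interpretation = .ciInterpret(ci, tolerance), tolerance = tolerance)
}

#' Bootstrap confidence interval for a combination index
#'
#' Nonparametric bootstrap over replicate endpoint signals: replicates of
#' every arm are resampled with replacement, effects and the requested CI
#' recomputed per resample.
#'
#' @param curves A [TreatmentCurveSet-class].
#' @param model `"linear"`, `"bliss_paper"` or `"bliss_canonical"`.
#' @param endpointH Endpoint hour.
#' @param nBoot Number of bootstrap resamples.
#' @param seed RNG seed.
#' @param level Confidence level.
#' @return List with `ci` (point estimate), `lower`, `upper`, `boot`
#'   (the resampled CI values).
#' @export
bootstrapCI <- function(curves, model = c("linear", "bliss_paper",
                                          "bliss_canonical"),
                        endpointH = 120, nBoot = 1000, seed = 1,
                        level = 0.95) {
  model <- match.arg(model)
  stopifnot(is(curves, "TreatmentCurveSet"))
  df <- curves@curves
  tSnap <- .snapEndpoint(df$time_h, endpointH)
  arms <- c("A", "B", "C", "ABC")
  sig <- lapply(c(curves@controlArm, arms), .endpointSignals, df = df,
                tSnap = tSnap)
  names(sig) <- c("control", arms)
  ciOf <- function(s) {
    e <- vapply(arms, function(a) 1 - mean(s[[a]]) / mean(s$control),
                numeric(1))
    switch(model,
           linear = sum(e[1:3]) / e[["ABC"]],
           bliss_paper = (sum(e[1:3]) - prod(e[1:3])) / e[["ABC"]],
           bliss_canonical = (1 - prod(1 - e[1:3])) / e[["ABC"]])
  }
  point <- ciOf(sig)
  boot <- withSeed(childSeed(seed, "synergy"), {
    vapply(seq_len(nBoot), function(i) {
      ciOf(lapply(sig, function(s) s[sample.int(length(s), replace = TRUE)]))
    }, numeric(1))
  })
  alpha <- (1 - level) / 2
  qs <- stats::quantile(boot, c(alpha, 1 - alpha), names = FALSE, na.rm = TRUE)
  list(ci = point, lower = qs[1], upper = qs[2], boot = boot)
}

#' One-way ANOVA with Tukey HSD over endpoint replicate values
#'
#' Omnibus F test across treatment groups plus Tukey honest-significant-
#' difference adjusted p-values for all pairs. Results are independent of
#' group ordering. When all groups are identical constants the omnibus and
#' pairwise p-values are reported as 1.
#'
#' @param groups Named list of numeric replicate endpoint values (>= 2
#'   groups with >= 2 values each).
#' @return List with `f` (ANOVA F), `p` (omnibus p), and `pairs`
#'   (data.frame `pair`, `diff`, `p_adj`).
#' @export
endpointComparison <- function(groups) {
  if (length(groups) < 2 || any(lengths(groups) < 2)) {
    stop("input error: need >= 2 groups with >= 2 replicates each",
         call. = FALSE)
  }
  groups <- groups[order(names(groups))]
  df <- data.frame(
    value = unlist(groups, use.names = FALSE),
    group = factor(rep(names(groups), lengths(groups))))
  if (stats::var(df$value) == 0) {
    pairs <- t(utils::combn(names(groups), 2))
    return(list(f = 0, p = 1,
                pairs = data.frame(pair = paste(pairs[, 2], pairs[, 1],
                                                sep = "-"),
                                   diff = 0, p_adj = 1)))
  }
  fit <- stats::aov(value ~ group, data = df)
  an <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit)$group
  list(f = an[["F value"]][1], p = an[["Pr(>F)"]][1],
       pairs = data.frame(pair = rownames(tk), diff = tk[, "diff"],
                          p_adj = tk[, "p adj"], row.names = NULL))
}
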