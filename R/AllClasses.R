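#' @import methods
NULL

# ---------------------------------------------------------------------------
# SynthConfig
# ---------------------------------------------------------------------------

#' Synthetic study configuration
#'
#' Holds every parameter of the synthetic-data generators: the growth-curve
#' simulator, the three correlated differential-expression studies with a
#' miRNA target map, the miRNA-family target sets, the seed-site sequence
#' generator and the survival cohort. One master `seed` expands to fixed
#' per-stream child seeds so the generators are independently reproducible.
#'
#' @slot seed master RNG seed (integer).
#' @slot nTimepoints number of imaging timepoints over the 0--120 h course.
#' @slot nReplicates replicate wells per treatment arm.
#' @slot noiseCV coefficient of variation of the multiplicative log-normal
#'   measurement noise on signals (fraction).
#' @slot plantedCI planted combination index under the linear interaction
#'   model (dimensionless, > 0; < 1 plants synergy).
#' @slot singleEffects fractional endpoint inhibition of the three single
#'   agents, each in \[0, 1).
#' @slot nGenes number of genes per differential-expression study.
#' @slot fracTargeted per-miRNA probability that a gene is a target.
#' @slot deltaPerMirna log2FC shift per additional targeting miRNA (log2
#'   units; negative plants silencing).
#' @slot deltaPerSite log2FC shift per binding site beyond the first of each
#'   targeting miRNA (log2 units).
#' @slot baselineSD per-study standard deviation of untargeted log2FC.
#' @slot studyCor fraction of baseline log2FC variance shared between studies.
#' @slot nPatients survival-cohort size.
#' @slot hazardBeta log-hazard per unit average z-score.
#' @slot censorRate expected fraction of censored patients, in \[0, 1).
#' @slot exprCor pairwise correlation of the three miRNA expression columns.
#' @slot nFamilies number of miRNA families.
#' @slot familyGroupSizes partition of the families into planted clusters.
#' @slot targetsPerFamily targets per family.
#' @slot withinOverlap fraction of targets shared within a planted group.
#' @slot betweenOverlap fraction of targets shared across groups
#'   (must be < `withinOverlap`).
#' @slot nSequences number of synthetic transcript sequences.
#' @slot seqLength transcript length in nucleotides.
#' @slot fracTriple fraction of sequences planted with at least one site for
#'   each of the three miRNAs.
#'
#' @seealso [synthConfig()] for the user-facing constructor with the default
#'   study conditions.
#' @exportClass SynthConfig
setClass("SynthConfig", representation(
  seed = "integer",
  nTimepoints = "integer",
  nReplicates = "integer",
  noiseCV = "numeric",
  plantedCI = "numeric",
  singleEffects = "numeric",
  nGenes = "integer",
  fracTargeted = "numeric",
  deltaPerMirna = "numeric",
  deltaPerSite = "numeric",
  baselineSD = "numeric",
  studyCor = "numeric",
  nPatients = "integer",
  hazardBeta = "numeric",
  censorRate = "numeric",
  exprCor = "numeric",
  nFamilies = "integer",
  familyGroupSizes = "integer",
  targetsPerFamily = "integer",
  withinOverlap = "numeric",
  betweenOverlap = "numeric",
  nSequences = "integer",
  seqLength = "integer",
  fracTriple = "numeric"
))

setValidity("SynthConfig", function(object) {
  msgs <- character()
  chk <- function(cond, msg) if (!isTRUE(cond)) msgs <<- c(msgs, msg)
  chk(object@plantedCI > 0, "plantedCI must be > 0")
  chk(length(object@singleEffects) == 3L, "singleEffects must have length 3")
  chk(all(object@singleEffects >= 0 & object@singleEffects < 1),
      "each singleEffects value must lie in [0, 1)")
  chk(sum(object@singleEffects) / object@plantedCI < 1,
      "sum(singleEffects)/plantedCI must be < 1 (combination effect must be a valid fraction)")
  chk(object@noiseCV >= 0, "noiseCV must be >= 0")
  chk(object@nTimepoints >= 2L, "nTimepoints must be >= 2")
  chk(object@nReplicates >= 1L, "nReplicates must be >= 1")
  chk(object@nGenes >= 1L, "nGenes must be >= 1")
  chk(object@fracTargeted > 0 && object@fracTargeted < 1,
      "fracTargeted must lie in (0, 1)")
  chk(object@baselineSD > 0, "baselineSD must be > 0")
  chk(object@studyCor >= 0 && object@studyCor <= 1,
      "studyCor must lie in [0, 1]")
  chk(is.finite(object@hazardBeta), "hazardBeta must be finite")
  chk(object@censorRate >= 0 && object@censorRate < 1,
      "censorRate must lie in [0, 1)")
  chk(abs(object@exprCor) < 1, "exprCor must lie in (-1, 1)")
  chk(object@nPatients >= 2L, "nPatients must be >= 2")
  chk(sum(object@familyGroupSizes) == object@nFamilies,
      "familyGroupSizes must sum to nFamilies")
  chk(all(object@familyGroupSizes >= 1L), "familyGroupSizes must be positive")
  chk(object@withinOverlap > object@betweenOverlap,
      "withinOverlap must be > betweenOverlap (planted structure unrecoverable otherwise)")
  chk(object@withinOverlap <= 1 && object@withinOverlap >= 0,
      "withinOverlap must lie in [0, 1]")
  chk(object@betweenOverlap >= 0, "betweenOverlap must be >= 0")
  chk(object@targetsPerFamily >= 1L, "targetsPerFamily must be >= 1")
  chk(object@nSequences >= 1L, "nSequences must be >= 1")
  chk(object@seqLength >= 30L,
      "seqLength too short to host requested sites (must be >= 30)")
  chk(object@fracTriple >= 0 && object@fracTriple <= 1,
      "fracTriple must lie in [0, 1]")
  if (length(msgs)) msgs else TRUE
})

# ---------------------------------------------------------------------------
# TreatmentCurveSet
# ---------------------------------------------------------------------------

#' Replicate growth/viability time-courses per treatment arm
#'
#' Wraps a long-format table with columns `arm`, `replicate`, `time_h`,
#' `signal`. Validity enforces strictly increasing times within each
#' (arm, replicate) trace, non-negative signals and presence of a control arm.
#'
#' @slot curves data.frame with columns `arm`, `replicate`, `time_h`, `signal`.
#' @slot controlArm label of the control arm.
#' @exportClass TreatmentCurveSet
setClass("TreatmentCurveSet", representation(
  curves = "data.frame",
  controlArm = "character"
))

setValidity("TreatmentCurveSet", function(object) {
  df <- object@curves
  msgs <- character()
  miss <- setdiff(c("arm", "replicate", "time_h", "signal"), names(df))
  if (length(miss)) {
    return(paste("curves table is missing column(s):",
                 paste(miss, collapse = ", ")))
  }
  if (any(df$signal < 0)) msgs <- c(msgs, "signal must be >= 0")
  if (!object@controlArm %in% df$arm) {
    msgs <- c(msgs, sprintf("control arm '%s' absent from curve set",
                            object@controlArm))
  }
  ok <- vapply(split(df$time_h, interaction(df$arm, df$replicate, drop = TRUE)),
               function(t) all(diff(t) > 0), logical(1))
  if (!all(ok)) {
    msgs <- c(msgs, "time points must be strictly increasing per replicate")
  }
  if (length(msgs)) msgs else TRUE
})

# ---------------------------------------------------------------------------
# EffectSet / CombinationIndex
# ---------------------------------------------------------------------------

#' Single-agent and combination endpoint effects
#'
#' Fractional inhibition of the endpoint signal relative to control for each
#' single agent (A, B, C) and the combination (ABC), with delta-method
#' standard errors over replicate endpoint means. Negative effects (growth
#' promotion) are retained but flagged.
#'
#' @slot effects named numeric: fractional inhibition per arm, combination last.
#' @slot se named numeric: standard error of each effect.
#' @slot endpointH endpoint time in hours (after snapping to the nearest
#'   recorded timepoint).
#' @slot nReplicates replicates per arm used at the endpoint.
#' @slot growthPromotion named logical: TRUE where the effect is negative.
#' @slot comboArm label of the combination arm.
#' @exportClass EffectSet
setClass("EffectSet", representation(
  effects = "numeric",
  se = "numeric",
  endpointH = "numeric",
  nReplicates = "integer",
  growthPromotion = "logical",
  comboArm = "character"
))

setValidity("EffectSet", function(object) {
  if (!all(is.finite(object@effects))) return("effects must be finite")
  if (!object@comboArm %in% names(object@effects)) {
    return("comboArm must name one of the effects")
  }
  TRUE
})

#' Combination index under a reference non-interaction model
#'
#' @slot model one of `"linear"`, `"bliss_paper"`, `"bliss_canonical"`.
#' @slot ci the combination index (dimensionless).
#' @slot interpretation `"synergy"` (CI < 1), `"additivity"` (CI = 1 within
#'   `tolerance`) or `"antagonism"` (CI > 1).
#' @slot tolerance half-width of the additivity band around 1.
#' @exportClass CombinationIndex
setClass("CombinationIndex", representation(
  model = "character",
  ci = "numeric",
  interpretation = "character",
  tolerance = "numeric"
))

setValidity("CombinationIndex", function(object) {
  if (!is.finite(object@ci)) return("ci must be finite")
  expected <- if (abs(object@ci - 1) <= object@tolerance) "additivity"
              else if (object@ci < 1) "synergy" else "antagonism"
  if (!identical(object@interpretation, expected)) {
    return("interpretation inconsistent with the <1 / =1 / >1 rule")
  }
  TRUE
})

# ---------------------------------------------------------------------------
# OverlapSets / EnrichmentResult
# ---------------------------------------------------------------------------

#' Multi-study differential-expression overlap sets
#'
#' Consensus of genes moving in one direction in at least `minStudies`
#' studies, after removing direction conflicts and (optionally) restricting
#' to protein-coding genes. lncRNAs passing the same consensus rule are kept
#' in a side channel for sequence-level site scanning.
#'
#' @slot direction `"down"` or `"up"`.
#' @slot perStudy named list of per-study gene sets (conflicts removed).
#' @slot consensus consensus gene set.
#' @slot removedConflicts genes with opposite directions across studies.
#' @slot lncConsensus lncRNA genes passing the consensus rule.
#' @slot regionCounts named integer vector of Venn region sizes; region names
#'   are study-membership keys such as `"110"`.
#' @slot minStudies minimum number of agreeing studies.
#' @slot codingOnly whether the consensus was restricted to protein-coding.
#' @exportClass OverlapSets
setClass("OverlapSets", representation(
  direction = "character",
  perStudy = "list",
  consensus = "character",
  removedConflicts = "character",
  lncConsensus = "character",
  regionCounts = "integer",
  minStudies = "integer",
  codingOnly = "logical"
))

setValidity("OverlapSets", function(object) {
  msgs <- character()
  un <- unique(unlist(object@perStudy, use.names = FALSE))
  if (!all(object@consensus %in% un)) {
    msgs <- c(msgs, "consensus must be a subset of the per-study union")
  }
  if (any(object@removedConflicts %in% un)) {
    msgs <- c(msgs, "conflicted genes must appear in no output set")
  }
  if (sum(object@regionCounts) != length(un)) {
    msgs <- c(msgs, "Venn region counts must sum to |union|")
  }
  if (length(msgs)) msgs else TRUE
})

#' Target-enrichment result against hypergeometric and permutation nulls
#'
#' @slot observedFraction fraction of the observed set targeted by at least
#'   `minMirnas` distinct miRNAs.
#' @slot observedCount corresponding gene count.
#' @slot setSize size of the observed set.
#' @slot nullMean,nullSD moments of the permutation null of the fraction.
#' @slot empiricalP permutation p with the +1 pseudo-count (never exactly 0).
#' @slot normalApproxP one-sided p from the normal approximation to the null.
#' @slot z standardized observed fraction, (observed - nullMean)/nullSD.
#' @slot hypergeomPOver,hypergeomPUnder exact hypergeometric tail ps.
#' @slot fold observed fraction / expected fraction.
#' @slot minMirnas the "targeted by at least" threshold.
#' @slot iters number of permutation iterations.
#' @slot seed RNG seed used for the draws.
#' @exportClass EnrichmentResult
setClass("EnrichmentResult", representation(
  observedFraction = "numeric",
  observedCount = "integer",
  setSize = "integer",
  nullMean = "numeric",
  nullSD = "numeric",
  empiricalP = "numeric",
  normalApproxP = "numeric",
  z = "numeric",
  hypergeomPOver = "numeric",
  hypergeomPUnder = "numeric",
  fold = "numeric",
  minMirnas = "integer",
  iters = "integer",
  seed = "integer"
))

setValidity("EnrichmentResult", function(object) {
  msgs <- character()
  if (!(object@empiricalP > 0 && object@empiricalP <= 1)) {
    msgs <- c(msgs, "empiricalP must lie in (0, 1]")
  }
  if (object@fold < 0) msgs <- c(msgs, "fold must be >= 0")
  if (is.finite(object@nullSD) && object@nullSD > 0 && is.finite(object@z)) {
    zz <- (object@observedFraction - object@nullMean) / object@nullSD
    if (abs(zz - object@z) > 1e-8) {
      msgs <- c(msgs, "z must equal (observed - nullMean)/nullSD")
    }
  }
  if (length(msgs)) msgs else TRUE
})

# ---------------------------------------------------------------------------
# SharedTargetMatrix
# ---------------------------------------------------------------------------

#' Pairwise shared-target counts and overlap percentages of miRNA families
#'
#' @slot families ordered family labels.
#' @slot counts symmetric integer matrix of shared-target counts; the
#'   diagonal holds the family target-set sizes.
#' @slot pct symmetric matrix of overlap percentages in \[0, 100\].
#' @slot normalize normalization of the percentage: `"min"` (share of the
#'   smaller set), `"jaccard"` or `"mean"`.
#' @exportClass SharedTargetMatrix
setClass("SharedTargetMatrix", representation(
  families = "character",
  counts = "matrix",
  pct = "matrix",
  normalize = "character"
))

setValidity("SharedTargetMatrix", function(object) {
  msgs <- character()
  if (!isSymmetric(unname(object@counts))) msgs <- c(msgs, "counts must be symmetric")
  if (!isSymmetric(unname(object@pct))) msgs <- c(msgs, "pct must be symmetric")
  if (any(object@pct < 0 | object@pct > 100, na.rm = TRUE)) {
    msgs <- c(msgs, "pct must lie in [0, 100]")
  }
  if (length(msgs)) msgs else TRUE
})

# ---------------------------------------------------------------------------
# SurvivalCohort
# ---------------------------------------------------------------------------

#' Patient cohort with miRNA expression and survival follow-up
#'
#' @slot patientId unique patient identifiers.
#' @slot expr numeric matrix, patients x miRNAs.
#' @slot time survival time (study units, >= 0).
#' @slot event 1 = death, 0 = censored.
#' @exportClass SurvivalCohort
setClass("SurvivalCohort", representation(
  patientId = "character",
  expr = "matrix",
  time = "numeric",
  event = "integer"
))

setValidity("SurvivalCohort", function(object) {
  msgs <- character()
  n <- length(object@patientId)
  if (anyDuplicated(object@patientId)) msgs <- c(msgs, "duplicate patient ids")
  if (nrow(object@expr) != n || length(object@time) != n ||
      length(object@event) != n) {
    msgs <- c(msgs, "patientId, expr rows, time and event must align")
  }
  if (any(object@time < 0)) msgs <- c(msgs, "time must be >= 0")
  if (!all(object@event %in% c(0L, 1L))) msgs <- c(msgs, "event must be 0 or 1")
  if (length(msgs)) msgs else TRUE
})
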