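#' @include AllClasses.R
NULL

#' Accessors for miRCombo classes
#'
#' Small accessor generics so downstream code never reaches into slots:
#' `curveData()` returns the long-format curve table, `effectValues()` and
#' `effectSE()` the named effect estimates and standard errors, `ciValue()`
#' and `ciInterpretation()` the combination index and its call,
#' `consensusGenes()`, `removedConflicts()`, `lncRNAGenes()` and
#' `regionCounts()` the overlap components, `overlapCounts()` / `overlapPct()`
#' the shared-target matrices, and `cohortTable()` the survival cohort as a
#' data.frame.
#'
#' @param object An object of the documented class.
#' @return See the individual method descriptions.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("curveData", function(object) standardGeneric("curveData"))

#' @rdname accessors
#' @export
setGeneric("effectValues", function(object) standardGeneric("effectValues"))

#' @rdname accessors
#' @export
setGeneric("effectSE", function(object) standardGeneric("effectSE"))

#' @rdname accessors
#' @export
setGeneric("ciValue", function(object) standardGeneric("ciValue"))

#' @rdname accessors
#' @export
setGeneric("ciInterpretation",
           function(object) standardGeneric("ciInterpretation"))

#' @rdname accessors
#' @export
setGeneric("consensusGenes", function(object) standardGeneric("consensusGenes"))

#' @rdname accessors
#' @export
setGeneric("removedConflicts",
           function(object) standardGeneric("removedConflicts"))

#' @rdname accessors
#' @export
setGeneric("lncRNAGenes", function(object) standardGeneric("lncRNAGenes"))

#' @rdname accessors
#' @export
setGeneric("regionCounts", function(object) standardGeneric("regionCounts"))

#' @rdname accessors
#' @export
setGeneric("overlapCounts", function(object) standardGeneric("overlapCounts"))

#' @rdname accessors
#' @export
setGeneric("overlapPct", function(object) standardGeneric("overlapPct"))

#' @rdname accessors
#' @export
setGeneric("cohortTable", function(object) standardGeneric("cohortTable"))

#' @rdname accessors
#' @export
setMethod("curveData", "TreatmentCurveSet", function(object) object@curves)

#' @rdname accessors
#' @export
setMethod("effectValues", "EffectSet", function(object) object@effects)

#' @rdname accessors
#' @export
setMethod("effectSE", "EffectSet", function(object) object@se)

#' @rdname accessors
#' @export
setMethod("ciValue", "CombinationIndex", function(object) object@ci)

#' @rdname accessors
#' @export
setMethod("ciInterpretation", "CombinationIndex",
          function(object) object@interpretation)

#' @rdname accessors
#' @export
setMethod("consensusGenes", "OverlapSets", function(object) object@consensus)

#' @rdname accessors
#' @export
setMethod("removedConflicts", "OverlapSets",
          function(object) object@removedConflicts)

#' @rdname accessors
#' @export
setMethod("lncRNAGenes", "OverlapSets", function(object) object@lncConsensus)

#' @rdname accessors
#' @export
setMethod("regionCounts", "OverlapSets", function(object) object@regionCounts)

#' @rdname accessors
#' @export
setMethod("overlapCounts", "SharedTargetMatrix", function(object) object@counts)

#' @rdname accessors
#' @export
setMethod("overlapPct", "SharedTargetMatrix", function(object) object@pct)

#' @rdname accessors
#' @export
setMethod("cohortTable", "SurvivalCohort", function(object) {
  data.frame(patient_id = object@patientId, object@expr,
             time = object@time, event = object@event,
             check.names = FALSE, stringsAsFactors = FALSE)
})

setMethod("show", "SynthConfig", function(object) {
  cat("SynthConfig (seed ", object@seed, ")\n", sep = "")
  cat("  growth: ", object@nTimepoints, " timepoints x ", object@nReplicates,
      " replicates, noise CV ", object@noiseCV, ", planted CI ",
      object@plantedCI, "\n", sep = "")
  cat("  DE: ", object@nGenes, " genes, frac targeted ", object@fracTargeted,
      ", delta/miRNA ", object@deltaPerMirna, ", delta/site ",
      object@deltaPerSite, "\n", sep = "")
  cat("  families: ", object@nFamilies, " in groups (",
      paste(object@familyGroupSizes, collapse = ","), "), within/between ",
      object@withinOverlap, "/", object@betweenOverlap, "\n", sep = "")
  cat("  sequences: ", object@nSequences, " x ", object@seqLength,
      " nt, triple fraction ", object@fracTriple, "\n", sep = "")
  cat("  survival: ", object@nPatients, " patients, hazard beta ",
      signif(object@hazardBeta, 3), ", censor rate ", object@censorRate,
      "\n", sep = "")
})

setMethod("show", "TreatmentCurveSet", function(object) {
  df <- object@curves
  cat("TreatmentCurveSet: ", length(unique(df$arm)), " arms (control: ",
      object@controlArm, "), ", length(unique(df$replicate)),
      " replicates, ", length(unique(df$time_h)), " timepoints\n", sep = "")
})

setMethod("show", "EffectSet", function(object) {
  cat("EffectSet at ", object@endpointH, " h (", object@nReplicates,
      " replicates)\n", sep = "")
  for (a in names(object@effects)) {
    cat(sprintf("  E_%s = %.4f (se %.4f)%s\n", a, object@effects[[a]],
                object@se[[a]],
                if (object@growthPromotion[[a]]) "  [growth promotion]" else ""))
  }
})

setMethod("show", "CombinationIndex", function(object) {
  cat(sprintf("CombinationIndex [%s]: CI = %.4f (%s)\n", object@model,
              object@ci, object@interpretation))
})

setMethod("show", "OverlapSets", function(object) {
  cat("OverlapSets (", object@direction, ", >= ", object@minStudies,
      " studies", if (object@codingOnly) ", protein-coding" else "", ")\n",
      sep = "")
  cat("  consensus: ", length(object@consensus), " genes; conflicts removed: ",
      length(object@removedConflicts), "; lncRNA side channel: ",
      length(object@lncConsensus), "\n", sep = "")
})

setMethod("show", "EnrichmentResult", function(object) {
  cat(sprintf(
    "EnrichmentResult (>= %d miRNAs): observed %.3f (n=%d), null %.3f +/- %.3f\n",
    object@minMirnas, object@observedFraction, object@setSize,
    object@nullMean, object@nullSD))
  cat(sprintf(
    "  empirical p = %.3g (iters %d), z = %.2f, normal-approx p = %.3g\n",
    object@empiricalP, object@iters, object@z, object@normalApproxP))
  cat(sprintf("  hypergeometric p(over) = %.3g, fold = %.3f\n",
              object@hypergeomPOver, object@fold))
})

setMethod("show", "SharedTargetMatrix", function(object) {
  cat("SharedTargetMatrix: ", length(object@families),
      " families, percentage normalized by '", object@normalize, "'\n",
      sep = "")
})

setMethod("show", "SurvivalCohort", function(object) {
  cat("SurvivalCohort: ", length(object@patientId), " patients, ",
      ncol(object@expr), " markers, ", sum(object@event), " events (",
      round(100 * (1 - mean(object@event))), "% censored)\n", sep = "")
})
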