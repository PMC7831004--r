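#' @include AllClasses.R synth.R synergy.R overlap.R dose.R cluster.R sites.R survival.R io.R
NULL

#' Read a pipeline run configuration
#'
#' A YAML file with an optional `synth:` block (arguments of
#' [synthConfig()]) and optional per-stage parameter blocks
#' (`synergy: endpoint_h, tolerance`; `overlap: direction, min_studies,
#' coding_only, min_mirnas, iters`; `dose: sd_max`; `cluster: min_targets,
#' k`; `sites: include_6mer`; `survival: split_quantile`). Unset values
#' fall back to the package defaults. All stage parameters are validated
#' before any stage runs.
#'
#' @param path YAML file path, or `NULL` for the default configuration.
#' @param seed Overrides the master seed when not `NULL`.
#' @return List with `synth` (a [SynthConfig-class]) and `stages` (a named
#'   list of validated per-stage parameters).
#' @export
readRunConfig <- function(path = NULL, seed = NULL) {
  raw <- if (is.null(path)) list() else yaml::read_yaml(path)
  synthArgs <- raw$synth
  if (!is.null(seed)) synthArgs$seed <- as.integer(seed)
  cfg <- do.call(synthConfig, as.list(synthArgs))
  defaults <- list(
    synergy = list(endpoint_h = 120, tolerance = 0.05),
    overlap = list(direction = "down", min_studies = 2L, coding_only = TRUE,
                   min_mirnas = 2L, iters = 2000L),
    dose = list(sd_max = 0.5),
    cluster = list(min_targets = 1L, k = NULL),
    sites = list(include_6mer = FALSE),
    survival = list(split_quantile = 0.5))
  stages <- defaults
  for (st in names(defaults)) {
    for (key in names(raw[[st]])) {
      if (!key %in% names(defaults[[st]])) {
        configError("unknown parameter '", key, "' in stage '", st, "'")
      }
      stages[[st]][[key]] <- raw[[st]][[key]]
    }
  }
  if (!stages$overlap$direction %in% c("down", "up")) {
    configError("overlap direction must be 'down' or 'up'")
  }
  if (stages$overlap$iters < 100) configError("overlap iters must be >= 100")
  if (stages$survival$split_quantile <= 0 ||
      stages$survival$split_quantile >= 1) {
    configError("survival split_quantile must lie in (0, 1)")
  }
  if (is.null(stages$cluster$k)) {
    stages$cluster$k <- length(cfg@familyGroupSizes)
  }
  list(synth = cfg, stages = stages)
}

#' Run the full synthetic-study pipeline
#'
#' Executes the seven stages in dependency order --
#' simulate, synergy, overlap, dose, cluster, sites, survival -- from a
#' single configuration and master seed, writing per-stage TSV outputs, a
#' plain-text log with per-stage timing, and a JSON summary that records
#' every parameter, headline statistic and output-file MD5 hash. Rerunning
#' with an identical configuration reproduces identical file hashes.
#'
#' @param config Path to a YAML run configuration, a [SynthConfig-class],
#'   or `NULL` for the default study conditions.
#' @param outDir Output directory (created if needed).
#' @param seed Overrides the master seed when not `NULL`.
#' @return Invisibly, the summary list (also written to `summary.json`).
#' @export
runPipeline <- function(config = NULL, outDir, seed = NULL) {
  rc <- if (is(config, "SynthConfig")) {
    cfg <- if (is.null(seed)) config else {
      v <- config; v@seed <- as.integer(seed); validObject(v); v
    }
    list(synth = cfg, stages = readRunConfig(NULL)$stages)
  } else {
    readRunConfig(config, seed = seed)
  }
  cfg <- rc$synth
  stages <- rc$stages
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  logPath <- file.path(outDir, "run.log")
  cat("", file = logPath)
  logLine <- function(...) {
    cat(paste0(...), "\n", sep = "", file = logPath, append = TRUE)
  }
  summary <- list(seed = cfg@seed, stages = list())
  files <- character()
  runStage <- function(name, fn) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(fn(), error = function(e) {
      logLine("FAIL ", name, ": ", conditionMessage(e),
              " (seed ", cfg@seed, ")")
      stop("stage '", name, "' failed (seed ", cfg@seed, "): ",
           conditionMessage(e), call. = FALSE)
    })
    dt <- proc.time()[["elapsed"]] - t0
    logLine(sprintf("OK   %-9s %6.2f s", name, dt))
    summary$stages[[name]] <<- c(res, list(seconds = round(dt, 3)))
    res
  }
  path <- function(...) {
    p <- file.path(outDir, ...)
    files <<- c(files, p)
    p
  }

  # --- simulate -----------------------------------------------------------
  sim <- new.env()
  runStage("simulate", function() {
    sim$curves <- simulateGrowthCurves(cfg,
                                       endpointH = stages$synergy$endpoint_h)
    writeCurves(sim$curves, path("curves.tsv"))
    sim$de <- simulateDEStudies(cfg)
    for (nm in names(sim$de$studies)) {
      writeTsv(sim$de$studies[[nm]], path(paste0("de_", nm, ".tsv")))
    }
    writeTsv(sim$de$targetMap, path("target_map.tsv"))
    writeTsv(sim$de$truth, path("de_truth.tsv"))
    sim$fam <- simulateFamilyTargets(cfg)
    writeFamilyTargets(sim$fam$families, path("families.gmt"))
    writeTsv(data.frame(family = names(sim$fam$groups),
                        group = sim$fam$groups), path("family_truth.tsv"))
    sim$seq <- simulateTargetSequences(cfg)
    Biostrings::writeXStringSet(sim$seq$sequences, path("sequences.fasta"))
    writeTsv(sim$seq$sites, path("planted_sites.tsv"))
    sim$cohort <- simulateSurvivalCohort(cfg)
    writeSurvivalCohort(sim$cohort, path("survival.tsv"))
    list(n_genes = cfg@nGenes, n_sequences = cfg@nSequences,
         n_patients = cfg@nPatients)
  })

  # --- synergy ------------------------------------------------------------
  runStage("synergy", function() {
    es <- computeEffectSet(sim$curves, endpointH = stages$synergy$endpoint_h)
    tol <- stages$synergy$tolerance
    cis <- list(linearCI(es, tol), blissCI(es, "paper", tol),
                blissCI(es, "canonical", tol))
    eff <- data.frame(arm = names(effectValues(es)),
                      effect = unname(effectValues(es)),
                      se = unname(effectSE(es)))
    writeTsv(eff, path("effects.tsv"))
    ciTab <- data.frame(
      model = vapply(cis, function(x) x@model, character(1)),
      ci = vapply(cis, ciValue, numeric(1)),
      interpretation = vapply(cis, ciInterpretation, character(1)))
    writeTsv(ciTab, path("combination_index.tsv"))
    list(endpoint_h = es@endpointH,
         linear_ci = ciTab$ci[1], bliss_paper_ci = ciTab$ci[2],
         bliss_canonical_ci = ciTab$ci[3],
         interpretation = ciTab$interpretation[1])
  })

  # --- overlap ------------------------------------------------------------
  ovEnv <- new.env()
  runStage("overlap", function() {
    op <- stages$overlap
    ov <- buildOverlap(sim$de$studies, direction = op$direction,
                       minStudies = op$min_studies,
                       codingOnly = op$coding_only)
    ovEnv$ov <- ov
    writeTsv(data.frame(gene_id = consensusGenes(ov)),
             path("consensus_genes.tsv"))
    writeTsv(data.frame(region = names(regionCounts(ov)),
                        n = unname(regionCounts(ov))),
             path("venn_counts.tsv"))
    universe <- unique(c(
      unlist(lapply(sim$de$studies, function(t) {
        t <- classifyDE(t)
        t$gene_id[t$label != "ns"]
      }), use.names = FALSE),
      removedConflicts(ov)))
    enr <- permutationEnrichment(consensusGenes(ov), universe,
                                 sim$de$targetMap,
                                 minMirnas = op$min_mirnas,
                                 iters = op$iters, seed = cfg@seed)
    jsonlite::write_json(
      list(observed_fraction = enr@observedFraction,
           null_mean = enr@nullMean, null_sd = enr@nullSD,
           empirical_p = enr@empiricalP, z = enr@z,
           normal_approx_p = enr@normalApproxP,
           hypergeom_p_over = enr@hypergeomPOver, fold = enr@fold),
      path("enrichment.json"), auto_unbox = TRUE, digits = NA)
    list(consensus_n = length(consensusGenes(ov)),
         conflicts_removed = length(removedConflicts(ov)),
         observed_fraction = enr@observedFraction,
         empirical_p = enr@empiricalP, z = enr@z, fold = enr@fold)
  })

  # --- dose ---------------------------------------------------------------
  runStage("dose", function() {
    byT <- lfcByTargeting(sim$de$studies, sim$de$targetMap)
    rec <- burdenClassification(consensusGenes(ovEnv$ov), sim$de$studies,
                                sim$de$targetMap,
                                sdMax = stages$dose$sd_max)
    writeTsv(rec, path("silencing_records.tsv"))
    sct <- siteCategoryTest(rec)
    jsonlite::write_json(
      list(wilcox_p_by_study = lapply(byT, `[[`, "wilcox_p"),
           monotone = lapply(byT, `[[`, "monotone"),
           chisq_p = sct$chisq_p, chisq_stat = sct$chisq_stat,
           high_low_wilcox_p = sct$wilcox_p),
      path("dose_tests.json"), auto_unbox = TRUE, digits = NA)
    list(monotone_all = all(unlist(lapply(byT, `[[`, "monotone"))),
         chisq_p = sct$chisq_p, high_low_wilcox_p = sct$wilcox_p)
  })

  # --- cluster ------------------------------------------------------------
  runStage("cluster", function() {
    cl <- stages$cluster
    filt <- filterFamilies(sim$fam$families, minTargets = cl$min_targets)
    stm <- sharedTargetMatrix(filt$families)
    writeTsv(as.data.frame(overlapCounts(stm)), path("shared_counts.tsv"))
    writeTsv(as.data.frame(overlapPct(stm)), path("shared_pct.tsv"))
    tree <- clusterFamilies(filt$families, k = cl$k, seed = cfg@seed)
    writeTsv(cbind(data.frame(family = names(tree$groups),
                              group = unname(tree$groups))),
             path("cluster_groups.tsv"))
    writeTsv(tree$merges, path("cluster_merges.tsv"))
    if (requireNamespace("ape", quietly = TRUE)) {
      ape::write.tree(ape::as.phylo(tree$hclust), path("dendrogram.nwk"))
    }
    list(n_families = length(filt$families), k = cl$k)
  })

  # --- sites --------------------------------------------------------------
  runStage("sites", function() {
    tt <- tripleTargeted(sim$seq$sequences,
                         include6mer = stages$sites$include_6mer)
    writeTsv(tt$sites, path("seed_sites.tsv"))
    writeTsv(data.frame(sequence_id = tt$ids), path("triple_targeted.tsv"))
    truthIds <- sort(sim$seq$tripleIds)
    list(n_sites = nrow(tt$sites), n_triple = length(tt$ids),
         matches_planted = identical(sort(tt$ids), truthIds))
  })

  # --- survival -----------------------------------------------------------
  runStage("survival", function() {
    scores <- zscoreAverage(sim$cohort)
    writeTsv(data.frame(patient_id = names(scores),
                        avg_z = unname(scores)), path("scores.tsv"))
    km <- kmLogrank(sim$cohort, scores,
                    splitQuantile = stages$survival$split_quantile)
    writeTsv(km$curves, path("km_curves.tsv"))
    pm <- pearsonMatrix(sim$cohort)
    jsonlite::write_json(
      list(logrank_chisq = km$chisq, logrank_p = km$p,
           threshold = km$threshold,
           pearson_r = as.data.frame(pm$r)),
      path("survival_tests.json"), auto_unbox = TRUE, digits = NA)
    list(logrank_p = km$p, logrank_chisq = km$chisq,
         mean_pairwise_r = mean(pm$r[upper.tri(pm$r)]))
  })

  summary$files <- lapply(stats::setNames(files, basename(files)),
                          function(f) unname(tools::md5sum(f)))
  jsonlite::write_json(summary, file.path(outDir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)
  logLine("DONE ", length(summary$stages), " stages")
  invisible(summary)
}
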