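#' @include AllClasses.R utils.R
NULL

#' Create a synthetic study configuration
#'
#' Builds a validated [SynthConfig-class] holding the conditions of the
#' simulated study: a five-arm live-cell growth experiment (control, three
#' single miRNA mimics, triple combination) with a planted combination index;
#' three correlated transfection DE studies whose log2 fold-changes shift
#' with the number of targeting miRNAs and binding sites; miRNA families
#' with planted shared-target structure; transcript sequences with planted
#' canonical seed sites; and a survival cohort whose hazard depends on the
#' planted average expression z-score.
#'
#' Defaults mirror the scale of a triple-mimic glioma stem cell experiment:
#' three low-dose single agents each inhibiting 10% of endpoint confluence,
#' a planted linear-model combination index of 0.35 (strong synergy), 5%
#' multiplicative measurement noise, three replicate wells, and a 120 h
#' course imaged every 6 h.
#'
#' @param seed Master integer RNG seed; expands to per-stream child seeds.
#' @param nTimepoints,nReplicates Growth-curve sampling design.
#' @param noiseCV CV of the multiplicative log-normal signal noise.
#' @param plantedCI Planted linear-model combination index (> 0).
#' @param singleEffects Three single-agent endpoint effects, each in \[0, 1).
#' @param nGenes,fracTargeted,deltaPerMirna,deltaPerSite,baselineSD,studyCor
#'   DE-study generator parameters (see slot docs in [SynthConfig-class]).
#' @param nPatients,hazardBeta,censorRate,exprCor Survival-cohort parameters.
#' @param nFamilies,familyGroupSizes,targetsPerFamily,withinOverlap,betweenOverlap
#'   miRNA-family generator parameters.
#' @param nSequences,seqLength,fracTriple Sequence generator parameters.
#' @return A validated [SynthConfig-class] object.
#' @examples
#' cfg <- synthConfig(seed = 1, noiseCV = 0)
#' curves <- simulateGrowthCurves(cfg)
#' @export
synthConfig <- function(seed = 1L,
                        nTimepoints = 21L, nReplicates = 3L,
                        noiseCV = 0.05, plantedCI = 0.35,
                        singleEffects = c(0.1, 0.1, 0.1),
                        nGenes = 5000L, fracTargeted = 0.25,
                        deltaPerMirna = -0.3, deltaPerSite = -0.4,
                        baselineSD = 0.5, studyCor = 0.6,
                        nPatients = 300L, hazardBeta = log(2),
                        censorRate = 0.2, exprCor = 0.6,
                        nFamilies = 6L, familyGroupSizes = c(3L, 3L),
                        targetsPerFamily = 200L,
                        withinOverlap = 0.8, betweenOverlap = 0.1,
                        nSequences = 60L, seqLength = 400L,
                        fracTriple = 0.5) {
  obj <- new("SynthConfig",
    seed = as.integer(seed),
    nTimepoints = as.integer(nTimepoints),
    nReplicates = as.integer(nReplicates),
    noiseCV = as.numeric(noiseCV),
    plantedCI = as.numeric(plantedCI),
    singleEffects = as.numeric(singleEffects),
    nGenes = as.integer(nGenes),
    fracTargeted = as.numeric(fracTargeted),
    deltaPerMirna = as.numeric(deltaPerMirna),
    deltaPerSite = as.numeric(deltaPerSite),
    baselineSD = as.numeric(baselineSD),
    studyCor = as.numeric(studyCor),
    nPatients = as.integer(nPatients),
    hazardBeta = as.numeric(hazardBeta),
    censorRate = as.numeric(censorRate),
    exprCor = as.numeric(exprCor),
    nFamilies = as.integer(nFamilies),
    familyGroupSizes = as.integer(familyGroupSizes),
    targetsPerFamily = as.integer(targetsPerFamily),
    withinOverlap = as.numeric(withinOverlap),
    betweenOverlap = as.numeric(betweenOverlap),
    nSequences = as.integer(nSequences),
    seqLength = as.integer(seqLength),
    fracTriple = as.numeric(fracTriple))
  v <- validObject(obj, test = TRUE)
  if (!isTRUE(v)) configError(paste(v, collapse = "; "))
  obj
}

# multiplicative log-normal factors with mean exactly 1 and the given CV
.noiseFactors <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Simulate five-arm growth curves with a planted combination index
#'
#' Generates logistic confluence trajectories over 0--120 h for a control
#' arm, three single-agent arms (A, B, C) and the triple-combination arm
#' (ABC). The planted fractional effect of arm X ramps linearly with time so
#' that the endpoint signal equals `control * (1 - E_X)` in expectation; the
#' combination endpoint effect is `sum(singleEffects) / plantedCI`, i.e. the
#' linear-interaction-model CI recovered from noiseless curves equals
#' `plantedCI` exactly. Each observation carries independent multiplicative
#' log-normal noise with mean 1 and CV `noiseCV`.
#'
#' @param cfg A [SynthConfig-class].
#' @param endpointH Endpoint hour (last timepoint of the course).
#' @return A [TreatmentCurveSet-class] with arms
#'   `control`, `A`, `B`, `C`, `ABC`.
#' @export
simulateGrowthCurves <- function(cfg, endpointH = 120) {
  stopifnot(is(cfg, "SynthConfig"))
  eSingle <- cfg@singleEffects
  eCombo <- sum(eSingle) / cfg@plantedCI
  effects <- c(control = 0, A = eSingle[1], B = eSingle[2], C = eSingle[3],
               ABC = eCombo)
  times <- seq(0, endpointH, length.out = cfg@nTimepoints)
  # logistic reference trajectory: ~5% confluence at t0, plateau 100
  k <- 100; r <- 0.07; tmid <- 60
  base <- k / (1 + exp(-r * (times - tmid)))
  withSeed(childSeed(cfg@seed, "growth"), {
    rows <- lapply(names(effects), function(arm) {
      ramp <- times / endpointH            # effect fully expressed at endpoint
      mu <- base * (1 - effects[[arm]] * ramp)
      do.call(rbind, lapply(seq_len(cfg@nReplicates), function(rep) {
        data.frame(arm = arm, replicate = rep, time_h = times,
                   signal = mu * .noiseFactors(length(mu), cfg@noiseCV),
                   stringsAsFactors = FALSE)
      }))
    })
    df <- do.call(rbind, rows)
    rownames(df) <- NULL
    new("TreatmentCurveSet", curves = df, controlArm = "control")
  })
}

#' Names and sequences of the three combination miRNAs
#'
#' Mature 5'-to-3' sequences (miRBase) of miR-124-3p, miR-128-3p and
#' miR-137-3p, the tumor-suppressor miRNAs whose combination the package's
#' default analyses model.
#'
#' @return Named character vector of three RNA sequences.
#' @export
comboMirnaSequences <- function() {
  c("miR-124" = "UAAGGCACGCGGUGAAUGCC",
    "miR-128" = "UCACAGUGAACCGGUCUCUUU",
    "miR-137" = "UUAUUGCUUAAGAAUACGCGUAG")
}

#' Simulate three correlated DE studies with a planted targeting effect
#'
#' Each gene is independently a target of each of the three miRNAs with
#' probability `fracTargeted`, with 1--3 binding sites per targeting miRNA.
#' Per-study log2 fold-changes are
#' `deltaPerMirna * nMirnas + deltaPerSite * (totalSites - nMirnas)` plus a
#' gene-level shared component and per-study noise
#' (`baselineSD`, `studyCor`). Adjusted p-values are a monotone transform of
#' |log2FC| with multiplicative jitter -- downstream stages only threshold
#' them. Biotypes include `protein_coding`, `lncRNA` and `other`.
#'
#' @param cfg A [SynthConfig-class].
#' @return List with elements `studies` (named list of three data.frames with
#'   columns `study`, `gene_id`, `biotype`, `log2fc`, `padj`), `targetMap`
#'   (data.frame `gene_id`, `mirna`, `site_count`) and `truth` (per-gene
#'   planted assignments: `gene_id`, `biotype`, `n_mirnas`, `total_sites`,
#'   `shift`).
#' @export
simulateDEStudies <- function(cfg) {
  stopifnot(is(cfg, "SynthConfig"))
  if (!(cfg@fracTargeted > 0 && cfg@fracTargeted < 1)) {
    configError("fracTargeted must lie in (0, 1)")
  }
  n <- cfg@nGenes
  mirnas <- names(comboMirnaSequences())
  withSeed(childSeed(cfg@seed, "de"), {
    genes <- sprintf("G%05d", seq_len(n))
    biotype <- sample(c("protein_coding", "lncRNA", "other"), n,
                      replace = TRUE, prob = c(0.90, 0.08, 0.02))
    targeted <- matrix(stats::rbinom(n * 3L, 1L, cfg@fracTargeted) == 1L,
                       nrow = n, dimnames = list(genes, mirnas))
    sites <- matrix(0L, nrow = n, ncol = 3L, dimnames = list(genes, mirnas))
    sites[targeted] <- sample(1:3, sum(targeted), replace = TRUE)
    nMir <- rowSums(targeted)
    totalSites <- rowSums(sites)
    shift <- cfg@deltaPerMirna * nMir +
      cfg@deltaPerSite * (totalSites - nMir)
    sdShared <- cfg@baselineSD * sqrt(cfg@studyCor)
    sdStudy <- cfg@baselineSD * sqrt(1 - cfg@studyCor)
    shared <- stats::rnorm(n, 0, sdShared)
    studies <- lapply(sprintf("study%d", 1:3), function(st) {
      lfc <- shift + shared + stats::rnorm(n, 0, sdStudy)
      padj <- pmin(1, 2 * stats::pnorm(-abs(lfc) / 0.2) *
                     exp(stats::rnorm(n, 0, 0.25)))
      padj <- pmax(padj, 1e-300)
      data.frame(study = st, gene_id = genes, biotype = biotype,
                 log2fc = lfc, padj = padj, stringsAsFactors = FALSE)
    })
    names(studies) <- sprintf("study%d", 1:3)
    idx <- which(targeted, arr.ind = TRUE)
    targetMap <- data.frame(
      gene_id = genes[idx[, 1]],
      mirna = mirnas[idx[, 2]],
      site_count = sites[targeted],
      stringsAsFactors = FALSE)
    targetMap <- targetMap[order(targetMap$gene_id, targetMap$mirna), ]
    rownames(targetMap) <- NULL
    truth <- data.frame(gene_id = genes, biotype = biotype,
                        n_mirnas = as.integer(nMir),
                        total_sites = as.integer(totalSites),
                        shift = shift, stringsAsFactors = FALSE)
    list(studies = studies, targetMap = targetMap, truth = truth)
  })
}

#' Simulate miRNA families with planted shared-target structure
#'
#' Families inside the same planted group share a group core of
#' `(withinOverlap - betweenOverlap) * targetsPerFamily` genes; all families
#' additionally share a global core of `betweenOverlap * targetsPerFamily`
#' genes; the remainder is private. Pairwise overlap fractions are therefore
#' `withinOverlap` within groups and `betweenOverlap` across groups by
#' construction.
#'
#' @param cfg A [SynthConfig-class].
#' @return List with `families` (named list of target-gene character vectors)
#'   and `groups` (named integer vector: planted group of each family).
#' @export
simulateFamilyTargets <- function(cfg) {
  stopifnot(is(cfg, "SynthConfig"))
  if (sum(cfg@familyGroupSizes) != cfg@nFamilies) {
    configError("familyGroupSizes must sum to nFamilies")
  }
  if (cfg@withinOverlap <= cfg@betweenOverlap) {
    configError("withinOverlap must be > betweenOverlap",
                " (planted structure unrecoverable)")
  }
  tpf <- cfg@targetsPerFamily
  nGlobal <- round(cfg@betweenOverlap * tpf)
  nGroup <- round(cfg@withinOverlap * tpf) - nGlobal
  nPrivate <- tpf - nGlobal - nGroup
  withSeed(childSeed(cfg@seed, "families"), {
    counter <- 0L
    draw <- function(k) {
      if (k <= 0L) return(character())
      ids <- sprintf("T%06d", counter + seq_len(k))
      counter <<- counter + k
      ids
    }
    globalCore <- draw(nGlobal)
    families <- list()
    groups <- integer()
    fi <- 0L
    for (g in seq_along(cfg@familyGroupSizes)) {
      groupCore <- draw(nGroup)
      for (j in seq_len(cfg@familyGroupSizes[g])) {
        fi <- fi + 1L
        fam <- sprintf("fam%02d", fi)
        families[[fam]] <- c(globalCore, groupCore, draw(nPrivate))
        groups[[fam]] <- g
      }
    }
    list(families = families, groups = groups)
  })
}

# reverse-complement of a DNA string (character in, character out)
.rcDNA <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# seed-derived target-site patterns of one miRNA (DNA alphabet)
.seedPatterns <- function(mirnaSeq) {
  s <- toupper(chartr("U", "T", mirnaSeq))
  if (nchar(s) < 8) {
    configError("miRNA sequence must be at least 8 nt, got ", nchar(s))
  }
  bad <- regmatches(s, gregexpr("[^ACGT]", s))[[1]]
  if (length(bad)) {
    stop("input error: non-nucleotide character '", bad[1],
         "' at position ", regexpr("[^ACGT]", s), call. = FALSE)
  }
  core6 <- .rcDNA(substr(s, 2, 7))          # match to miRNA positions 2-7
  m8 <- .rcDNA(substr(s, 8, 8))             # extra 5' target base for m8 match
  list(core6 = core6, m8 = m8,
       site7m8 = paste0(m8, core6),         # 7mer-m8
       site8 = paste0(m8, core6, "A"),      # 8mer
       site7A1 = paste0(core6, "A"))        # 7mer-A1
}

#' Simulate transcript sequences with planted canonical seed sites
#'
#' Background sequences are rejection-sampled so that, after planting, a
#' full canonical-seed scan recovers exactly the planted site table: no
#' accidental 8mer/7mer-m8/7mer-A1 site for any of the supplied miRNAs
#' survives in the background or at planting junctions. A fixed fraction
#' `fracTriple` of sequences carries at least one site for all three miRNAs;
#' the rest carry sites for 0--2 of them.
#'
#' @param cfg A [SynthConfig-class].
#' @param mirnas Named character vector of miRNA sequences (RNA or DNA,
#'   5'-to-3', >= 8 nt). Default: the three combination miRNAs.
#' @param plantSites If `FALSE`, emit pure site-free background sequences
#'   (negative control); the truth table is then empty.
#' @return List with `sequences` (a [Biostrings::DNAStringSet-class]),
#'   `sites` (planted-site table: `sequence_id`, `mirna`, `site_type`,
#'   `start`, `end`, 0-based half-open) and `tripleIds` (ids planted with
#'   sites for all three miRNAs).
#' @export
simulateTargetSequences <- function(cfg, mirnas = comboMirnaSequences(),
                                    plantSites = TRUE) {
  stopifnot(is(cfg, "SynthConfig"))
  pats <- lapply(mirnas, .seedPatterns)
  L <- cfg@seqLength
  minLen <- 30L
  if (L < minLen) configError("seqLength too short to host requested sites")
  nSeq <- cfg@nSequences
  withSeed(childSeed(cfg@seed, "sequences"), {
    ids <- sprintf("lnc%04d", seq_len(nSeq))
    nTriple <- if (plantSites) round(cfg@fracTriple * nSeq) else 0L
    tripleIdx <- if (nTriple > 0) sort(sample.int(nSeq, nTriple)) else integer()
    siteTypes <- c("8mer", "7mer-m8", "7mer-A1")
    allSeqs <- character(nSeq)
    allSites <- list()
    bgDraw <- function() {
      repeat {
        bg <- paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
                    collapse = "")
        hit <- any(vapply(pats, function(p) grepl(p$core6, bg, fixed = TRUE),
                          logical(1)))
        if (!hit) return(bg)
      }
    }
    for (i in seq_len(nSeq)) {
      whichMir <- if (!plantSites) character() else if (i %in% tripleIdx) {
        names(mirnas)
      } else {
        k <- sample(0:2, 1L, prob = c(0.4, 0.4, 0.2))
        if (k > 0) sample(names(mirnas), k) else character()
      }
      plan <- list()
      for (m in whichMir) {
        for (s in seq_len(sample(1:2, 1L))) {
          plan[[length(plan) + 1L]] <- list(
            mirna = m, type = sample(siteTypes, 1L))
        }
      }
      for (attempt in seq_len(200L)) {
        chars <- strsplit(bgDraw(), "")[[1]]
        used <- logical(L)
        sites <- list()
        ok <- TRUE
        for (p in plan) {
          pat <- pats[[p$mirna]]
          placed <- FALSE
          for (try in seq_len(50L)) {
            q <- sample(3:(L - 8L), 1L)  # 1-based start of the 6mer core
            span <- (q - 2L):(q + 7L)    # occupied incl. one-base margins
            if (any(used[span])) next
            core <- strsplit(pat$core6, "")[[1]]
            chars[q:(q + 5L)] <- core
            if (p$type %in% c("8mer", "7mer-m8")) {
              chars[q - 1L] <- pat$m8
            } else {
              # 7mer-A1: the base 5' of the core must NOT complete an m8 match
              chars[q - 1L] <- if (pat$m8 == "C") "G" else "C"
            }
            if (p$type %in% c("8mer", "7mer-A1")) {
              chars[q + 6L] <- "A"
            } else {
              chars[q + 6L] <- "C"       # 7mer-m8: no downstream A
            }
            used[span] <- TRUE
            start0 <- switch(p$type,
                             "8mer" = q - 2L, "7mer-m8" = q - 2L,
                             "7mer-A1" = q - 1L)
            width <- if (p$type == "8mer") 8L else 7L
            sites[[length(sites) + 1L]] <- data.frame(
              sequence_id = ids[i], mirna = p$mirna, site_type = p$type,
              start = start0, end = start0 + width,
              stringsAsFactors = FALSE)
            placed <- TRUE
            break
          }
          if (!placed) { ok <- FALSE; break }
        }
        if (!ok) next
        seqStr <- paste(chars, collapse = "")
        planted <- if (length(sites)) do.call(rbind, sites) else
          data.frame(sequence_id = character(), mirna = character(),
                     site_type = character(), start = integer(),
                     end = integer(), stringsAsFactors = FALSE)
        found <- .scanSeedsOne(seqStr, ids[i], mirnas, pats,
                               types = siteTypes, include6mer = FALSE)
        if (.sitesEqual(planted, found)) {
          allSeqs[i] <- seqStr
          allSites[[i]] <- planted
          break
        }
        if (attempt == 200L) {
          stop("failed to plant sites without collisions in sequence ",
               ids[i], call. = FALSE)
        }
      }
    }
    sites <- do.call(rbind, allSites[!vapply(allSites, is.null, logical(1))])
    if (is.null(sites)) {
      sites <- data.frame(sequence_id = character(), mirna = character(),
                          site_type = character(), start = integer(),
                          end = integer(), stringsAsFactors = FALSE)
    }
    rownames(sites) <- NULL
    seqs <- Biostrings::DNAStringSet(allSeqs)
    names(seqs) <- ids
    list(sequences = seqs, sites = sites, tripleIds = ids[tripleIdx])
  })
}

# order-insensitive equality of site tables on the identifying columns
.sitesEqual <- function(a, b) {
  key <- function(x) sort(paste(x$sequence_id, x$mirna, x$site_type,
                                x$start, x$end))
  identical(key(a), key(b))
}

#' Simulate a survival cohort with a planted average-z-score hazard
#'
#' Three equicorrelated miRNA expression columns (pairwise correlation
#' `exprCor`); each patient's event time is exponential with rate
#' `lambda0 * exp(hazardBeta * avgZ)` where `avgZ` is the cohort-standardized
#' average z-score of the three markers; censoring is independent
#' exponential calibrated so that about `censorRate` of patients are
#' censored.
#'
#' @param cfg A [SynthConfig-class].
#' @param lambda0 Baseline hazard (per study time unit).
#' @return A [SurvivalCohort-class].
#' @export
simulateSurvivalCohort <- function(cfg, lambda0 = 1 / 50) {
  stopifnot(is(cfg, "SynthConfig"))
  n <- cfg@nPatients
  withSeed(childSeed(cfg@seed, "survival"), {
    rho <- cfg@exprCor
    sigma <- matrix(rho, 3, 3); diag(sigma) <- 1
    z <- matrix(stats::rnorm(n * 3L), n, 3L) %*% chol(sigma)
    expr <- 8 + 2 * z
    colnames(expr) <- names(comboMirnaSequences())
    avgZ <- rowMeans(scale(expr))
    rate <- lambda0 * exp(cfg@hazardBeta * avgZ)
    tEvent <- stats::rexp(n, rate)
    tCens <- if (cfg@censorRate > 0) {
      stats::rexp(n, lambda0 * cfg@censorRate / (1 - cfg@censorRate))
    } else {
      rep(Inf, n)
    }
    new("SurvivalCohort",
        patientId = sprintf("P%04d", seq_len(n)),
        expr = expr,
        time = pmin(tEvent, tCens),
        event = as.integer(tEvent <= tCens))
  })
}
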