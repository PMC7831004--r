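#' @include AllClasses.R utils.R
NULL

#' Classify genes as up, down or not significant
#'
#' A gene is `up` iff `padj < padjThresh` and `log2fc >= lfcThresh`, `down`
#' iff `padj < padjThresh` and `log2fc <= -lfcThresh`, else `ns`. The fold-
#' change boundary is inclusive (`>=`), the adjusted-p boundary strict.
#'
#' @param table DE table with columns `gene_id`, `log2fc`, `padj` (and
#'   usually `biotype`).
#' @param lfcThresh Absolute log2 fold-change threshold (> 0).
#' @param padjThresh Adjusted-p threshold (> 0).
#' @return The input data.frame with an added `label` column
#'   (`up`/`down`/`ns`).
#' @examples
#' classifyDE(data.frame(gene_id = "g", log2fc = 0.5, padj = 0.049))$label
#' @export
classifyDE <- function(table, lfcThresh = 0.5, padjThresh = 0.05) {
  if (!(lfcThresh > 0 && padjThresh > 0)) {
    stop("input error: thresholds must be > 0", call. = FALSE)
  }
  checkColumns(table, c("gene_id", "log2fc", "padj"), "DE table")
  sig <- table$padj < padjThresh
  table$label <- ifelse(sig & table$log2fc >= lfcThresh, "up",
                        ifelse(sig & table$log2fc <= -lfcThresh, "down",
                               "ns"))
  table
}

#' Build the multi-study consensus overlap of one DE direction
#'
#' The consensus set holds genes classified in the stated direction in at
#' least `minStudies` studies, after removing genes with conflicting
#' behavior (the stated direction in one study and the opposite in
#' another) and, when `codingOnly`, restricting to protein-coding genes.
#' lncRNAs passing the same direction/consensus rule are kept in a side
#' channel regardless of `codingOnly`, for sequence-level site scanning.
#' Full Venn region counts over the (conflict-free) per-study sets are
#' reported.
#'
#' @param studies Named list of >= 2 DE tables (columns `gene_id`,
#'   `biotype`, `log2fc`, `padj`; one row per gene per study).
#' @param direction `"down"` or `"up"`.
#' @param minStudies Minimum number of agreeing studies for consensus.
#' @param codingOnly Restrict the consensus to protein-coding genes.
#' @param lfcThresh,padjThresh Passed to [classifyDE()].
#' @return An [OverlapSets-class].
#' @export
buildOverlap <- function(studies, direction = c("down", "up"),
                         minStudies = 2L, codingOnly = TRUE,
                         lfcThresh = 0.5, padjThresh = 0.05) {
  direction <- match.arg(direction)
  if (length(studies) < 2) {
    stop("input error: need at least 2 studies", call. = FALSE)
  }
  if (is.null(names(studies))) {
    names(studies) <- sprintf("study%d", seq_along(studies))
  }
  other <- if (direction == "down") "up" else "down"
  labelled <- lapply(names(studies), function(nm) {
    tab <- studies[[nm]]
    checkColumns(tab, c("gene_id", "biotype", "log2fc", "padj"),
                 paste0("study '", nm, "'"))
    if (anyDuplicated(tab$gene_id)) {
      stop("input error: duplicated gene_id within study '", nm, "'",
           call. = FALSE)
    }
    classifyDE(tab, lfcThresh, padjThresh)
  })
  names(labelled) <- names(studies)
  dirSets <- lapply(labelled, function(t) t$gene_id[t$label == direction])
  otherSets <- lapply(labelled, function(t) t$gene_id[t$label == other])
  conflicts <- sort(intersect(unique(unlist(dirSets)),
                              unique(unlist(otherSets))))
  dirSets <- lapply(dirSets, setdiff, y = conflicts)
  biotype <- do.call(rbind, lapply(labelled, function(t) {
    t[, c("gene_id", "biotype")]
  }))
  biotype <- biotype[!duplicated(biotype$gene_id), ]
  bioOf <- stats::setNames(biotype$biotype, biotype$gene_id)
  union <- unique(unlist(dirSets))
  nHits <- rowSums(vapply(dirSets, function(s) union %in% s,
                          logical(length(union))))
  hitKey <- apply(vapply(dirSets, function(s) union %in% s,
                         logical(length(union))), 1L,
                  function(z) paste(as.integer(z), collapse = ""))
  regionCounts <- table(factor(hitKey, levels = .vennKeys(length(dirSets))))
  consensusAll <- union[nHits >= minStudies]
  lnc <- sort(consensusAll[bioOf[consensusAll] == "lncRNA"])
  consensus <- consensusAll
  if (codingOnly) {
    consensus <- consensus[bioOf[consensus] == "protein_coding"]
  }
  new("OverlapSets",
      direction = direction,
      perStudy = dirSets,
      consensus = sort(consensus),
      removedConflicts = conflicts,
      lncConsensus = lnc,
      regionCounts = stats::setNames(as.integer(regionCounts),
                                     names(regionCounts)),
      minStudies = as.integer(minStudies),
      codingOnly = codingOnly)
}

# membership keys "100", "010", ..., "111" for k studies (non-empty regions)
.vennKeys <- function(k) {
  grid <- expand.grid(rep(list(c(0L, 1L)), k))[-1, , drop = FALSE]
  apply(grid, 1L, paste, collapse = "")
}

# distinct targeting miRNAs per gene from a long target map
.mirnaCounts <- function(targetMap) {
  checkColumns(targetMap, c("gene_id", "mirna"), "target map")
  tab <- table(unique(targetMap[, c("gene_id", "mirna")])$gene_id)
  stats::setNames(as.integer(tab), names(tab))
}

#' Fraction of a gene set targeted by at least k miRNAs
#'
#' @param geneSet Character vector of gene ids (non-empty).
#' @param targetMap Long-format map with columns `gene_id`, `mirna` (and
#'   optionally `site_count`).
#' @param minMirnas Minimum number of distinct targeting miRNAs.
#' @return List with `count` and `fraction`.
#' @export
targetFraction <- function(geneSet, targetMap, minMirnas = 1L) {
  if (length(geneSet) == 0) {
    stop("undefined-fraction error: empty gene set", call. = FALSE)
  }
  if (nrow(targetMap) == 0) {
    stop("input error: empty target map", call. = FALSE)
  }
  counts <- .mirnaCounts(targetMap)
  hit <- counts[geneSet]
  hit[is.na(hit)] <- 0L
  k <- sum(hit >= minMirnas)
  list(count = as.integer(k), fraction = k / length(geneSet))
}

#' Exact hypergeometric over/under-representation test
#'
#' For `X ~ Hypergeometric(N, K, n)` (a size-`n` draw from a universe of `N`
#' genes of which `K` are annotated), reports `p_over = P(X >= k)`,
#' `p_under = P(X <= k)` and the fold enrichment `(k/n)/(K/N)`.
#'
#' @param k Annotated genes observed in the set.
#' @param n Set size.
#' @param K Annotated genes in the universe.
#' @param N Universe size.
#' @return List with `p_over`, `p_under`, `fold`, `expected`.
#' @examples
#' hypergeomEnrichment(4, 4, 5, 10)$p_over  # 5/210
#' @export
hypergeomEnrichment <- function(k, n, K, N) {
  bad <- k < 0 || n < 0 || K < 0 || N < 1 || n > N || K > N ||
    k > min(n, K) || k < max(0, n - (N - K))
  if (bad) {
    stop("input error: impossible counts (k=", k, ", n=", n, ", K=", K,
         ", N=", N, ")", call. = FALSE)
  }
  pOver <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  pUnder <- stats::phyper(k, K, N - K, n)
  list(p_over = pOver, p_under = pUnder,
       fold = (k / n) / (K / N), expected = n * K / N)
}

#' Permutation test for miRNA-target enrichment in a gene set
#'
#' Draws `iters` random subsets of size `|observedSet|` without replacement
#' from `universe` and computes, for each, the fraction of genes targeted by
#' at least `minMirnas` distinct miRNAs. The empirical p-value uses the +1
#' pseudo-count, `(1 + #{null >= observed}) / (iters + 1)`, and is therefore
#' never exactly zero; the z-score and the one-sided normal-approximation p
#' from the null mean and SD are reported alongside (the only route to
#' p-values far below the permutation resolution). The exact hypergeometric
#' test on the same counts is included for reference.
#'
#' @param observedSet Character vector of gene ids, a subset of `universe`.
#' @param universe Character vector of gene ids to resample from (typically
#'   all genes classified up or down in any study).
#' @param targetMap Long-format map with columns `gene_id`, `mirna`.
#' @param minMirnas Minimum number of distinct targeting miRNAs.
#' @param iters Number of permutation iterations (>= 100).
#' @param seed RNG seed.
#' @param returnNull Keep the full null vector in the result attributes.
#' @return An [EnrichmentResult-class]; when `returnNull` the null vector is
#'   attached as attribute `"null"`.
#' @export
permutationEnrichment <- function(observedSet, universe, targetMap,
                                  minMirnas = 2L, iters = 10000L, seed = 1L,
                                  returnNull = FALSE) {
  if (iters < 100) stop("input error: iters must be >= 100", call. = FALSE)
  universe <- unique(universe)
  if (!all(observedSet %in% universe)) {
    stop("input error: observedSet must be a subset of the universe",
         call. = FALSE)
  }
  nSet <- length(observedSet)
  if (nSet == 0 || nSet > length(universe)) {
    stop("input error: observed set size must lie in [1, |universe|]",
         call. = FALSE)
  }
  counts <- .mirnaCounts(targetMap)
  targeted <- stats::setNames(counts[universe] >= minMirnas, universe)
  targeted[is.na(targeted)] <- FALSE
  obsCount <- sum(targeted[observedSet])
  obs <- obsCount / nSet
  nullFrac <- withSeed(childSeed(seed, "overlap"), {
    tv <- as.logical(targeted)
    nU <- length(tv)
    vapply(seq_len(iters), function(i) {
      sum(tv[sample.int(nU, nSet)]) / nSet
    }, numeric(1))
  })
  nullMean <- mean(nullFrac)
  nullSD <- stats::sd(nullFrac)
  empiricalP <- (1 + sum(nullFrac >= obs)) / (iters + 1)
  z <- if (nullSD > 0) (obs - nullMean) / nullSD else NA_real_
  normalP <- if (is.finite(z)) stats::pnorm(z, lower.tail = FALSE) else
    NA_real_
  hyp <- hypergeomEnrichment(obsCount, nSet, sum(targeted),
                             length(universe))
  res <- new("EnrichmentResult",
             observedFraction = obs,
             observedCount = as.integer(obsCount),
             setSize = as.integer(nSet),
             nullMean = nullMean, nullSD = nullSD,
             empiricalP = empiricalP, normalApproxP = normalP, z = z,
             hypergeomPOver = hyp$p_over, hypergeomPUnder = hyp$p_under,
             fold = if (nullMean > 0) obs / nullMean else
               if (obs == 0) 1 else Inf,
             minMirnas = as.integer(minMirnas),
             iters = as.integer(iters), seed = as.integer(seed))
  if (returnNull) attr(res, "null") <- nullFrac
  res
}
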