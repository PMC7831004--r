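#' @include AllClasses.R overlap.R
NULL

#' Silencing magnitude by number of targeting miRNAs
#'
#' For each study, restricts to downregulated and not-differentially-
#' expressed genes (upregulated genes are excluded), stratifies by the
#' number of distinct miRNAs targeting each gene (0--3) and reports the
#' median log2 fold-change per stratum, a two-sided Wilcoxon rank-sum test
#' of the 0-miRNA group against the >= 1-miRNA group, and a monotonicity
#' flag (medians strictly decreasing with targeting count). Empty strata are
#' skipped with a warning.
#'
#' @param studies Named list of DE tables (columns `gene_id`, `log2fc`,
#'   `padj`).
#' @param targetMap Long-format map with columns `gene_id`, `mirna`.
#' @param lfcThresh,padjThresh Passed to [classifyDE()].
#' @return Named list per study: `medians` (named by targeting count),
#'   `n` (stratum sizes), `wilcox_p` (0 vs >= 1), `monotone` (logical).
#' @export
lfcByTargeting <- function(studies, targetMap, lfcThresh = 0.5,
                           padjThresh = 0.05) {
  counts <- .mirnaCounts(targetMap)
  lapply(studies, function(tab) {
    tab <- classifyDE(tab, lfcThresh, padjThresh)
    tab <- tab[tab$label %in% c("down", "ns"), ]
    nm <- counts[tab$gene_id]
    nm[is.na(nm)] <- 0L
    strata <- split(tab$log2fc, factor(nm, levels = 0:3))
    empty <- lengths(strata) == 0
    if (any(empty)) {
      warning("empty targeting-count stratum skipped: ",
              paste(names(strata)[empty], collapse = ", "))
    }
    med <- vapply(strata[!empty], stats::median, numeric(1))
    g0 <- strata[["0"]]
    g1 <- unlist(strata[c("1", "2", "3")], use.names = FALSE)
    wp <- if (length(g0) && length(g1)) {
      suppressWarnings(
        stats::wilcox.test(g0, g1, alternative = "two.sided",
                           exact = (length(g0) <= 6 &&
                                      length(g1) <= 6))$p.value)
    } else {
      NA_real_
    }
    list(medians = med, n = lengths(strata)[!empty], wilcox_p = wp,
         monotone = all(diff(med) < 0))
  })
}

#' Classify consensus genes into high/low silencing by site burden
#'
#' Each gene downregulated in at least two studies is assigned its mean and
#' (n-1) standard deviation of log2 fold-change across the studies where it
#' was measured, and the total number of binding sites summed
#' indiscriminately over the three miRNAs. Genes with SD above `sdMax` are
#' excluded; on the remaining genes, quartiles of the mean log2FC (linear
#' interpolation of the order statistics at positions `(n+1)p`, quantile
#' type 6) define the classes: `high` silencing means
#' mean log2FC <= Q1 (most negative), `low` means >= Q3, the rest `mid`.
#' Boundary ties are included in the extreme class.
#'
#' @param consensusGenes Genes downregulated in >= 2 studies (e.g.
#'   `consensusGenes(buildOverlap(...))`).
#' @param studies Named list of DE tables with `gene_id` and `log2fc`.
#' @param targetMap Long map with `gene_id`, `mirna`, `site_count`.
#' @param sdMax Exclusion threshold on the between-study SD of log2FC.
#' @return data.frame with one row per gene: `gene_id`, `mean_log2fc`,
#'   `sd_log2fc`, `n_studies`, `n_mirnas`, `total_sites`,
#'   `silencing_class` (`high`/`mid`/`low`/`excluded`).
#' @export
burdenClassification <- function(consensusGenes, studies, targetMap,
                                 sdMax = 0.5) {
  checkColumns(targetMap, c("gene_id", "mirna", "site_count"), "target map")
  lfc <- do.call(rbind, lapply(studies, function(t) {
    checkColumns(t, c("gene_id", "log2fc"), "DE table")
    t[t$gene_id %in% consensusGenes, c("gene_id", "log2fc")]
  }))
  byGene <- split(lfc$log2fc, lfc$gene_id)
  byGene <- byGene[lengths(byGene) >= 2]
  if (!all(consensusGenes %in% names(byGene))) {
    stop("input error: consensus genes must be measured in >= 2 studies",
         call. = FALSE)
  }
  siteSum <- tapply(targetMap$site_count, targetMap$gene_id, sum)
  mirN <- .mirnaCounts(targetMap)
  genes <- sort(names(byGene))
  rec <- data.frame(
    gene_id = genes,
    mean_log2fc = vapply(byGene[genes], mean, numeric(1)),
    sd_log2fc = vapply(byGene[genes], stats::sd, numeric(1)),
    n_studies = as.integer(lengths(byGene[genes])),
    stringsAsFactors = FALSE)
  rec$n_mirnas <- as.integer(ifelse(is.na(mirN[genes]), 0L, mirN[genes]))
  rec$total_sites <- as.integer(ifelse(is.na(siteSum[genes]), 0L,
                                       siteSum[genes]))
  rownames(rec) <- NULL
  excluded <- rec$sd_log2fc > sdMax
  kept <- rec[!excluded, ]
  if (nrow(kept) < 4) {
    stop("insufficient-data error: fewer than 4 genes after SD filtering",
         call. = FALSE)
  }
  q <- stats::quantile(kept$mean_log2fc, c(0.25, 0.75), type = 6,
                       names = FALSE)
  cls <- rep("mid", nrow(rec))
  cls[rec$mean_log2fc <= q[1]] <- "high"
  cls[rec$mean_log2fc >= q[2]] <- "low"
  if (q[1] == q[2]) {
    warning("degenerate quartiles (Q1 == Q3): all genes classified at the ",
            "boundary; downstream class tests are uninformative")
    cls <- rep("mid", nrow(rec))
  }
  cls[excluded] <- "excluded"
  rec$silencing_class <- cls
  attr(rec, "quartiles") <- q
  rec
}

#' Association of silencing class with binding-site burden
#'
#' Builds the 2x2 table of silencing class (`high` vs `low`) against
#' single-site vs multiple-site genes and tests it by a chi-squared test
#' without continuity correction; additionally compares `total_sites`
#' between the high- and low-silencing classes by a two-sided Wilcoxon
#' rank-sum test. If any expected cell is below 1 the chi-squared result is
#' flagged unreliable.
#'
#' @param records Output of [burdenClassification()].
#' @param singleMax Largest total site count still counted as "single"
#'   (default 1).
#' @return List with `table` (2x2 counts), `chisq_stat`, `chisq_p`,
#'   `expected`, `unreliable` (any expected cell < 1), `wilcox_p`.
#' @export
siteCategoryTest <- function(records, singleMax = 1L) {
  hi <- records[records$silencing_class == "high", ]
  lo <- records[records$silencing_class == "low", ]
  if (nrow(hi) == 0 || nrow(lo) == 0) {
    stop("input error: high and low silencing classes must be non-empty",
         call. = FALSE)
  }
  cls <- factor(c(rep("high", nrow(hi)), rep("low", nrow(lo))),
                levels = c("high", "low"))
  sites <- c(hi$total_sites, lo$total_sites)
  cat2 <- factor(ifelse(sites <= singleMax, "single", "multiple"),
                 levels = c("single", "multiple"))
  tab <- table(cls, cat2)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0) ||
      stats::var(as.integer(cat2)) == 0) {
    chis <- list(statistic = 0, p.value = 1,
                 expected = outer(rowSums(tab), colSums(tab)) / sum(tab))
  } else {
    chis <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  }
  wp <- suppressWarnings(
    stats::wilcox.test(hi$total_sites, lo$total_sites,
                       alternative = "two.sided",
                       exact = (nrow(hi) <= 6 && nrow(lo) <= 6))$p.value)
  list(table = tab,
       chisq_stat = unname(chis$statistic),
       chisq_p = unname(chis$p.value),
       expected = chis$expected,
       unreliable = any(chis$expected < 1),
       wilcox_p = wp)
}
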