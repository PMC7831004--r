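#' @include AllClasses.R utils.R
NULL

.checkFamilies <- function(families) {
  if (!is.list(families) || is.null(names(families)) ||
      anyDuplicated(names(families))) {
    stop("input error: families must be a uniquely named list of ",
         "target-gene vectors", call. = FALSE)
  }
  lapply(families, unique)
}

#' Filter miRNA families by target-set size
#'
#' Retains families with at least `minTargets` predicted targets and emits
#' the list of genes shared by at least two retained families.
#'
#' @param families Named list of target-gene character vectors.
#' @param minTargets Minimum target-set size.
#' @return List with `families` (the retained subset) and `shared` (genes
#'   targeted by >= 2 retained families).
#' @export
filterFamilies <- function(families, minTargets = 1000L) {
  families <- .checkFamilies(families)
  keep <- families[lengths(families) >= minTargets]
  if (!length(keep)) {
    warning("no family passes the minTargets filter")
  }
  tab <- table(unlist(keep, use.names = FALSE))
  list(families = keep, shared = sort(names(tab)[tab >= 2]))
}

#' Pairwise shared-target counts and overlap percentages
#'
#' `counts[i, j]` is the number of genes targeted by both families (the
#' diagonal holds target-set sizes); `pct[i, j]` is the overlap percentage,
#' by default normalized by the smaller of the two sets
#' (`100 * |Ti ∩ Tj| / min(|Ti|, |Tj|)`); Jaccard and mean-size
#' normalizations are available.
#'
#' @param families Named list of target-gene character vectors (>= 1).
#' @param normalize `"min"`, `"jaccard"` or `"mean"`.
#' @return A [SharedTargetMatrix-class].
#' @export
sharedTargetMatrix <- function(families, normalize = c("min", "jaccard",
                                                       "mean")) {
  normalize <- match.arg(normalize)
  families <- .checkFamilies(families)
  if (length(families) < 1) stop("input error: need >= 1 family",
                                 call. = FALSE)
  labs <- names(families)
  k <- length(labs)
  counts <- matrix(0L, k, k, dimnames = list(labs, labs))
  pct <- matrix(0, k, k, dimnames = list(labs, labs))
  sizes <- lengths(families)
  for (i in seq_len(k)) {
    counts[i, i] <- sizes[i]
    pct[i, i] <- 100
    if (i < k) for (j in (i + 1):k) {
      ov <- length(intersect(families[[i]], families[[j]]))
      counts[i, j] <- counts[j, i] <- ov
      denom <- switch(normalize,
                      min = min(sizes[i], sizes[j]),
                      jaccard = sizes[i] + sizes[j] - ov,
                      mean = (sizes[i] + sizes[j]) / 2)
      p <- if (denom > 0) 100 * ov / denom else 0
      pct[i, j] <- pct[j, i] <- p
    }
  }
  new("SharedTargetMatrix", families = labs, counts = counts, pct = pct,
      normalize = normalize)
}

# binary membership matrix of families over genes shared by >= 2 families
.membershipMatrix <- function(families) {
  tab <- table(unlist(families, use.names = FALSE))
  shared <- names(tab)[tab >= 2]
  feats <- if (length(shared)) shared else sort(unique(names(tab)))
  m <- vapply(families, function(t) as.numeric(feats %in% t),
              numeric(length(feats)))
  t(m)
}

#' Hierarchically cluster miRNA families on shared targets
#'
#' Each family is embedded as a binary membership vector over the genes
#' shared by at least two families, and the families are clustered with
#' Ward's criterion on Euclidean distances (`stats::hclust`,
#' `method = "ward.D2"`). Families are sorted by label before clustering so
#' the tree is independent of input order. Optional bootstrap support
#' resamples the gene features with replacement and reports, per pair of
#' families, the fraction of resamples in which the pair lands in the same
#' flat group at `k` groups.
#'
#' @param families Named list of target-gene character vectors (>= 2).
#' @param k Number of flat groups to cut (default 2; `NULL` for none).
#' @param bootstrap Number of bootstrap resamples (0 = off).
#' @param seed RNG seed for the bootstrap.
#' @return List with `hclust` (the tree), `merges` (data.frame of merge
#'   heights), `groups` (named flat assignment at `k`, or `NULL`),
#'   `degenerate` (TRUE when all membership vectors are identical) and
#'   `support` (pairwise co-clustering matrix, or `NULL`).
#' @export
clusterFamilies <- function(families, k = 2L, bootstrap = 0L, seed = 1L) {
  families <- .checkFamilies(families)
  if (length(families) < 2) {
    stop("input error: need >= 2 families to cluster", call. = FALSE)
  }
  families <- families[order(names(families))]
  m <- .membershipMatrix(families)
  degenerate <- all(stats::dist(m) == 0)
  if (degenerate) {
    warning("all family membership vectors are identical: ",
            "zero-height merge chain")
  }
  hc <- stats::hclust(stats::dist(m, method = "euclidean"),
                      method = "ward.D2")
  groups <- if (!is.null(k)) {
    stats::cutree(hc, k = min(k, length(families)))
  }
  support <- NULL
  if (bootstrap > 0 && !is.null(k) && ncol(m) > 1) {
    labs <- rownames(m)
    co <- matrix(0, length(labs), length(labs),
                 dimnames = list(labs, labs))
    withSeed(childSeed(seed, "cluster"), {
      for (b in seq_len(bootstrap)) {
        mb <- m[, sample.int(ncol(m), replace = TRUE), drop = FALSE]
        hb <- stats::hclust(stats::dist(mb), method = "ward.D2")
        gb <- stats::cutree(hb, k = min(k, length(labs)))
        co <- co + outer(gb, gb, "==")
      }
    })
    support <- co / bootstrap
  }
  list(hclust = hc,
       merges = data.frame(step = seq_along(hc$height),
                           height = hc$height),
       groups = groups, degenerate = degenerate, support = support)
}
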