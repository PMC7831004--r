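#' @include utils.R synth.R
NULL

# Validate and normalize target sequences to uppercase DNA characters.
# Accepts a DNAStringSet or a (preferably named) character vector.
.normalizeTargets <- function(targets) {
  if (is(targets, "DNAStringSet") || is(targets, "RNAStringSet")) {
    x <- as.character(targets)
  } else if (is.character(targets)) {
    x <- targets
  } else {
    stop("input error: targets must be a DNAStringSet or character vector",
         call. = FALSE)
  }
  if (length(x) == 0) stop("input error: empty sequence set", call. = FALSE)
  if (is.null(names(x))) names(x) <- sprintf("seq%04d", seq_along(x))
  # FASTA headers: keep the id up to the first whitespace
  names(x) <- sub("\\s.*$", "", names(x))
  x <- toupper(chartr("u", "T", chartr("U", "T", x)))
  for (i in seq_along(x)) {
    m <- regexpr("[^ACGT]", x[[i]])
    if (m > 0) {
      stop("input error: non-nucleotide character '",
           substr(x[[i]], m, m), "' at position ", m, " of sequence '",
           names(x)[i], "'", call. = FALSE)
    }
  }
  x
}

.emptySiteTable <- function() {
  data.frame(sequence_id = character(), mirna = character(),
             site_type = character(), start = integer(), end = integer(),
             matched_subsequence = character(), stringsAsFactors = FALSE)
}

# Scan one target sequence (plain character) for canonical sites of the
# given miRNAs. `pats` is a named list of .seedPatterns() outputs.
.scanSeedsOne <- function(seqStr, id, mirnas, pats,
                          types = c("8mer", "7mer-m8", "7mer-A1"),
                          include6mer = FALSE) {
  L <- nchar(seqStr)
  subject <- Biostrings::DNAString(seqStr)
  out <- list()
  for (m in names(mirnas)) {
    p <- pats[[m]]
    starts <- Biostrings::start(Biostrings::matchPattern(p$core6, subject))
    if (!length(starts)) next
    prev <- ifelse(starts > 1, substring(seqStr, starts - 1, starts - 1), "")
    nxt <- ifelse(starts + 6 <= L, substring(seqStr, starts + 6, starts + 6), "")
    hasM8 <- prev == p$m8
    hasA <- nxt == "A"
    type <- ifelse(hasM8 & hasA, "8mer",
                   ifelse(hasM8, "7mer-m8",
                          ifelse(hasA, "7mer-A1", "6mer")))
    start0 <- ifelse(hasM8, starts - 2L, starts - 1L)
    width <- ifelse(type == "8mer", 8L, ifelse(type == "6mer", 6L, 7L))
    keep <- type %in% types | (include6mer & type == "6mer")
    if (!any(keep)) next
    ord <- order(start0[keep])
    s0 <- as.integer(start0[keep][ord])
    w <- as.integer(width[keep][ord])
    out[[m]] <- data.frame(
      sequence_id = id, mirna = m, site_type = type[keep][ord],
      start = s0, end = s0 + w,
      matched_subsequence = substring(seqStr, s0 + 1L, s0 + w),
      stringsAsFactors = FALSE)
  }
  if (!length(out)) return(.emptySiteTable())
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Scan target sequences for canonical miRNA seed sites
#'
#' Reports every occurrence of the reverse complement of miRNA seed
#' positions 2--8 in the sense strand of each target (7mer-m8); occurrences
#' followed by a downstream `A` on the target are 8mer sites; matches to
#' positions 2--7 followed by an `A` are 7mer-A1 sites. Sites are classified
#' exclusively by their most specific type, overlapping occurrences are all
#' reported, and coordinates are 0-based half-open on the provided sequence.
#' U and T are interchangeable on input. Only the provided (sense) sequence
#' is scanned; the reverse strand is never searched.
#'
#' @param mirnaSeq miRNA sequence, 5'-to-3', RNA or DNA alphabet, >= 8 nt.
#' @param targets Target sequences: a [Biostrings::DNAStringSet-class] or a
#'   named character vector.
#' @param mirna Label recorded in the `mirna` output column.
#' @param types Site types to report (subset of `8mer`, `7mer-m8`,
#'   `7mer-A1`).
#' @param include6mer Also report bare 6mer core matches (off by default:
#'   high false-positive rate).
#' @return data.frame with columns `sequence_id`, `mirna`, `site_type`,
#'   `start`, `end` (0-based half-open) and `matched_subsequence`, in
#'   deterministic left-to-right order within each sequence.
#' @examples
#' # miRNA whose positions 2-8 reverse-complement to "GACGTAC"
#' scanSeedSites("AGTACGTCAA", c(t1 = "TTGACGTACATT"))
#' @export
scanSeedSites <- function(mirnaSeq, targets,
                          mirna = "miRNA",
                          types = c("8mer", "7mer-m8", "7mer-A1"),
                          include6mer = FALSE) {
  types <- match.arg(types, c("8mer", "7mer-m8", "7mer-A1", "6mer"),
                     several.ok = TRUE)
  pats <- list(.seedPatterns(mirnaSeq))
  names(pats) <- mirna
  x <- .normalizeTargets(targets)
  mirs <- stats::setNames(mirnaSeq, mirna)
  res <- lapply(seq_along(x), function(i) {
    .scanSeedsOne(x[[i]], names(x)[i], mirs, pats,
                  types = types, include6mer = include6mer)
  })
  res <- do.call(rbind, res)
  rownames(res) <- NULL
  res
}

#' Identify transcripts carrying seed sites for all three miRNAs
#'
#' Scans every target sequence for canonical sites of each supplied miRNA
#' and returns the intersection: sequences with at least one site for each
#' miRNA, with per-(sequence, miRNA) site counts.
#'
#' @param targets Target sequences (e.g. lncRNAs):
#'   [Biostrings::DNAStringSet-class] or named character vector.
#' @param mirnas Named character vector of exactly three distinct miRNA
#'   sequences; defaults to the three combination miRNAs.
#' @param types,include6mer Passed to [scanSeedSites()].
#' @return List with `ids` (sequence ids targeted by all three miRNAs, in
#'   input order), `counts` (data.frame `sequence_id`, `mirna`, `n_sites`
#'   over all scanned sequences) and `sites` (the full site table).
#' @export
tripleTargeted <- function(targets, mirnas = comboMirnaSequences(),
                           types = c("8mer", "7mer-m8", "7mer-A1"),
                           include6mer = FALSE) {
  if (length(mirnas) != 3L) {
    stop("input error: exactly three miRNA sequences are required",
         call. = FALSE)
  }
  seeds <- vapply(mirnas, function(s) {
    substr(toupper(chartr("U", "T", s)), 2, 8)
  }, character(1))
  if (anyDuplicated(seeds)) {
    warning("degenerate input: two or more miRNAs share an identical seed; ",
            "results computed anyway")
  }
  x <- .normalizeTargets(targets)
  sites <- do.call(rbind, lapply(names(mirnas), function(m) {
    scanSeedSites(mirnas[[m]], x, mirna = m, types = types,
                  include6mer = include6mer)
  }))
  counts <- expand.grid(sequence_id = names(x), mirna = names(mirnas),
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  tab <- table(factor(sites$sequence_id, levels = names(x)),
               factor(sites$mirna, levels = names(mirnas)))
  counts$n_sites <- as.integer(tab[cbind(counts$sequence_id, counts$mirna)])
  hit <- rowSums(tab > 0) == length(mirnas)
  list(ids = names(x)[hit[names(x)]],
       counts = counts[order(counts$sequence_id, counts$mirna), ],
       sites = sites)
}
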