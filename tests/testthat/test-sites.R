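# miRNA "AGTACGTCAA": positions 2-8 = GTACGTC, whose reverse complement on
# the target is GACGTAC; the 6mer core (positions 2-7) maps to ACGTAC.
mir <- "AGTACGTCAA"

test_that("canonical site types are classified from the seed match context", {
  # planted 8mer: G|ACGTAC|A at 0-based offset 2
  hits <- scanSeedSites(mir, c(t1 = "TTGACGTACATT"))
  expect_identical(nrow(hits), 1L)
  expect_identical(hits$site_type, "8mer")
  expect_identical(hits$start, 2L)
  expect_identical(hits$end, 10L)
  expect_identical(hits$matched_subsequence, "GACGTACA")
  # same heptamer without the downstream A: 7mer-m8
  hits <- scanSeedSites(mir, c(t1 = "TTGACGTACGTT"))
  expect_identical(hits$site_type, "7mer-m8")
  expect_identical(hits$start, 2L)
  expect_identical(hits$end, 9L)
  # core + A without the m8 match: 7mer-A1
  hits <- scanSeedSites(mir, c(t1 = "TTCACGTACATT"))
  expect_identical(hits$site_type, "7mer-A1")
  expect_identical(hits$start, 3L)
  expect_identical(hits$end, 10L)
  # bare core is a 6mer, reported only on request
  expect_identical(nrow(scanSeedSites(mir, c(t1 = "TTCACGTACGTT"))), 0L)
  h6 <- scanSeedSites(mir, c(t1 = "TTCACGTACGTT"), include6mer = TRUE)
  expect_identical(h6$site_type, "6mer")
})

test_that("RNA and DNA alphabets are interchangeable", {
  h1 <- scanSeedSites("AGUACGUCAA", c(t1 = "UUGACGUACAUU"))
  h2 <- scanSeedSites(mir, c(t1 = "TTGACGTACATT"))
  expect_identical(h1$site_type, h2$site_type)
  expect_identical(h1$start, h2$start)
})

test_that("repeated sites, absent sites and bad inputs behave by contract", {
  # the same planted heptamer twice gives two sites with distinct starts
  hits <- scanSeedSites(mir, c(t1 = "AAGACGTACATTTTGACGTACATT"))
  expect_identical(nrow(hits), 2L)
  expect_identical(hits$start, c(2L, 14L))
  # a target without the complementary hexamer yields nothing
  expect_identical(nrow(scanSeedSites(mir, c(t1 = "AAAAAAAAAAAA"))), 0L)
  # the reverse strand is never scanned
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString("TTGACGTACATT")))
  expect_identical(nrow(scanSeedSites(mir, setNames(rc, "t1"))), 0L)
  expect_error(scanSeedSites("ACGUACG", c(t1 = "ACGT")), "at least 8")
  expect_error(scanSeedSites(mir, c(t1 = "ACGTNACGTACGT")),
               "non-nucleotide character 'N' at position 5")
  expect_error(scanSeedSites(mir, character()), "empty sequence set")
})

test_that("scanner recovers planted sites exactly (no FP, no FN)", {
  cfg <- synthConfig(seed = 52, nSequences = 25L)
  sq <- simulateTargetSequences(cfg)
  found <- do.call(rbind, lapply(names(comboMirnaSequences()), function(m) {
    scanSeedSites(comboMirnaSequences()[[m]], sq$sequences, mirna = m)
  }))
  key <- function(d) sort(paste(d$sequence_id, d$mirna, d$site_type,
                                d$start, d$end))
  expect_identical(key(found), key(sq$sites))
})

test_that("triple-targeted transcripts match the planted ground truth", {
  cfg <- synthConfig(seed = 53, nSequences = 24L, fracTriple = 0.5)
  sq <- simulateTargetSequences(cfg)
  tt <- tripleTargeted(sq$sequences)
  expect_setequal(tt$ids, sq$tripleIds)
  # per-(sequence, miRNA) counts agree with the planted table
  planted <- table(sq$sites$sequence_id, sq$sites$mirna)
  for (i in seq_len(nrow(tt$counts))) {
    row <- tt$counts[i, ]
    want <- if (row$sequence_id %in% rownames(planted) &&
                row$mirna %in% colnames(planted)) {
      planted[row$sequence_id, row$mirna]
    } else 0L
    expect_equal(row$n_sites, unname(want))
  }
  # a sequence with sites for only two miRNAs is excluded
  two <- setdiff(unique(sq$sites$sequence_id), sq$tripleIds)
  if (length(two)) expect_false(any(two %in% tt$ids))
  expect_error(tripleTargeted(sq$sequences, comboMirnaSequences()[1:2]),
               "exactly three")
  expect_warning(
    tripleTargeted(sq$sequences[1],
                   c(a = mir, b = mir, c = "CCGTACGTCAA")),
    "identical seed")
})

test_that("site intervals always slice the matched subsequence", {
  cfg <- synthConfig(seed = 54, nSequences = 12L)
  sq <- simulateTargetSequences(cfg)
  tt <- tripleTargeted(sq$sequences)
  seqs <- as.character(sq$sequences)
  widths <- c(`8mer` = 8L, `7mer-m8` = 7L, `7mer-A1` = 7L)
  for (i in seq_len(nrow(tt$sites))) {
    row <- tt$sites[i, ]
    expect_identical(row$end - row$start, widths[[row$site_type]])
    expect_identical(row$matched_subsequence,
                     substr(seqs[[row$sequence_id]], row$start + 1, row$end))
  }
})
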