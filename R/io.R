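#' @include AllClasses.R utils.R
NULL

#' Read and write miRCombo tables
#'
#' Plain-TSV readers and writers for the package's data containers:
#' growth curves (`arm`, `replicate`, `time_h`, `signal`), DE study tables
#' (`study`, `gene_id`, `biotype`, `log2fc`, `padj`), target maps
#' (`gene_id`, `mirna`, `site_count`), family target sets (GMT-like:
#' family, tab, one gene per remaining field) and survival cohorts
#' (`patient_id`, one column per marker, `time`, `event`).
#'
#' @param path File path.
#' @param x Object to write.
#' @return Readers return the corresponding container; writers return
#'   `path` invisibly.
#' @name mircombo-io
NULL

#' @rdname mircombo-io
#' @export
readCurves <- function(path) {
  df <- readTsv(path)
  checkColumns(df, c("arm", "replicate", "time_h", "signal"), "curves TSV")
  control <- if ("control" %in% df$arm) "control" else df$arm[1]
  new("TreatmentCurveSet", curves = df, controlArm = control)
}

#' @rdname mircombo-io
#' @export
writeCurves <- function(x, path) {
  stopifnot(is(x, "TreatmentCurveSet"))
  writeTsv(x@curves, path)
}

#' @rdname mircombo-io
#' @export
readDEStudy <- function(path) {
  df <- readTsv(path)
  checkColumns(df, c("gene_id", "biotype", "log2fc", "padj"), "DE TSV")
  df
}

#' @rdname mircombo-io
#' @export
readTargetMap <- function(path) {
  df <- readTsv(path)
  checkColumns(df, c("gene_id", "mirna", "site_count"), "target map TSV")
  df
}

#' @rdname mircombo-io
#' @export
readFamilyTargets <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (length(parts) && length(parts[[1]]) >= 3 &&
      identical(parts[[1]][1:2], c("family", "gene_id"))) {
    # long format: family, gene_id
    df <- readTsv(path)
    return(split(df$gene_id, df$family))
  }
  fams <- lapply(parts, function(p) unique(p[-1][nzchar(p[-1])]))
  names(fams) <- vapply(parts, `[[`, character(1), 1L)
  fams
}

#' @rdname mircombo-io
#' @export
writeFamilyTargets <- function(x, path) {
  lines <- vapply(names(x), function(f) {
    paste(c(f, x[[f]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname mircombo-io
#' @export
readSurvivalCohort <- function(path) {
  df <- readTsv(path)
  checkColumns(df, c("patient_id", "time", "event"), "survival TSV")
  markers <- setdiff(names(df), c("patient_id", "time", "event"))
  new("SurvivalCohort",
      patientId = as.character(df$patient_id),
      expr = as.matrix(df[, markers, drop = FALSE]),
      time = as.numeric(df$time),
      event = as.integer(df$event))
}

#' @rdname mircombo-io
#' @export
writeSurvivalCohort <- function(x, path) {
  stopifnot(is(x, "SurvivalCohort"))
  writeTsv(cohortTable(x), path)
}
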