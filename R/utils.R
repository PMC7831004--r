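#' Evaluate an expression with a temporary RNG seed
#'
#' Runs `code` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so seeded package functions never perturb the global stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
withSeed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Named generator streams: one master seed expands to fixed per-stream child
# seeds, so adding a generator never perturbs existing streams.
.streamOffsets <- c(
  growth = 11L, de = 12L, families = 13L, sequences = 14L, survival = 15L,
  synergy = 21L, overlap = 22L, dose = 23L, cluster = 24L, sites = 25L,
  km = 26L, pipeline = 31L
)

#' Derive a per-stream child seed from a master seed
#'
#' @param seed Master integer seed.
#' @param stream Stream name (one of the package's generator/analysis streams).
#' @return An integer seed < 2^31, distinct across streams.
#' @keywords internal
childSeed <- function(seed, stream) {
  stream <- match.arg(stream, names(.streamOffsets))
  (abs(as.integer(seed)) %% 2000000L) * 1000L + .streamOffsets[[stream]]
}

#' Stop with a configuration error naming the violated bound
#' @keywords internal
#' @noRd
configError <- function(...) {
  stop("configuration error: ", ..., call. = FALSE)
}

#' Check that a data frame carries required columns
#' @keywords internal
#' @noRd
checkColumns <- function(df, cols, what = "input table") {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop("schema error: ", what, " is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

#' Write a TSV with header, no quoting, no row names
#' @keywords internal
#' @noRd
writeTsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a TSV written by [writeTsv()]
#' @keywords internal
#' @noRd
readTsv <- function(path) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE)
}
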