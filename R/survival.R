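#' @include AllClasses.R utils.R
NULL

.exprMatrix <- function(x) {
  if (is(x, "SurvivalCohort")) x@expr else as.matrix(x)
}

#' Per-patient average expression z-score
#'
#' Standardizes each marker column across patients (mean 0, sample SD 1)
#' and returns the per-patient row mean of the standardized values.
#'
#' @param x A [SurvivalCohort-class] or a numeric matrix
#'   (patients x markers).
#' @return Numeric vector of per-patient scores (named by patient id when
#'   available).
#' @examples
#' zscoreAverage(matrix(c(0, 2), ncol = 1))  # -0.7071, +0.7071
#' @export
zscoreAverage <- function(x) {
  m <- .exprMatrix(x)
  if (nrow(m) < 2) stop("input error: need >= 2 patients", call. = FALSE)
  sds <- apply(m, 2, stats::sd)
  if (any(sds == 0)) {
    bad <- colnames(m)[sds == 0]
    if (is.null(bad)) bad <- which(sds == 0)
    stop("input error: zero-variance column: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  z <- rowMeans(scale(m))
  if (is(x, "SurvivalCohort")) names(z) <- x@patientId
  z
}

#' Kaplan-Meier curves and log-rank test over a score split
#'
#' Splits the cohort at a quantile of the per-patient score (default the
#' median of the average z-score); patients strictly above the threshold
#' form the `high` group, ties go to `low`. Product-limit survival curves
#' are estimated per group and the two-group log-rank chi-squared test is
#' reported. A group with zero events is flagged low-information but the
#' test is still computed.
#'
#' @param cohort A [SurvivalCohort-class].
#' @param scores Per-patient scores; default `zscoreAverage(cohort)`.
#' @param splitQuantile Quantile of `scores` used as the threshold.
#' @return List with `threshold`, `group` (per-patient factor),
#'   `chisq` (log-rank statistic), `p`, `curves` (data.frame `group`,
#'   `time`, `n_risk`, `n_event`, `surv`), `medianSurvival` (per group) and
#'   `lowInformation` (TRUE when a group has zero events).
#' @export
kmLogrank <- function(cohort, scores = NULL, splitQuantile = 0.5) {
  stopifnot(is(cohort, "SurvivalCohort"))
  if (is.null(scores)) scores <- zscoreAverage(cohort)
  if (length(scores) != length(cohort@patientId)) {
    stop("input error: scores must align with the cohort", call. = FALSE)
  }
  thr <- stats::quantile(scores, splitQuantile, type = 7, names = FALSE)
  group <- factor(ifelse(scores > thr, "high", "low"),
                  levels = c("low", "high"))
  if (any(table(group) == 0)) {
    stop("input error: a split group is empty; choose another quantile",
         call. = FALSE)
  }
  time <- cohort@time
  event <- cohort@event
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  chisq <- unname(sd$chisq)
  p <- stats::pchisq(chisq, df = 1, lower.tail = FALSE)
  fit <- survival::survfit(survival::Surv(time, event) ~ group)
  strata <- rep(names(fit$strata), fit$strata)
  curves <- data.frame(
    group = sub("^group=", "", strata),
    time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
    surv = fit$surv, stringsAsFactors = FALSE)
  med <- summary(fit)$table[, "median"]
  names(med) <- sub("^group=", "", names(med))
  lowInfo <- any(tapply(event, group, sum) == 0)
  if (lowInfo) warning("a group has zero events: log-rank p is ",
                       "low-information")
  list(threshold = thr, group = group, chisq = chisq, p = p,
       curves = curves, medianSurvival = med, lowInformation = lowInfo)
}

#' Pairwise Pearson correlation matrix with p-values
#'
#' Pearson correlation for every pair of marker columns, with two-sided
#' p-values from the t transform of r (as in `stats::cor.test`).
#'
#' @param x A [SurvivalCohort-class] or numeric matrix
#'   (patients x markers, >= 3 rows).
#' @return List with `r` (correlation matrix, unit diagonal) and `p`
#'   (two-sided p-values, NA on the diagonal).
#' @export
pearsonMatrix <- function(x) {
  m <- .exprMatrix(x)
  if (nrow(m) < 3) stop("input error: need >= 3 patients", call. = FALSE)
  if (any(apply(m, 2, stats::sd) == 0)) {
    stop("input error: zero-variance column", call. = FALSE)
  }
  r <- stats::cor(m, method = "pearson")
  k <- ncol(m)
  p <- matrix(NA_real_, k, k, dimnames = dimnames(r))
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (i != j) {
        p[i, j] <- stats::cor.test(m[, i], m[, j])$p.value
      }
    }
  }
  list(r = r, p = p)
}
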