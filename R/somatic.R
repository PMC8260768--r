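#' Two-sided Fisher exact test for a 2x2 table
#'
#' Exact two-sided p-value for the table `[a, b; c, d]` obtained by summing,
#' over the hypergeometric distribution with the observed margins, the
#' probabilities of all tables at most as probable as the observed one
#' (with a 1e-7 relative tolerance on the probability comparison, as is
#' standard for this definition).
#'
#' In the somatic filter the table is
#' `[tumor_alt, tumor_ref; remission_alt, remission_ref]`.
#'
#' @param a,b,c,d non-negative integer cell counts.
#' @return two-sided p-value in (0, 1]. A table with an all-zero margin is
#'   degenerate and returns 1 (with a message).
#' @examples
#' fisherExactTwoSided(5, 5, 5, 5)   # symmetric table -> 1
#' fisherExactTwoSided(10, 0, 0, 10) # 2 / choose(20, 10)
#' @export
fisherExactTwoSided <- function(a, b, c, d) {
  counts <- c(a, b, c, d)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("cell counts must be non-negative integers")
  r1 <- a + b; c1 <- a + c; n <- a + b + c + d
  if (r1 == 0L || r1 == n || c1 == 0L || c1 == n) {
    message("degenerate 2x2 table (all-zero margin): p = 1 by convention")
    return(1)
  }
  x <- max(0L, c1 - (n - r1)):min(r1, c1)
  probs <- dhyper(x, r1, n - r1, c1)
  p_obs <- dhyper(a, r1, n - r1, c1)
  p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  min(1, p)
}

#' Somatic filter parameters
#'
#' Defaults follow the composite tumor-versus-remission rule used for
#' paired leukemia/remission exomes: tumor VAF at least 5%, relative VAF
#' difference at least 20%, Fisher exact p below alpha, remission VAF
#' strictly below 5%.
#'
#' @param min_tumor_vaf minimum tumor VAF (inclusive).
#' @param min_relative_diff minimum relative difference
#'   `(VAF_T - VAF_R) / VAF_T` (inclusive); with `diff_mode = "absolute"`
#'   the rule is `VAF_T - VAF_R >= min_relative_diff` instead.
#' @param max_remission_vaf remission VAF upper bound (exclusive).
#' @param alpha significance level for the Fisher test (exclusive).
#' @param diff_mode `"relative"` (default) or `"absolute"`; the published
#'   wording ("relative difference ... minimum 20%") admits both readings.
#' @return named list of validated parameters.
#' @export
filterParams <- function(min_tumor_vaf = 0.05, min_relative_diff = 0.20,
                         max_remission_vaf = 0.05, alpha = 0.05,
                         diff_mode = c("relative", "absolute")) {
  diff_mode <- match.arg(diff_mode)
  vals <- c(min_tumor_vaf, min_relative_diff, max_remission_vaf, alpha)
  if (any(vals <= 0) || any(vals > 1))
    stop("all filter thresholds must lie in (0, 1]")
  list(min_tumor_vaf = min_tumor_vaf, min_relative_diff = min_relative_diff,
       max_remission_vaf = max_remission_vaf, alpha = alpha,
       diff_mode = diff_mode)
}

#' Composite tumor-versus-remission somatic variant filter
#'
#' Applies, to each candidate variant, the conjunction of four rules:
#' tumor VAF >= `min_tumor_vaf`; relative (or absolute) VAF difference
#' >= `min_relative_diff`; two-sided Fisher exact p on
#' `[tumor_alt, tumor_ref; remission_alt, remission_ref]` < `alpha`;
#' remission VAF < `max_remission_vaf`. Records with zero depth in either
#' sample are rejected with rule `"no_coverage"`. Every record receives a
#' decision listing the rules it failed.
#'
#' @param records variant `data.frame` with count columns `tumor_ref`,
#'   `tumor_alt`, `remission_ref`, `remission_alt` (see
#'   [readVariantTable()]); VAF columns are (re)derived from the counts.
#' @param params parameter list from [filterParams()].
#' @param verbose log a kept/dropped summary with `message()`.
#' @return the input `data.frame` with columns `vaf_tumor`,
#'   `vaf_remission`, `fisher_p`, `kept` (logical) and `failed_rules`
#'   (comma-separated rule names, `""` when kept) appended.
#' @export
filterSomatic <- function(records, params = filterParams(), verbose = FALSE) {
  stopifnot(is.data.frame(records))
  need <- c("tumor_ref", "tumor_alt", "remission_ref", "remission_alt")
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop("records are missing column(s): ", paste(miss, collapse = ", "))
  records <- addVafColumns(records)
  n <- nrow(records)
  fisher_p <- rep(NA_real_, n)
  failed <- vector("list", n)
  for (i in seq_len(n)) {
    r <- records[i, ]
    if (is.na(r$vaf_tumor) || is.na(r$vaf_remission)) {
      failed[[i]] <- "no_coverage"
      next
    }
    f <- character()
    if (r$vaf_tumor < params$min_tumor_vaf) f <- c(f, "min_tumor_vaf")
    diff <- switch(params$diff_mode,
      relative = if (r$vaf_tumor > 0)
        (r$vaf_tumor - r$vaf_remission) / r$vaf_tumor else -Inf,
      absolute = r$vaf_tumor - r$vaf_remission)
    if (diff < params$min_relative_diff) f <- c(f, "min_relative_diff")
    fisher_p[i] <- fisherExactTwoSided(r$tumor_alt, r$tumor_ref,
                                       r$remission_alt, r$remission_ref)
    if (fisher_p[i] >= params$alpha) f <- c(f, "fisher")
    if (r$vaf_remission >= params$max_remission_vaf) f <- c(f, "max_remission_vaf")
    failed[[i]] <- f
  }
  records$fisher_p <- fisher_p
  records$kept <- lengths(failed) == 0L
  records$failed_rules <- vapply(failed, paste, character(1), collapse = ",")
  if (verbose)
    message(sprintf("filterSomatic: %d records in, %d kept, %d rejected",
                    n, sum(records$kept), sum(!records$kept)))
  records
}

#' Odds ratio with exact test for a 2x2 co-occurrence table
#'
#' Sample odds ratio `(a*d)/(b*c)` for a 2x2 table (for example fusion
#' status by mutation status across a patient cohort), with the two-sided
#' Fisher exact p-value from [fisherExactTwoSided()]. When any cell is
#' zero, the Haldane-Anscombe correction (0.5 added to every cell) is
#' applied to the odds ratio only, and flagged.
#'
#' @param table 2x2 numeric matrix or length-4 vector `(a, b, c, d)` read
#'   row-wise.
#' @return list with `or`, `p`, and `corrected` (logical).
#' @examples
#' oddsRatioTest(c(5, 5, 5, 5))
#' @export
oddsRatioTest <- function(table) {
  x <- as.vector(t(as.matrix(table)))
  if (length(x) != 4L) stop("expected a 2x2 table")
  if (any(x < 0)) stop("counts must be non-negative")
  a <- x[1]; b <- x[2]; c <- x[3]; d <- x[4]
  if ((a == 0 && b == 0) || (c == 0 && d == 0) ||
      (a == 0 && c == 0) || (b == 0 && d == 0))
    stop("odds ratio undefined: a full margin is zero")
  corrected <- any(x == 0)
  if (corrected) {
    or <- ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c + 0.5))
  } else {
    or <- (a * d) / (b * c)
  }
  p <- fisherExactTwoSided(a, b, c, d)
  list(or = or, p = p, corrected = corrected)
}
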