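# Coerce a ranked input (data.frame from rankGenes() or a named numeric
# vector) to a named score vector sorted by decreasing score.
.asRanked <- function(ranked) {
  if (is.data.frame(ranked)) {
    stopifnot(all(c("gene", "score") %in% names(ranked)))
    v <- setNames(ranked$score, ranked$gene)
  } else {
    stopifnot(is.numeric(ranked), !is.null(names(ranked)))
    v <- ranked
  }
  if (anyDuplicated(names(v))) stop("duplicate genes in ranked list")
  if (is.unsorted(rev(v))) v <- sort(v, decreasing = TRUE)
  v
}

# Extremum selection shared by all ES code paths: largest |value| with a
# 1e-9 relative tolerance, ties broken toward the earliest list position.
# (+x and -x ties are real: the tolerance keeps the choice independent of
# the accumulation order of the running sum.)
.esPick <- function(values, positions) {
  m <- max(abs(values))
  o <- order(positions)
  values[o][which(abs(values[o]) >= m * (1 - 1e-9))[1L]]
}

# ES from sorted hit positions without materialising the running sum:
# between hits the sum decays linearly, so its extrema lie just before or
# just after a hit.
.esFromPositions <- function(pos, hit_weights, N) {
  k <- length(pos)
  w <- hit_weights / sum(hit_weights)
  H <- cumsum(w)
  miss <- 1 / (N - k)
  after <- H - (pos - seq_len(k)) * miss
  before <- c(0, H[-k]) - (pos - seq_len(k)) * miss
  keep <- pos > 1L
  .esPick(c(after, before[keep]), c(pos, pos[keep] - 1L))
}

#' Weighted running-sum enrichment score
#'
#' The classic pre-ranked enrichment statistic: walking down the ranked
#' list, the running sum rises by `|score|^weight` (normalised over the
#' set's hits) at each gene-set member and falls by `1/(N - |set|)` at
#' each miss; the enrichment score is the extremum of largest absolute
#' value. The leading edge contains the hits up to the extremum (positive
#' ES) or from the extremum onward (negative ES).
#'
#' @param ranked ranked list: a `data.frame` from [rankGenes()] or a
#'   named numeric vector of ranking scores (sorted descending; unsorted
#'   input is sorted).
#' @param gene_set character vector of gene ids; must intersect the list
#'   and must not cover it entirely.
#' @param weight exponent on the ranking scores; 0 gives the unweighted
#'   Kolmogorov-Smirnov form.
#' @return list with `es`, `running_sum` (named numeric along the list)
#'   and `leading_edge` (gene ids).
#' @export
enrichmentScore <- function(ranked, gene_set, weight = 1) {
  v <- .asRanked(ranked)
  N <- length(v)
  hit <- names(v) %in% gene_set
  k <- sum(hit)
  if (k == 0L) stop("gene set does not intersect the ranked list")
  if (k == N) stop("gene set covers the entire ranked list")
  w <- abs(v[hit])^weight
  if (sum(w) == 0) {
    if (weight == 0) w <- rep(1, k)
    else stop("degenerate ranking: all hit scores are zero at this weight")
  }
  step <- rep(-1 / (N - k), N)
  step[hit] <- w / sum(w)
  running <- cumsum(step)
  names(running) <- names(v)
  m <- max(abs(running))
  i_ext <- which(abs(running) >= m * (1 - 1e-9))[1L]
  es <- running[[i_ext]]
  le <- if (es >= 0) names(v)[hit & seq_len(N) <= i_ext]
        else names(v)[hit & seq_len(N) >= i_ext]
  list(es = es, running_sum = running, leading_edge = le)
}

#' Gene-set permutation test for a pre-ranked enrichment score
#'
#' The null distribution is built by resampling random gene sets of the
#' same size from the ranked universe;
#' `p = (1 + #\{|ES_null| >= |ES|\}) / (n_perm + 1)`. The normalised score
#' divides ES by the mean |null ES| among null scores of matching sign.
#' Deterministic under `seed`.
#'
#' @inheritParams enrichmentScore
#' @param n_perm number of permutations (at least 100).
#' @param seed RNG seed.
#' @return an [EnrichmentResult-class] object.
#' @export
permutationTest <- function(ranked, gene_set, n_perm = 1000L, seed, weight = 1) {
  if (n_perm < 100L) stop("'n_perm' must be >= 100")
  v <- .asRanked(ranked)
  obs <- enrichmentScore(v, gene_set, weight)
  N <- length(v)
  k <- sum(names(v) %in% gene_set)
  absw <- abs(v)^weight
  null_es <- withr::with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      pos <- sort.int(sample.int(N, k))
      hw <- absw[pos]
      if (sum(hw) == 0) hw <- rep(1, k)
      .esFromPositions(pos, hw, N)
    }, numeric(1))
  })
  if (all(null_es == 0)) stop("degenerate null: all permutation scores are zero")
  p <- (1 + sum(abs(null_es) >= abs(obs$es))) / (n_perm + 1)
  same_sign <- if (obs$es >= 0) null_es > 0 else null_es < 0
  nes <- if (any(same_sign)) obs$es / mean(abs(null_es[same_sign])) else NA_real_
  new("EnrichmentResult", es = unname(obs$es), nes = nes, pValue = p,
      nPerm = as.integer(n_perm), leadingEdge = obs$leading_edge)
}
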