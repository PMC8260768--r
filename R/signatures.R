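#' TPM normalization of a counts matrix
#'
#' Per sample, counts are divided by gene length in kb to give a rate, and
#' rates are rescaled to sum to one million (transcripts per million).
#'
#' @param counts genes x samples numeric matrix with gene rownames.
#' @param gene_lengths named vector of gene lengths in bp, covering every
#'   gene in `counts`.
#' @return TPM matrix; every column of a non-degenerate sample sums to
#'   1e6. All-zero samples stay all-zero, with a warning.
#' @examples
#' m <- matrix(c(10, 10), 2, 1, dimnames = list(c("g1", "g2"), "s1"))
#' tpmNormalize(m, c(g1 = 1000, g2 = 2000))
#' @export
tpmNormalize <- function(counts, gene_lengths) {
  stopifnot(is.matrix(counts), !is.null(rownames(counts)))
  miss <- setdiff(rownames(counts), names(gene_lengths))
  if (length(miss))
    stop("gene_lengths missing for: ", paste(head(miss, 3), collapse = ", "))
  len_kb <- gene_lengths[rownames(counts)] / 1000
  if (any(len_kb <= 0)) stop("gene lengths must be positive")
  rate <- counts / len_kb
  tot <- colSums(rate)
  if (any(tot == 0)) {
    warning(sum(tot == 0), " all-zero sample(s) cannot be normalized")
    tot[tot == 0] <- 1
  }
  sweep(rate, 2, tot, "/") * 1e6
}

#' Counts-per-10k log normalization for cell-level matrices
#'
#' Each cell's counts are scaled to `scale_factor` total and log1p
#' transformed -- the normalization layer used for per-cell scoring and
#' gene-gene correlation.
#'
#' @param counts genes x cells matrix.
#' @param scale_factor library-size target (default 1e4).
#' @return log-normalized matrix.
#' @export
logNormalizeCells <- function(counts, scale_factor = 1e4) {
  tot <- colSums(counts)
  if (any(tot == 0)) {
    warning(sum(tot == 0), " zero-count cell(s) left all-zero")
    tot[tot == 0] <- 1
  }
  log1p(sweep(counts, 2, tot, "/") * scale_factor)
}

#' Cell QC thresholds
#'
#' Defaults follow the published filter: drop cells with ribosomal read
#' fraction above 0.6, mitochondrial read fraction above 0.1, or fewer
#' than 200 expressed genes (all comparisons strict).
#'
#' @param max_ribo_fraction,max_mito_fraction strict upper bounds.
#' @param min_genes strict lower bound on expressed genes.
#' @return named list of thresholds.
#' @export
qcThresholds <- function(max_ribo_fraction = 0.6, max_mito_fraction = 0.1,
                         min_genes = 200L) {
  if (max_ribo_fraction <= 0 || max_ribo_fraction >= 1 ||
      max_mito_fraction <= 0 || max_mito_fraction >= 1)
    stop("fractions must lie in (0, 1)")
  list(max_ribo_fraction = max_ribo_fraction,
       max_mito_fraction = max_mito_fraction,
       min_genes = as.integer(min_genes))
}

#' Filter poor-quality cells
#'
#' A cell is dropped iff its ribosomal fraction exceeds
#' `max_ribo_fraction`, its mitochondrial fraction exceeds
#' `max_mito_fraction`, or it expresses fewer than `min_genes` genes
#' (strict comparisons; a cell exactly at a bound is kept).
#'
#' @param counts genes x cells count matrix.
#' @param mito_genes,ribo_genes gene ids counted as mitochondrial /
#'   ribosomal (subsets of `rownames(counts)`).
#' @param thresholds list from [qcThresholds()].
#' @return list with `kept` (cell ids) and `qc` (per-cell `data.frame`:
#'   `cell`, `ribo_fraction`, `mito_fraction`, `n_genes`, `kept`).
#' @export
qcFilterCells <- function(counts, mito_genes, ribo_genes,
                          thresholds = qcThresholds()) {
  if (!is.matrix(counts) || ncol(counts) == 0L) stop("empty matrix")
  stopifnot(all(mito_genes %in% rownames(counts)),
            all(ribo_genes %in% rownames(counts)))
  tot <- colSums(counts)
  ribo <- colSums(counts[ribo_genes, , drop = FALSE]) / pmax(tot, 1)
  mito <- colSums(counts[mito_genes, , drop = FALSE]) / pmax(tot, 1)
  ngene <- colSums(counts > 0)
  kept <- !(ribo > thresholds$max_ribo_fraction |
            mito > thresholds$max_mito_fraction |
            ngene < thresholds$min_genes)
  list(kept = colnames(counts)[kept],
       qc = data.frame(cell = colnames(counts), ribo_fraction = ribo,
                       mito_fraction = mito, n_genes = ngene, kept = kept,
                       row.names = NULL, stringsAsFactors = FALSE))
}

#' Two-group differential expression stand-in
#'
#' A deliberately simple two-group test for synthetic end-to-end runs:
#' per gene, the log2 fold change of group means on log2(CPM + 1) and a
#' Welch two-sample t p-value, Benjamini-Hochberg adjusted across genes.
#' Externally produced DE tables (e.g. from a negative-binomial GLM fit)
#' can be consumed directly by [deriveSignature()] and [rankGenes()].
#'
#' @param counts genes x samples count matrix.
#' @param groupA_ids,groupB_ids column ids of the two groups (each at
#'   least 2 samples).
#' @return `data.frame` with columns `gene`, `log2_fold_change`,
#'   `p_value`, `adjusted_p`. Genes with zero variance in both groups and
#'   equal means get p = 1.
#' @export
differentialExpression <- function(counts, groupA_ids, groupB_ids) {
  stopifnot(all(groupA_ids %in% colnames(counts)),
            all(groupB_ids %in% colnames(counts)))
  if (length(groupA_ids) < 2L || length(groupB_ids) < 2L)
    stop("each group needs at least 2 samples")
  cpm <- sweep(counts, 2, pmax(colSums(counts), 1), "/") * 1e6
  l <- log2(cpm + 1)
  A <- l[, groupA_ids, drop = FALSE]; B <- l[, groupB_ids, drop = FALSE]
  nA <- ncol(A); nB <- ncol(B)
  mA <- rowMeans(A); mB <- rowMeans(B)
  vA <- rowSums((A - mA)^2) / (nA - 1)
  vB <- rowSums((B - mB)^2) / (nB - 1)
  se2 <- vA / nA + vB / nB
  t_stat <- ifelse(se2 > 0, (mA - mB) / sqrt(se2), NA_real_)
  df <- ifelse(se2 > 0,
               se2^2 / ((vA / nA)^2 / (nA - 1) + (vB / nB)^2 / (nB - 1)),
               NA_real_)
  p <- ifelse(is.na(t_stat), 1, 2 * pt(-abs(t_stat), df))
  # zero spread but unequal means cannot happen on finite data unless both
  # variances vanish with mA != mB; treat as maximally significant
  p[is.na(t_stat) & mA != mB] <- 0
  data.frame(gene = rownames(counts), log2_fold_change = mA - mB,
             p_value = p, adjusted_p = p.adjust(p, "BH"),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Derive up/down gene signatures from a DE table
#'
#' Genes with fold change strictly above `fc_thresh` (i.e. log2 fold
#' change > log2(fc_thresh)) and adjusted p strictly below `padj_thresh`
#' form the up signature; the mirror-image genes form the down signature.
#'
#' @param de_table `data.frame` with columns `gene`, `log2_fold_change`,
#'   `adjusted_p`.
#' @param fc_thresh linear fold-change threshold (strict).
#' @param padj_thresh adjusted-p threshold (strict).
#' @return list with gene-id vectors `up` and `down` (disjoint).
#' @export
deriveSignature <- function(de_table, fc_thresh = 2, padj_thresh = 0.05) {
  lfc <- de_table$log2_fold_change
  ok <- de_table$adjusted_p < padj_thresh
  list(up = de_table$gene[ok & lfc > log2(fc_thresh)],
       down = de_table$gene[ok & lfc < -log2(fc_thresh)])
}

#' Bulk signature scoring by z-scored gene means
#'
#' Each signature gene is z-scored across samples (sample SD, n-1), the
#' per-sample mean over signature genes is taken, and the means are
#' z-scored across samples again to give the final rescaled score.
#'
#' @param matrix genes x samples expression matrix (any normalized layer).
#' @param gene_set character vector of signature genes; genes absent from
#'   the matrix are dropped with a warning, constant genes likewise.
#' @param gene_wise z-score each gene across samples (default, the
#'   standard construction); `FALSE` instead z-scores each sample across
#'   the signature genes before averaging.
#' @return `data.frame` with columns `sample_id`, `raw_mean`, `score`
#'   (mean 0, SD 1 across samples).
#' @export
scoreSignatureBulk <- function(matrix, gene_set, gene_wise = TRUE) {
  if (ncol(matrix) < 2L) stop("need at least 2 samples to rescale scores")
  present <- intersect(gene_set, rownames(matrix))
  if (!length(present)) stop("no signature gene present in the matrix")
  if (length(present) < length(gene_set))
    warning(length(gene_set) - length(present),
            " signature gene(s) absent from the matrix; dropped")
  m <- matrix[present, , drop = FALSE]
  if (gene_wise) {
    sds <- apply(m, 1, sd)
    if (any(sds == 0)) {
      warning(sum(sds == 0), " constant signature gene(s) dropped")
      m <- m[sds > 0, , drop = FALSE]
      if (!nrow(m)) stop("all signature genes constant across samples")
      sds <- sds[sds > 0]
    }
    z <- (m - rowMeans(m)) / sds
  } else {
    z <- apply(m, 2, function(col) (col - mean(col)) / sd(col))
  }
  raw <- colMeans(z)
  data.frame(sample_id = colnames(matrix), raw_mean = raw,
             score = (raw - mean(raw)) / sd(raw),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Per-cell module score with expression-matched controls
#'
#' AddModuleScore-style construction: genes are binned by average
#' expression into `n_bins` equal-occupancy bins; for each signature gene,
#' `n_ctrl` control genes are drawn from its bin; the cell score is the
#' mean signature expression minus the mean control expression, and scores
#' are finally z-scored across cells.
#'
#' @param matrix genes x cells log-normalized matrix (see
#'   [logNormalizeCells()]).
#' @param gene_set signature gene ids (absent genes dropped with warning).
#' @param n_bins expression bins.
#' @param n_ctrl control genes drawn per signature gene (with replacement
#'   when a bin is smaller than requested, logged).
#' @param seed RNG seed for the control draw.
#' @return `data.frame` with columns `cell_id`, `raw_score`, `score`.
#' @export
scoreSignatureCells <- function(matrix, gene_set, n_bins = 24L, n_ctrl = 100L,
                                seed) {
  if (nrow(matrix) < n_bins) stop("need at least n_bins genes")
  present <- intersect(gene_set, rownames(matrix))
  if (!length(present)) stop("no signature gene present in the matrix")
  if (length(present) < length(gene_set))
    warning(length(gene_set) - length(present),
            " signature gene(s) absent from the matrix; dropped")
  avg <- rowMeans(matrix)
  bin <- cut(rank(avg, ties.method = "first"), breaks = n_bins, labels = FALSE)
  names(bin) <- rownames(matrix)
  withr::with_seed(seed, {
    ctrl <- unlist(lapply(present, function(g) {
      pool <- setdiff(names(bin)[bin == bin[[g]]], g)
      if (length(pool) < n_ctrl) {
        message(sprintf("bin %d has %d genes < %d controls; sampling with replacement",
                        bin[[g]], length(pool), n_ctrl))
        sample(pool, n_ctrl, replace = TRUE)
      } else sample(pool, n_ctrl)
    }))
    raw <- colMeans(matrix[present, , drop = FALSE]) -
      colMeans(matrix[ctrl, , drop = FALSE])
    s <- sd(raw)
    data.frame(cell_id = colnames(matrix), raw_score = raw,
               score = if (s > 0) (raw - mean(raw)) / s else raw * 0,
               row.names = NULL, stringsAsFactors = FALSE)
  })
}

#' Rank genes for pre-ranked enrichment
#'
#' Ranking statistic `-sign(log2FC) * log10(adjusted p)`; since log10 of a
#' small p is negative, upregulated significant genes rank at the top.
#' Adjusted p-values of zero are clipped at the smallest positive double
#' with a warning. Ties are broken by gene id.
#'
#' @param de_table `data.frame` with columns `gene`, `log2_fold_change`,
#'   `adjusted_p`.
#' @return `data.frame` with columns `gene`, `score`, sorted by
#'   decreasing score.
#' @export
rankGenes <- function(de_table) {
  padj <- de_table$adjusted_p
  if (any(padj <= 0)) {
    warning(sum(padj <= 0), " adjusted p-value(s) clipped at machine minimum")
    padj <- pmax(padj, .Machine$double.xmin)
  }
  score <- -sign(de_table$log2_fold_change) * log10(padj)
  o <- order(-score, de_table$gene)
  data.frame(gene = de_table$gene[o], score = score[o],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Correlate every gene with an anchor gene
#'
#' Pearson correlation of each gene's expression with the anchor gene
#' across cells/samples, with the top-k and bottom-k correlated genes
#' (anchor excluded; constant genes excluded as undefined).
#'
#' @param matrix genes x cells log-normalized expression matrix.
#' @param anchor_gene gene id present in the matrix; must not be constant.
#' @param k genes to report at each extreme.
#' @return list with `correlations` (named vector, anchor excluded),
#'   `top` and `bottom` (gene ids).
#' @export
correlateWithGene <- function(matrix, anchor_gene, k = 25L) {
  if (!anchor_gene %in% rownames(matrix)) stop("anchor gene not in matrix")
  anchor <- matrix[anchor_gene, ]
  if (sd(anchor) == 0) stop("anchor gene is constant across cells")
  r <- suppressWarnings(as.vector(cor(anchor, t(matrix))))
  names(r) <- rownames(matrix)
  r <- r[names(r) != anchor_gene]
  r <- r[!is.na(r)]
  o <- order(r, decreasing = TRUE)
  list(correlations = r,
       top = names(r)[utils::head(o, k)],
       bottom = rev(names(r)[utils::tail(o, k)]))
}
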