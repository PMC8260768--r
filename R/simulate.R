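.BASES <- c("A", "C", "G", "T")

.randomDNA <- function(len) {
  paste(sample(.BASES, len, replace = TRUE), collapse = "")
}

# Substitution-only sequencing errors: each base is replaced by one of the
# three other bases independently with probability `rate`.
.addSubstitutions <- function(seq, rate) {
  if (rate <= 0) return(seq)
  ch <- strsplit(seq, "", fixed = TRUE)[[1L]]
  hit <- which(runif(length(ch)) < rate)
  for (i in hit) ch[i] <- sample(setdiff(.BASES, ch[i]), 1L)
  paste(ch, collapse = "")
}

#' Synthetic exon marker sequences for the TCF7-SPI1 fusion
#'
#' Generates fixed random marker sequences standing in for TCF7 exons 1-7
#' and SPI1 exons 3-5, plus the fusion junction marker (the 3' half of the
#' TCF7 exon 4 marker joined to the 5' half of the SPI1 exon 3 marker).
#' Read classification is defined by which markers a read spans, so random
#' sequences of realistic exon-marker length are sufficient; they carry no
#' homology to the real genes (synthetic stand-ins).
#'
#' @param exon_length marker length in nt.
#' @param seed RNG seed fixing the marker sequences.
#' @return named list: `tcf7` (7 markers), `spi1` (markers 3-5), and the
#'   classification markers `tcf7_e4`, `tcf7_e7`, `spi1_e3`, `junction`.
#' @export
fusionMarkers <- function(exon_length = 40L, seed = 7101L) {
  withr::with_seed(seed, {
    tcf7 <- vapply(1:7, function(i) .randomDNA(exon_length), character(1))
    spi1 <- setNames(vapply(3:5, function(i) .randomDNA(exon_length), character(1)),
                     paste0("e", 3:5))
    names(tcf7) <- paste0("e", 1:7)
    half <- exon_length %/% 2L
    list(tcf7 = tcf7, spi1 = spi1,
         tcf7_e4 = tcf7[["e4"]], tcf7_e7 = tcf7[["e7"]],
         spi1_e3 = spi1[["e3"]],
         junction = paste0(substr(tcf7[["e4"]], exon_length - half + 1L, exon_length),
                           substr(spi1[["e3"]], 1L, half)))
  })
}

#' Simulate a cell-barcode whitelist
#'
#' Random barcodes with pairwise Hamming distance greater than
#' `2 * max_mismatches`, so mismatch-tolerant demultiplexing cannot
#' confuse two whitelist entries.
#'
#' @param n_cells number of barcodes.
#' @param barcode_length barcode length in nt.
#' @param max_mismatches demultiplexing mismatch tolerance to guard against.
#' @param seed RNG seed.
#' @return character vector of barcodes.
#' @export
simulateWhitelist <- function(n_cells, barcode_length = 16L,
                              max_mismatches = 1L, seed) {
  withr::with_seed(seed, {
    bcs <- character(0)
    while (length(bcs) < n_cells) {
      cand <- .randomDNA(barcode_length)
      ok <- all(vapply(bcs, function(b) {
        sum(strsplit(cand, "")[[1L]] != strsplit(b, "")[[1L]]) > 2L * max_mismatches
      }, logical(1)))
      if (ok) bcs <- c(bcs, cand)
    }
    bcs
  })
}

#' Simulate paired tumor/remission variant tables with known truth
#'
#' Somatic records draw tumor alt counts from Binomial(depth, VAF) with a
#' tumor VAF drawn uniformly from `tumor_vaf_range` and a remission VAF of
#' zero; germline records draw both samples at VAF 0.5. Deterministic
#' under `seed`.
#'
#' @param n_somatic,n_germline record counts (their sum must be positive).
#' @param depth sequencing depth per sample (reads per site).
#' @param tumor_vaf_range length-1 or length-2 numeric in (0, 1]: the
#'   somatic tumor VAF, or a range to draw it from.
#' @param seed RNG seed.
#' @return list with `variants` (a variant `data.frame` as from
#'   [readVariantTable()]) and `truth` (`data.frame`: `chrom`, `pos`,
#'   `label` in somatic/germline, `true_vaf`).
#' @export
simulatePairedVariants <- function(n_somatic, n_germline, depth = 100L,
                                   tumor_vaf_range = c(0.1, 0.4), seed) {
  if (n_somatic + n_germline == 0L) stop("no records requested")
  if (depth < 1L) stop("'depth' must be >= 1")
  if (any(tumor_vaf_range <= 0) || any(tumor_vaf_range > 1))
    stop("'tumor_vaf_range' must lie in (0, 1]")
  withr::with_seed(seed, {
    n <- n_somatic + n_germline
    label <- c(rep("somatic", n_somatic), rep("germline", n_germline))
    vaf <- ifelse(label == "somatic",
                  runif(n, min(tumor_vaf_range), max(tumor_vaf_range)), 0.5)
    tumor_alt <- rbinom(n, depth, vaf)
    remission_alt <- rbinom(n, depth, ifelse(label == "somatic", 0, 0.5))
    variants <- data.frame(
      chrom = "chr1", pos = seq_len(n), ref = "A", alt = "T",
      tumor_ref = depth - tumor_alt, tumor_alt = tumor_alt,
      remission_ref = depth - remission_alt, remission_alt = remission_alt,
      stringsAsFactors = FALSE)
    list(variants = addVafColumns(variants),
         truth = data.frame(chrom = "chr1", pos = seq_len(n), label = label,
                            true_vaf = vaf, stringsAsFactors = FALSE))
  })
}

#' Simulate barcoded long reads with fusion or canonical structure
#'
#' Each read carries its cell's 16-nt barcode near one end (a short random
#' prefix, the barcode, a random spacer, then the transcript body), and the
#' whole read is reverse-complemented with probability 1/2 so barcodes
#' appear in both orientations, as cDNA strands do. The body concatenates
#' synthetic exon markers: TCF7 e1-e4 followed by SPI1 e3-e5 for fusion
#' reads, or TCF7 e1-e7 for canonical reads. Substitution errors are
#' applied uniformly at `sub_error_rate`; all reads exceed 250 nt.
#'
#' @param whitelist cell barcodes (16 nt each).
#' @param n_cells number of cells to draw reads from (first
#'   `n_cells` whitelist entries).
#' @param reads_per_cell reads per cell.
#' @param fusion_fraction probability a read has fusion structure.
#' @param sub_error_rate per-base substitution error rate.
#' @param seed RNG seed.
#' @param markers marker list from [fusionMarkers()].
#' @return list with `reads` (FASTQ `data.frame` as from [readFastq()])
#'   and `truth` (`data.frame`: `read_id`, `barcode`, `class`,
#'   `orientation`).
#' @export
simulateLongReads <- function(whitelist, n_cells = length(whitelist),
                              reads_per_cell = 50L, fusion_fraction = 0.5,
                              sub_error_rate = 0.005, seed,
                              markers = fusionMarkers()) {
  if (any(nchar(whitelist) != 16L)) stop("whitelist barcodes must be 16 nt")
  if (fusion_fraction < 0 || fusion_fraction > 1)
    stop("'fusion_fraction' must be in [0, 1]")
  if (n_cells > length(whitelist)) stop("n_cells exceeds whitelist size")
  withr::with_seed(seed, {
    fusion_body <- paste0(paste(markers$tcf7[1:4], collapse = ""),
                          paste(markers$spi1, collapse = ""))
    canonical_body <- paste(markers$tcf7, collapse = "")
    n <- n_cells * reads_per_cell
    barcode <- rep(whitelist[seq_len(n_cells)], each = reads_per_cell)
    is_fusion <- runif(n) < fusion_fraction
    revcomp <- runif(n) < 0.5
    seqs <- character(n)
    for (i in seq_len(n)) {
      s <- paste0(.randomDNA(20L), barcode[i], .randomDNA(12L),
                  if (is_fusion[i]) fusion_body else canonical_body,
                  .randomDNA(10L))
      s <- .addSubstitutions(s, sub_error_rate)
      if (revcomp[i]) s <- .revcomp(s)
      seqs[i] <- s
    }
    ids <- sprintf("read_%05d", seq_len(n))
    list(
      reads = data.frame(read_id = ids, sequence = seqs,
                         quality = strrep("I", nchar(seqs)),
                         stringsAsFactors = FALSE),
      truth = data.frame(read_id = ids, barcode = barcode,
                         class = ifelse(is_fusion, "fusion", "canonical"),
                         orientation = ifelse(revcomp, "reverse_complement",
                                              "forward"),
                         stringsAsFactors = FALSE))
  })
}

#' Simulate a two-group expression matrix with a planted signature
#'
#' Negative-binomial counts with gene-wise mean drawn log-normally and a
#' common dispersion. The first `n_signature_up` planted genes are shifted
#' up by `log2_effect` in group A and the next `n_signature_down` shifted
#' down by the same amount, defining a ground-truth up/down signature.
#'
#' @param n_groupA,n_groupB samples per group (each at least 2).
#' @param n_genes total genes.
#' @param n_signature_up,n_signature_down planted signature sizes.
#' @param log2_effect planted log2 fold change (>= 0; 0 gives a null
#'   matrix for calibration runs).
#' @param dispersion NB dispersion (variance = mu + dispersion * mu^2).
#' @param mean_log,sd_log log-normal parameters of gene base means.
#' @param seed RNG seed.
#' @return list with `counts` (genes x samples matrix), `lengths` (named
#'   gene lengths in bp), `groups` (named character vector, `"A"`/`"B"`)
#'   and `truth` (`data.frame`: `gene`, `planted` in up/down/none).
#' @export
simulateExpression <- function(n_groupA = 10L, n_groupB = 10L, n_genes = 2000L,
                               n_signature_up = 50L, n_signature_down = 50L,
                               log2_effect = 2, dispersion = 0.05,
                               mean_log = log(50), sd_log = 1, seed) {
  if (n_groupA < 2L || n_groupB < 2L)
    stop("each group needs at least 2 samples")
  if (n_signature_up + n_signature_down > n_genes)
    stop("signature larger than gene universe")
  if (log2_effect < 0) stop("'log2_effect' must be >= 0")
  withr::with_seed(seed, {
    genes <- sprintf("gene_%04d", seq_len(n_genes))
    samples <- c(sprintf("A_%02d", seq_len(n_groupA)),
                 sprintf("B_%02d", seq_len(n_groupB)))
    groups <- setNames(rep(c("A", "B"), c(n_groupA, n_groupB)), samples)
    mu <- exp(rnorm(n_genes, mean_log, sd_log))
    planted <- rep("none", n_genes)
    planted[seq_len(n_signature_up)] <- "up"
    planted[n_signature_up + seq_len(n_signature_down)] <- "down"
    shift <- ifelse(planted == "up", 2^log2_effect,
                    ifelse(planted == "down", 2^-log2_effect, 1))
    size <- 1 / dispersion
    counts <- matrix(0, n_genes, length(samples),
                     dimnames = list(genes, samples))
    for (j in seq_along(samples)) {
      m <- if (groups[j] == "A") mu * shift else mu
      counts[, j] <- rnbinom(n_genes, mu = m, size = size)
    }
    list(counts = counts,
         lengths = setNames(sample(200:5000, n_genes, replace = TRUE), genes),
         groups = groups,
         truth = data.frame(gene = genes, planted = planted,
                            stringsAsFactors = FALSE))
  })
}

#' Simulate a limiting-dilution dose-response table
#'
#' Single-hit model: responders per dose are Binomial(n_per_dose,
#' 1 - exp(-dose * f_true)).
#'
#' @param f_true true active-cell frequency, in (0, 1).
#' @param doses cells injected per animal at each dose level; defaults to
#'   the four-step ladder 2e6, 2e5, 2e4, 2e3.
#' @param n_per_dose animals per dose.
#' @param seed RNG seed.
#' @return `data.frame` with columns `dose`, `tested`, `responding`.
#' @export
simulateLimitingDilution <- function(f_true, doses = c(2e6, 2e5, 2e4, 2e3),
                                     n_per_dose = 5L, seed) {
  if (f_true <= 0 || f_true >= 1) stop("'f_true' must be in (0, 1)")
  if (any(doses <= 0)) stop("doses must be positive")
  withr::with_seed(seed, {
    p <- 1 - exp(-doses * f_true)
    data.frame(dose = doses, tested = n_per_dose,
               responding = rbinom(length(doses), n_per_dose, p))
  })
}
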