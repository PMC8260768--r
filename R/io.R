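#' Read a 4-line FASTQ file
#'
#' Reads standard 4-line FASTQ records into a data frame with one row per
#' read. Identifiers are stripped of the leading `"@"` (and of any trailing
#' comment after the first whitespace is *not* removed -- the full header is
#' kept). Malformed records raise an error naming the 1-based record index.
#'
#' @param path path to an uncompressed FASTQ file.
#' @return `data.frame` with columns `read_id`, `sequence`, `quality`
#'   (character; per-base phred string).
#' @examples
#' fq <- tempfile(fileext = ".fastq")
#' writeLines(c("@r1", "ACGT", "+", "IIII"), fq)
#' readFastq(fq)
#' @export
readFastq <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  if (length(lines) && !nzchar(lines[length(lines)]))
    lines <- lines[-length(lines)]
  if (length(lines) == 0L)
    return(data.frame(read_id = character(), sequence = character(),
                      quality = character(), stringsAsFactors = FALSE))
  if (length(lines) %% 4L != 0L)
    stop(sprintf("truncated FASTQ: record %d is incomplete (%d lines total)",
                 length(lines) %/% 4L + 1L, length(lines)))
  n <- length(lines) %/% 4L
  hdr <- lines[seq(1L, by = 4L, length.out = n)]
  seqs <- lines[seq(2L, by = 4L, length.out = n)]
  plus <- lines[seq(3L, by = 4L, length.out = n)]
  qual <- lines[seq(4L, by = 4L, length.out = n)]
  bad <- which(!startsWith(hdr, "@"))
  if (length(bad))
    stop(sprintf("malformed FASTQ: record %d header does not start with '@'", bad[1L]))
  bad <- which(!startsWith(plus, "+"))
  if (length(bad))
    stop(sprintf("malformed FASTQ: record %d separator line does not start with '+'", bad[1L]))
  bad <- which(nchar(qual) != nchar(seqs))
  if (length(bad))
    stop(sprintf("malformed FASTQ: record %d quality length %d != sequence length %d",
                 bad[1L], nchar(qual[bad[1L]]), nchar(seqs[bad[1L]])))
  bad <- which(!nzchar(seqs))
  if (length(bad))
    stop(sprintf("malformed FASTQ: record %d has an empty sequence", bad[1L]))
  data.frame(read_id = sub("^@", "", hdr), sequence = seqs, quality = qual,
             stringsAsFactors = FALSE)
}

#' Write reads as 4-line FASTQ
#'
#' Inverse of [readFastq()]: `readFastq(writeFastq(x, p))` reproduces `x`.
#' Reads without a quality string (`NA`) are written with a constant `"I"`
#' quality line of the sequence length.
#'
#' @param reads `data.frame` with columns `read_id`, `sequence` and
#'   optionally `quality`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeFastq <- function(reads, path) {
  stopifnot(is.data.frame(reads), all(c("read_id", "sequence") %in% names(reads)))
  qual <- if ("quality" %in% names(reads)) reads$quality else rep(NA_character_, nrow(reads))
  missing_q <- is.na(qual)
  qual[missing_q] <- strrep("I", nchar(reads$sequence[missing_q]))
  if (any(nchar(qual) != nchar(reads$sequence)))
    stop("quality strings must match sequence lengths")
  out <- character(4L * nrow(reads))
  if (nrow(reads)) {
    out[seq(1L, by = 4L, length.out = nrow(reads))] <- paste0("@", reads$read_id)
    out[seq(2L, by = 4L, length.out = nrow(reads))] <- reads$sequence
    out[seq(3L, by = 4L, length.out = nrow(reads))] <- "+"
    out[seq(4L, by = 4L, length.out = nrow(reads))] <- qual
  }
  writeLines(out, path)
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' One gene set per tab-separated line: name, description, then genes.
#' Duplicate genes within a line are de-duplicated with a warning; lines
#' with fewer than three fields (no genes) are an error.
#'
#' @param path path to a GMT file.
#' @return named list of gene sets; each element is a character vector of
#'   unique gene ids with a `description` attribute.
#' @export
readGmt <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 3L)
      stop(sprintf("GMT parse error at line %d: expected name, description and >= 1 gene", i))
    genes <- fields[-(1:2)]
    if (anyDuplicated(genes)) {
      warning(sprintf("GMT line %d ('%s'): %d duplicate gene(s) removed",
                      i, fields[1L], sum(duplicated(genes))))
      genes <- unique(genes)
    }
    s <- genes
    attr(s, "description") <- fields[2L]
    sets[[fields[1L]]] <- s
  }
  sets
}

#' Write gene sets to a GMT file
#'
#' @param sets named list of character vectors (optionally carrying a
#'   `description` attribute).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeGmt <- function(sets, path) {
  stopifnot(is.list(sets), !is.null(names(sets)))
  lines <- vapply(names(sets), function(nm) {
    desc <- attr(sets[[nm]], "description")
    if (is.null(desc)) desc <- ""
    paste(c(nm, desc, sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a gene-by-sample matrix from TSV
#'
#' Genes are rows; the first column must be `gene_id`. Duplicate gene or
#' sample identifiers are rejected.
#'
#' @param path path to a TSV file.
#' @return numeric matrix with gene rownames and sample colnames.
#' @export
readCountsMatrix <- function(path) {
  tab <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(tab)[1L] != "gene_id")
    stop("first column of a counts matrix must be 'gene_id'")
  if (anyDuplicated(tab$gene_id))
    stop("duplicate gene identifiers in counts matrix")
  if (anyDuplicated(names(tab)[-1L]))
    stop("duplicate sample identifiers in counts matrix")
  m <- as.matrix(tab[, -1L, drop = FALSE])
  rownames(m) <- tab$gene_id
  if (!is.numeric(m)) stop("counts matrix values must be numeric")
  if (any(m < 0)) stop("counts matrix values must be non-negative")
  m
}

#' Write a gene-by-sample matrix as TSV
#'
#' @param m numeric matrix with gene rownames and sample colnames.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeCountsMatrix <- function(m, path) {
  stopifnot(is.matrix(m), !is.null(rownames(m)), !is.null(colnames(m)))
  tab <- data.frame(gene_id = rownames(m), m, check.names = FALSE,
                    stringsAsFactors = FALSE)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a paired tumor/remission variant table from TSV
#'
#' Expects columns `chrom`, `pos`, `ref`, `alt`, `tumor_ref`, `tumor_alt`,
#' `remission_ref`, `remission_alt`. VAF columns are derived on read.
#'
#' @param path path to a TSV file.
#' @return `data.frame` of variant records with `vaf_tumor`/`vaf_remission`
#'   columns added (NA where depth is zero).
#' @export
readVariantTable <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("chrom", "pos", "ref", "alt",
            "tumor_ref", "tumor_alt", "remission_ref", "remission_alt")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("variant table is missing column(s): ", paste(miss, collapse = ", "))
  addVafColumns(tab)
}

#' @keywords internal
addVafColumns <- function(tab) {
  td <- tab$tumor_ref + tab$tumor_alt
  rd <- tab$remission_ref + tab$remission_alt
  tab$vaf_tumor <- ifelse(td > 0, tab$tumor_alt / td, NA_real_)
  tab$vaf_remission <- ifelse(rd > 0, tab$remission_alt / rd, NA_real_)
  tab
}

#' Read a limiting-dilution dose-response table from TSV
#'
#' Expects columns `dose`, `tested`, `responding`.
#'
#' @param path path to a TSV file.
#' @return validated `data.frame`.
#' @export
readDoseResponse <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("dose", "tested", "responding")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("dose-response table is missing column(s): ", paste(miss, collapse = ", "))
  validateDoseResponse(tab)
  tab
}

#' Read a barcode whitelist
#'
#' Plain text, one cell barcode per line. All barcodes must have the same
#' stated length (default 16 nt, the 10x cell-barcode length).
#'
#' @param path path to the whitelist file.
#' @param barcode_length required barcode length in nt.
#' @return character vector of barcodes.
#' @export
readWhitelist <- function(path, barcode_length = 16L) {
  bcs <- readLines(path)
  bcs <- bcs[nzchar(bcs)]
  bad <- which(nchar(bcs) != barcode_length)
  if (length(bad))
    stop(sprintf("whitelist entry %d ('%s') is not %d nt", bad[1L], bcs[bad[1L]],
                 barcode_length))
  if (anyDuplicated(bcs)) stop("duplicate barcodes in whitelist")
  bcs
}

#' Write a machine-readable JSON summary of a pipeline stage
#'
#' Scalar values are unboxed so the file holds plain JSON numbers/strings.
#'
#' @param x named list of summary values.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeJsonSummary <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
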