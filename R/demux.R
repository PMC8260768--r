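# Per-offset Hamming mismatch counts of `pattern` against every ungapped
# placement inside `subject`. Non-ACGT characters mismatch everything,
# including themselves (raw byte comparison on an alphabet restricted to
# A/C/G/T; other bytes are remapped to distinct sentinels on each side).
.hammingAll <- function(subject, pattern) {
  sw <- charToRaw(subject)
  pw <- charToRaw(pattern)
  Lp <- length(pw)
  noff <- length(sw) - Lp + 1L
  if (noff < 1L) return(integer(0))
  acgt <- charToRaw("ACGT")
  sw[!(sw %in% acgt)] <- as.raw(1L)  # sentinel on subject side
  pw[!(pw %in% acgt)] <- as.raw(2L)  # different sentinel on pattern side
  idx <- rep(seq_len(noff), Lp) + rep(seq_len(Lp) - 1L, each = noff)
  S <- matrix(sw[idx], nrow = noff)
  P <- matrix(pw, nrow = noff, ncol = Lp, byrow = TRUE)
  as.integer(rowSums(S != P))
}

.revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Minimum-Hamming-distance scan of a barcode against a window
#'
#' Slides the barcode over every ungapped offset of the window and returns
#' the leftmost offset achieving the minimum Hamming distance
#' (substitutions only). Non-ACGT characters mismatch every base.
#'
#' @param window_seq window sequence (character).
#' @param barcode barcode sequence (character).
#' @return list with `position` (1-based offset of the best placement) and
#'   `mismatches`; both `NA` when the window is shorter than the barcode.
#' @examples
#' hammingScan("AAACCCGGGTTT", "CCGG")
#' @export
hammingScan <- function(window_seq, barcode) {
  mm <- .hammingAll(window_seq, barcode)
  if (!length(mm)) return(list(position = NA_integer_, mismatches = NA_integer_))
  i <- which.min(mm)  # leftmost on ties
  list(position = i, mismatches = mm[i])
}

#' Demultiplexing parameters
#'
#' Defaults follow direct sequence matching of 10x cell barcodes in
#' nanopore reads: the first and last 200 nt of any read longer than
#' 250 nt are scanned for each whitelist barcode, forward and
#' reverse-complemented, accepting fewer than 2 mismatches.
#'
#' @param barcode_length barcode length in nt.
#' @param window nt scanned at each read end.
#' @param min_read_length reads must be strictly longer than this.
#' @param max_mismatches maximum substitutions for an accepted barcode hit.
#' @return named list of validated parameters.
#' @export
demuxParams <- function(barcode_length = 16L, window = 200L,
                        min_read_length = 250L, max_mismatches = 1L) {
  if (window < barcode_length) stop("'window' must be >= barcode length")
  if (max_mismatches >= barcode_length)
    stop("'max_mismatches' must be < barcode length")
  list(barcode_length = as.integer(barcode_length), window = as.integer(window),
       min_read_length = as.integer(min_read_length),
       max_mismatches = as.integer(max_mismatches))
}

#' Assign a cell barcode to a long read
#'
#' Scans the first and last `window` nt of the read (clipped to the read
#' when the read is shorter than two windows) against every whitelist
#' barcode in forward and reverse-complement orientation. The hit with the
#' fewest mismatches wins, provided it has at most `max_mismatches`; two
#' *distinct* barcodes tied at the best mismatch count make the read
#' `ambiguous`; no acceptable hit leaves it `unassigned`; reads not longer
#' than `min_read_length` are `too_short`.
#'
#' @param sequence read sequence (character).
#' @param whitelist character vector of barcodes, all of
#'   `params$barcode_length` nt.
#' @param params parameter list from [demuxParams()].
#' @return list with `status` (`assigned`/`ambiguous`/`unassigned`/
#'   `too_short`), `barcode`, `orientation` (`forward`/
#'   `reverse_complement`), `position` (1-based in the read), and
#'   `mismatches` (`NA` unless assigned).
#' @export
assignBarcode <- function(sequence, whitelist, params = demuxParams()) {
  if (!length(whitelist)) stop("empty whitelist")
  if (any(nchar(whitelist) != params$barcode_length))
    stop(sprintf("whitelist barcodes must all be %d nt", params$barcode_length))
  no_hit <- list(status = "unassigned", barcode = NA_character_,
                 orientation = NA_character_, position = NA_integer_,
                 mismatches = NA_integer_)
  L <- nchar(sequence)
  if (L <= params$min_read_length)
    return(within_status(no_hit, "too_short"))
  w <- min(params$window, L)
  windows <- list(
    list(seq = substr(sequence, 1L, w), offset = 0L),
    list(seq = substr(sequence, L - w + 1L, L), offset = L - w)
  )
  rc <- .revcomp(whitelist)
  best <- NULL
  for (win in windows) {
    for (b in seq_along(whitelist)) {
      for (ori in c("forward", "reverse_complement")) {
        pat <- if (ori == "forward") whitelist[b] else rc[b]
        hit <- hammingScan(win$seq, pat)
        if (is.na(hit$mismatches) || hit$mismatches > params$max_mismatches) next
        cand <- list(barcode = whitelist[b], orientation = ori,
                     position = hit$position + win$offset,
                     mismatches = hit$mismatches)
        if (is.null(best) || cand$mismatches < best$mismatches) {
          best <- cand
          best$tied <- FALSE
        } else if (cand$mismatches == best$mismatches &&
                   cand$barcode != best$barcode) {
          best$tied <- TRUE
        }
      }
    }
  }
  if (is.null(best)) return(no_hit)
  if (best$tied)
    return(within_status(no_hit, "ambiguous"))
  list(status = "assigned", barcode = best$barcode,
       orientation = best$orientation, position = best$position,
       mismatches = best$mismatches)
}

within_status <- function(x, status) { x$status <- status; x }

# Mismatch-tolerant marker presence: the marker (or its reverse complement)
# occurs somewhere in the read with at most `tol` substitutions.
.hasMarker <- function(read, marker, tol) {
  mm <- .hammingAll(read, marker)
  if (length(mm) && min(mm) <= tol) return(TRUE)
  mm <- .hammingAll(read, .revcomp(marker))
  length(mm) && min(mm) <= tol
}

#' Classify a long read as fusion, canonical or other
#'
#' A read is a *fusion read* when it contains the 5'-partner exon 4
#' marker, the junction marker and the 3'-partner exon 3 marker; a
#' *canonical read* when it contains the 5'-partner exon 4 and exon 7
#' markers; anything else is *other*. Marker search is mismatch-tolerant
#' (up to `tolerance` of the marker length, both orientations). A read
#' matching both rule sets is returned as `other` with a conflict flag.
#'
#' @param sequence read sequence (character).
#' @param markers named list with elements `tcf7_e4`, `spi1_e3`, `tcf7_e7`
#'   and `junction` (character sequences), e.g. from [fusionMarkers()].
#' @param tolerance mismatches allowed per marker, as a fraction of marker
#'   length.
#' @return list with `class` (`fusion`/`canonical`/`other`) and `conflict`
#'   (logical).
#' @export
classifyRead <- function(sequence, markers, tolerance = 0.10) {
  need <- c("tcf7_e4", "spi1_e3", "tcf7_e7", "junction")
  miss <- setdiff(need, names(markers))
  if (length(miss))
    stop("missing marker(s): ", paste(miss, collapse = ", "))
  has <- vapply(need, function(nm) {
    .hasMarker(sequence, markers[[nm]], floor(tolerance * nchar(markers[[nm]])))
  }, logical(1))
  is_fusion <- has["tcf7_e4"] && has["junction"] && has["spi1_e3"]
  is_canonical <- has["tcf7_e4"] && has["tcf7_e7"]
  if (is_fusion && is_canonical)
    return(list(class = "other", conflict = TRUE))
  if (is_fusion) return(list(class = "fusion", conflict = FALSE))
  if (is_canonical) return(list(class = "canonical", conflict = FALSE))
  list(class = "other", conflict = FALSE)
}

#' Demultiplex a FASTQ of long reads and classify them
#'
#' Runs [assignBarcode()] and [classifyRead()] over every read, writes one
#' FASTQ per cell containing exactly the reads assigned to that barcode,
#' and summarises per-cell assigned/fusion/canonical counts. Total reads
#' are conserved: assigned + ambiguous + unassigned + too_short equals the
#' input count.
#'
#' @param fastq path to the input FASTQ (or a read `data.frame` from
#'   [readFastq()]).
#' @param whitelist character vector of cell barcodes.
#' @param markers marker list as in [classifyRead()].
#' @param params parameter list from [demuxParams()].
#' @param out_dir directory for per-cell FASTQ files and the JSON run
#'   report; `NULL` skips writing.
#' @param verbose log per-stage counts.
#' @return list with `assignments` (per-read `data.frame`: `read_id`,
#'   `status`, `barcode`, `orientation`, `position`, `mismatches`,
#'   `read_class`, `conflict`), `summary` (per-cell `data.frame`:
#'   `barcode`, `n_assigned`, `n_fusion`, `n_canonical`, `n_other`) and
#'   `counts` (named totals by status).
#' @export
demuxRun <- function(fastq, whitelist, markers, params = demuxParams(),
                     out_dir = NULL, verbose = FALSE) {
  reads <- if (is.character(fastq)) readFastq(fastq) else fastq
  n <- nrow(reads)
  res <- vector("list", n)
  for (i in seq_len(n)) {
    a <- assignBarcode(reads$sequence[i], whitelist, params)
    cl <- if (a$status == "assigned") classifyRead(reads$sequence[i], markers)
          else list(class = NA_character_, conflict = NA)
    res[[i]] <- data.frame(read_id = reads$read_id[i], status = a$status,
                           barcode = a$barcode, orientation = a$orientation,
                           position = a$position, mismatches = a$mismatches,
                           read_class = cl$class, conflict = cl$conflict,
                           stringsAsFactors = FALSE)
  }
  assignments <- do.call(rbind, res)
  if (is.null(assignments))
    assignments <- data.frame(read_id = character(), status = character(),
                              barcode = character(), orientation = character(),
                              position = integer(), mismatches = integer(),
                              read_class = character(), conflict = logical())
  counts <- vapply(c("assigned", "ambiguous", "unassigned", "too_short"),
                   function(s) sum(assignments$status == s), integer(1))
  summary <- do.call(rbind, lapply(whitelist, function(bc) {
    sel <- assignments$status == "assigned" & assignments$barcode == bc
    data.frame(barcode = bc, n_assigned = sum(sel),
               n_fusion = sum(sel & assignments$read_class == "fusion"),
               n_canonical = sum(sel & assignments$read_class == "canonical"),
               n_other = sum(sel & assignments$read_class == "other"),
               stringsAsFactors = FALSE)
  }))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (bc in whitelist) {
      sel <- assignments$status == "assigned" & assignments$barcode == bc
      writeFastq(reads[match(assignments$read_id[sel], reads$read_id), ],
                 file.path(out_dir, paste0(bc, ".fastq")))
    }
    write.table(summary, file.path(out_dir, "demux_summary.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    writeJsonSummary(c(list(n_reads = n), as.list(counts),
                       list(n_fusion = sum(summary$n_fusion),
                            n_canonical = sum(summary$n_canonical))),
                     file.path(out_dir, "demux_report.json"))
  }
  if (verbose)
    message(sprintf(
      "demuxRun: %d reads; %d assigned, %d ambiguous, %d unassigned, %d too short",
      n, counts["assigned"], counts["ambiguous"], counts["unassigned"],
      counts["too_short"]))
  list(assignments = assignments, summary = summary, counts = counts)
}
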