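#' Construct a gene model
#'
#' @param name gene symbol.
#' @param strand `"+"` or `"-"`.
#' @param exon_starts,exon_ends genomic exon coordinates (1-based
#'   inclusive), given in transcript (5'->3') order: increasing on `"+"`,
#'   decreasing on `"-"`.
#' @param protein_length length of the encoded protein in amino acids.
#' @param domains `data.frame` with columns `domain`, `start`, `end`
#'   (protein coordinates, 1-based inclusive).
#' @return a [GeneModel-class] object.
#' @examples
#' GeneModel("TCF7", "+", c(100, 300, 500), c(199, 399, 599), 384,
#'           data.frame(domain = "CTNNB1", start = 1, end = 55))
#' @export
GeneModel <- function(name, strand, exon_starts, exon_ends, protein_length,
                      domains = data.frame(domain = character(),
                                           start = integer(), end = integer())) {
  stopifnot(length(exon_starts) == length(exon_ends))
  new("GeneModel", name = name, strand = strand,
      exons = IRanges::IRanges(start = pmin(exon_starts, exon_ends),
                               end = pmax(exon_starts, exon_ends)),
      proteinLength = as.integer(protein_length),
      domains = as.data.frame(domains))
}

#' Read gene models from exon and domain TSV tables
#'
#' The exon table is a minimal GFF-like TSV with columns `gene`, `strand`,
#' `exon` (1-based index in transcript order), `start`, `end`
#' (1-based inclusive genomic coordinates) and `protein_length`. The
#' optional domain table has columns `gene`, `domain`, `start`, `end`
#' (protein coordinates).
#'
#' @param exon_path path to the exon TSV.
#' @param domain_path optional path to the domain TSV.
#' @return named list of [GeneModel-class] objects.
#' @export
readGeneModels <- function(exon_path, domain_path = NULL) {
  ex <- read.delim(exon_path, stringsAsFactors = FALSE)
  need <- c("gene", "strand", "exon", "start", "end", "protein_length")
  miss <- setdiff(need, names(ex))
  if (length(miss))
    stop("exon table is missing column(s): ", paste(miss, collapse = ", "))
  doms <- if (!is.null(domain_path)) read.delim(domain_path, stringsAsFactors = FALSE)
          else data.frame(gene = character(), domain = character(),
                          start = integer(), end = integer())
  lapply(split(ex, ex$gene)[unique(ex$gene)], function(g) {
    g <- g[order(g$exon), ]
    d <- doms[doms$gene == g$gene[1L], c("domain", "start", "end")]
    GeneModel(g$gene[1L], g$strand[1L], g$start, g$end, g$protein_length[1L], d)
  })
}

# Which exons of `gene` lie 5' (side = "five") or 3' (side = "three") of an
# intronic genomic position. Errors if the position falls inside an exon.
.retainedExons <- function(gene, pos, side) {
  s <- IRanges::start(exons(gene)); e <- IRanges::end(exons(gene))
  inside <- which(pos >= s & pos <= e)
  if (length(inside))
    stop(sprintf("exonic breakpoint unsupported: position %d is inside %s exon %d",
                 pos, geneName(gene), inside[1L]))
  upstream <- if (gene@strand == "+") e < pos else s > pos
  idx <- which(upstream)
  if (side == "five") {
    if (!length(idx))
      stop(sprintf("breakpoint lies upstream of every %s exon", geneName(gene)))
    seq_len(max(idx))
  } else {
    keep <- setdiff(seq_along(s), seq_len(if (length(idx)) max(idx) else 0L))
    if (!length(keep))
      stop(sprintf("breakpoint lies downstream of every %s exon", geneName(gene)))
    keep
  }
}

#' Build the exon structure of a fusion transcript
#'
#' Joins the exons of the 5' partner upstream of its intronic breakpoint to
#' the exons of the 3' partner downstream of its intronic breakpoint. Any
#' position within the same intron yields the same transcript; a position
#' inside an exon is an error (`"exonic breakpoint unsupported"`).
#'
#' @param geneA,geneB [GeneModel-class] objects for the 5' and 3' partner.
#' @param breakA,breakB intronic genomic breakpoint positions (1-based)
#'   in each gene's coordinate system.
#' @return `data.frame` with columns `gene`, `exon` (index in the parent
#'   transcript), `start`, `end`, in fusion transcript order.
#' @examples
#' tcf7 <- GeneModel("TCF7", "+", seq(1, 601, 100), seq(40, 640, 100), 384)
#' spi1 <- GeneModel("SPI1", "+", seq(1, 401, 100), seq(40, 440, 100), 271)
#' buildFusionTranscript(tcf7, spi1, breakA = 350, breakB = 250)
#' @export
buildFusionTranscript <- function(geneA, geneB, breakA, breakB) {
  ia <- .retainedExons(geneA, breakA, "five")
  ib <- .retainedExons(geneB, breakB, "three")
  rbind(
    data.frame(gene = geneName(geneA), exon = ia,
               start = IRanges::start(exons(geneA))[ia],
               end = IRanges::end(exons(geneA))[ia]),
    data.frame(gene = geneName(geneB), exon = ib,
               start = IRanges::start(exons(geneB))[ib],
               end = IRanges::end(exons(geneB))[ib])
  )
}

#' Model the fusion protein from segment coordinates
#'
#' Joins the amino-terminal segment of protein A (residues 1..`a_end`) to
#' the segment `b_start`..`b_end` of protein B. The fusion length is
#' `a_end + (b_end - b_start + 1)`. A domain is retained only when it lies
#' fully inside its retained segment; retained B domains are shifted into
#' fusion coordinates by `a_end - b_start + 1`.
#'
#' @param a_end last retained residue of protein A.
#' @param b_start,b_end first and last retained residues of protein B.
#' @param domainsA,domainsB optional `data.frame`s (`domain`, `start`,
#'   `end`) of protein domains in each parent's coordinates.
#' @param fiveName,threeName partner gene names for reporting.
#' @param exons optional fusion exon table from [buildFusionTranscript()].
#' @param fiveLastExon,threeFirstExon optional exon indices for reporting.
#' @return a [FusionModel-class] object.
#' @examples
#' # TCF1 residues 1-182 joined to PU.1 residues 52-271: 402 aa
#' totalLength(fusionProtein(182, 52, 271))
#' @export
fusionProtein <- function(a_end, b_start, b_end,
                          domainsA = NULL, domainsB = NULL,
                          fiveName = "geneA", threeName = "geneB",
                          exons = NULL,
                          fiveLastExon = NA_integer_,
                          threeFirstExon = NA_integer_) {
  a_end <- as.integer(a_end); b_start <- as.integer(b_start); b_end <- as.integer(b_end)
  if (a_end < 1L) stop("'a_end' must be >= 1")
  if (b_start < 1L || b_start > b_end) stop("need 1 <= b_start <= b_end")
  shift <- a_end - b_start + 1L
  dom <- data.frame(domain = character(), origin = character(),
                    start = integer(), end = integer())
  if (!is.null(domainsA) && nrow(domainsA)) {
    keep <- domainsA$end <= a_end & domainsA$start >= 1L
    if (any(keep))
      dom <- rbind(dom, data.frame(domain = domainsA$domain[keep],
                                   origin = fiveName,
                                   start = as.integer(domainsA$start[keep]),
                                   end = as.integer(domainsA$end[keep])))
  }
  if (!is.null(domainsB) && nrow(domainsB)) {
    keep <- domainsB$start >= b_start & domainsB$end <= b_end
    if (any(keep))
      dom <- rbind(dom, data.frame(domain = domainsB$domain[keep],
                                   origin = threeName,
                                   start = as.integer(domainsB$start[keep]) + shift,
                                   end = as.integer(domainsB$end[keep]) + shift))
  }
  new("FusionModel",
      fiveName = fiveName, threeName = threeName,
      fiveLastExon = as.integer(fiveLastExon),
      threeFirstExon = as.integer(threeFirstExon),
      exons = if (is.null(exons)) data.frame(gene = character(), exon = integer(),
                                             start = integer(), end = integer())
              else exons,
      aEnd = a_end, bStart = b_start, bEnd = b_end,
      totalLength = a_end + (b_end - b_start + 1L),
      domains = dom)
}

#' Build a full fusion model from gene models and breakpoints
#'
#' Convenience wrapper combining [buildFusionTranscript()] and
#' [fusionProtein()].
#'
#' @inheritParams buildFusionTranscript
#' @inheritParams fusionProtein
#' @return a [FusionModel-class] object with exon structure attached.
#' @export
fusionModel <- function(geneA, geneB, breakA, breakB, a_end, b_start, b_end) {
  ex <- buildFusionTranscript(geneA, geneB, breakA, breakB)
  nA <- sum(ex$gene == geneName(geneA))
  fusionProtein(a_end, b_start, b_end,
                domainsA = domains(geneA), domainsB = domains(geneB),
                fiveName = geneName(geneA), threeName = geneName(geneB),
                exons = ex,
                fiveLastExon = ex$exon[nA],
                threeFirstExon = ex$exon[nA + 1L])
}

#' Amino-terminal truncation of a fusion protein
#'
#' Removes the first `n_removed` residues of the fusion protein (for
#' example deleting the beta-catenin binding region at the N-terminus) and
#' reports the resulting length and surviving domains. Domains overlapping
#' the removed region are dropped; the rest are shifted left by
#' `n_removed`.
#'
#' @param fm a [FusionModel-class] object.
#' @param n_removed number of N-terminal residues removed; must be less
#'   than the fusion A-segment length.
#' @return list with `total_length`, `removed` and `domains` (shifted).
#' @examples
#' fm <- fusionProtein(182, 52, 271)
#' removeNTerminal(fm, 55)$total_length  # 347
#' @export
removeNTerminal <- function(fm, n_removed) {
  stopifnot(is(fm, "FusionModel"))
  n_removed <- as.integer(n_removed)
  if (n_removed < 1L || n_removed >= fm@aEnd)
    stop("'n_removed' must be in [1, aEnd)")
  dom <- fm@domains
  if (nrow(dom)) {
    keep <- dom$start > n_removed
    dom <- dom[keep, , drop = FALSE]
    dom$start <- dom$start - n_removed
    dom$end <- dom$end - n_removed
  }
  list(total_length = fm@totalLength - n_removed, removed = n_removed,
       domains = dom)
}

#' Does a read support the fusion breakpoint?
#'
#' A read supports the fusion when it aligns across the junction with at
#' least `m` consecutive bases on each side of the breakpoint, allowing at
#' most `max_mismatches_per_side` substitutions per side. The junction is
#' described by a window of `2k` nt centred on the breakpoint.
#'
#' @param read read sequence (character).
#' @param junction_window even-length sequence centred on the junction;
#'   must be at least `2m` nt.
#' @param m matched bases required on each side of the junction.
#' @param max_mismatches_per_side substitutions tolerated per side.
#' @return `TRUE` if the read supports the fusion junction.
#' @export
classifyBreakpointRead <- function(read, junction_window, m = 20L,
                                   max_mismatches_per_side = 2L) {
  k2 <- nchar(junction_window)
  if (k2 %% 2L != 0L) stop("junction window must have even length")
  if (k2 < 2L * m) stop("junction window shorter than 2m")
  k <- k2 %/% 2L
  left <- substr(junction_window, k - m + 1L, k)
  right <- substr(junction_window, k + 1L, k + m)
  L <- nchar(read)
  if (L < 2L * m) return(FALSE)
  mmL <- .hammingAll(read, left)
  mmR <- .hammingAll(read, right)
  # left core at offset o must be followed immediately by the right core
  o <- seq_len(L - 2L * m + 1L)
  any(mmL[o] <= max_mismatches_per_side & mmR[o + m] <= max_mismatches_per_side)
}
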