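#' @import methods
#' @importClassesFrom IRanges IRanges
#' @importFrom stats dhyper p.adjust pchisq pnorm pt qnorm optimize uniroot
#'   rbinom rnbinom rnorm runif sd var cor setNames
#' @importFrom utils head read.delim write.table
NULL

#' Gene model with exons, protein length and domain annotation
#'
#' A minimal transcript-centric gene model: exons are stored in transcript
#' (5'->3') order as an [IRanges::IRanges] of genomic intervals, together
#' with the encoded protein length and named protein domains in 1-based
#' inclusive amino-acid coordinates.
#'
#' @slot name gene symbol.
#' @slot strand `"+"` or `"-"`.
#' @slot exons [IRanges::IRanges] of exon intervals in transcript order
#'   (genomic starts increase on `"+"`, decrease on `"-"`).
#' @slot proteinLength integer, length of the encoded protein in aa.
#' @slot domains `data.frame` with columns `domain`, `start`, `end`
#'   (aa, 1-based inclusive).
#'
#' @seealso [GeneModel()] for the user constructor.
#' @exportClass GeneModel
setClass("GeneModel",
  representation(
    name = "character",
    strand = "character",
    exons = "IRanges",
    proteinLength = "integer",
    domains = "data.frame"
  )
)

setValidity("GeneModel", function(object) {
  msg <- character()
  if (length(object@name) != 1L || !nzchar(object@name))
    msg <- c(msg, "'name' must be a single non-empty string")
  if (!identical(object@strand, "+") && !identical(object@strand, "-"))
    msg <- c(msg, "'strand' must be \"+\" or \"-\"")
  ex <- object@exons
  if (length(ex) == 0L) msg <- c(msg, "gene model needs at least one exon")
  if (length(ex) > 1L) {
    s <- IRanges::start(ex); e <- IRanges::end(ex)
    ordered <- if (identical(object@strand, "-")) {
      all(diff(s) < 0) && all(utils::head(s, -1) > e[-1])
    } else {
      all(diff(s) > 0) && all(s[-1] > utils::head(e, -1))
    }
    if (!ordered)
      msg <- c(msg, "exons must be non-overlapping and in 5'->3' transcript order")
  }
  if (length(object@proteinLength) != 1L || is.na(object@proteinLength) ||
      object@proteinLength < 1L)
    msg <- c(msg, "'proteinLength' must be a positive integer")
  d <- object@domains
  if (nrow(d)) {
    if (!all(c("domain", "start", "end") %in% names(d)))
      msg <- c(msg, "'domains' needs columns domain, start, end")
    else if (any(d$start < 1L) || any(d$end > object@proteinLength) ||
             any(d$start > d$end))
      msg <- c(msg, "domains must lie within [1, proteinLength]")
  }
  if (length(msg)) msg else TRUE
})

#' Fusion transcript/protein model
#'
#' Result of joining the 5' part of one gene model to the 3' part of
#' another at intronic breakpoints. Holds the fused exon table, the two
#' protein segments in the coordinates of their parent proteins, the total
#' fusion protein length and the domains retained in the fusion (in fusion
#' protein coordinates, 1-based inclusive).
#'
#' @slot fiveName,threeName names of the 5' and 3' partner genes.
#' @slot fiveLastExon index (1-based, transcript order) of the last
#'   retained 5'-partner exon.
#' @slot threeFirstExon index of the first retained 3'-partner exon.
#' @slot exons `data.frame` with columns `gene`, `exon`, `start`, `end`.
#' @slot aEnd last residue of the 5' (A) segment in A's protein coordinates.
#' @slot bStart,bEnd first and last residues of the 3' (B) segment in B's
#'   protein coordinates.
#' @slot totalLength total fusion protein length in aa,
#'   `aEnd + (bEnd - bStart + 1)`.
#' @slot domains `data.frame` of retained domains: `domain`, `origin`,
#'   `start`, `end` in fusion protein coordinates.
#'
#' @seealso [fusionProtein()], [buildFusionTranscript()]
#' @exportClass FusionModel
setClass("FusionModel",
  representation(
    fiveName = "character",
    threeName = "character",
    fiveLastExon = "integer",
    threeFirstExon = "integer",
    exons = "data.frame",
    aEnd = "integer",
    bStart = "integer",
    bEnd = "integer",
    totalLength = "integer",
    domains = "data.frame"
  )
)

setValidity("FusionModel", function(object) {
  msg <- character()
  if (object@aEnd < 1L) msg <- c(msg, "'aEnd' must be >= 1")
  if (object@bStart < 1L || object@bStart > object@bEnd)
    msg <- c(msg, "need 1 <= bStart <= bEnd")
  expected <- object@aEnd + (object@bEnd - object@bStart + 1L)
  if (object@totalLength != expected)
    msg <- c(msg, sprintf("totalLength %d != aEnd + (bEnd - bStart + 1) = %d",
                          object@totalLength, expected))
  if (length(msg)) msg else TRUE
})

#' Single-hit limiting dilution estimate
#'
#' Maximum-likelihood estimate of the active-cell frequency under the
#' single-hit Poisson model P(response at dose d) = 1 - exp(-d f), with a
#' Wald 95% confidence interval computed on log f.
#'
#' @slot fHat estimated frequency, cells^-1.
#' @slot oneIn `1 / fHat`, the "1 in N cells" form.
#' @slot ciLower,ciUpper 95% CI bounds on the frequency scale.
#' @slot logLik maximised log-likelihood.
#' @slot table the input dose-response `data.frame`.
#'
#' @seealso [fitSingleHit()]
#' @exportClass LDAEstimate
setClass("LDAEstimate",
  representation(
    fHat = "numeric",
    oneIn = "numeric",
    ciLower = "numeric",
    ciUpper = "numeric",
    logLik = "numeric",
    table = "data.frame"
  )
)

setValidity("LDAEstimate", function(object) {
  msg <- character()
  if (object@fHat <= 0 || object@fHat >= 1)
    msg <- c(msg, "'fHat' must be in (0, 1)")
  if (object@ciLower > object@fHat || object@ciUpper < object@fHat)
    msg <- c(msg, "confidence interval must contain fHat")
  if (length(msg)) msg else TRUE
})

#' Pre-ranked enrichment result
#'
#' Weighted Kolmogorov-Smirnov-style enrichment score of a gene set against
#' a ranked list, with a gene-set permutation p-value and a sign-matched
#' normalised score.
#'
#' @slot es enrichment score, in [-1, 1].
#' @slot nes normalised enrichment score (ES / mean |null ES| of matching
#'   sign); `NA` if no null scores share the sign of `es`.
#' @slot pValue permutation p-value, in [1/(nPerm+1), 1].
#' @slot nPerm number of permutations used.
#' @slot leadingEdge genes driving the score (hits up to the extremum for
#'   positive ES, from the extremum onward for negative ES).
#'
#' @seealso [permutationTest()], [enrichmentScore()]
#' @exportClass EnrichmentResult
setClass("EnrichmentResult",
  representation(
    es = "numeric",
    nes = "numeric",
    pValue = "numeric",
    nPerm = "integer",
    leadingEdge = "character"
  )
)

setValidity("EnrichmentResult", function(object) {
  msg <- character()
  if (abs(object@es) > 1 + 1e-12) msg <- c(msg, "|es| must be <= 1")
  lo <- 1 / (object@nPerm + 1)
  if (object@pValue < lo - 1e-12 || object@pValue > 1)
    msg <- c(msg, "pValue must be in [1/(nPerm+1), 1]")
  if (length(msg)) msg else TRUE
})
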