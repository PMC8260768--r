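#' @rdname GeneModel-class
#' @export
setMethod("geneName", "GeneModel", function(x) x@name)

#' @rdname GeneModel-class
#' @export
setMethod("exons", "GeneModel", function(x) x@exons)

#' @rdname GeneModel-class
#' @export
setMethod("proteinLength", "GeneModel", function(x) x@proteinLength)

#' @rdname GeneModel-class
#' @export
setMethod("domains", "GeneModel", function(x) x@domains)

#' @rdname GeneModel-class
#' @export
setMethod("show", "GeneModel", function(object) {
  cat("GeneModel:", object@name, sprintf("(%s strand)\n", object@strand))
  cat("  ", length(object@exons), "exons;",
      object@proteinLength, "aa protein;",
      nrow(object@domains), "domains\n")
  invisible(object)
})

#' @rdname FusionModel-class
#' @export
setMethod("totalLength", "FusionModel", function(x) x@totalLength)

#' @rdname FusionModel-class
#' @export
setMethod("fusionExons", "FusionModel", function(x) x@exons)

#' @rdname FusionModel-class
#' @export
setMethod("retainedDomains", "FusionModel", function(x) x@domains)

#' @rdname FusionModel-class
#' @export
setMethod("proteinSegments", "FusionModel", function(x) {
  data.frame(
    segment = c("A", "B"),
    gene = c(x@fiveName, x@threeName),
    from = c(1L, x@bStart),
    to = c(x@aEnd, x@bEnd),
    fusion_from = c(1L, x@aEnd + 1L),
    fusion_to = c(x@aEnd, x@totalLength)
  )
})

#' @rdname FusionModel-class
#' @param object a `FusionModel`.
#' @export
setMethod("show", "FusionModel", function(object) {
  cat(sprintf("FusionModel: %s-%s\n", object@fiveName, object@threeName))
  cat(sprintf("  protein: %s 1-%d + %s %d-%d = %d aa\n",
              object@fiveName, object@aEnd,
              object@threeName, object@bStart, object@bEnd,
              object@totalLength))
  if (nrow(object@exons))
    cat("  exons:",
        paste(sprintf("%s:%d", object@exons$gene, object@exons$exon),
              collapse = " "), "\n")
  if (nrow(object@domains))
    cat("  retained domains:",
        paste(object@domains$domain, collapse = ", "), "\n")
  invisible(object)
})

#' @rdname LDAEstimate-class
#' @export
setMethod("fHat", "LDAEstimate", function(x) x@fHat)

#' @rdname LDAEstimate-class
#' @export
setMethod("oneIn", "LDAEstimate", function(x) x@oneIn)

#' @rdname LDAEstimate-class
#' @export
setMethod("freqCI", "LDAEstimate", function(x) c(lower = x@ciLower, upper = x@ciUpper))

#' @rdname LDAEstimate-class
#' @param object an `LDAEstimate`.
#' @export
setMethod("show", "LDAEstimate", function(object) {
  cat("LDAEstimate (single-hit model)\n")
  cat(sprintf("  frequency: %.4g  (1 in %.0f cells)\n", object@fHat, object@oneIn))
  cat(sprintf("  95%% CI: 1 in %.0f - 1 in %.0f\n",
              1 / object@ciUpper, 1 / object@ciLower))
  invisible(object)
})

#' @rdname EnrichmentResult-class
#' @export
setMethod("esStat", "EnrichmentResult", function(x) x@es)

#' @rdname EnrichmentResult-class
#' @export
setMethod("nesStat", "EnrichmentResult", function(x) x@nes)

#' @rdname EnrichmentResult-class
#' @export
setMethod("permPValue", "EnrichmentResult", function(x) x@pValue)

#' @rdname EnrichmentResult-class
#' @export
setMethod("leadingEdge", "EnrichmentResult", function(x) x@leadingEdge)

#' @rdname EnrichmentResult-class
#' @param object an `EnrichmentResult`.
#' @export
setMethod("show", "EnrichmentResult", function(object) {
  cat(sprintf("EnrichmentResult: ES = %.3f, NES = %.3f, p = %.4g (%d permutations)\n",
              object@es, object@nes, object@pValue, object@nPerm))
  cat(sprintf("  leading edge: %d genes\n", length(object@leadingEdge)))
  invisible(object)
})
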