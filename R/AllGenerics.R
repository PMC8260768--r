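#' @rdname GeneModel-class
#' @param object,x a `GeneModel`, `FusionModel`, `LDAEstimate` or
#'   `EnrichmentResult` as documented on each method.
#' @export
setGeneric("geneName", function(x) standardGeneric("geneName"))

#' @rdname GeneModel-class
#' @export
setGeneric("exons", function(x) standardGeneric("exons"))

#' @rdname GeneModel-class
#' @export
setGeneric("proteinLength", function(x) standardGeneric("proteinLength"))

#' @rdname GeneModel-class
#' @export
setGeneric("domains", function(x) standardGeneric("domains"))

#' @rdname FusionModel-class
#' @param x object.
#' @export
setGeneric("totalLength", function(x) standardGeneric("totalLength"))

#' @rdname FusionModel-class
#' @export
setGeneric("fusionExons", function(x) standardGeneric("fusionExons"))

#' @rdname FusionModel-class
#' @export
setGeneric("retainedDomains", function(x) standardGeneric("retainedDomains"))

#' @rdname FusionModel-class
#' @export
setGeneric("proteinSegments", function(x) standardGeneric("proteinSegments"))

#' @rdname LDAEstimate-class
#' @param x object.
#' @export
setGeneric("fHat", function(x) standardGeneric("fHat"))

#' @rdname LDAEstimate-class
#' @export
setGeneric("oneIn", function(x) standardGeneric("oneIn"))

#' @rdname LDAEstimate-class
#' @export
setGeneric("freqCI", function(x) standardGeneric("freqCI"))

#' @rdname EnrichmentResult-class
#' @param x object.
#' @export
setGeneric("esStat", function(x) standardGeneric("esStat"))

#' @rdname EnrichmentResult-class
#' @export
setGeneric("nesStat", function(x) standardGeneric("nesStat"))

#' @rdname EnrichmentResult-class
#' @export
setGeneric("permPValue", function(x) standardGeneric("permPValue"))

#' @rdname EnrichmentResult-class
#' @export
setGeneric("leadingEdge", function(x) standardGeneric("leadingEdge"))
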