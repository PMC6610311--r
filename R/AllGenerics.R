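#' @rdname CommunitySet-class
#' @param x a `CommunitySet`
#' @export
setGeneric("communityTree", function(x) standardGeneric("communityTree"))

#' @rdname CommunitySet-class
#' @export
setGeneric("communityCounts", function(x) standardGeneric("communityCounts"))

#' @rdname CommunitySet-class
#' @export
setGeneric("sampleData", function(x) standardGeneric("sampleData"))

#' @rdname CommunitySet-class
#' @export
setGeneric("taxonNames", function(x) standardGeneric("taxonNames"))

#' @rdname CommunitySet-class
#' @export
setGeneric("sampleNames", function(x) standardGeneric("sampleNames"))

#' @rdname CommunitySet-class
#' @export
setGeneric("sampleGroups", function(x) standardGeneric("sampleGroups"))

#' @rdname TurnoverResult-class
#' @param x a `TurnoverResult`
#' @export
setGeneric("turnoverPairs", function(x) standardGeneric("turnoverPairs"))

#' @rdname ProcessSummary-class
#' @param x a `ProcessSummary`
#' @export
setGeneric("processFractions", function(x) standardGeneric("processFractions"))

#' @rdname ProcessSummary-class
#' @export
setGeneric("processCounts", function(x) standardGeneric("processCounts"))

#' @rdname sesMNTD
#' @export
setGeneric("sesMNTD", function(x, ...) standardGeneric("sesMNTD"))

#' @rdname betaNTI
#' @export
setGeneric("betaNTI", function(x, ...) standardGeneric("betaNTI"))

#' @rdname rcBray
#' @export
setGeneric("rcBray", function(x, ...) standardGeneric("rcBray"))
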