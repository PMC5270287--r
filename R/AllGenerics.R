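#' @rdname VariantCohort-class
#' @export
setGeneric("calls", function(x) standardGeneric("calls"))

#' @rdname VariantCohort-class
#' @export
setGeneric("variantKeys", function(x) standardGeneric("variantKeys"))

#' @rdname Pedigree-class
#' @export
setGeneric("families", function(x) standardGeneric("families"))

#' @rdname Pedigree-class
#' @export
setGeneric("familyMembers", function(x, family) standardGeneric("familyMembers"))

#' @rdname Pedigree-class
#' @export
setGeneric("affectedIds", function(x, family) standardGeneric("affectedIds"))

#' @rdname Pedigree-class
#' @export
setGeneric("unaffectedIds", function(x, family) standardGeneric("unaffectedIds"))

#' @rdname FilterTrace-class
#' @export
setGeneric("traceCounts", function(x) standardGeneric("traceCounts"))

#' @rdname FilterTrace-class
#' @export
setGeneric("traceStages", function(x) standardGeneric("traceStages"))

#' @rdname summarizeTrace
#' @export
setGeneric("summarizeTrace", function(x, stage) standardGeneric("summarizeTrace"))

#' @rdname CaseControlCounts-class
#' @export
setGeneric("caseCounts", function(x) standardGeneric("caseCounts"))

#' @rdname CaseControlCounts-class
#' @export
setGeneric("controlCounts", function(x) standardGeneric("controlCounts"))
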