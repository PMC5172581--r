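#' @rdname GenotypePanel-accessors
#' @export
setGeneric("dosage", function(x) standardGeneric("dosage"))

#' @rdname GenotypePanel-accessors
#' @export
setGeneric("lineGroups", function(x) standardGeneric("lineGroups"))

#' @rdname GenotypePanel-accessors
#' @export
setGeneric("lineGroups<-", function(x, value) standardGeneric("lineGroups<-"))

#' @rdname GenotypePanel-accessors
#' @export
setGeneric("markerRanges", function(x) standardGeneric("markerRanges"))

#' @rdname DiversityProfile-accessors
#' @export
setGeneric("gdValues", function(x) standardGeneric("gdValues"))

#' @rdname DiversityProfile-accessors
#' @export
setGeneric("chromStats", function(x) standardGeneric("chromStats"))

#' @rdname vennCounts
#' @export
setGeneric("vennCounts", function(x) standardGeneric("vennCounts"))
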