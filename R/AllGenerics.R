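#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @export
setGeneric("sampleTotals", function(x) standardGeneric("sampleTotals"))

#' @export
setGeneric("chromCounts", function(x) standardGeneric("chromCounts"))

#' @export
setGeneric("binGC", function(x) standardGeneric("binGC"))

#' @export
setGeneric("binRetained", function(x) standardGeneric("binRetained"))

#' @export
setGeneric("targetChrom", function(x) standardGeneric("targetChrom"))

#' @export
setGeneric("referenceChroms", function(x) standardGeneric("referenceChroms"))

#' @export
setGeneric("subsampleCounts",
           function(x, nTarget, seed, ...) standardGeneric("subsampleCounts"))

#' @export
setGeneric("writeModel", function(model, path) standardGeneric("writeModel"))
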