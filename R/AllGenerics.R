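#' @rdname CtExperiment-accessors
#' @export
setGeneric("ctValues", function(x) standardGeneric("ctValues"))

#' @rdname CtExperiment-accessors
#' @export
setGeneric("mirnaNames", function(x) standardGeneric("mirnaNames"))

#' @rdname CtExperiment-accessors
#' @export
setGeneric("plates", function(x) standardGeneric("plates"))

#' @rdname CtExperiment-accessors
#' @export
setGeneric("duplicateGroups", function(x) standardGeneric("duplicateGroups"))

#' @rdname CtExperiment-accessors
#' @export
setGeneric("sampleGroups", function(x) standardGeneric("sampleGroups"))

#' @rdname CtExperiment-accessors
#' @export
setGeneric("ctMaxCycle", function(x) standardGeneric("ctMaxCycle"))
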