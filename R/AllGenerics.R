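#' @rdname smoothProfile
#' @export
setGeneric("smoothProfile", function(profile, window = 3L)
  standardGeneric("smoothProfile"))

#' @rdname countModes
#' @export
setGeneric("countModes", function(profile, modeTolerance = 0.02)
  standardGeneric("countModes"))

#' @rdname risesAfterMidlife
#' @export
setGeneric("risesAfterMidlife",
           function(profile, params = artClassifierParams())
  standardGeneric("risesAfterMidlife"))

#' @rdname classifyART
#' @export
setGeneric("classifyART", function(profile, params = artClassifierParams())
  standardGeneric("classifyART"))

#' @rdname PrevalenceProfile
#' @export
setGeneric("traitId", function(x) standardGeneric("traitId"))

#' @rdname PrevalenceProfile
#' @export
setGeneric("ageBins", function(x) standardGeneric("ageBins"))

#' @rdname PrevalenceProfile
#' @export
setGeneric("profileValues", function(x) standardGeneric("profileValues"))

#' @rdname PrevalenceProfile
#' @export
setGeneric("valueKind", function(x) standardGeneric("valueKind"))

#' @rdname PrevalenceProfile
#' @param x A `PrevalenceProfile`.
#' @export
setMethod("traitId", "PrevalenceProfile", function(x) x@traitId)

#' @rdname PrevalenceProfile
#' @export
setMethod("ageBins", "PrevalenceProfile", function(x) x@ageBins)

#' @rdname PrevalenceProfile
#' @export
setMethod("profileValues", "PrevalenceProfile", function(x) x@values)

#' @rdname PrevalenceProfile
#' @export
setMethod("valueKind", "PrevalenceProfile", function(x) x@valueKind)
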