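#' @rdname speciesCounts
#' @export
setGeneric("speciesCounts", function(object) standardGeneric("speciesCounts"))

#' @rdname speciesNames
#' @export
setGeneric("speciesNames", function(object, ...) standardGeneric("speciesNames"))

#' @rdname stateMatrix
#' @export
setGeneric("stateMatrix", function(object) standardGeneric("stateMatrix"))

#' @rdname stateMatrix
#' @export
setGeneric("inputMatrix", function(object) standardGeneric("inputMatrix"))

#' @rdname stateMatrix
#' @export
setGeneric("trajectoryTimes", function(object) standardGeneric("trajectoryTimes"))

#' @rdname plantStep
#' @export
setGeneric("plantStep", function(plant, input, ...) standardGeneric("plantStep"))

#' @rdname predictSurrogate
#' @export
setGeneric("predictSurrogate", function(model, v, ...)
  standardGeneric("predictSurrogate"))
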