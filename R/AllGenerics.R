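#' @rdname BeamProfile-class
#' @param object,x an object.
#' @export
setGeneric("doughnutRadius", function(x) standardGeneric("doughnutRadius"))

#' @rdname ExcitationSequence-class
#' @export
setGeneric("exposurePositions", function(x) standardGeneric("exposurePositions"))

#' @rdname ExcitationSequence-class
#' @export
setGeneric("numExposures", function(x) standardGeneric("numExposures"))

#' @rdname ExcitationSequence-class
#' @export
setGeneric("patternSize", function(x) standardGeneric("patternSize"))

#' @rdname CountRecord-class
#' @export
setGeneric("photonCounts", function(x) standardGeneric("photonCounts"))

#' @rdname PrecisionMap-class
#' @export
setGeneric("sigmaValues", function(x) standardGeneric("sigmaValues"))

#' Summary statistics of a precision map
#'
#' @param x a [PrecisionMap-class].
#' @return named list: `min`, `max`, `center` (value at the lattice node
#'   nearest the origin), `mean`, `cv` (coefficient of variation sd/mean)
#'   and `dynamicRange` (max/center), all over the full map lattice, in nm
#'   (ratios dimensionless).
#' @export
setGeneric("mapSummary", function(x) standardGeneric("mapSummary"))
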