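#' @include AllClasses.R
NULL

#' Accessor generics
#'
#' Small accessor generics for the wingmorph S4 containers. Slot access via
#' \code{@} is considered internal; these are the supported surface.
#'
#' @param x a wingmorph object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("markerCoords", function(x) standardGeneric("markerCoords"))

#' @rdname accessors
#' @export
setGeneric("markerLabels", function(x) standardGeneric("markerLabels"))

#' @rdname accessors
#' @export
setGeneric("frameTimes", function(x) standardGeneric("frameTimes"))

#' @rdname accessors
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' @rdname accessors
#' @export
setGeneric("nLandmarks", function(x) standardGeneric("nLandmarks"))

#' @rdname accessors
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))

#' @rdname accessors
#' @export
setGeneric("templateCoords", function(x) standardGeneric("templateCoords"))

#' @rdname accessors
#' @export
setGeneric("shapeScores", function(x) standardGeneric("shapeScores"))

#' @rdname accessors
#' @export
setGeneric("singularValues", function(x) standardGeneric("singularValues"))

#' @rdname accessors
#' @export
setGeneric("varianceProportions",
  function(x) standardGeneric("varianceProportions"))

#' @rdname accessors
#' @export
setGeneric("tangentMatrix", function(x) standardGeneric("tangentMatrix"))

#' @rdname accessors
#' @export
setGeneric("meshArea", function(x) standardGeneric("meshArea"))

#' @rdname accessors
#' @export
setGeneric("strokePhase", function(x) standardGeneric("strokePhase"))

#' @rdname accessors
#' @export
setGeneric("descriptorFrame", function(x) standardGeneric("descriptorFrame"))
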