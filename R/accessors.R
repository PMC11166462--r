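#' @include AllGenerics.R
NULL

#' @rdname accessors
setMethod("markerCoords", "MarkerTimeSeries", function(x) x@coords)

#' @rdname accessors
setMethod("markerCoords", "WingPlanform", function(x) x@coords)

#' @rdname accessors
setMethod("markerLabels", "MarkerTimeSeries", function(x) x@labels)

#' @rdname accessors
setMethod("frameTimes", "MarkerTimeSeries", function(x) x@times)

#' @rdname accessors
setMethod("nFrames", "MarkerTimeSeries", function(x) dim(x@coords)[1])

#' @rdname accessors
setMethod("nLandmarks", "MarkerTimeSeries", function(x) dim(x@coords)[2])

#' @rdname accessors
setMethod("nLandmarks", "WingPlanform", function(x) nrow(x@coords))

#' @rdname accessors
setMethod("samplingRate", "MarkerTimeSeries", function(x)
  1 / mean(diff(x@times)))

#' @rdname accessors
setMethod("samplingRate", "SimulationConfig", function(x) x@samplingRate)

#' @rdname accessors
setMethod("templateCoords", "TemplateShape", function(x) x@coords)

#' @rdname accessors
setMethod("templateCoords", "ShapeBasis", function(x) x@template@coords)

#' @rdname accessors
setMethod("shapeScores", "ShapeScores", function(x) x@scores)

#' @rdname accessors
setMethod("singularValues", "ShapeBasis", function(x) x@d)

#' @rdname accessors
setMethod("varianceProportions", "ShapeBasis", function(x)
  x@varianceProportions)

#' @rdname accessors
setMethod("tangentMatrix", "TangentCoords", function(x) x@matrix)

#' @rdname accessors
setMethod("meshArea", "WingMesh", function(x) sum(x@elementAreas))

#' @rdname accessors
setMethod("strokePhase", "StrokeCycles", function(x) x@phase)

#' @rdname accessors
setMethod("strokePhase", "ShapeScores", function(x) x@phase)

#' @rdname accessors
setMethod("descriptorFrame", "DescriptorSeries", function(x) x@frame)

setMethod("show", "WingPlanform", function(object) {
  cat("WingPlanform:", nrow(object@coords), "landmarks, span",
    format(object@span), "mm, root chord", format(object@rootChord), "mm\n",
    " leading edge:", length(object@leadingEdge), "landmarks;",
    "trailing edge:", length(object@trailingEdge), "landmarks\n")
})

setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig: f =", object@strokeFrequency, "Hz, amplitude",
    object@strokeAmplitude, "deg,", object@nCycles, "cycles @",
    object@samplingRate, "Hz\n mode amplitudes:",
    paste(sprintf("%s=%.4g", .modeNames, object@modeAmplitudes),
      collapse = ", "),
    "\n noise SD:", object@noiseSd, "mm; seed:", object@seed, "\n")
})

setMethod("show", "MarkerTimeSeries", function(object) {
  cat("MarkerTimeSeries:", dim(object@coords)[1], "frames x",
    dim(object@coords)[2], "markers @",
    format(1 / mean(diff(object@times)), digits = 5), "Hz\n",
    " individual:", object@individual, "; condition:", object@condition, "\n")
})

setMethod("show", "WingMesh", function(object) {
  cat("WingMesh:", nrow(object@vertices), "vertices,",
    nrow(object@faces), "faces, area",
    format(sum(object@elementAreas), digits = 6), "mm^2\n")
})

setMethod("show", "StrokeCycles", function(object) {
  cat("StrokeCycles:", length(object@frequencies), "complete cycles,",
    "mean frequency", format(mean(object@frequencies), digits = 5), "Hz\n")
})

setMethod("show", "TemplateShape", function(object) {
  cat("TemplateShape:", nrow(object@coords), "landmarks,",
    if (object@scaled) "unit centroid size" else
      paste("centroid size", format(object@centroidSize, digits = 6)), "\n")
})

setMethod("show", "AlignedSeries", function(object) {
  eps <- sqrt(apply(object@residuals^2, 1, sum))
  cat("AlignedSeries:", dim(object@residuals)[1], "frames,",
    if (object@scaled) "scaled" else "unscaled", "alignment\n",
    " Procrustes distance to template: mean",
    format(mean(eps), digits = 4), ", max", format(max(eps), digits = 4), "\n")
})

setMethod("show", "ShapeBasis", function(object) {
  p <- object@varianceProportions
  cat("ShapeBasis: rank", ncol(object@V),
    if (object@scaled) "(scaled alignment)" else "(unscaled alignment)", "\n",
    " leading variance proportions:",
    paste(sprintf("%.1f%%", 100 * utils::head(p, 4)), collapse = ", "), "\n")
})

setMethod("show", "ShapeScores", function(object) {
  cat("ShapeScores:", nrow(object@scores), "frames x", ncol(object@scores),
    "shape variables; condition:", object@condition, "\n")
})

setMethod("show", "SpectrumSummary", function(object) {
  cat("SpectrumSummary: peak frequencies (Hz):",
    paste(format(object@peaks$peak_frequency_hz, digits = 4),
      collapse = ", "), "\n")
})

setMethod("show", "CrossCorrelation", function(object) {
  i <- which.max(abs(object@table$rho))
  cat("CrossCorrelation:", nrow(object@table), "lag bins; max |rho| =",
    format(abs(object@table$rho[i]), digits = 3), "at lag",
    format(object@table$lag[i]), "cycles\n")
})

setMethod("show", "RegressionTable", function(object) {
  cat("RegressionTable:", nrow(object@r2), "responses,",
    nrow(object@coefficients), "coefficients\n")
  print(object@r2, row.names = FALSE)
})

setMethod("show", "SplineComparison", function(object) {
  cat("SplineComparison:", length(object@phaseGrid), "phase points,",
    length(object@differences), "treatment(s), AR(1) coefficient",
    object@arCoefficient, "\n")
  for (nm in names(object@differences)) {
    d <- object@differences[[nm]]
    cat("  ", nm, ": ", sum(d$significant), "/", nrow(d),
      " phases flagged\n", sep = "")
  }
})
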