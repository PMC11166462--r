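#' @import methods
NULL

## ---------------------------------------------------------------------------
## Core data containers. Coordinates are millimetres throughout; the wing
## frame is right-handed with x spanwise (shoulder -> tip), y chordwise
## (leading -> trailing edge) and z dorsal; the lab frame is right-handed
## with +Z opposing gravity.
## ---------------------------------------------------------------------------

#' WingPlanform: a resting wing outline populated with landmarks
#'
#' Landmark positions of a wing at rest (planar, z = 0), together with the
#' ordered leading/trailing-edge landmark indices and the shoulder and tip
#' landmarks. This is the geometry the synthetic generator deforms and the
#' geometric operations use to identify the wing perimeter.
#'
#' @slot coords k x 3 landmark coordinates (mm), wing frame, z = 0 at rest.
#' @slot leadingEdge,trailingEdge integer indices of edge landmarks, each
#'   ordered by increasing spanwise coordinate x.
#' @slot shoulder,tip single landmark indices; the tip has maximal x.
#' @slot span,rootChord wing span and root chord (mm).
#' @exportClass WingPlanform
setClass("WingPlanform",
  representation(coords = "matrix", leadingEdge = "integer",
    trailingEdge = "integer", shoulder = "integer", tip = "integer",
    span = "numeric", rootChord = "numeric"))

setValidity("WingPlanform", function(object) {
  msg <- character()
  k <- nrow(object@coords)
  if (ncol(object@coords) != 3L) msg <- c(msg, "coords must be k x 3")
  if (k < 20L || k > 200L) msg <- c(msg, "landmark count must be in [20, 200]")
  if (any(!is.finite(object@coords))) msg <- c(msg, "non-finite coordinates")
  if (max(abs(object@coords[, 3])) > 1e-8)
    msg <- c(msg, "rest-pose landmarks must have z = 0")
  for (nm in c("leadingEdge", "trailingEdge")) {
    idx <- slot(object, nm)
    if (length(idx) < 2L || any(idx < 1L | idx > k))
      msg <- c(msg, paste(nm, "indices out of range or too few"))
    else if (is.unsorted(object@coords[idx, 1], strictly = FALSE))
      msg <- c(msg, paste(nm, "must be ordered by increasing x"))
  }
  if (abs(object@coords[object@tip, 1] - max(object@coords[, 1])) > 1e-8)
    msg <- c(msg, "tip landmark must have maximal x")
  if (object@span <= 0 || object@rootChord <= 0)
    msg <- c(msg, "span and rootChord must be positive")
  if (length(msg)) msg else TRUE
})

#' SimulationConfig: stroke kinematics and deformation-mode settings
#'
#' Parameters of the synthetic flapping-wing generator: rigid stroke
#' kinematics (azimuthal sweep at the stroke frequency, elevation at twice
#' the stroke frequency giving the J-shaped tip path, stroke-plane tilt),
#' the amplitudes and phase offsets of the four injected deformation modes,
#' tracking-noise level, sampling rate and duration.
#'
#' @slot strokeFrequency stroke frequency f (Hz).
#' @slot strokeAmplitude peak-to-peak azimuthal amplitude (deg).
#' @slot elevationAmplitude elevation amplitude (deg) at 2f.
#' @slot strokePlaneAngle stroke-plane tilt from horizontal (deg).
#' @slot modeAmplitudes named numeric(4): \code{twist_deg} (tip sectional
#'   angle amplitude, deg), \code{fold_fraction} (maximal relative spanwise
#'   contraction), \code{span_bend_fraction} (tip deflection as a fraction
#'   of span), \code{area_redistribution_fraction} (relative chordwise
#'   scaling gradient).
#' @slot modePhases numeric(4) phase offsets in cycles.
#' @slot noiseSd additive isotropic Gaussian tracking noise SD (mm).
#' @slot samplingRate sampling rate (Hz), at least 20 f.
#' @slot nCycles number of stroke cycles simulated.
#' @slot seed integer seed for the generator's private RNG stream.
#' @exportClass SimulationConfig
setClass("SimulationConfig",
  representation(strokeFrequency = "numeric", strokeAmplitude = "numeric",
    elevationAmplitude = "numeric", strokePlaneAngle = "numeric",
    modeAmplitudes = "numeric", modePhases = "numeric", noiseSd = "numeric",
    samplingRate = "numeric", nCycles = "numeric", seed = "integer"))

.modeNames <- c("twist_deg", "fold_fraction", "span_bend_fraction",
  "area_redistribution_fraction")

setValidity("SimulationConfig", function(object) {
  msg <- character()
  if (object@strokeFrequency <= 0) msg <- c(msg, "strokeFrequency must be > 0")
  if (object@samplingRate < 20 * object@strokeFrequency)
    msg <- c(msg, "samplingRate must be at least 20x strokeFrequency")
  if (object@nCycles < 2) msg <- c(msg, "nCycles must be >= 2")
  if (length(object@modeAmplitudes) != 4L ||
      !identical(names(object@modeAmplitudes), .modeNames))
    msg <- c(msg, paste("modeAmplitudes must be named", paste(.modeNames, collapse = ", ")))
  if (any(object@modeAmplitudes < 0)) msg <- c(msg, "mode amplitudes must be >= 0")
  if (length(object@modePhases) != 4L) msg <- c(msg, "modePhases must have length 4")
  if (object@modeAmplitudes["fold_fraction"] >= 1)
    msg <- c(msg, "fold_fraction must be < 1")
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
  if (any(c(object@strokeAmplitude, object@elevationAmplitude) < 0))
    msg <- c(msg, "amplitudes must be >= 0")
  if (length(msg)) msg else TRUE
})

#' MarkerTimeSeries: tracked landmark trajectories
#'
#' The tracked configurations of the wing: a T x k x 3 coordinate array in
#' the lab frame with timestamps, marker labels and trial metadata.
#'
#' @slot coords numeric array T x k x 3 (mm, lab frame).
#' @slot times numeric(T) timestamps (s), constant sampling interval.
#' @slot labels character(k) marker names.
#' @slot condition,individual free-text trial metadata.
#' @exportClass MarkerTimeSeries
setClass("MarkerTimeSeries",
  representation(coords = "array", times = "numeric", labels = "character",
    condition = "character", individual = "character"))

setValidity("MarkerTimeSeries", function(object) {
  msg <- character()
  d <- dim(object@coords)
  if (length(d) != 3L || d[3] != 3L) msg <- c(msg, "coords must be T x k x 3")
  else {
    if (d[1] < 2L) msg <- c(msg, "need at least 2 frames")
    if (length(object@times) != d[1]) msg <- c(msg, "times length must match frames")
    if (length(object@labels) != d[2]) msg <- c(msg, "labels length must match markers")
    if (any(!is.finite(object@coords))) msg <- c(msg, "non-finite coordinates")
    dt <- diff(object@times)
    if (length(dt) && (any(dt <= 0) || diff(range(dt)) > 1e-6 * mean(dt)))
      msg <- c(msg, "sampling interval must be constant and positive")
  }
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## Surface reconstruction containers
## ---------------------------------------------------------------------------

#' ChordSegmentSet: spanwise chord segments along the wing
#'
#' Paired points interpolated along the leading and trailing edges at
#' matched normalized arclength, joined to form chordal line segments.
#'
#' @slot lePoints,tePoints n x 3 interpolated edge points (mm).
#' @slot sectionRadii distance of each section from the wing base (mm),
#'   strictly increasing.
#' @exportClass ChordSegmentSet
setClass("ChordSegmentSet",
  representation(lePoints = "matrix", tePoints = "matrix",
    sectionRadii = "numeric"))

setValidity("ChordSegmentSet", function(object) {
  msg <- character()
  if (nrow(object@lePoints) != nrow(object@tePoints))
    msg <- c(msg, "le/te point lists must have equal length")
  if (length(object@sectionRadii) != nrow(object@lePoints))
    msg <- c(msg, "sectionRadii length mismatch")
  if (is.unsorted(object@sectionRadii, strictly = TRUE))
    msg <- c(msg, "sectionRadii must be strictly increasing")
  if (length(msg)) msg else TRUE
})

#' WingMesh: triangulated wing surface
#'
#' A triangulated surface over the wing planform: landmark vertices plus
#' internal fill points connected by Delaunay triangulation, with faces
#' whose centroids fall outside the wing perimeter pruned. Element areas
#' (dA) and element centroid radii from the wing base (r) support area and
#' second-moment integrals. The 2D template parameterization \code{uv} is
#' retained so the template mesh can be projected through tracked landmark
#' positions at each frame.
#'
#' @slot vertices V x 3 vertex coordinates (mm).
#' @slot faces F x 3 integer vertex indices.
#' @slot elementAreas,elementRadii per-face areas (mm^2) and centroid
#'   distances from the wing base (mm).
#' @slot uv V x 2 template-plane coordinates of the vertices.
#' @slot basePoint length-3 wing-base (shoulder) position (mm).
#' @slot baseLandmark index of the wing-base (shoulder) landmark vertex.
#' @slot nLandmarks number of leading vertices that are tracked landmarks.
#' @slot internalSpacing internal fill-point spacing (mm).
#' @exportClass WingMesh
setClass("WingMesh",
  representation(vertices = "matrix", faces = "matrix",
    elementAreas = "numeric", elementRadii = "numeric", uv = "matrix",
    basePoint = "numeric", baseLandmark = "integer", nLandmarks = "integer",
    internalSpacing = "numeric"))

setValidity("WingMesh", function(object) {
  msg <- character()
  V <- nrow(object@vertices); F <- nrow(object@faces)
  if (ncol(object@vertices) != 3L) msg <- c(msg, "vertices must be V x 3")
  if (ncol(object@faces) != 3L) msg <- c(msg, "faces must be F x 3")
  if (F > 0 && (min(object@faces) < 1L || max(object@faces) > V))
    msg <- c(msg, "faces reference invalid vertices")
  if (length(object@elementAreas) != F || length(object@elementRadii) != F)
    msg <- c(msg, "element attribute length mismatch")
  if (F > 0 && any(object@elementAreas <= 0))
    msg <- c(msg, "element areas must be positive")
  if (nrow(object@uv) != V) msg <- c(msg, "uv must be V x 2")
  if (length(msg)) msg else TRUE
})

#' StrokeCycles: stroke-reversal segmentation of a trial
#'
#' Pronation/supination reversal times located from azimuth extrema with
#' sub-sample quadratic refinement, per-cycle stroke frequencies, and a
#' per-frame stroke phase in [0, 1) anchored at pronation (downstroke
#' onset).
#'
#' @slot reversalTimes reversal times (s), alternating types.
#' @slot reversalType character, "pronation" or "supination" per reversal.
#' @slot phase numeric(T) per-frame phase in [0,1); NA outside complete
#'   pronation-to-pronation cycles.
#' @slot cycle integer(T) cycle index per frame (NA outside cycles).
#' @slot downstroke logical(T), TRUE during downstroke.
#' @slot frequencies per-cycle stroke frequency 1/duration (Hz).
#' @slot midDownstrokeFrames,midUpstrokeFrames frame indices nearest the
#'   half-interval times.
#' @exportClass StrokeCycles
setClass("StrokeCycles",
  representation(reversalTimes = "numeric", reversalType = "character",
    phase = "numeric", cycle = "integer", downstroke = "logical",
    frequencies = "numeric", midDownstrokeFrames = "integer",
    midUpstrokeFrames = "integer"))

setValidity("StrokeCycles", function(object) {
  msg <- character()
  if (length(object@reversalTimes) != length(object@reversalType))
    msg <- c(msg, "reversal times/types length mismatch")
  if (length(object@reversalType) > 1 &&
      any(object@reversalType[-1] == object@reversalType[-length(object@reversalType)]))
    msg <- c(msg, "reversals must alternate")
  if (any(object@frequencies <= 0)) msg <- c(msg, "frequencies must be > 0")
  if (length(msg)) msg else TRUE
})

#' DescriptorSeries: per-frame kinematic and morphological descriptors
#'
#' One row per frame: azimuth, elevation and wing-plane angle (deg), mesh
#' surface area S (mm^2), non-dimensional second moment of area, tip-to-
#' root twist (deg), mid-span chordwise camber and spanwise camber
#' (dimensionless), and wing length R (mm). The full per-section chordwise
#' camber profile is carried alongside.
#'
#' @slot frame data.frame of per-frame descriptors.
#' @slot chordCamberProfile frames x sections matrix of h_chord/c.
#' @slot sectionRadii radii (mm) of the camber sections.
#' @exportClass DescriptorSeries
setClass("DescriptorSeries",
  representation(frame = "data.frame", chordCamberProfile = "matrix",
    sectionRadii = "numeric"))

## ---------------------------------------------------------------------------
## Shape decomposition containers
## ---------------------------------------------------------------------------

#' TemplateShape: the converged mean shape of a GPA alignment
#'
#' @slot coords k x 3 template landmark coordinates, centroid at the
#'   origin; unit centroid size when the alignment scaled.
#' @slot centroidSize centroid size of the template (1 when scaled).
#' @slot scaled logical, whether configurations were scaled to unit
#'   centroid size during alignment.
#' @exportClass TemplateShape
setClass("TemplateShape",
  representation(coords = "matrix", centroidSize = "numeric",
    scaled = "logical"))

setValidity("TemplateShape", function(object) {
  msg <- character()
  if (max(abs(colMeans(object@coords))) > 1e-10)
    msg <- c(msg, "template centroid must be at the origin")
  if (object@scaled && abs(sqrt(sum(object@coords^2)) - 1) > 1e-10)
    msg <- c(msg, "scaled template must have unit centroid size")
  if (length(msg)) msg else TRUE
})

#' AlignedSeries: per-frame Procrustes fits to the template
#'
#' Stores, for every frame, the similarity transform of the fitted model
#' X_t = lambda_t (X_M + e_t) Gamma_t + b_t and the shape residuals e_t.
#' Reconstructing through the stored transforms reproduces the input
#' configurations to machine precision.
#'
#' @slot residuals T x k x 3 array of shape residuals e_t.
#' @slot scales numeric(T) scale factors lambda_t (all 1 when unscaled).
#' @slot rotations 3 x 3 x T rotation matrices Gamma_t (det +1).
#' @slot translations T x 3 centroid translations b_t.
#' @slot scaled logical flag.
#' @exportClass AlignedSeries
setClass("AlignedSeries",
  representation(residuals = "array", scales = "numeric",
    rotations = "array", translations = "matrix", scaled = "logical"))

setValidity("AlignedSeries", function(object) {
  msg <- character()
  T <- dim(object@residuals)[1]
  if (length(object@scales) != T || dim(object@rotations)[3] != T ||
      nrow(object@translations) != T)
    msg <- c(msg, "per-frame transform lengths must match residual frames")
  if (any(object@scales <= 0)) msg <- c(msg, "scales must be positive")
  for (t in seq_len(min(T, 5L))) {   # spot-check orthogonality
    G <- object@rotations[, , t]
    if (max(abs(crossprod(G) - diag(3))) > 1e-8 || det(G) < 0)
      msg <- c(msg, "rotations must be special orthogonal")
  }
  if (length(msg)) msg else TRUE
})

#' TangentCoords: tangent-plane shape coordinates
#'
#' Aligned pre-shapes orthogonally projected onto the hyperplane tangent
#' to the pre-shape sphere at the template; the template itself maps to the
#' zero vector.
#'
#' @slot matrix T x 3k tangent coordinates.
#' @slot scaled logical flag inherited from the alignment.
#' @exportClass TangentCoords
setClass("TangentCoords",
  representation(matrix = "matrix", scaled = "logical"))

#' ShapeBasis: SVD shape variables of the tangent coordinates
#'
#' Right singular vectors (shape variables) of the column-mean-centered
#' tangent coordinate matrix, singular values and variance proportions
#' d^2 / sum d^2, with the template and training column means needed to
#' project new configurations onto the basis.
#'
#' @slot V 3k x rank right singular vectors.
#' @slot d singular values, non-increasing.
#' @slot varianceProportions d^2 / sum(d^2).
#' @slot columnMeans training column means of the tangent coordinates.
#' @slot template the TemplateShape of the alignment.
#' @slot scaled logical flag.
#' @exportClass ShapeBasis
setClass("ShapeBasis",
  representation(V = "matrix", d = "numeric",
    varianceProportions = "numeric", columnMeans = "numeric",
    template = "TemplateShape", scaled = "logical"))

setValidity("ShapeBasis", function(object) {
  msg <- character()
  r <- ncol(object@V)
  if (length(object@d) != r) msg <- c(msg, "d length must match basis rank")
  if (is.unsorted(rev(object@d))) msg <- c(msg, "singular values must be non-increasing")
  if (max(abs(crossprod(object@V) - diag(r))) > 1e-8)
    msg <- c(msg, "V must have orthonormal columns")
  if (abs(sum(object@varianceProportions) - 1) > 1e-10)
    msg <- c(msg, "variance proportions must sum to 1")
  if (length(msg)) msg else TRUE
})

#' ShapeScores: per-frame projections onto the shape variables
#'
#' @slot scores T x m score matrix (columns of U D).
#' @slot phase optional per-frame stroke phase (NA when unknown).
#' @slot condition,individual trial metadata carried through.
#' @exportClass ShapeScores
setClass("ShapeScores",
  representation(scores = "matrix", phase = "numeric",
    condition = "character", individual = "character"))

## ---------------------------------------------------------------------------
## Temporal statistics containers
## ---------------------------------------------------------------------------

#' SpectrumSummary: periodogram peaks of the shape scores
#'
#' @slot peaks data.frame with one row per shape variable: peak frequency
#'   (Hz) and peak power.
#' @slot frequencies periodogram frequency grid (Hz).
#' @slot power frequencies x variables power matrix.
#' @exportClass SpectrumSummary
setClass("SpectrumSummary",
  representation(peaks = "data.frame", frequencies = "numeric",
    power = "matrix"))

#' CrossCorrelation: lagged correlation of a score with a descriptor
#'
#' Pearson correlations at integer-frame lags, binned to a 0.02 stroke-
#' phase grid (maximum-magnitude coefficient retained per bin), with
#' per-lag significance from a heteroskedasticity-robust t-statistic.
#'
#' @slot table data.frame with columns lag (stroke-cycle fraction),
#'   rho, tstat, p, significant.
#' @exportClass CrossCorrelation
setClass("CrossCorrelation", representation(table = "data.frame"))

#' RegressionTable: standardized multiple regressions of scores
#'
#' @slot coefficients data.frame: response, term, beta, lower, upper,
#'   significant (interval excludes zero).
#' @slot r2 data.frame: response, r2_full, r2_nokinematics.
#' @exportClass RegressionTable
setClass("RegressionTable",
  representation(coefficients = "data.frame", r2 = "data.frame"))

#' SplineComparison: cyclic-spline comparison against a reference smooth
#'
#' Phase-normalized reference smooth of the typical condition, and for each
#' treatment an average (intercept) difference and a cyclic penalized
#' difference smooth with pointwise intervals, fitted with AR(1) residuals.
#' The treatment mean fit equals reference + intercept + difference smooth
#' on the phase grid.
#'
#' @slot phaseGrid evaluation phases in [0, 1).
#' @slot reference data.frame: phase, fit, se.
#' @slot differences named list (one per treatment) of data.frames with
#'   columns phase, delta, lower, upper, significant.
#' @slot intercepts data.frame: treatment, estimate, lower, upper,
#'   significant.
#' @slot arCoefficient AR(1) coefficient used.
#' @exportClass SplineComparison
setClass("SplineComparison",
  representation(phaseGrid = "numeric", reference = "data.frame",
    differences = "list", intercepts = "data.frame",
    arCoefficient = "numeric"))
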