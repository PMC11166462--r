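# Shared fixtures, built in code at test time.

# a small rectangular planform built by hand: straight parallel edges so
# every chord equals the root chord (analytic reference geometry)
rectPlanform <- function(span = 20, chord = 5, nEdge = 8, nInner = 8) {
  xe <- seq(0, span, length.out = nEdge)
  le <- cbind(xe, 0, 0)
  te <- cbind(xe, chord, 0)
  gx <- seq(span / 6, span * 5 / 6, length.out = nInner)
  inner <- cbind(gx, chord / 2, 0)
  coords <- rbind(le, te, inner)
  new("WingPlanform", coords = coords,
    leadingEdge = seq_len(as.integer(nEdge)),
    trailingEdge = as.integer(nEdge + seq_len(nEdge)),
    shoulder = 1L, tip = as.integer(nEdge),
    span = span, rootChord = chord)
}

# planform from explicit edge curves y_le(x), y_te(x) (x-monotone edges)
curvePlanform <- function(span, yLe, yTe, nEdge = 10, innerY = NULL) {
  xe <- seq(0, span, length.out = nEdge)
  le <- cbind(xe, yLe(xe), 0)
  te <- cbind(xe, yTe(xe), 0)
  if (is.null(innerY)) innerY <- function(x) (yLe(x) + yTe(x)) / 2
  gx <- seq(span / 8, span * 7 / 8, length.out = max(4L, 20L - 2L * nEdge))
  inner <- cbind(gx, innerY(gx), 0)
  coords <- rbind(le, te, inner)
  new("WingPlanform", coords = coords,
    leadingEdge = seq_len(as.integer(nEdge)),
    trailingEdge = as.integer(nEdge + seq_len(nEdge)),
    shoulder = 1L, tip = as.integer(nEdge),
    span = span, rootChord = yTe(0) - yLe(0))
}

# standard synthetic trial at the study conditions, thinned for analysis
simTrial <- function(planform = makePlanform(60, 55, 20), nCycles = 10,
    noiseSd = 0.05, thin = 4L, seed = 1L, ...) {
  cfg <- simulationConfig(nCycles = nCycles, noiseSd = noiseSd,
    seed = seed, ...)
  thinFrames(simulateTrajectory(planform, cfg), thin)
}

# deformation-free rigid-motion config (all modes off)
rigidConfig <- function(nCycles = 4, noiseSd = 0, seed = 1L, ...) {
  cfg <- simulationConfig(nCycles = nCycles, noiseSd = noiseSd,
    seed = seed, ...)
  cfg@modeAmplitudes[] <- 0
  cfg
}

modeAmps <- function(twist = 0, fold = 0, bend = 0, redis = 0) {
  c(twist_deg = twist, fold_fraction = fold, span_bend_fraction = bend,
    area_redistribution_fraction = redis)
}

randomRotation <- function() {
  qr.Q(qr(matrix(stats::rnorm(9), 3)))
}
properRotation <- function() {
  R <- randomRotation()
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

applyRigid <- function(coords, R, b = c(0, 0, 0), s = 1) {
  out <- coords
  for (t in seq_len(dim(coords)[1]))
    out[t, , ] <- s * coords[t, , ] %*% R + rep(1, dim(coords)[2]) %o% b
  out
}

# full decomposition pipeline in one call
decompose <- function(series, scale = TRUE) {
  al <- gpaAlign(series, scale = scale)
  tc <- tangentProject(al$aligned, al$template)
  dec <- svdDecompose(tc, al$template)
  list(template = al$template, aligned = al$aligned, tangent = tc,
    basis = dec$basis, scores = dec$scores)
}

# phase-indexed test data for the spline comparisons
phaseData <- function(nCycles, nPhase = 50, f = function(p) sin(2 * pi * p),
    sd = 0.3) {
  do.call(rbind, lapply(seq_len(nCycles), function(i) {
    p <- (seq_len(nPhase) - 1) / nPhase
    data.frame(cycle = i, phase = p, value = f(p) + stats::rnorm(nPhase, 0, sd))
  }))
}
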