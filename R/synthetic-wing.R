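#' @include AllClasses.R
NULL

## run expr with a private RNG stream; the session RNG state is untouched
.withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

.rotZ <- function(a) {
  ca <- cos(a); sa <- sin(a)
  matrix(c(ca, sa, 0, -sa, ca, 0, 0, 0, 1), 3, 3)
}

.rotY <- function(a) {
  ca <- cos(a); sa <- sin(a)
  matrix(c(ca, 0, -sa, 0, 1, 0, sa, 0, ca), 3, 3)
}

.deg2rad <- function(x) x * pi / 180
.rad2deg <- function(x) x * 180 / pi

#' Lay out landmarks on a tapered wing planform
#'
#' Builds a resting (planar) wing outline with an elliptic-like chord taper
#' towards the tip and populates it with \code{k} landmarks: points along
#' the leading and trailing edges, a tip landmark, and an interior grid
#' fill. The leading edge runs along the spanwise axis (y = 0) and the
#' trailing edge at y = c(x), with chord
#' c(x) = rootChord * sqrt(1 - (x/span)^2). The construction is
#' deterministic for fixed arguments.
#'
#' @param k number of landmarks (20 to 200).
#' @param span wing span (mm).
#' @param rootChord chord at the wing root (mm).
#' @param edgeFraction fraction of landmarks allocated to each edge.
#' @return a \linkS4class{WingPlanform}.
#' @examples
#' pf <- makePlanform(60, span = 55, rootChord = 20)
#' pf
#' @export
makePlanform <- function(k, span, rootChord, edgeFraction = 0.28) {
  if (k < 20L) stop("k too small to populate both edges (need >= 20)")
  if (span <= 0 || rootChord <= 0) stop("span and rootChord must be positive")
  k <- as.integer(k)
  chord <- function(x) rootChord * sqrt(pmax(0, 1 - (x / span)^2))

  nEdge <- max(4L, round(edgeFraction * k))
  nInterior <- k - 2L * nEdge - 1L
  if (nInterior < 1L) {
    nEdge <- (k - 2L) %/% 2L
    nInterior <- k - 2L * nEdge - 1L
  }

  # edge stations, tip excluded (the tip is its own landmark shared by
  # both edges); slight crowding towards the tip where the chord tapers
  # fastest. The planform tapers symmetrically about a straight mid-chord
  # line, which keeps sectional rotations orthogonal to span-only
  # deformation patterns under alignment.
  s <- seq(0, 1, length.out = nEdge + 1L)[-(nEdge + 1L)]
  xe <- span * sin(s * pi / 2) * 0.97 / sin(0.97 * pi / 2)
  xe <- pmin(xe, span * 0.97)
  le <- cbind(xe, (rootChord - chord(xe)) / 2, 0)
  te <- cbind(xe, (rootChord + chord(xe)) / 2, 0)
  tip <- c(span, rootChord / 2, 0)

  # interior fill: points placed in pairs mirrored about the chord
  # midline (plus midline points), thinned deterministically; the
  # symmetric layout keeps sectional-rotation patterns orthogonal to
  # span-only deformation patterns
  nPairs <- nInterior %/% 2L
  nMidline <- nInterior - 2L * nPairs
  h <- sqrt(span * rootChord / max(nInterior, 1L))
  repeat {
    gx <- seq(h / 2, span - h / 2, by = h)
    gd <- seq(h / 2, rootChord / 2, by = h)
    g <- expand.grid(x = gx, d = gd)
    margin <- 0.08 * rootChord
    keep <- g$d < chord(g$x) / 2 - margin
    g <- g[keep, , drop = FALSE]
    if (nrow(g) >= nPairs || h < span / 200) break
    h <- h * 0.8
  }
  if (nrow(g) < nPairs)
    stop("could not place ", nInterior, " interior landmarks")
  ord <- order(g$x, g$d)
  pick <- ord[round(seq(1, length(ord), length.out = nPairs))]
  mid <- rootChord / 2
  interior <- rbind(cbind(g$x[pick], mid - g$d[pick], 0),
    cbind(g$x[pick], mid + g$d[pick], 0))
  if (nMidline > 0L)
    interior <- rbind(interior, cbind(span * 0.45, mid, 0))

  coords <- rbind(le, te, tip, interior)
  rownames(coords) <- NULL
  leIdx <- c(order(le[, 1]), 2L * nEdge + 1L)          # tip closes the edge
  teIdx <- c(nEdge + order(te[, 1]), 2L * nEdge + 1L)
  new("WingPlanform", coords = coords, leadingEdge = as.integer(leIdx),
    trailingEdge = as.integer(teIdx), shoulder = 1L,
    tip = as.integer(2L * nEdge + 1L), span = span, rootChord = rootChord)
}

#' Construct a simulation configuration
#'
#' Defaults emulate typical hummingbird hoverfeeding kinematics: a 41 Hz
#' stroke with 129 deg peak-to-peak azimuthal amplitude, elevation at twice
#' the stroke frequency (J-shaped tip path) with amplitude 15% of the
#' stroke amplitude, and a 13.3 deg stroke-plane tilt. Default mode phases
#' put the twist peaks at the mid-strokes and the fold maximum a quarter
#' cycle later (mid-downstroke area maximum).
#'
#' @param strokeFrequency stroke frequency (Hz).
#' @param strokeAmplitude peak-to-peak azimuthal amplitude (deg).
#' @param elevationAmplitude elevation amplitude (deg) at twice the stroke
#'   frequency; defaults to 15% of \code{strokeAmplitude}.
#' @param strokePlaneAngle stroke-plane tilt (deg).
#' @param modeAmplitudes named numeric(4); see
#'   \linkS4class{SimulationConfig}.
#' @param modePhases phase offsets in cycles for the four modes.
#' @param noiseSd additive tracking noise SD (mm).
#' @param samplingRate sampling rate (Hz).
#' @param nCycles number of stroke cycles.
#' @param seed RNG seed.
#' @return a \linkS4class{SimulationConfig}.
#' @export
simulationConfig <- function(strokeFrequency = 41, strokeAmplitude = 129,
    elevationAmplitude = 0.15 * strokeAmplitude, strokePlaneAngle = 13.3,
    modeAmplitudes = c(twist_deg = 15, fold_fraction = 0.12,
      span_bend_fraction = 0.03, area_redistribution_fraction = 0.03),
    modePhases = c(0, -0.25, 0, -0.25), noiseSd = 0.05,
    samplingRate = 2200, nCycles = 10, seed = 1L) {
  ma <- modeAmplitudes[.modeNames]
  names(ma) <- .modeNames
  new("SimulationConfig", strokeFrequency = strokeFrequency,
    strokeAmplitude = strokeAmplitude,
    elevationAmplitude = elevationAmplitude,
    strokePlaneAngle = strokePlaneAngle, modeAmplitudes = ma,
    modePhases = as.numeric(modePhases), noiseSd = noiseSd,
    samplingRate = samplingRate, nCycles = nCycles, seed = as.integer(seed))
}

## chordwise midline (per landmark) interpolated from the edge landmarks;
## sectional rotations and chord scalings pivot about it
.chordMidline <- function(planform) {
  x <- planform@coords[, 1]
  leInt <- stats::approx(planform@coords[planform@leadingEdge, 1],
    planform@coords[planform@leadingEdge, 2], xout = x, rule = 2)$y
  teInt <- stats::approx(planform@coords[planform@trailingEdge, 1],
    planform@coords[planform@trailingEdge, 2], xout = x, rule = 2)$y
  (leInt + teInt) / 2
}

## deformation field in the wing frame, before rigid kinematics.
## All mode displacements are evaluated on the rest coordinates so modes
## superpose; twist and spanwise bending displace only z (out-of-plane),
## folding and area redistribution only x/y (in-plane). Sections rotate
## and rescale about the local chord midline, which keeps the four
## spatial patterns close to mutually orthogonal.
.deformPlanform <- function(P, span, amp, phaseArg, ymid) {
  x <- P[, 1]; y <- P[, 2]
  yc <- y - ymid
  # pivot station of the redistribution gradient: the chord-variance
  # centroid, so redistribution is orthogonal to uniform chord scaling
  xw <- sum(yc^2 * x) / sum(yc^2)
  out <- P
  # (a) twist: sectional inclination linear in x, implemented as a vertical
  # shear so the section angle at station x is exactly theta(x, t)
  theta <- .deg2rad(amp["twist_deg"]) * (x / span) * sin(phaseArg[1])
  out[, 3] <- out[, 3] + yc * tan(theta)
  # (c) spanwise bend at 2f: tip deflection span_bend_fraction * span
  out[, 3] <- out[, 3] +
    amp["span_bend_fraction"] * span * (x / span)^2 * sin(phaseArg[3])
  # (b) fold: spanwise contraction (area change), factor in (1-fold, 1]
  out[, 1] <- x * (1 - amp["fold_fraction"] * (1 + sin(phaseArg[2])) / 2)
  # (d) area redistribution at 2f: chordwise scaling linear in x
  out[, 2] <- ymid + yc *
    (1 + amp["area_redistribution_fraction"] * (2 * (x - xw) / span) *
       sin(phaseArg[4]))
  out
}

#' Simulate flapping-wing landmark trajectories
#'
#' Applies, per frame and in the wing frame, the four deformation modes
#' (tip-to-root twist at the stroke frequency f, wing folding at f,
#' spanwise bending at 2f, chordwise area redistribution at 2f), then the
#' rigid stroke kinematics (azimuthal sweep (A/2) cos(2 pi f t), elevation
#' at 2f, stroke-plane rotation), then additive isotropic Gaussian tracking
#' noise from a private seeded RNG stream.
#'
#' @param planform a \linkS4class{WingPlanform}.
#' @param config a \linkS4class{SimulationConfig}.
#' @return a \linkS4class{MarkerTimeSeries} with
#'   \code{T = round(nCycles * samplingRate / strokeFrequency)} frames.
#' @examples
#' pf <- makePlanform(60, 55, 20)
#' mts <- simulateTrajectory(pf, simulationConfig(nCycles = 2))
#' mts
#' @export
simulateTrajectory <- function(planform, config) {
  validObject(planform); validObject(config)
  f <- config@strokeFrequency
  fs <- config@samplingRate
  T <- round(config@nCycles * fs / f)
  times <- (seq_len(T) - 1L) / fs
  P <- planform@coords
  k <- nrow(P)
  amp <- config@modeAmplitudes
  ph <- config@modePhases
  A <- .deg2rad(config@strokeAmplitude)
  eAmp <- .deg2rad(config@elevationAmplitude)
  beta <- .deg2rad(config@strokePlaneAngle)
  Rplane <- .rotY(beta)

  coords <- array(NA_real_, c(T, k, 3))
  w <- 2 * pi * f
  ymid <- .chordMidline(planform)
  for (t in seq_len(T)) {
    tt <- times[t]
    phaseArg <- c(w * tt + 2 * pi * ph[1], w * tt + 2 * pi * ph[2],
      2 * w * tt + 2 * pi * ph[3], 2 * w * tt + 2 * pi * ph[4])
    D <- .deformPlanform(P, planform@span, amp, phaseArg, ymid)
    psi <- (A / 2) * cos(w * tt)
    elev <- eAmp * sin(2 * w * tt)
    R <- Rplane %*% .rotZ(psi) %*% .rotY(-elev)
    coords[t, , ] <- D %*% t(R)
  }
  if (config@noiseSd > 0)
    coords <- coords + .withSeed(config@seed,
      array(stats::rnorm(length(coords), 0, config@noiseSd), dim(coords)))
  new("MarkerTimeSeries", coords = coords, times = times,
    labels = sprintf("m%02d", seq_len(k)), condition = "typical",
    individual = "sim")
}

#' Thin a marker time series by an integer factor
#'
#' Keeps every \code{factor}-th frame, e.g. to downsample a 2200 Hz
#' recording to 550 Hz for analysis.
#'
#' @param series a \linkS4class{MarkerTimeSeries}.
#' @param factor integer thinning factor.
#' @return a \linkS4class{MarkerTimeSeries}.
#' @export
thinFrames <- function(series, factor) {
  factor <- as.integer(factor)
  if (factor < 1L) stop("factor must be a positive integer")
  keep <- seq(1L, dim(series@coords)[1], by = factor)
  new("MarkerTimeSeries", coords = series@coords[keep, , , drop = FALSE],
    times = series@times[keep], labels = series@labels,
    condition = series@condition, individual = series@individual)
}

## total tangent-space sum of squares (about column means) of a simulated
## series run through the real alignment pipeline
.tangentSS <- function(planform, config, scale = TRUE) {
  mts <- simulateTrajectory(planform, config)
  al <- gpaAlign(mts, scale = scale)
  tc <- tangentProject(al$aligned, al$template)
  X <- sweep(tc@matrix, 2, colMeans(tc@matrix))
  sum(X^2)
}

## realized joint variance shares per mode: run the full pipeline on the
## all-modes simulation and assign SVD components to modes by the
## correlation of their score time courses with the known injected
## temporal signals
.jointShares <- function(planform, config, scale = TRUE) {
  mts <- simulateTrajectory(planform, config)
  al <- gpaAlign(mts, scale = scale)
  tc <- tangentProject(al$aligned, al$template)
  dec <- svdDecompose(tc, al$template)
  vp <- dec$basis@varianceProportions
  S <- dec$scores@scores
  w <- 2 * pi * config@strokeFrequency
  tt <- mts@times
  mult <- c(1, 1, 2, 2)
  refs <- vapply(1:4, function(m)
    sin(mult[m] * w * tt + 2 * pi * config@modePhases[m]),
    numeric(length(tt)))
  nc <- min(ncol(S), 8L)
  cm <- abs(stats::cor(refs, S[, seq_len(nc), drop = FALSE]))
  assign <- rep(NA_integer_, 4)
  for (step in 1:4) {
    i <- which(cm == max(cm, na.rm = TRUE), arr.ind = TRUE)[1, ]
    assign[i[1]] <- i[2]
    cm[i[1], ] <- NA; cm[, i[2]] <- NA
  }
  list(shares = vp[assign], components = assign, proportions = vp)
}

#' Calibrate deformation-mode amplitudes to target variance shares
#'
#' Finds mode amplitudes whose realized tangent-space variance shares match
#' \code{targetShares} (shares of total variance; any remainder up to 1 is
#' contributed by tracking noise at \code{config@noiseSd}). A first stage
#' simulates every mode alone with noise off, measures its injected
#' tangent-space variance through the real alignment pipeline
#' (\code{\link{gpaAlign}} + \code{\link{tangentProject}}), measures the
#' noise variance with all modes off, and rescales the amplitudes (mode
#' variance is approximately quadratic in amplitude). A second stage
#' refines the amplitudes against the all-modes simulation, assigning SVD
#' components to modes by the correlation of their score time courses with
#' the injected temporal signals, so that the realized joint variance
#' proportions — which include mode interaction through the alignment —
#' match the targets.
#'
#' @param planform a \linkS4class{WingPlanform}.
#' @param config a \linkS4class{SimulationConfig}; its \code{noiseSd} fixes
#'   the absolute variance scale when the target shares sum to less than 1.
#' @param targetShares numeric(4) of positive shares summing to at most 1,
#'   ordered as the modes in \code{config@modeAmplitudes}.
#' @param tol convergence tolerance on each share, in proportion units
#'   (default 0.01, i.e. one percentage point).
#' @param maxIter maximum number of calibration iterations.
#' @param scale logical; calibrate under scaled alignment (the default).
#' @return named numeric(4) of calibrated mode amplitudes, with the
#'   realized shares in attribute \code{"realizedShares"}.
#' @export
calibrateModeAmplitudes <- function(planform, config, targetShares,
    tol = 0.01, maxIter = 20L, scale = TRUE) {
  if (length(targetShares) != 4L || any(targetShares < 0))
    stop("targetShares must be four non-negative proportions")
  if (sum(targetShares) > 1 + 1e-8)
    stop("targetShares must sum to at most 1 (remainder is noise)")
  active <- targetShares > 0

  noiseCfg <- config
  noiseCfg@modeAmplitudes[] <- 0
  vNoise <- if (config@noiseSd > 0)
    .tangentSS(planform, noiseCfg, scale = scale) else 0
  noiseShare <- 1 - sum(targetShares)
  if (vNoise == 0 && noiseShare > 1e-8)
    warning("target shares sum to ", sum(targetShares),
      " but noiseSd is 0; shares are normalized over the modes only")

  amp <- config@modeAmplitudes
  start <- c(twist_deg = 10, fold_fraction = 0.1,
    span_bend_fraction = 0.02, area_redistribution_fraction = 0.02)
  amp[active] <- ifelse(amp[active] > 0, amp[active], start[active])
  amp[!active] <- 0

  # stage 1: single-mode runs pin the amplitude scale
  for (iter in seq_len(maxIter)) {
    v <- numeric(4)
    for (m in which(active)) {
      cfg <- config
      cfg@noiseSd <- 0
      cfg@modeAmplitudes[] <- 0
      cfg@modeAmplitudes[m] <- amp[m]
      v[m] <- .tangentSS(planform, cfg, scale = scale)
    }
    realized <- v / (sum(v) + vNoise)
    if (all(abs(realized[active] - targetShares[active]) < tol)) break
    cconst <- ifelse(v > 0, v / amp^2, NA_real_)
    if (vNoise > 0 && noiseShare > 1e-8) {
      vTarget <- targetShares / noiseShare * vNoise   # noise pins the scale
    } else {
      # without a noise floor the absolute deformation scale is free;
      # keep it small enough that the tangent-space linearization holds
      # and alignment-induced mode interactions stay negligible
      T <- round(config@nCycles * config@samplingRate /
        config@strokeFrequency)
      vTarget <- targetShares / sum(targetShares) * (T * 4e-5)
    }
    amp[active] <- sqrt(vTarget[active] / cconst[active])
    amp["fold_fraction"] <- min(amp["fold_fraction"], 0.95)
    if (iter == maxIter)
      stop("mode-amplitude calibration (single-mode stage) did not ",
        "converge after ", maxIter, " iterations")
  }

  # stage 2: refine against the joint simulation, where alignment-induced
  # mode interactions redistribute variance between components
  if (sum(active) > 1L) {
    cfg <- config
    for (iter2 in seq_len(maxIter)) {
      cfg@modeAmplitudes <- amp[seq_len(4)]
      js <- .jointShares(planform, cfg, scale = scale)
      realized <- ifelse(active, js$shares, 0)
      if (all(abs(realized[active] - targetShares[active]) < tol)) {
        names(amp) <- .modeNames
        attr(amp, "realizedShares") <- realized
        attr(amp, "iterations") <- iter2
        return(amp)
      }
      upd <- sqrt(targetShares[active] / pmax(realized[active], 1e-6))
      amp[active] <- amp[active] * pmin(pmax(upd, 0.6), 1.6)  # damped
      amp["fold_fraction"] <- min(amp["fold_fraction"], 0.95)
    }
    stop("mode-amplitude calibration did not converge after ", maxIter,
      " joint iterations; last share residuals: ",
      paste(sprintf("%.3f", realized - targetShares), collapse = ", "))
  }
  names(amp) <- .modeNames
  attr(amp, "realizedShares") <- realized
  return(amp)
}
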