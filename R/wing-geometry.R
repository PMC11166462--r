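#' @include AllClasses.R
NULL

#' Wing position and plane angles of one configuration
#'
#' Azimuth and elevation of the wing are measured from the direction
#' running from the wing base (shoulder landmark) to the landmark centroid
#' in the lab frame; the geometric wing-plane angle alpha is taken from the
#' total-least-squares plane through the landmark centroid. Elevation is
#' reported against the horizontal plane and alpha against the vertical
#' plane, so a wing lying flat in the horizontal plane has elevation 0 and
#' alpha 90 deg.
#'
#' @param configuration k x 3 landmark coordinates (mm, lab frame).
#' @param baseIndex index of the wing-base (shoulder) landmark.
#' @return named numeric: \code{azimuth_deg}, \code{elevation_deg},
#'   \code{plane_angle_deg}.
#' @export
wingAngles <- function(configuration, baseIndex = 1L) {
  if (nrow(configuration) < 3L) stop("need at least 3 landmarks")
  ctr <- colMeans(configuration)
  v <- ctr - configuration[baseIndex, ]
  vn <- sqrt(sum(v^2))
  if (vn == 0) stop("degenerate geometry: base coincides with the centroid")
  cc <- sweep(configuration, 2, ctr)
  ev <- eigen(crossprod(cc), symmetric = TRUE)
  if (ev$values[2] < 1e-10 * max(ev$values[1], 1))
    stop("degenerate geometry: landmarks are collinear")
  n <- ev$vectors[, 3]
  c(azimuth_deg = .rad2deg(atan2(v[2], v[1])),
    elevation_deg = .rad2deg(asin(v[3] / vn)),
    plane_angle_deg = .rad2deg(asin(min(1, abs(n[3])))))
}

## quadratic sub-sample refinement of an extremum at index i
.refineExtremum <- function(y, i, times) {
  dt <- times[2] - times[1]
  a <- y[i - 1]; b <- y[i]; cc <- y[i + 1]
  den <- a - 2 * b + cc
  delta <- if (abs(den) < 1e-15) 0 else 0.5 * (a - cc) / den
  delta <- max(-0.5, min(0.5, delta))
  times[i] + delta * dt
}

#' Segment a trial into stroke cycles from the azimuth series
#'
#' Locates alternating azimuth maxima (pronation, downstroke onset) and
#' minima (supination) after a light low-pass filter (cutoff five times
#' the dominant frequency), refines each reversal to sub-sample precision
#' with a local quadratic fit, and derives per-cycle stroke frequencies
#' (1 / cycle duration), per-frame phases in [0, 1) anchored at pronation,
#' and the mid-downstroke / mid-upstroke frames.
#'
#' @param azimuth numeric(T) azimuth series (deg).
#' @param times numeric(T) timestamps (s), constant interval.
#' @return a \linkS4class{StrokeCycles}.
#' @export
segmentStrokes <- function(azimuth, times) {
  T <- length(azimuth)
  if (T != length(times) || T < 8L) stop("insufficient data")
  if (stats::sd(azimuth) < 1e-12)
    stop("insufficient data: azimuth series is constant")
  fs <- 1 / mean(diff(times))

  # dominant frequency for the filter cutoff
  y0 <- azimuth - mean(azimuth)
  sp <- Mod(stats::fft(y0))[seq_len(floor(T / 2))]
  fgrid <- fs * (seq_len(floor(T / 2)) - 1) / T
  f0 <- fgrid[which.max(sp[-1]) + 1L]
  cutoff <- 5 * f0
  y <- if (cutoff < 0.45 * fs && f0 > 0) {
    bf <- signal::butter(2, cutoff / (fs / 2))
    as.numeric(signal::filtfilt(bf, y0))
  } else y0

  dy <- diff(y)
  s <- sign(dy)
  s[s == 0] <- 1
  turns <- which(diff(s) != 0) + 1L    # interior extrema indices
  # filter transients distort extrema near the series boundaries
  margin <- 0.25 / f0
  turns <- turns[times[turns] > times[1] + margin &
                 times[turns] < times[T] - margin]
  if (length(turns) < 3L) stop("insufficient data: fewer than 3 reversals")
  isMax <- y[turns] > y[pmax(1L, turns - 1L)]
  revTimes <- vapply(turns, function(i) .refineExtremum(y, i, times),
    numeric(1))
  revType <- ifelse(isMax, "pronation", "supination")

  pro <- revTimes[revType == "pronation"]
  sup <- revTimes[revType == "supination"]
  phase <- rep(NA_real_, T)
  cyc <- rep(NA_integer_, T)
  down <- rep(NA, T)
  freqs <- numeric(0)
  midD <- integer(0); midU <- integer(0)
  if (length(pro) >= 2L) {
    freqs <- 1 / diff(pro)
    for (i in seq_len(length(pro) - 1L)) {
      t0 <- pro[i]; t1 <- pro[i + 1L]
      inCyc <- which(times >= t0 & times < t1)
      phase[inCyc] <- (times[inCyc] - t0) / (t1 - t0)
      cyc[inCyc] <- i
      sWithin <- sup[sup > t0 & sup < t1]
      if (length(sWithin)) {
        tSup <- sWithin[1]
        down[inCyc] <- times[inCyc] < tSup
        midD <- c(midD, which.min(abs(times - (t0 + tSup) / 2)))
        midU <- c(midU, which.min(abs(times - (tSup + t1) / 2)))
      }
    }
  }
  new("StrokeCycles", reversalTimes = revTimes, reversalType = revType,
    phase = phase, cycle = cyc, downstroke = down, frequencies = freqs,
    midDownstrokeFrames = midD, midUpstrokeFrames = midU)
}

## natural-spline interpolation of an ordered edge point sequence,
## parameterized by the normalized projection onto the span axis and
## evaluated at spanwise stations s in [0, 1]; spanwise parameterization
## keeps paired leading/trailing points at the same station so the chord
## segments are true spanwise sections
.interpEdge <- function(pts, s, spanAxis = NULL) {
  if (is.null(spanAxis)) {
    spanAxis <- pts[nrow(pts), ] - pts[1, ]
  }
  u <- spanAxis / sqrt(sum(spanAxis^2))
  proj <- as.numeric(sweep(pts, 2, pts[1, ]) %*% u)
  if (is.unsorted(proj, strictly = TRUE))
    stop("edge points are not ordered along the span axis")
  proj <- proj / proj[length(proj)]
  vapply(seq_len(ncol(pts)), function(j)
    stats::spline(proj, pts[, j], xout = s, method = "natural")$y,
    numeric(length(s)))
}

#' Interpolate chordal line segments along the wing
#'
#' Interpolates \code{nSections} points along the leading and trailing
#' edges (arclength-parameterized natural splines through the ordered edge
#' landmarks) and joins spanwise paired points, matched by normalized
#' arclength, into chordal line segments. Section radii are distances of
#' the segment midpoints from the wing base.
#'
#' @param configuration k x 3 landmark coordinates (mm).
#' @param planform a \linkS4class{WingPlanform} supplying the edge indices;
#'   alternatively pass \code{leadingEdge}, \code{trailingEdge} and
#'   \code{baseIndex} directly.
#' @param nSections number of chord segments (default 40).
#' @param leadingEdge,trailingEdge ordered landmark index vectors.
#' @param baseIndex wing-base landmark index.
#' @return a \linkS4class{ChordSegmentSet}.
#' @export
buildChordSegments <- function(configuration, planform = NULL,
    nSections = 40L, leadingEdge = NULL, trailingEdge = NULL,
    baseIndex = NULL) {
  if (!is.null(planform)) {
    leadingEdge <- planform@leadingEdge
    trailingEdge <- planform@trailingEdge
    baseIndex <- planform@shoulder
  }
  if (length(leadingEdge) < 3L || length(trailingEdge) < 3L)
    stop("edges need at least 3 landmarks each")
  if (nSections < 2L) stop("need at least 2 sections")
  s <- seq(0, 1, length.out = nSections)
  le <- .interpEdge(configuration[leadingEdge, ], s)
  te <- .interpEdge(configuration[trailingEdge, ], s)
  base <- configuration[baseIndex, ]
  mid <- (le + te) / 2
  radii <- sqrt(rowSums(sweep(mid, 2, base)^2))
  if (is.unsorted(radii, strictly = TRUE))
    stop("section radii are not strictly increasing; check edge ordering")
  new("ChordSegmentSet", lePoints = le, tePoints = te, sectionRadii = radii)
}

#' Sectional chord angles and tip-to-root twist
#'
#' \code{sectionAngles} measures each chordal segment's inclination (deg)
#' to the wing's own reference plane — the total-least-squares plane of
#' the segment endpoints, with its normal signed consistently with the
#' span (base to tip) and mean chord directions, so that a trailing edge
#' lying dorsal of the leading edge gives a positive angle.
#' \code{wingTwist} returns the signed tip-to-root twist
#' Theta = alpha_tip - alpha_root between the outermost and innermost
#' sections; because the reference plane moves rigidly with the wing, the
#' twist is invariant to rigid lab-frame motion, and wash-out (tip less
#' inclined than root) is negative.
#'
#' @param segments a \linkS4class{ChordSegmentSet}, or for
#'   \code{wingTwist} alternatively a numeric vector of section angles
#'   (deg) ordered root to tip.
#' @return numeric: per-section angles (deg), or the twist (deg).
#' @export
sectionAngles <- function(segments) {
  le <- segments@lePoints; te <- segments@tePoints
  .sectionAnglesXY(le, te)
}

## inclination of chords te - le out of the wing-attached frame spanned by
## the span axis (e1) and the mean chord direction (e2); because the frame
## rides rigidly with the wing, the angles (and the tip-to-root twist) are
## invariant to rigid lab-frame motion, and a uniform sectional rotation
## about the span axis shifts all angles equally
.sectionAnglesXY <- function(le, te) {
  mid <- (le + te) / 2
  e1 <- mid[nrow(mid), ] - mid[1, ]
  e1 <- e1 / sqrt(sum(e1^2))
  m <- colMeans(te - le)
  e2 <- m - sum(m * e1) * e1
  e2 <- e2 / sqrt(sum(e2^2))
  e3 <- c(e1[2] * e2[3] - e1[3] * e2[2], e1[3] * e2[1] - e1[1] * e2[3],
    e1[1] * e2[2] - e1[2] * e2[1])
  d <- te - le
  dn <- d %*% e3
  inPlane <- sqrt(pmax(0, rowSums(d^2) - dn^2))
  .rad2deg(atan2(dn, inPlane))
}

#' @rdname sectionAngles
#' @export
wingTwist <- function(segments) {
  a <- if (is(segments, "ChordSegmentSet")) sectionAngles(segments)
    else as.numeric(segments)
  if (length(a) < 2L) stop("need at least 2 sections")
  a[length(a)] - a[1L]
}

## check an ordered closed polygon for self-intersection (O(n^2))
.selfIntersects <- function(px, py) {
  n <- length(px)
  nxt <- c(seq_len(n)[-1], 1L)
  segInt <- function(a1, a2, b1, b2) {
    d1 <- (b2[1] - b1[1]) * (a1[2] - b1[2]) - (b2[2] - b1[2]) * (a1[1] - b1[1])
    d2 <- (b2[1] - b1[1]) * (a2[2] - b1[2]) - (b2[2] - b1[2]) * (a2[1] - b1[1])
    d3 <- (a2[1] - a1[1]) * (b1[2] - a1[2]) - (a2[2] - a1[2]) * (b1[1] - a1[1])
    d4 <- (a2[1] - a1[1]) * (b2[2] - a1[2]) - (a2[2] - a1[2]) * (b2[1] - a1[1])
    (d1 * d2 < 0) && (d3 * d4 < 0)
  }
  for (i in seq_len(n - 2L)) {
    for (j in seq(i + 2L, n)) {
      if (i == 1L && j == n) next          # adjacent through closure
      a1 <- c(px[i], py[i]); a2 <- c(px[nxt[i]], py[nxt[i]])
      b1 <- c(px[j], py[j]); b2 <- c(px[nxt[j]], py[nxt[j]])
      if (segInt(a1, a2, b1, b2)) return(TRUE)
    }
  }
  FALSE
}

#' Triangulate the wing planform
#'
#' Projects an approximately planar template configuration (typically the
#' mid-downstroke pose) onto its total-least-squares plane, adds internal
#' fill points on a grid at \code{internalSpacing}, triangulates landmarks
#' plus fill points by Delaunay triangulation, and prunes faces whose
#' centroids fall outside the wing perimeter polygon (ordered leading-edge
#' landmarks, tip, trailing edge reversed, closed across the root).
#'
#' @param configuration k x 3 template landmark coordinates (mm).
#' @param planform a \linkS4class{WingPlanform} supplying edge ordering.
#' @param internalSpacing fill-point spacing (mm), default 0.5.
#' @return a \linkS4class{WingMesh}; vertices 1..k are the landmarks.
#' @export
triangulateWing <- function(configuration, planform, internalSpacing = 0.5) {
  k <- nrow(configuration)
  ctr <- colMeans(configuration)
  cc <- sweep(configuration, 2, ctr)
  ev <- eigen(crossprod(cc), symmetric = TRUE)
  E <- ev$vectors[, 1:2]
  uv <- cc %*% E

  # perimeter: leading edge root-to-tip, trailing edge tip-to-root,
  # closed across the root (landmarks shared between the edge lists,
  # e.g. the tip, contribute once)
  le <- planform@leadingEdge
  te <- planform@trailingEdge
  polyIdx <- c(le, rev(te))
  polyIdx <- polyIdx[!duplicated(polyIdx)]
  px <- uv[polyIdx, 1]; py <- uv[polyIdx, 2]
  if (.selfIntersects(px, py))
    stop("invalid geometry: wing perimeter is self-intersecting")

  # staggered fill grid: rows offset by half a spacing (regular grids are
  # degenerate, cocircular inputs for Delaunay triangulation)
  gx <- seq(min(px), max(px), by = internalSpacing)
  gy <- seq(min(py), max(py), by = internalSpacing * sqrt(3) / 2)
  g <- as.matrix(expand.grid(u = gx, v = gy))
  odd <- (match(g[, 2], gy) %% 2L) == 1L
  g[odd, 1] <- g[odd, 1] + internalSpacing / 2
  inside <- sp::point.in.polygon(g[, 1], g[, 2], px, py) == 1
  g <- g[inside, , drop = FALSE]
  if (nrow(g)) {                     # drop fill points crowding a landmark
    minD <- apply(g, 1, function(p)
      min((uv[, 1] - p[1])^2 + (uv[, 2] - p[2])^2))
    g <- g[minD > (0.35 * internalSpacing)^2, , drop = FALSE]
  }

  allUV <- rbind(uv, g)
  # triangulate deterministically jittered copies (collinear landmark
  # runs are degenerate input); connectivity only — geometry keeps the
  # exact coordinates
  h <- 0.01 * internalSpacing
  ju <- allUV[, 1] + h * sin(1e4 * (3.1 * allUV[, 1] + 7.7 * allUV[, 2]))
  jv <- allUV[, 2] + h * sin(1e4 * (5.3 * allUV[, 1] + 2.9 * allUV[, 2]))
  tm <- interp::tri.mesh(ju, jv)
  faces <- interp::triangles(tm)[, 1:3, drop = FALSE]
  cx <- (allUV[faces[, 1], 1] + allUV[faces[, 2], 1] + allUV[faces[, 3], 1]) / 3
  cy <- (allUV[faces[, 1], 2] + allUV[faces[, 2], 2] + allUV[faces[, 3], 2]) / 3
  keep <- sp::point.in.polygon(cx, cy, px, py) > 0
  faces <- faces[keep, , drop = FALSE]

  # vertices in 3D: landmarks keep their tracked positions, fill points
  # are embedded in the fitted plane
  vfill <- sweep(g %*% t(E), 2, ctr, "+")
  vertices <- rbind(configuration, vfill)
  geom <- .faceGeometry(vertices, faces,
    basePoint = configuration[planform@shoulder, ])
  pos <- geom$areas > 1e-12
  faces <- faces[pos, , drop = FALSE]
  if (!nrow(faces)) stop("invalid geometry: triangulation yielded no faces")
  new("WingMesh", vertices = vertices, faces = faces,
    elementAreas = geom$areas[pos], elementRadii = geom$radii[pos],
    uv = allUV, basePoint = configuration[planform@shoulder, ],
    baseLandmark = planform@shoulder, nLandmarks = as.integer(k),
    internalSpacing = internalSpacing)
}

## triangle areas and centroid radii from the base point
.faceGeometry <- function(vertices, faces, basePoint) {
  a <- vertices[faces[, 1], , drop = FALSE]
  b <- vertices[faces[, 2], , drop = FALSE]
  cc <- vertices[faces[, 3], , drop = FALSE]
  u <- b - a; v <- cc - a
  cr <- cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
    u[, 3] * v[, 1] - u[, 1] * v[, 3],
    u[, 1] * v[, 2] - u[, 2] * v[, 1])
  areas <- 0.5 * sqrt(rowSums(cr^2))
  ctr <- (a + b + cc) / 3
  radii <- sqrt(rowSums(sweep(ctr, 2, basePoint)^2))
  list(areas = areas, radii = radii)
}

## thin-plate spline system mapping landmark uv to target values, with a
## ridge penalty on the bending weights; returns a reusable factorization
.tpsSystem <- function(uv, lambda = 1e-4) {
  k <- nrow(uv)
  if (k < 4L) stop("degenerate geometry: too few landmarks for surface fit")
  D <- as.matrix(stats::dist(uv))
  K <- ifelse(D > 0, D^2 * log(D), 0)
  P <- cbind(1, uv)
  A <- rbind(cbind(K + lambda * diag(k), P), cbind(t(P), matrix(0, 3, 3)))
  lu <- tryCatch(solve(A), error = function(e)
    stop("degenerate geometry: rank-deficient surface fit"))
  list(Ainv = lu, uv = uv, k = k)
}

.tpsWeights <- function(sys, targets) {
  rhs <- rbind(targets, matrix(0, 3, ncol(targets)))
  sys$Ainv %*% rhs
}

## evaluation matrix: rows are query uv points, columns kernel + affine
.tpsEvalMatrix <- function(sys, quv) {
  D <- sqrt(outer(quv[, 1], sys$uv[, 1], "-")^2 +
            outer(quv[, 2], sys$uv[, 2], "-")^2)
  K <- ifelse(D > 0, D^2 * log(D), 0)
  cbind(K, 1, quv)
}

#' Project the template mesh through a frame's landmark positions
#'
#' Fits a smoothness-regularized thin-plate deformation from the template
#' parameter plane to the frame's tracked 3D landmark positions and maps
#' every template mesh vertex through it, producing the frame's 3D wing
#' surface; element areas and centroid radii are recomputed in 3D. With
#' the default regularization, landmark vertices interpolate their tracked
#' positions to well under 0.1 mm for noise-free data.
#'
#' @param mesh the template \linkS4class{WingMesh}.
#' @param configuration k x 3 tracked landmark coordinates of the frame.
#' @param lambda ridge regularization of the thin-plate weights.
#' @return a \linkS4class{WingMesh} for the frame.
#' @export
projectMesh <- function(mesh, configuration, lambda = 1e-4) {
  k <- mesh@nLandmarks
  if (nrow(configuration) != k)
    stop("configuration must have the template's ", k, " landmarks")
  sys <- .tpsSystem(mesh@uv[seq_len(k), , drop = FALSE], lambda)
  W <- .tpsWeights(sys, configuration)
  B <- .tpsEvalMatrix(sys, mesh@uv)
  vertices <- B %*% W
  base <- configuration[mesh@baseLandmark, ]
  geom <- .faceGeometry(vertices, mesh@faces, base)
  pos <- geom$areas > 1e-12
  new("WingMesh", vertices = vertices, faces = mesh@faces[pos, , drop = FALSE],
    elementAreas = geom$areas[pos], elementRadii = geom$radii[pos],
    uv = mesh@uv, basePoint = base, baseLandmark = mesh@baseLandmark,
    nLandmarks = mesh@nLandmarks, internalSpacing = mesh@internalSpacing)
}

#' Non-dimensional second moment of wing area
#'
#' Computes the area-normalized second moment
#' \deqn{\hat S_2^2 = \sum_f r_f^2 \, dA_f / (S R^2)}
#' over the mesh elements, where r is the element centroid radius from the
#' wing base, S the total mesh area and R the wing length, and returns its
#' square root. The measure is invariant to uniform scaling and equals
#' sqrt(1/3) for a uniform rectangle spanning r in [0, R].
#'
#' @param mesh a \linkS4class{WingMesh}.
#' @param R wing length (mm).
#' @return the non-dimensional second moment of area (scalar in [0, 1]).
#' @export
secondMoment <- function(mesh, R) {
  S <- sum(mesh@elementAreas)
  if (S <= 0) stop("degenerate geometry: zero mesh area")
  if (R <= 0) stop("R must be positive")
  sqrt(sum(mesh@elementRadii^2 * mesh@elementAreas) / (S * R^2))
}

## maximum perpendicular deviation of points from the line through the
## first and last points; returns deviation and chord length
.chordDeviation <- function(pts) {
  p0 <- pts[1, ]; p1 <- pts[nrow(pts), ]
  d <- p1 - p0
  len <- sqrt(sum(d^2))
  if (len < 1e-12) stop("degenerate geometry: zero chord length")
  dn <- d / len
  rel <- sweep(pts, 2, p0)
  proj <- rel %*% dn
  perp <- rel - proj %*% t(dn)
  list(h = max(sqrt(rowSums(perp^2))), length = len)
}

#' Chordwise camber of a surface strip
#'
#' Maximum height of a chordwise surface strip above its chord line,
#' divided by the chord length (h_chord / c). The strip is given as points
#' sampled along the section from leading to trailing edge.
#'
#' @param strip m x 3 points along the section (m >= 3).
#' @return camber h_chord / c (dimensionless, non-negative).
#' @export
chordwiseCamber <- function(strip) {
  if (nrow(strip) < 3L) stop("need at least 3 surface samples")
  cd <- .chordDeviation(strip)
  cd$h / cd$length
}

#' Spanwise camber and wing length
#'
#' Given points sampled on the wing surface along the line connecting a
#' point 0.05 c behind the shoulder to the wing tip, returns the wing
#' length R (distance between the line's endpoints) and the spanwise
#' camber h_span / R, the maximum surface height above that line.
#'
#' @param spanCurve m x 3 surface points along the reference line, ordered
#'   base to tip.
#' @return list with elements \code{camber} (h_span / R) and \code{R}
#'   (mm).
#' @export
spanwiseCamber <- function(spanCurve) {
  if (nrow(spanCurve) < 3L) stop("need at least 3 surface samples")
  cd <- .chordDeviation(spanCurve)
  list(camber = cd$h / cd$length, R = cd$length)
}

#' Per-frame kinematic and morphological descriptors
#'
#' Runs the full per-frame descriptor pipeline: wing angles per frame,
#' stroke segmentation from the azimuth series, template mesh construction
#' at the (first) mid-downstroke, thin-plate projection of the template
#' mesh through every frame's landmarks, and from the projected surface
#' the area S, the non-dimensional second moment of area, tip-to-root
#' twist, per-section and mid-span chordwise camber, spanwise camber and
#' wing length R.
#'
#' @param series a \linkS4class{MarkerTimeSeries}.
#' @param planform the matching \linkS4class{WingPlanform}.
#' @param nSections number of chord sections (default 40).
#' @param nChordSamples surface samples per chord section.
#' @param internalSpacing mesh fill spacing (mm).
#' @param templateFrame frame index used as the mesh template; defaults to
#'   the first mid-downstroke frame.
#' @param lambda thin-plate regularization, see \code{\link{projectMesh}}.
#' @return list with elements \code{descriptors}
#'   (\linkS4class{DescriptorSeries}), \code{cycles}
#'   (\linkS4class{StrokeCycles}) and \code{templateMesh}
#'   (\linkS4class{WingMesh}).
#' @export
computeDescriptors <- function(series, planform, nSections = 40L,
    nChordSamples = 21L, internalSpacing = 0.5, templateFrame = NULL,
    lambda = 1e-4) {
  X <- series@coords
  T <- dim(X)[1]; k <- dim(X)[2]
  ang <- t(vapply(seq_len(T), function(t)
    wingAngles(X[t, , ], baseIndex = planform@shoulder), numeric(3)))
  cycles <- segmentStrokes(ang[, 1], series@times)
  if (is.null(templateFrame)) {
    if (!length(cycles@midDownstrokeFrames))
      stop("no mid-downstroke frame found; pass templateFrame explicitly")
    templateFrame <- cycles@midDownstrokeFrames[1]
  }
  tmplCfg <- X[templateFrame, , ]
  mesh <- triangulateWing(tmplCfg, planform, internalSpacing)

  # fixed uv sampling layout: mesh vertices, chord-section samples and the
  # spanwise reference line; the thin-plate system is factorized once
  sys <- .tpsSystem(mesh@uv[seq_len(k), , drop = FALSE], lambda)
  # stop just short of the tip, where a tapered chord degenerates to zero
  sGrid <- seq(0, 0.98, length.out = nSections)
  leUV <- .interpEdge(mesh@uv[planform@leadingEdge, , drop = FALSE], sGrid)
  teUV <- .interpEdge(mesh@uv[planform@trailingEdge, , drop = FALSE], sGrid)
  w <- seq(0, 1, length.out = nChordSamples)
  chordUV <- do.call(rbind, lapply(seq_len(nSections), function(j)
    cbind((1 - w) * leUV[j, 1] + w * teUV[j, 1],
          (1 - w) * leUV[j, 2] + w * teUV[j, 2])))
  shoulderUV <- mesh@uv[planform@shoulder, ]
  rootDir <- teUV[1, ] - leUV[1, ]
  rootChordLen <- sqrt(sum(rootDir^2))
  p0UV <- shoulderUV + 0.05 * rootChordLen * rootDir / rootChordLen
  tipUV <- mesh@uv[planform@tip, ]
  nSpan <- 41L
  wsp <- seq(0, 1, length.out = nSpan)
  spanUV <- cbind((1 - wsp) * p0UV[1] + wsp * tipUV[1],
                  (1 - wsp) * p0UV[2] + wsp * tipUV[2])
  Bmesh <- .tpsEvalMatrix(sys, mesh@uv)
  Bchord <- .tpsEvalMatrix(sys, chordUV)
  Bspan <- .tpsEvalMatrix(sys, spanUV)

  out <- data.frame(time_s = series@times, azimuth_deg = ang[, 1],
    elevation_deg = ang[, 2], plane_angle_deg = ang[, 3],
    area_mm2 = NA_real_, second_moment = NA_real_, twist_deg = NA_real_,
    midspan_camber = NA_real_, span_camber = NA_real_,
    wing_length_mm = NA_real_)
  camberProf <- matrix(NA_real_, T, nSections)
  le3 <- .interpEdge(tmplCfg[planform@leadingEdge, , drop = FALSE], sGrid)
  te3 <- .interpEdge(tmplCfg[planform@trailingEdge, , drop = FALSE], sGrid)
  mid3 <- (le3 + te3) / 2
  sectR <- sqrt(rowSums(sweep(mid3, 2, tmplCfg[planform@shoulder, ])^2))
  midIdx <- which.min(abs(sectR - max(sectR) / 2))

  for (t in seq_len(T)) {
    W <- .tpsWeights(sys, X[t, , ])
    verts <- Bmesh %*% W
    geom <- .faceGeometry(verts, mesh@faces, X[t, planform@shoulder, ])
    S <- sum(geom$areas)
    spanPts <- Bspan %*% W
    sc <- spanwiseCamber(spanPts)
    chordPts <- Bchord %*% W
    # sectional angles from chordal segments interpolated along the
    # tracked edges themselves (not the smoothed surface)
    alphas <- .sectionAnglesXY(
      .interpEdge(X[t, planform@leadingEdge, ], sGrid),
      .interpEdge(X[t, planform@trailingEdge, ], sGrid))
    for (j in seq_len(nSections)) {
      strip <- chordPts[((j - 1) * nChordSamples + 1):(j * nChordSamples), ,
        drop = FALSE]
      cd <- .chordDeviation(strip)
      camberProf[t, j] <- cd$h / cd$length
    }
    out$area_mm2[t] <- S
    out$second_moment[t] <-
      sqrt(sum(geom$radii^2 * geom$areas) / (S * sc$R^2))
    out$twist_deg[t] <- alphas[nSections] - alphas[1]
    out$midspan_camber[t] <- camberProf[t, midIdx]
    out$span_camber[t] <- sc$camber
    out$wing_length_mm[t] <- sc$R
  }
  desc <- new("DescriptorSeries", frame = out,
    chordCamberProfile = camberProf, sectionRadii = sectR)
  list(descriptors = desc, cycles = cycles, templateMesh = mesh)
}
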