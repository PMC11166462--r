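test_that("wing angles follow the lab-frame conventions", {
  pf <- rectPlanform()
  cfg <- markerCoords(pf)
  a <- wingAngles(cfg, baseIndex = pf@shoulder)
  expect_equal(unname(a["elevation_deg"]), 0, tolerance = 1e-10)
  expect_equal(unname(a["plane_angle_deg"]), 90, tolerance = 1e-10)

  Rz <- matrix(c(cos(pi / 6), sin(pi / 6), 0, -sin(pi / 6), cos(pi / 6), 0,
    0, 0, 1), 3, 3)
  a2 <- wingAngles(cfg %*% t(Rz), baseIndex = pf@shoulder)
  expect_equal(unname(a2["azimuth_deg"] - a["azimuth_deg"]), 30,
    tolerance = 1e-8)
  expect_equal(unname(a2["elevation_deg"]), 0, tolerance = 1e-8)
  expect_equal(unname(a2["plane_angle_deg"]), 90, tolerance = 1e-8)

  # closed-form tilt: rotating a planar cloud about y by phi lowers the
  # plane angle from 90 to 90 - phi
  set.seed(1)
  cloud <- cbind(runif(40, 0, 10), runif(40, 0, 5), 0)
  for (phi in c(10, 35, 60)) {
    Ry <- matrix(c(cos(phi * pi / 180), 0, -sin(phi * pi / 180), 0, 1, 0,
      sin(phi * pi / 180), 0, cos(phi * pi / 180)), 3, 3)
    at <- wingAngles(cloud %*% t(Ry))
    expect_equal(unname(at["plane_angle_deg"]), 90 - phi, tolerance = 1e-6)
  }
  expect_error(wingAngles(cbind(1:9, 2 * (1:9), 0 * (1:9))), "collinear")
})

test_that("stroke segmentation locates reversals and frequencies", {
  fs <- 2200
  tt <- (0:(5 * fs / 41)) / fs
  az <- 64.5 * cos(2 * pi * 41 * tt)
  cyc <- segmentStrokes(az, tt)
  expect_true(all(abs(cyc@frequencies - 41) < 0.5))
  expect_true(all(cyc@reversalType[-1] != head(cyc@reversalType, -1)))

  # time equivariance: a phase-shifted sinusoid shifts reversals alike
  dphi <- 0.1
  cyc2 <- segmentStrokes(64.5 * cos(2 * pi * 41 * tt - dphi), tt)
  shift <- dphi / (2 * pi * 41)
  i1 <- cyc@reversalTimes > 2 * shift & cyc@reversalTimes < max(tt) - 0.02
  matched <- vapply(cyc@reversalTimes[i1], function(rt)
    min(abs(cyc2@reversalTimes - (rt + shift))), numeric(1))
  expect_lt(max(matched), 1e-4)

  expect_error(segmentStrokes(rep(1, 100), (0:99) / fs), "insufficient")
})

test_that("generator stroke frequency is recovered within 2 percent", {
  mts <- simTrial(makePlanform(30, 55, 20), nCycles = 6)
  ang <- t(apply(markerCoords(mts), 1, wingAngles))
  cyc <- segmentStrokes(ang[, 1], frameTimes(mts))
  expect_lt(abs(mean(cyc@frequencies) - 41) / 41, 0.02)
})

test_that("chord segments reproduce analytic section chords", {
  pf <- rectPlanform(span = 20, chord = 5)
  segs <- buildChordSegments(markerCoords(pf), pf)
  chords <- sqrt(rowSums((segs@tePoints - segs@lePoints)^2))
  expect_equal(chords, rep(5, 40), tolerance = 1e-8)
  expect_true(all(diff(segs@sectionRadii) > 0))

  s2 <- buildChordSegments(markerCoords(pf), pf, nSections = 2L)
  expect_equal(nrow(s2@lePoints), 2)
  expect_equal(s2@lePoints[1, 1], 0, tolerance = 1e-8)
  expect_equal(s2@lePoints[2, 1], 20, tolerance = 1e-8)

  # symmetric elliptic planform: chord at station x is c0 sqrt(1-(x/b)^2)
  c0 <- 6; b <- 20
  pfE <- curvePlanform(b, function(x) c0 / 2 - c0 / 2 * sqrt(pmax(0, 1 - (x / b)^2)),
    function(x) c0 / 2 + c0 / 2 * sqrt(pmax(0, 1 - (x / b)^2)), nEdge = 12)
  segsE <- buildChordSegments(markerCoords(pfE), pfE, nSections = 30L)
  chordsE <- sqrt(rowSums((segsE@tePoints - segsE@lePoints)^2))
  xs <- (segsE@lePoints[, 1] + segsE@tePoints[, 1]) / 2
  analytic <- c0 * sqrt(pmax(0, 1 - (xs / b)^2))
  keep <- 1:26    # spline interpolation degrades at the degenerate tip
  expect_lt(max(abs(chordsE[keep] - analytic[keep]) / analytic[keep]), 0.03)

  expect_error(buildChordSegments(markerCoords(pf), leadingEdge = 1:2,
    trailingEdge = 9:16, baseIndex = 1L), "at least 3")
})

test_that("wing triangulation recovers analytic planform areas", {
  sq <- rectPlanform(span = 1, chord = 1, nEdge = 8, nInner = 8)
  mesh <- triangulateWing(markerCoords(sq), sq, internalSpacing = 0.05)
  expect_equal(meshArea(mesh), 1, tolerance = 0.005)

  # L-shaped perimeter: pruning leaves no face centroid outside and the
  # area matches the shoelace area of the polygon
  pfL <- curvePlanform(10, function(x) 0 * x,
    function(x) ifelse(x < 5, 4, 1.5), nEdge = 12)
  meshL <- triangulateWing(markerCoords(pfL), pfL, internalSpacing = 0.1)
  poly <- c(pfL@leadingEdge, rev(pfL@trailingEdge))
  poly <- poly[!duplicated(poly)]
  px <- meshL@uv[poly, 1]; py <- meshL@uv[poly, 2]
  shoelace <- abs(sum(px * c(py[-1], py[1]) - c(px[-1], px[1]) * py)) / 2
  ctr <- (meshL@uv[meshL@faces[, 1], ] + meshL@uv[meshL@faces[, 2], ] +
    meshL@uv[meshL@faces[, 3], ]) / 3
  expect_true(all(sp::point.in.polygon(ctr[, 1], ctr[, 2], px, py) > 0))
  expect_equal(meshArea(meshL), shoelace, tolerance = 0.005)

  # smooth convex-ish polygon against its own shoelace area
  pfC <- curvePlanform(12, function(x) -0.8 * x * (12 - x) / 36,
    function(x) 3 + 1.2 * x * (12 - x) / 36, nEdge = 14)
  meshC <- triangulateWing(markerCoords(pfC), pfC, internalSpacing = 0.1)
  polyC <- c(pfC@leadingEdge, rev(pfC@trailingEdge))
  polyC <- polyC[!duplicated(polyC)]
  pxc <- meshC@uv[polyC, 1]; pyc <- meshC@uv[polyC, 2]
  shoelaceC <- abs(sum(pxc * c(pyc[-1], pyc[1]) - c(pxc[-1], pxc[1]) * pyc)) / 2
  expect_equal(meshArea(meshC), shoelaceC, tolerance = 0.005)

  # crossing trailing edge makes the perimeter self-intersect
  pfX <- curvePlanform(10, function(x) 0 * x,
    function(x) ifelse(x < 5, 2, -1), nEdge = 10)
  expect_error(triangulateWing(markerCoords(pfX), pfX), "self-intersecting")
})

test_that("template mesh projection is exact for rigid motion", {
  pf <- rectPlanform(span = 10, chord = 5, nEdge = 8, nInner = 8)
  mesh <- triangulateWing(markerCoords(pf), pf, internalSpacing = 0.4)

  ident <- projectMesh(mesh, markerCoords(pf))
  expect_equal(ident@vertices, mesh@vertices, tolerance = 1e-6)

  set.seed(5)
  R <- properRotation(); b <- c(3, -2, 7)
  rot <- markerCoords(pf) %*% R + rep(1, nLandmarks(pf)) %o% b
  proj <- projectMesh(mesh, rot)
  expect_equal(proj@vertices,
    mesh@vertices %*% R + rep(1, nrow(mesh@vertices)) %o% b,
    tolerance = 1e-4)
  expect_lt(abs(meshArea(proj) - meshArea(mesh)) / meshArea(mesh), 1e-3)
})

test_that("projected mesh area approaches the developable area of a bend", {
  # landmarks at several chordwise stations so the surface fit can track
  # the cylinder between the edges
  xe <- seq(0, 10, length.out = 6)
  coords <- do.call(rbind, lapply(c(0, 1.25, 2.5, 3.75, 5), function(y)
    cbind(xe, y, 0)))
  pf <- new("WingPlanform", coords = coords, leadingEdge = 1:6,
    trailingEdge = 25:30, shoulder = 1L, tip = 6L, span = 10,
    rootChord = 5)
  Rc <- 6
  bend <- function(cfg) cbind(cfg[, 1], Rc * sin(cfg[, 2] / Rc),
    Rc * (1 - cos(cfg[, 2] / Rc)))
  bent <- bend(markerCoords(pf))
  errs <- vapply(c(1, 0.3), function(h) {
    mesh <- triangulateWing(markerCoords(pf), pf, internalSpacing = h)
    abs(meshArea(projectMesh(mesh, bent)) - 50) / 50
  }, numeric(1))
  expect_lt(errs[2], errs[1] + 1e-6)   # finer fill converges
  expect_lt(errs[2], 0.02)
})

test_that("second moment of area matches closed-form fixtures", {
  # uniform slender rectangle spanning r in [0, R]: Shat2^2 = 1/3
  pf <- rectPlanform(span = 20, chord = 0.6, nEdge = 10, nInner = 6)
  mesh <- triangulateWing(markerCoords(pf), pf, internalSpacing = 0.12)
  expect_equal(secondMoment(mesh, 20)^2, 1 / 3, tolerance = 0.005)
  expect_equal(secondMoment(mesh, 20), sqrt(1 / 3), tolerance = 0.003)

  # all area concentrated at r = R
  tri <- new("WingMesh",
    vertices = rbind(c(20, 0, 0), c(20.01, 0.01, 0), c(20, 0.02, 0)),
    faces = matrix(1:3, 1), elementAreas = 1, elementRadii = 20,
    uv = matrix(0, 3, 2), basePoint = c(0, 0, 0), baseLandmark = 1L,
    nLandmarks = 3L, internalSpacing = 1)
  expect_equal(secondMoment(tri, 20), 1, tolerance = 1e-10)

  # linearly tapering chord c(r) = c0 (1 - r/R): Shat2^2 = 1/6
  span <- 20; c0 <- 0.6
  xle <- seq(0, span, length.out = 11)
  xte <- seq(0, 0.97 * span, length.out = 10)
  coords <- rbind(cbind(xle, 0, 0), cbind(xte, c0 * (1 - xte / span), 0))
  pfT <- new("WingPlanform", coords = coords, leadingEdge = 1:11,
    trailingEdge = 12:21, shoulder = 1L, tip = 11L, span = span,
    rootChord = c0)
  meshT <- triangulateWing(coords, pfT, internalSpacing = 0.1)
  expect_equal(secondMoment(meshT, span)^2, 1 / 6, tolerance = 0.005)

  # uniform scale invariance
  pf2 <- rectPlanform(span = 40, chord = 1.2, nEdge = 10, nInner = 6)
  mesh2 <- triangulateWing(markerCoords(pf2), pf2, internalSpacing = 0.24)
  expect_equal(secondMoment(mesh2, 40), secondMoment(mesh, 20),
    tolerance = 1e-3)
  expect_error(secondMoment(tri, -1), "positive")
})

test_that("twist and camber fixtures are exact", {
  expect_equal(wingTwist(c(10, 25)), 15)
  pf <- rectPlanform()
  expect_equal(wingTwist(buildChordSegments(markerCoords(pf), pf)), 0,
    tolerance = 1e-10)

  # flat strip
  flat <- cbind(0, seq(0, 10, length.out = 21), 0)
  expect_equal(chordwiseCamber(flat), 0, tolerance = 1e-12)

  # circular arc of height 1 over chord 10 -> camber 0.1
  Rc <- (25 + 1) / 2
  y <- seq(0, 10, length.out = 41)
  arc <- cbind(0, y, (1 - Rc) + sqrt(Rc^2 - (y - 5)^2))
  expect_equal(chordwiseCamber(arc), 0.1, tolerance = 1e-10)

  # parabolic arc sampled at 41 points: h/c to 1e-6
  h <- 0.7; cl <- 10
  par <- cbind(0, y, 4 * h * (y / cl) * (1 - y / cl))
  expect_equal(chordwiseCamber(par), h / cl, tolerance = 1e-6)

  # spanwise camber: flat, circular, and scale-invariant
  span <- seq(0, 20, length.out = 41)
  expect_equal(spanwiseCamber(cbind(span, 0, 0))$camber, 0, tolerance = 1e-12)
  s <- 1.5; L <- 20
  Rs <- (L^2 / 4 + s^2) / (2 * s)
  arcS <- cbind(span, 0, (s - Rs) + sqrt(Rs^2 - (span - 10)^2))
  sc <- spanwiseCamber(arcS)
  expect_equal(sc$camber, s / L, tolerance = 1e-10)
  expect_equal(sc$R, L, tolerance = 1e-10)
  sc2 <- spanwiseCamber(2 * arcS)
  expect_equal(sc2$camber, sc$camber, tolerance = 1e-12)
  expect_equal(sc2$R, 2 * L, tolerance = 1e-10)
})

test_that("morphological descriptors are invariant to rigid lab motion", {
  pf <- makePlanform(40, 55, 20)
  cfg <- simulationConfig(nCycles = 2, noiseSd = 0,
    modeAmplitudes = modeAmps(twist = 12, fold = 0.08, bend = 0.02,
      redis = 0.02))
  mts <- thinFrames(simulateTrajectory(pf, cfg), 8L)
  set.seed(9)
  R <- properRotation(); b <- c(10, -5, 3)
  mts2 <- new("MarkerTimeSeries", coords = applyRigid(markerCoords(mts), R, b),
    times = frameTimes(mts), labels = markerLabels(mts),
    condition = "typical", individual = "sim")
  d1 <- computeDescriptors(mts, pf, internalSpacing = 1.5, templateFrame = 4L)
  d2 <- computeDescriptors(mts2, pf, internalSpacing = 1.5, templateFrame = 4L)
  f1 <- descriptorFrame(d1$descriptors); f2 <- descriptorFrame(d2$descriptors)
  expect_equal(f2$twist_deg, f1$twist_deg, tolerance = 1e-6)
  # surface-based descriptors rebuild the fill grid in the rotated frame,
  # so equality is to mesh resolution rather than machine precision
  for (col in c("area_mm2", "second_moment", "midspan_camber",
      "span_camber", "wing_length_mm"))
    expect_equal(f2[[col]], f1[[col]], tolerance = 1e-3, label = col)
  expect_gt(max(abs(f2$azimuth_deg - f1$azimuth_deg)), 1)
})

test_that("wing folding reduces the mesh area at maximal fold", {
  pf <- makePlanform(40, 55, 20)
  cfg <- simulationConfig(strokeAmplitude = 0, elevationAmplitude = 0,
    strokePlaneAngle = 0, nCycles = 2, noiseSd = 0,
    modeAmplitudes = modeAmps(fold = 0.15))
  mts <- simulateTrajectory(pf, cfg)
  # fold factor 1 - 0.15 (1 + sin(wt - pi/2)) / 2 is maximal at wt = pi/2
  tmax <- which.min(1 - 0.15 * (1 + sin(2 * pi * 41 * frameTimes(mts) - pi / 2)) / 2)
  mesh <- triangulateWing(markerCoords(pf), pf, internalSpacing = 1)
  aFold <- meshArea(projectMesh(mesh, markerCoords(mts)[tmax, , ]))
  expect_lt(aFold, meshArea(mesh))
})
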