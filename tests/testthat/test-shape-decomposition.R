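test_that("exactly superimposable configurations align to zero residuals", {
  set.seed(11)
  pf <- makePlanform(24, 30, 10)
  base <- markerCoords(pf)
  T <- 8
  X <- array(NA_real_, c(T, nrow(base), 3))
  for (t in seq_len(T))
    X[t, , ] <- (0.5 + runif(1)) * base %*% properRotation() +
      rep(1, nrow(base)) %o% rnorm(3, 0, 20)
  al <- gpaAlign(X, scale = TRUE)
  expect_lt(max(procrustesDistance(al$aligned)), 1e-9)

  # template equals the common shape up to a similarity transform
  z <- sweep(base, 2, colMeans(base))
  z <- z / sqrt(sum(z^2))
  M <- al$template@coords
  R <- svd(crossprod(z, M))
  expect_equal(sum(R$d), 1, tolerance = 1e-8)   # full Procrustes similarity

  # reconstruction identity: lambda (X_M + e) Gamma + b reproduces inputs
  for (t in c(1L, T)) {
    rec <- al$aligned@scales[t] *
      (M + al$aligned@residuals[t, , ]) %*% al$aligned@rotations[, , t] +
      rep(1, nrow(base)) %o% al$aligned@translations[t, ]
    expect_equal(rec, X[t, , ], tolerance = 1e-9)
  }
})

test_that("two-configuration alignment matches brute-force minimizers", {
  # independent oracle: numeric minimization of || z1 R - z2 ||^2 over
  # rotations parameterized by Euler angles, from multiple starts
  bruteForce <- function(z1, z2) {
    obj <- function(a) {
      Rz <- matrix(c(cos(a[1]), sin(a[1]), 0, -sin(a[1]), cos(a[1]), 0,
        0, 0, 1), 3)
      Ry <- matrix(c(cos(a[2]), 0, -sin(a[2]), 0, 1, 0,
        sin(a[2]), 0, cos(a[2])), 3)
      Rx <- matrix(c(1, 0, 0, 0, cos(a[3]), sin(a[3]),
        0, -sin(a[3]), cos(a[3])), 3)
      sum((z1 %*% (Rz %*% Ry %*% Rx) - z2)^2)
    }
    best <- Inf
    for (i in 1:12) {
      o <- stats::optim(runif(3, -pi, pi), obj,
        control = list(reltol = 1e-14, maxit = 2000))
      best <- min(best, o$value)
    }
    best
  }
  set.seed(21)
  for (i in 1:20) {
    k <- sample(5:12, 1)
    A <- matrix(rnorm(3 * k), k)
    B <- A + matrix(rnorm(3 * k, 0, 0.2), k)
    pre <- function(X) {
      Xc <- sweep(X, 2, colMeans(X))
      Xc / sqrt(sum(Xc^2))
    }
    z1 <- pre(A); z2 <- pre(B)
    al <- gpaAlign(aperm(array(c(A, B), c(k, 3, 2)), c(3, 1, 2)),
      scale = TRUE)
    # pairwise squared distance between the two aligned pre-shapes equals
    # twice the summed squared residuals, and the brute-force minimum
    dGpa <- sum((al$aligned@residuals[1, , ] - al$aligned@residuals[2, , ])^2)
    expect_equal(dGpa, bruteForce(z1, z2), tolerance = 1e-6)
  }
})

test_that("two-configuration alignment agrees with vegan's Procrustes", {
  set.seed(31)
  k <- 10
  A <- matrix(rnorm(3 * k), k)
  B <- A + matrix(rnorm(3 * k, 0, 0.1), k)
  al <- gpaAlign(aperm(array(c(A, B), c(k, 3, 2)), c(3, 1, 2)), scale = TRUE)
  dGpa <- sum((al$aligned@residuals[1, , ] - al$aligned@residuals[2, , ])^2)
  pr <- vegan::procrustes(scale(A, scale = FALSE), scale(B, scale = FALSE),
    symmetric = TRUE)
  # vegan reports the full-Procrustes ss = 1 - s^2 with s the sum of
  # singular values; the rotation-only pre-shape distance is 2 (1 - s)
  expect_equal(dGpa, 2 * (1 - sqrt(1 - pr$ss)), tolerance = 1e-6)
})

test_that("scaling keeps wing folding as in-plane shape variance", {
  pf <- makePlanform(40, 55, 20)
  cfg <- simulationConfig(nCycles = 4, noiseSd = 0,
    modeAmplitudes = modeAmps(fold = 0.12))
  mts <- thinFrames(simulateTrajectory(pf, cfg), 4L)
  inplaneFraction <- function(al) {
    M <- al$template@coords
    n <- eigen(crossprod(sweep(M, 2, colMeans(M))),
      symmetric = TRUE)$vectors[, 3]
    E <- al$aligned@residuals
    oop <- sum(vapply(seq_len(dim(E)[1]), function(t)
      sum((E[t, , ] %*% n)^2), numeric(1)))
    1 - oop / sum(E^2)
  }
  alS <- gpaAlign(mts, scale = TRUE)
  alU <- gpaAlign(mts, scale = FALSE)
  expect_gt(inplaneFraction(alS), 0.95)
  # residual norms differ between the runs beyond a common scale factor
  eS <- procrustesDistance(alS$aligned)
  eU <- procrustesDistance(alU$aligned)
  expect_gt(max(abs(eS / mean(eS) - eU / mean(eU))), 0.01)
})

test_that("Procrustes and Riemannian distances obey the closed forms", {
  expect_equal(riemannianDistance(0), 0)
  expect_equal(riemannianDistance(1), pi / 3)
  expect_equal(riemannianDistance(2), pi)
  expect_error(riemannianDistance(2.1), "\\[0, 2\\]")
  eps <- seq(0.05, 2, by = 0.05)
  expect_true(all(riemannianDistance(eps) >= eps))
  expect_equal(procrustesDistance(matrix(0, 5, 3)), 0)
})

test_that("tangent projection maps the template to zero and norms to sin(rho)", {
  pf <- makePlanform(20, 30, 10)
  M <- sweep(markerCoords(pf), 2, colMeans(markerCoords(pf)))
  M <- M / sqrt(sum(M^2))
  template <- new("TemplateShape", coords = M, centroidSize = 1,
    scaled = TRUE)
  k <- nrow(M)
  mkAligned <- function(res) new("AlignedSeries",
    residuals = aperm(array(res, c(k, 3, 1)), c(3, 1, 2)),
    scales = 1, rotations = array(diag(3), c(3, 3, 1)),
    translations = matrix(0, 1, 3), scaled = TRUE)

  tc0 <- tangentProject(mkAligned(matrix(0, k, 3)), template)
  expect_lt(max(abs(tangentMatrix(tc0))), 1e-12)

  # geodesic construction: a pre-shape at Riemannian distance rho has
  # orthogonal tangent projection of norm sin(rho)
  set.seed(5)
  w <- rnorm(3 * k)
  w <- w - sum(w * as.numeric(M)) * as.numeric(M)
  w <- w / sqrt(sum(w^2))
  for (rho in c(0.05, 0.3, 1.0)) {
    u <- cos(rho) * as.numeric(M) + sin(rho) * w
    res <- matrix(u, k, 3) - M
    tc <- tangentProject(mkAligned(res), template)
    expect_equal(sqrt(sum(tangentMatrix(tc)^2)), sin(rho),
      tolerance = 1e-10)
    # small residuals: tangent coordinates equal residuals to O(eps^2)
    if (rho <= 0.05)
      expect_lt(max(abs(tangentMatrix(tc) - as.numeric(res))), rho^2)
  }
})

test_that("SVD decomposition has the stated algebraic structure", {
  set.seed(7)
  # rank-1 tangent matrix
  u <- rnorm(20); v <- rnorm(30)
  M0 <- matrix(rnorm(30), 10, 3)
  M0 <- sweep(M0, 2, colMeans(M0)); M0 <- M0 / sqrt(sum(M0^2))
  tmpl <- new("TemplateShape", coords = M0, centroidSize = 1, scaled = TRUE)
  tc1 <- new("TangentCoords", matrix = u %o% v, scaled = TRUE)
  d1 <- svdDecompose(tc1, tmpl)
  expect_equal(varianceProportions(d1$basis)[1], 1, tolerance = 1e-10)

  # reconstruction identity U D V' on a generic matrix
  X <- matrix(rnorm(20 * 30), 20, 30)
  tc <- new("TangentCoords", matrix = X, scaled = TRUE)
  d <- svdDecompose(tc, tmpl)
  Xc <- sweep(X, 2, colMeans(X))
  expect_equal(shapeScores(d$scores) %*% t(d$basis@V), Xc,
    tolerance = 1e-8)
  expect_equal(sum(varianceProportions(d$basis)), 1, tolerance = 1e-10)
  # scores' column variances are proportional to d^2
  sc <- shapeScores(d$scores)
  expect_equal(colSums(sc^2), singularValues(d$basis)^2, tolerance = 1e-8)

  expect_error(svdDecompose(new("TangentCoords",
    matrix = matrix(0, 5, 9), scaled = TRUE), tmpl), "degenerate")
})

test_that("the decomposition is invariant to a common rigid motion", {
  pf <- makePlanform(30, 55, 20)
  mts <- simTrial(pf, nCycles = 3, thin = 8L)
  d1 <- decompose(mts)
  set.seed(13)
  X2 <- applyRigid(markerCoords(mts), properRotation(), c(5, 8, -2), s = 1.7)
  d2 <- decompose(new("MarkerTimeSeries", coords = X2,
    times = frameTimes(mts), labels = markerLabels(mts),
    condition = "typical", individual = "sim"))
  expect_equal(procrustesDistance(d2$aligned), procrustesDistance(d1$aligned),
    tolerance = 1e-8)
  expect_equal(singularValues(d2$basis), singularValues(d1$basis),
    tolerance = 1e-8)
  s1 <- shapeScores(d1$scores); s2 <- shapeScores(d2$scores)
  for (j in 1:4) {
    flip <- sign(sum(s1[, j] * s2[, j]))
    expect_equal(flip * s2[, j], s1[, j], tolerance = 1e-6)
  }
})

test_that("mode reconstructions are complete and anchored at the template", {
  pf <- makePlanform(30, 55, 20)
  mts <- simTrial(pf, nCycles = 3, thin = 8L)
  d <- decompose(mts)
  expect_equal(reconstructMode(d$basis, 1, 0), templateCoords(d$basis),
    tolerance = 1e-12)
  expect_error(reconstructMode(d$basis, ncol(d$basis@V) + 1L, 0.1),
    "out of range")

  # full-score reconstruction reproduces each frame's aligned pre-shape
  sc <- shapeScores(d$scores)
  M <- templateCoords(d$basis)
  for (t in c(1L, 5L, nrow(sc))) {
    rec <- reconstructShape(d$basis, sc[t, ])
    expect_equal(rec, M + d$aligned@residuals[t, , ], tolerance = 1e-6)
  }
})

test_that("single-mode deformation fields are recovered by the first shape variable", {
  pf <- makePlanform(40, 55, 20)
  cfg <- simulationConfig(nCycles = 4, noiseSd = 0.01,
    modeAmplitudes = modeAmps(twist = 10))
  mts <- thinFrames(simulateTrajectory(pf, cfg), 4L)
  d <- decompose(mts)
  sc <- shapeScores(d$scores)
  tstar <- which.max(abs(sc[, 1]))
  recon <- reconstructMode(d$basis, 1, sc[tstar, 1])
  actual <- d$aligned@residuals[tstar, , ]
  expect_gt(abs(cor(as.numeric(recon - templateCoords(d$basis)),
    as.numeric(actual))), 0.99)
})

test_that("deformation vector angles separate in-plane from out-of-plane modes", {
  M0 <- matrix(c(rnorm(20), rnorm(20), rep(0, 20)), 20, 3)
  M0 <- sweep(M0, 2, colMeans(M0)); M0 <- M0 / sqrt(sum(M0^2))
  tmpl <- new("TemplateShape", coords = M0, centroidSize = 1, scaled = TRUE)
  mkBasis <- function(pattern) {
    v <- as.numeric(pattern); v <- v / sqrt(sum(v^2))
    new("ShapeBasis", V = cbind(v), d = 1, varianceProportions = 1,
      columnMeans = rep(0, 60), template = tmpl, scaled = TRUE)
  }
  set.seed(2)
  zOnly <- cbind(matrix(0, 20, 2), rnorm(20))
  expect_equal(deformationVectorAngle(mkBasis(zOnly), 1, 0.1), 90,
    tolerance = 1e-6)
  xyOnly <- cbind(matrix(rnorm(40), 20, 2), rep(0, 20))
  expect_equal(deformationVectorAngle(mkBasis(xyOnly), 1, 0.1), 0,
    tolerance = 1e-6)
})

test_that("projection onto a fixed basis is consistent and linear", {
  pf <- makePlanform(30, 55, 20)
  mts <- simTrial(pf, nCycles = 3, thin = 8L)
  d <- decompose(mts)
  proj <- projectOntoBasis(mts, d$basis)
  expect_equal(shapeScores(proj), shapeScores(d$scores), tolerance = 1e-8)

  # rigid-motion copies of the template score to zero
  M <- templateCoords(d$basis)
  set.seed(17)
  X <- array(NA_real_, c(5, nrow(M), 3))
  for (t in 1:5)
    X[t, , ] <- 40 * M %*% properRotation() + rep(1, nrow(M)) %o% rnorm(3)
  rig <- new("MarkerTimeSeries", coords = X, times = (0:4) / 100,
    labels = markerLabels(mts), condition = "typical", individual = "t")
  expect_lt(max(abs(shapeScores(projectOntoBasis(rig, d$basis)))), 1e-8)

  # doubling a small fold amplitude about doubles the associated score
  cfgs <- lapply(c(0.02, 0.04), function(a)
    simulationConfig(nCycles = 3, noiseSd = 0,
      modeAmplitudes = modeAmps(fold = a)))
  base <- decompose(thinFrames(simulateTrajectory(pf, cfgs[[1]]), 8L))
  amp1 <- diff(range(shapeScores(base$scores)[, 1]))
  treat <- thinFrames(simulateTrajectory(pf, cfgs[[2]]), 8L)
  amp2 <- diff(range(shapeScores(projectOntoBasis(treat, base$basis))[, 1]))
  expect_equal(amp2 / amp1, 2, tolerance = 0.1)
})

test_that("landmark sampling curves saturate with subset size", {
  pf <- makePlanform(40, 55, 20)
  mts <- simTrial(pf, nCycles = 4)
  full <- landmarkSamplingCurve(mts, 40L, nReps = 1L, seed = 1L)
  expect_equal(full$recovered, 1, tolerance = 1e-8)

  curve <- landmarkSamplingCurve(mts, c(6L, 15L, 30L), nReps = 5L, seed = 2L)
  expect_true(all(diff(curve$recovered) > -0.02))   # non-decreasing
  expect_error(landmarkSamplingCurve(mts, 2L), "between 3")
})
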