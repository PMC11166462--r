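#' @include AllClasses.R
NULL

## optimal rotation (reflection excluded) taking configuration z onto M,
## i.e. argmin over R in SO(3) of || z R - M ||_F
.opaRotation <- function(z, M) {
  A <- crossprod(z, M)
  sv <- svd(A)
  R <- sv$u %*% t(sv$v)
  if (det(R) < 0) {
    u <- sv$u
    u[, 3] <- -u[, 3]    # flip the direction of least variance, never reflect
    R <- u %*% t(sv$v)
  }
  R
}

#' Generalized Procrustes alignment of a landmark time series
#'
#' Iterative least-squares superimposition of all configurations to a
#' converged template shape. Each configuration is centered (and, when
#' \code{scale = TRUE}, scaled to unit centroid size), rotated to the
#' current mean shape by orthogonal Procrustes analysis with reflections
#' excluded, and the mean is recomputed until it changes by less than
#' \code{tol} (relative). The fitted model for frame t is
#' \code{X_t = lambda_t (X_M + e_t) Gamma_t + b_t}; the residuals
#' \code{e_t} are the elements of shape.
#'
#' @param series a \linkS4class{MarkerTimeSeries} (or T x k x 3 array).
#' @param scale logical; scale configurations to unit centroid size. With
#'   \code{scale = FALSE}, configurations are centered and rotated only and
#'   all \code{lambda_t} are 1.
#' @param tol relative convergence tolerance on the template coordinates.
#' @param maxIter maximum number of GPA iterations.
#' @return list with elements \code{template}
#'   (\linkS4class{TemplateShape}) and \code{aligned}
#'   (\linkS4class{AlignedSeries}).
#' @export
gpaAlign <- function(series, scale = TRUE, tol = 1e-9, maxIter = 200L) {
  X <- if (is(series, "MarkerTimeSeries")) series@coords else series
  d <- dim(X)
  if (length(d) != 3L || d[3] != 3L) stop("need a T x k x 3 array")
  T <- d[1]; k <- d[2]
  if (T < 2L) stop("need at least 2 frames")
  if (k < 3L) stop("need at least 3 landmarks")

  trans <- matrix(NA_real_, T, 3)
  sizes <- numeric(T)
  Z <- array(NA_real_, c(T, k, 3))
  for (t in seq_len(T)) {
    cfg <- X[t, , ]
    b <- colMeans(cfg)
    cc <- sweep(cfg, 2, b)
    s <- sqrt(sum(cc^2))
    if (s == 0) stop("degenerate configuration at frame ", t)
    trans[t, ] <- b
    sizes[t] <- s
    Z[t, , ] <- if (scale) cc / s else cc
  }

  M <- Z[1, , ]
  if (scale) M <- M / sqrt(sum(M^2))
  rot <- array(NA_real_, c(3, 3, T))
  aligned <- array(NA_real_, c(T, k, 3))
  converged <- FALSE
  for (iter in seq_len(maxIter)) {
    for (t in seq_len(T)) {
      R <- .opaRotation(Z[t, , ], M)
      rot[, , t] <- R
      aligned[t, , ] <- Z[t, , ] %*% R
    }
    Mnew <- apply(aligned, c(2, 3), mean)
    Mnew <- sweep(Mnew, 2, colMeans(Mnew))
    if (scale) Mnew <- Mnew / sqrt(sum(Mnew^2))
    delta <- sqrt(sum((Mnew - M)^2)) / sqrt(sum(M^2))
    M <- Mnew
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged)
    stop("GPA did not converge after ", maxIter,
      " iterations (last relative change ", format(delta), ")")

  # final rotations and residuals against the converged template
  for (t in seq_len(T)) {
    R <- .opaRotation(Z[t, , ], M)
    rot[, , t] <- R
    aligned[t, , ] <- Z[t, , ] %*% R
  }
  resid <- aligned - rep(1, T) %o% M
  # Gamma_t in the model is the inverse of the fitting rotation
  gam <- array(NA_real_, c(3, 3, T))
  for (t in seq_len(T)) gam[, , t] <- t(rot[, , t])

  template <- new("TemplateShape", coords = M,
    centroidSize = sqrt(sum(M^2)), scaled = scale)
  alignedS <- new("AlignedSeries", residuals = resid,
    scales = if (scale) sizes else rep(1, T), rotations = gam,
    translations = trans, scaled = scale)
  list(template = template, aligned = alignedS)
}

#' Procrustes and Riemannian shape distances
#'
#' \code{procrustesDistance} returns the Procrustes distance
#' epsilon = sqrt(tr(e e^T)) of each frame's residual matrix from the
#' template; \code{riemannianDistance} maps epsilon to the Riemannian
#' distance rho = 2 asin(epsilon / 2).
#'
#' @param e an \linkS4class{AlignedSeries} (per-frame distances) or a
#'   single k x 3 residual matrix.
#' @return numeric vector (or scalar) of distances.
#' @export
procrustesDistance <- function(e) {
  if (is(e, "AlignedSeries")) sqrt(apply(e@residuals^2, 1, sum))
  else sqrt(sum(e^2))
}

#' @param epsilon Procrustes distance(s) in [0, 2].
#' @rdname procrustesDistance
#' @export
riemannianDistance <- function(epsilon) {
  if (any(epsilon < 0 | epsilon > 2))
    stop("epsilon must lie in [0, 2]")
  2 * asin(epsilon / 2)
}

#' Orthogonal projection into the template's tangent space
#'
#' Each aligned configuration, as a unit pre-shape vector, is orthogonally
#' projected onto the hyperplane tangent to the pre-shape sphere at the
#' template; the template itself maps to the zero vector and a shape at
#' Riemannian distance rho maps to a vector of norm sin(rho). Unscaled
#' alignments are normalized internally for the projection and the result
#' re-scaled by the configuration's centroid size.
#'
#' @param aligned an \linkS4class{AlignedSeries}.
#' @param template the matching \linkS4class{TemplateShape}.
#' @return a \linkS4class{TangentCoords}.
#' @export
tangentProject <- function(aligned, template) {
  T <- dim(aligned@residuals)[1]
  k <- dim(aligned@residuals)[2]
  M <- template@coords
  mhat <- as.numeric(M) / sqrt(sum(M^2))
  out <- matrix(NA_real_, T, 3 * k)
  for (t in seq_len(T)) {
    v <- as.numeric(M + aligned@residuals[t, , ])
    sz <- sqrt(sum(v^2))
    u <- v / sz
    p <- u - sum(u * mhat) * mhat
    out[t, ] <- if (aligned@scaled) p else sz * p
  }
  new("TangentCoords", matrix = out, scaled = aligned@scaled)
}

#' SVD decomposition of tangent coordinates into shape variables
#'
#' Column-mean-centers the tangent coordinate matrix and takes its
#' economy-size singular value decomposition U D V'. The columns of V are
#' the shape variables, the columns of U D the per-frame shape scores, and
#' d^2 / sum(d^2) the proportion of shape variance explained by each
#' ranked singular value. A deterministic sign convention (the largest-
#' magnitude loading of each shape variable is positive) makes the
#' decomposition reproducible across platforms.
#'
#' @param tangent a \linkS4class{TangentCoords}.
#' @param template the \linkS4class{TemplateShape} of the alignment
#'   (stored in the basis for reconstruction and projection).
#' @return list with elements \code{basis} (\linkS4class{ShapeBasis}) and
#'   \code{scores} (\linkS4class{ShapeScores}).
#' @export
svdDecompose <- function(tangent, template) {
  X <- tangent@matrix
  cm <- colMeans(X)
  Xc <- sweep(X, 2, cm)
  if (max(abs(Xc)) < 1e-14)
    stop("degenerate decomposition: tangent coordinates have no variation")
  sv <- svd(Xc)
  r <- sum(sv$d > max(sv$d) * 1e-10)
  U <- sv$u[, seq_len(r), drop = FALSE]
  V <- sv$v[, seq_len(r), drop = FALSE]
  dvals <- sv$d[seq_len(r)]
  for (j in seq_len(r)) {      # deterministic sign convention
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) { V[, j] <- -V[, j]; U[, j] <- -U[, j] }
  }
  scores <- U %*% diag(dvals, r)
  basis <- new("ShapeBasis", V = V, d = dvals,
    varianceProportions = dvals^2 / sum(dvals^2), columnMeans = cm,
    template = template, scaled = tangent@scaled)
  ss <- new("ShapeScores", scores = scores,
    phase = rep(NA_real_, nrow(scores)), condition = "", individual = "")
  list(basis = basis, scores = ss)
}

## inverse of the orthogonal tangent projection for a tangent vector p
## (scaled alignments): the unit pre-shape is sqrt(1 - |p|^2) m_hat + p
.inverseTangent <- function(p, template) {
  k <- nrow(template@coords)
  mhat <- as.numeric(template@coords) / sqrt(sum(template@coords^2))
  if (template@scaled) {
    n2 <- sum(p^2)
    if (n2 >= 1) stop("tangent vector norm must be < 1")
    u <- sqrt(1 - n2) * mhat + p
    matrix(u, k, 3)
  } else {
    template@coords + matrix(p, k, 3)
  }
}

#' Reconstruct configurations from shape scores
#'
#' \code{reconstructMode} zeroes out all shape variables but the m-th and
#' maps \code{score * V_m} back through the inverse tangent projection,
#' visualizing the deformation carried by one shape variable (at score 0
#' the template is returned exactly). \code{reconstructShape} maps a full
#' score vector (plus the training column means) back to the aligned
#' configuration.
#'
#' @param basis a \linkS4class{ShapeBasis}.
#' @param m shape-variable index.
#' @param score scalar shape score.
#' @return a k x 3 configuration.
#' @export
reconstructMode <- function(basis, m, score) {
  if (m < 1L || m > ncol(basis@V)) stop("mode index out of range")
  .inverseTangent(score * basis@V[, m], basis@template)
}

#' @param scores numeric vector of scores for all retained shape variables.
#' @rdname reconstructMode
#' @export
reconstructShape <- function(basis, scores) {
  p <- basis@columnMeans + as.numeric(basis@V %*% scores)
  .inverseTangent(p, basis@template)
}

#' Mean deformation-vector angle to the wing plane
#'
#' For each landmark, takes the vector from the template to the position
#' reconstructed from shape variable \code{m} at \code{score}, and measures
#' its angle to the template's plane (the complement pi/2 - phi of the
#' vector's elevation in spherical coordinates with the plane normal as
#' pole). The mean over landmarks, in degrees in [0, 90], measures the
#' in-plane (small angles) versus out-of-plane (large angles) composition
#' of the deformation carried by that shape variable.
#'
#' @param basis a \linkS4class{ShapeBasis}.
#' @param m shape-variable index.
#' @param score shape score at which to reconstruct; typically the maximum
#'   absolute training score (the default uses the singular value d_m,
#'   i.e. the root sum of squared training scores).
#' @return mean angle in degrees.
#' @export
deformationVectorAngle <- function(basis, m, score = basis@d[m]) {
  if (m < 1L || m > ncol(basis@V)) stop("mode index out of range")
  # displacement field carried by the shape variable; the spherical
  # shrink of the full reconstruction toward the template is a pure size
  # artifact of the projection and is excluded
  k <- nrow(basis@template@coords)
  delta <- matrix(score * basis@V[, m], k, 3)
  # template plane normal from the total least squares plane
  Mc <- sweep(basis@template@coords, 2, colMeans(basis@template@coords))
  n <- eigen(crossprod(Mc), symmetric = TRUE)$vectors[, 3]
  zc <- abs(delta %*% n)
  ipl <- sqrt(pmax(0, rowSums(delta^2) - zc^2))
  len <- sqrt(rowSums(delta^2))
  keep <- len > max(len) * 1e-9
  if (!any(keep)) stop("degenerate mode: all deformation vectors are zero")
  mean(atan2(zc[keep], ipl[keep])) * 180 / pi
}

## align one configuration to a fixed template (no template re-estimation)
.alignToTemplate <- function(cfg, template) {
  b <- colMeans(cfg)
  cc <- sweep(cfg, 2, b)
  s <- sqrt(sum(cc^2))
  z <- if (template@scaled) cc / s else cc
  R <- .opaRotation(z, template@coords)
  list(aligned = z %*% R, size = s)
}

#' Project new configurations onto an existing shape basis
#'
#' Aligns each frame of a new series to the fixed template (no template
#' re-estimation), projects into the template's tangent space, centers
#' with the training column means, and multiplies by the shape variables
#' V. This is how treatment-condition configurations are scored on a basis
#' constructed from reference-condition data only.
#'
#' @param series a \linkS4class{MarkerTimeSeries} with the template's
#'   landmark set.
#' @param basis a \linkS4class{ShapeBasis}.
#' @return a \linkS4class{ShapeScores}.
#' @export
projectOntoBasis <- function(series, basis) {
  X <- series@coords
  k <- nrow(basis@template@coords)
  if (dim(X)[2] != k)
    stop("landmark mismatch: series has ", dim(X)[2],
      " landmarks but the template has ", k)
  T <- dim(X)[1]
  M <- basis@template@coords
  mhat <- as.numeric(M) / sqrt(sum(M^2))
  out <- matrix(NA_real_, T, 3 * k)
  for (t in seq_len(T)) {
    al <- .alignToTemplate(X[t, , ], basis@template)
    v <- as.numeric(al$aligned)
    sz <- sqrt(sum(v^2))
    u <- v / sz
    p <- u - sum(u * mhat) * mhat
    out[t, ] <- if (basis@scaled) p else sz * p
  }
  sc <- sweep(out, 2, basis@columnMeans) %*% basis@V
  new("ShapeScores", scores = sc, phase = rep(NA_real_, T),
    condition = series@condition, individual = series@individual)
}

#' Landmark sampling curves
#'
#' Measures how much of the complete landmark set's shape variation is
#' recovered by random subsets of landmarks: for each subset size and
#' replicate, a random subset is drawn, the full alignment + SVD pipeline
#' is run on the subset, and the complete-set tangent coordinates are
#' regressed on the subset-derived shape scores. Recovered variance is
#' 1 - RSS/TSS; a plateau of the curve indicates that the marker set has
#' saturated the shape information.
#'
#' @param series a \linkS4class{MarkerTimeSeries}.
#' @param subsetSizes integer vector of subset sizes (each >= 3).
#' @param nReps replicates per size.
#' @param seed seed for the subset draws (private RNG stream).
#' @param scale logical, passed to \code{\link{gpaAlign}}.
#' @return data.frame with columns \code{size}, \code{recovered} (mean
#'   recovered-variance proportion) and \code{sd} over replicates.
#' @export
landmarkSamplingCurve <- function(series, subsetSizes, nReps = 20L,
    seed = 1L, scale = TRUE) {
  k <- dim(series@coords)[2]
  if (any(subsetSizes < 3L) || any(subsetSizes > k))
    stop("subset sizes must be between 3 and the landmark count")
  if (nReps < 1L) stop("nReps must be >= 1")

  full <- gpaAlign(series, scale = scale)
  Y <- tangentProject(full$aligned, full$template)@matrix
  Yc <- sweep(Y, 2, colMeans(Y))
  tss <- sum(Yc^2)

  .withSeed(seed, {
    res <- lapply(subsetSizes, function(s) {
      rec <- vapply(seq_len(nReps), function(rep) {
        idx <- sort(sample.int(k, s))
        sub <- series@coords[, idx, , drop = FALSE]
        al <- gpaAlign(sub, scale = scale)
        tc <- tangentProject(al$aligned, al$template)
        dec <- svdDecompose(tc, al$template)
        S <- dec$scores@scores
        fit <- stats::lm.fit(cbind(1, S), Yc)
        1 - sum(fit$residuals^2) / tss
      }, numeric(1))
      data.frame(size = s, recovered = mean(rec), sd = stats::sd(rec))
    })
    do.call(rbind, res)
  })
}
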