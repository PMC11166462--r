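#' @include AllClasses.R
NULL

#' Periodogram peak frequencies of shape scores
#'
#' Computes a tapered periodogram (Hann window, zero-padding to the next
#' power of two) of each mean-removed score column and locates the
#' frequency of maximum power, excluding the zero bin. Shape variables of
#' a flapping wing are expected to peak at integer multiples of the stroke
#' frequency.
#'
#' @param scores a \linkS4class{ShapeScores} or numeric matrix (frames x
#'   variables).
#' @param samplingRate sampling rate of the frames (Hz).
#' @return a \linkS4class{SpectrumSummary}.
#' @export
peakFrequency <- function(scores, samplingRate) {
  S <- if (is(scores, "ShapeScores")) scores@scores else as.matrix(scores)
  T <- nrow(S)
  if (T < 8L) stop("insufficient data for a periodogram")
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(T) / (T + 1))   # Hann taper
  nfft <- 2^ceiling(log2(T))
  nf <- nfft %/% 2
  freqs <- samplingRate * (seq_len(nf) - 1) / nfft
  P <- matrix(NA_real_, nf, ncol(S))
  for (j in seq_len(ncol(S))) {
    y <- (S[, j] - mean(S[, j])) * w
    sp <- Mod(stats::fft(c(y, rep(0, nfft - T))))^2
    P[, j] <- sp[seq_len(nf)]
  }
  pk <- apply(P[-1, , drop = FALSE], 2, which.max) + 1L
  peaks <- data.frame(variable = seq_len(ncol(S)),
    peak_frequency_hz = freqs[pk],
    peak_power = P[cbind(pk, seq_len(ncol(S)))])
  new("SpectrumSummary", peaks = peaks, frequencies = freqs, power = P)
}

## heteroskedasticity-robust t-statistic for a correlation: with
## e_t = (x_t - xbar)(y_t - ybar), t = sum(e) / sqrt(sum(e^2))
.robustCorTest <- function(x, y) {
  e <- (x - mean(x)) * (y - mean(y))
  tt <- sum(e) / sqrt(sum(e^2))
  c(rho = stats::cor(x, y), tstat = tt,
    p = 2 * stats::pnorm(-abs(tt)))
}

#' Cross-correlation of a shape score with a descriptor
#'
#' Pearson correlations between the score and the descriptor lagged by
#' whole frames, \code{rho(k) = cor(score_t, descriptor_(t-k))}. Lags are
#' converted to stroke-cycle fractions using the mean frames-per-cycle of
#' \code{cycles} and rounded to the nearest 0.02 phase; within each 0.02
#' bin the maximum-magnitude coefficient is retained. Per-lag significance
#' uses a heteroskedasticity-robust t-statistic on the cross products.
#'
#' @param score,descriptor equal-length numeric series sampled jointly.
#' @param cycles the trial's \linkS4class{StrokeCycles}.
#' @param maxLag maximum |lag| in stroke-cycle fractions (default 0.5).
#' @param alpha significance level for the per-lag flags.
#' @return a \linkS4class{CrossCorrelation}.
#' @export
crossCorrelation <- function(score, descriptor, cycles, maxLag = 0.5,
    alpha = 0.05) {
  T <- length(score)
  if (length(descriptor) != T)
    stop("score and descriptor must have equal length")
  if (stats::sd(score) < 1e-14 || stats::sd(descriptor) < 1e-14)
    stop("undefined correlation: constant series")
  fpc <- mean(table(cycles@cycle[!is.na(cycles@cycle)]))
  if (!is.finite(fpc) || fpc <= 0) stop("cycles contain no complete cycle")
  maxK <- round(maxLag * fpc)
  rows <- lapply(seq(-maxK, maxK), function(k) {
    if (k >= 0) { x <- score[(1 + k):T]; y <- descriptor[1:(T - k)] }
    else { x <- score[1:(T + k)]; y <- descriptor[(1 - k):T] }
    if (length(x) < 8L) return(NULL)
    r <- .robustCorTest(x, y)
    data.frame(frameLag = k, lag = round(k / fpc / 0.02) * 0.02,
      rho = r["rho"], tstat = r["tstat"], p = r["p"])
  })
  tab <- do.call(rbind, rows)
  # keep the maximum-|rho| coefficient within each 0.02 phase bin
  tab <- do.call(rbind, lapply(split(tab, tab$lag), function(d)
    d[which.max(abs(d$rho)), ]))
  tab <- tab[order(tab$lag), ]
  tab$significant <- tab$p < alpha
  rownames(tab) <- NULL
  new("CrossCorrelation", table = tab)
}

#' Standardized multiple regression of shape scores on descriptors
#'
#' Regresses each (z-scored) shape score column on the z-scored descriptor
#' and kinematic columns by ordinary least squares, so coefficients are
#' comparable standardized effects (beta). Intervals use the HC3
#' heteroskedasticity-robust covariance. R-squared is reported for the
#' full model and for the model excluding the kinematic covariates
#' (azimuth and elevation by default), which are included to absorb mutual
#' correlation with stroke phase.
#'
#' @param scores a \linkS4class{ShapeScores} or numeric matrix.
#' @param descriptors data.frame of numeric predictor columns.
#' @param kinematicTerms column names treated as kinematic covariates.
#' @param level confidence level for the intervals.
#' @param conditionLimit design condition number above which a collinearity
#'   warning is raised.
#' @return a \linkS4class{RegressionTable}.
#' @export
standardizedRegression <- function(scores, descriptors,
    kinematicTerms = c("azimuth_deg", "elevation_deg"), level = 0.95,
    conditionLimit = 100) {
  S <- if (is(scores, "ShapeScores")) scores@scores else as.matrix(scores)
  D <- as.data.frame(descriptors)
  if (nrow(D) != nrow(S)) stop("scores and descriptors must align by frame")
  if (nrow(S) < 10 * (ncol(D) + 1))
    stop("need at least 10x more frames than predictors")
  if (any(!vapply(D, is.numeric, logical(1))))
    stop("all descriptor columns must be numeric")
  zscore <- function(x) {
    s <- stats::sd(x)
    if (s < 1e-14) stop("constant predictor column")
    (x - mean(x)) / s
  }
  Z <- as.data.frame(lapply(D, zscore))
  X <- as.matrix(cbind(`(Intercept)` = 1, Z))
  if (qr(X)$rank < ncol(X)) stop("singular design matrix")
  kap <- kappa(X, exact = TRUE)
  if (kap > conditionLimit)
    warning("predictors are strongly collinear (condition number ",
      format(kap, digits = 4), ")")
  zq <- stats::qnorm(1 - (1 - level) / 2)
  kin <- intersect(kinematicTerms, colnames(D))

  coefRows <- list(); r2Rows <- list()
  for (j in seq_len(ncol(S))) {
    y <- zscore(S[, j])
    fit <- stats::lm(y ~ ., data = Z)
    vc <- sandwich::vcovHC(fit, type = "HC3")
    b <- stats::coef(fit)
    se <- sqrt(diag(vc))
    keep <- names(b) != "(Intercept)"
    coefRows[[j]] <- data.frame(response = j, term = names(b)[keep],
      beta = unname(b[keep]), lower = unname(b[keep] - zq * se[keep]),
      upper = unname(b[keep] + zq * se[keep]))
    r2full <- summary(fit)$r.squared
    r2nok <- if (length(kin)) {
      summary(stats::lm(y ~ ., data = Z[setdiff(colnames(Z), kin)]))$r.squared
    } else r2full
    r2Rows[[j]] <- data.frame(response = j, r2_full = r2full,
      r2_nokinematics = r2nok)
  }
  co <- do.call(rbind, coefRows)
  co$significant <- co$lower > 0 | co$upper < 0
  new("RegressionTable", coefficients = co, r2 = do.call(rbind, r2Rows))
}

#' Normalize stroke cycles to unit duration
#'
#' Resamples each complete stroke cycle of one or more series onto a
#' common phase grid of \code{nPhasePoints} points in [0, 1) by linear
#' interpolation, retaining the cycle identity for repeated-measures
#' structure. Frames outside complete pronation-to-pronation cycles are
#' dropped with a message.
#'
#' @param values numeric vector or frames x m matrix of per-frame values.
#' @param cycles the trial's \linkS4class{StrokeCycles}.
#' @param nPhasePoints number of phase-grid points per cycle.
#' @return data.frame with columns \code{cycle}, \code{phase} and one
#'   value column per input column.
#' @export
normalizeCycles <- function(values, cycles, nPhasePoints = 50L) {
  V <- as.matrix(values)
  if (nrow(V) != length(cycles@phase))
    stop("values must have one row per frame of the segmented trial")
  grid <- (seq_len(nPhasePoints) - 1) / nPhasePoints
  ok <- !is.na(cycles@cycle)
  nDropped <- sum(!ok)
  if (nDropped > 0)
    message(nDropped, " frame(s) outside complete cycles dropped")
  ids <- sort(unique(cycles@cycle[ok]))
  if (!length(ids)) stop("no complete stroke cycle in the series")
  # interpolate on the continuous cumulative phase so that neighbouring
  # cycles bracket the grid points at the cycle boundaries
  cp <- cycles@cycle[ok] + cycles@phase[ok]
  Vok <- V[ok, , drop = FALSE]
  out <- do.call(rbind, lapply(ids, function(i) {
    resampled <- vapply(seq_len(ncol(V)), function(j)
      stats::approx(cp, Vok[, j], xout = i + grid, rule = 2)$y,
      numeric(nPhasePoints))
    cbind(cycle = i, phase = grid, resampled)
  }))
  out <- as.data.frame(out)
  names(out) <- c("cycle", "phase",
    if (!is.null(colnames(V))) colnames(V) else
      paste0("value", seq_len(ncol(V))))
  out
}

#' Fit the cyclic reference smooth of a phase-indexed score
#'
#' Penalized cyclic cubic regression spline of the value on stroke phase,
#' with the smoothing parameter chosen by generalized cross-validation.
#' This captures the population-typical temporal variation of a shape
#' score over the normalized stroke cycle.
#'
#' @param data data.frame with columns \code{phase} and \code{value} (and
#'   optionally \code{cycle}); typically from \code{\link{normalizeCycles}}.
#' @param nBasis number of cyclic basis functions (default 20).
#' @param phaseGrid phases at which to evaluate the smooth; defaults to the
#'   sorted unique phases in \code{data}.
#' @return list with elements \code{model} (the mgcv fit) and \code{grid}
#'   (data.frame phase, fit, se).
#' @export
fitReferenceSmooth <- function(data, nBasis = 20L, phaseGrid = NULL) {
  if (!all(c("phase", "value") %in% names(data)))
    stop("data must have columns 'phase' and 'value'")
  fit <- mgcv::gam(value ~ s(phase, bs = "cc", k = nBasis),
    data = data, knots = list(phase = c(0, 1)), method = "GCV.Cp")
  if (is.null(phaseGrid)) phaseGrid <- sort(unique(data$phase))
  pr <- mgcv::predict.gam(fit, newdata = data.frame(phase = phaseGrid),
    se.fit = TRUE)
  list(model = fit,
    grid = data.frame(phase = phaseGrid, fit = as.numeric(pr$fit),
      se = as.numeric(pr$se.fit)))
}

## order a phase-indexed data frame by cycle then phase and mark the first
## observation of each cycle (for AR(1) restarts)
.cycleOrder <- function(data) {
  if (!"cycle" %in% names(data)) data$cycle <- 1
  data <- data[order(data$cycle, data$phase), ]
  data$.arStart <- !duplicated(data$cycle)
  data
}

#' Treatment difference smooth against a reference
#'
#' Fits the difference between a treatment's phase-indexed scores and the
#' reference smooth's prediction as an average (intercept) difference plus
#' a cyclic penalized difference smooth, with AR(1) prewhitening of the
#' within-cycle residuals at the given coefficient. Phase intervals where
#' the pointwise interval of the difference smooth excludes zero are
#' flagged, as is an intercept interval excluding zero. The treatment mean
#' fit equals reference + intercept + difference smooth on the phase grid.
#'
#' @param data treatment data.frame with columns \code{phase},
#'   \code{value}, \code{cycle}, on the same phase grid as the reference.
#' @param reference a fit from \code{\link{fitReferenceSmooth}}.
#' @param arCoefficient AR(1) residual coefficient in [0, 1).
#' @param nBasis cyclic basis dimension of the difference smooth.
#' @param level level of the pointwise intervals.
#' @return list with elements \code{delta} (data.frame phase, delta,
#'   lower, upper, significant), \code{intercept} (estimate, lower, upper,
#'   significant), \code{model}, and \code{aic} (whitened-innovation AIC).
#' @export
differenceSmooth <- function(data, reference, arCoefficient = 0,
    nBasis = 20L, level = 0.95) {
  if (arCoefficient < 0 || arCoefficient >= 1)
    stop("arCoefficient must lie in [0, 1)")
  refPhases <- reference$grid$phase
  if (!all(unique(data$phase) %in% refPhases))
    stop("phase-grid mismatch between treatment data and reference")
  data <- .cycleOrder(data)
  data$d <- data$value - as.numeric(mgcv::predict.gam(reference$model,
    newdata = data.frame(phase = data$phase)))
  fit <- mgcv::bam(d ~ s(phase, bs = "cc", k = nBasis), data = data,
    knots = list(phase = c(0, 1)), rho = arCoefficient,
    AR.start = data$.arStart, method = "fREML")
  zq <- stats::qnorm(1 - (1 - level) / 2)

  nd <- data.frame(phase = refPhases)
  sm <- mgcv::predict.gam(fit, newdata = nd, type = "terms", se.fit = TRUE)
  delta <- as.numeric(sm$fit[, 1]); dse <- as.numeric(sm$se.fit[, 1])
  deltaDf <- data.frame(phase = refPhases, delta = delta,
    lower = delta - zq * dse, upper = delta + zq * dse)
  deltaDf$significant <- deltaDf$lower > 0 | deltaDf$upper < 0

  b0 <- stats::coef(fit)[1]
  se0 <- sqrt(stats::vcov(fit)[1, 1])
  intercept <- data.frame(estimate = unname(b0),
    lower = unname(b0 - zq * se0), upper = unname(b0 + zq * se0))
  intercept$significant <- intercept$lower > 0 | intercept$upper < 0

  # Gaussian AIC on the whitened within-cycle innovations
  r <- data$d - stats::fitted(fit)
  eps <- r
  notFirst <- !data$.arStart
  eps[notFirst] <- r[notFirst] - arCoefficient * r[which(notFirst) - 1L]
  eps[data$.arStart] <- r[data$.arStart] * sqrt(1 - arCoefficient^2)
  n <- length(eps)
  sig2 <- mean(eps^2)
  ll <- -n / 2 * (log(2 * pi * sig2) + 1) +
    sum(data$.arStart) * 0.5 * log(1 - arCoefficient^2)
  aic <- -2 * ll + 2 * (sum(fit$edf) + 1)

  list(delta = deltaDf, intercept = intercept, model = fit, aic = aic)
}

#' Select the AR(1) coefficient by AIC
#'
#' Fits the difference-smooth model at each candidate AR(1) coefficient
#' and returns the one minimizing the whitened-innovation AIC.
#'
#' @param data treatment data.frame as for \code{\link{differenceSmooth}}.
#' @param reference a fit from \code{\link{fitReferenceSmooth}}.
#' @param candidates candidate coefficients in [0, 1).
#' @param nBasis cyclic basis dimension.
#' @return the AIC-minimizing coefficient.
#' @export
selectArCoefficient <- function(data, reference,
    candidates = seq(0, 0.95, by = 0.05), nBasis = 20L) {
  if (any(candidates < 0 | candidates >= 1))
    stop("candidates must lie in [0, 1)")
  aics <- vapply(candidates, function(rho)
    differenceSmooth(data, reference, arCoefficient = rho,
      nBasis = nBasis)$aic, numeric(1))
  candidates[which.min(aics)]
}

#' Compare treatment conditions against a typical-condition reference
#'
#' Convenience wrapper assembling a full \linkS4class{SplineComparison}:
#' fits the cyclic reference smooth on the typical condition, selects the
#' AR(1) coefficient on the pooled data, and fits one difference smooth
#' per treatment.
#'
#' @param typical phase-indexed data.frame (phase, value, cycle) for the
#'   reference condition.
#' @param treatments named list of phase-indexed data.frames, one per
#'   treatment condition.
#' @param nBasis cyclic basis dimension.
#' @param arCoefficient AR(1) coefficient; \code{NULL} selects it by AIC
#'   on the first treatment.
#' @param level interval level.
#' @return a \linkS4class{SplineComparison}.
#' @export
compareShapeScores <- function(typical, treatments, nBasis = 20L,
    arCoefficient = NULL, level = 0.95) {
  ref <- fitReferenceSmooth(typical, nBasis = nBasis)
  if (is.null(arCoefficient))
    arCoefficient <- selectArCoefficient(treatments[[1]], ref,
      nBasis = nBasis)
  diffs <- lapply(treatments, differenceSmooth, reference = ref,
    arCoefficient = arCoefficient, nBasis = nBasis, level = level)
  intercepts <- do.call(rbind, lapply(names(diffs), function(nm)
    cbind(treatment = nm, diffs[[nm]]$intercept)))
  new("SplineComparison", phaseGrid = ref$grid$phase,
    reference = ref$grid,
    differences = lapply(diffs, `[[`, "delta"),
    intercepts = intercepts, arCoefficient = arCoefficient)
}
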