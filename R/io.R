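#' @include AllClasses.R
NULL

.landmarkCols <- c("frame", "time_s", "marker", "x_mm", "y_mm", "z_mm",
  "individual", "condition")

#' Write and read marker trajectories as long-format CSV
#'
#' The on-disk format is one row per frame and marker with columns
#' \code{frame, time_s, marker, x_mm, y_mm, z_mm, individual, condition},
#' a single header line, UTF-8 encoding and '.' as the decimal separator.
#'
#' @param series a \linkS4class{MarkerTimeSeries}.
#' @param path file path.
#' @return \code{readLandmarks} returns a \linkS4class{MarkerTimeSeries};
#'   \code{writeLandmarks} returns \code{path} invisibly.
#' @export
writeLandmarks <- function(series, path) {
  T <- dim(series@coords)[1]; k <- dim(series@coords)[2]
  num <- function(x) sprintf("%.17g", x)   # full double round-trip precision
  df <- data.frame(frame = rep(seq_len(T), each = k),
    time_s = num(rep(series@times, each = k)),
    marker = rep(series@labels, T),
    x_mm = num(as.numeric(t(series@coords[, , 1]))),
    y_mm = num(as.numeric(t(series@coords[, , 2]))),
    z_mm = num(as.numeric(t(series@coords[, , 3]))),
    individual = series@individual, condition = series@condition)
  utf8 <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(utf8))
  utils::write.csv(df, utf8, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeLandmarks
#' @export
readLandmarks <- function(path) {
  if (!file.size(path) > 0) stop("parse error: empty file ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
    colClasses = "character", encoding = "UTF-8")
  missingCols <- setdiff(.landmarkCols, names(df))
  if (length(missingCols))
    stop("schema error: missing columns ", paste(missingCols, collapse = ", "))
  if (!nrow(df)) stop("parse error: no data rows in ", path)
  for (cl in c("frame", "time_s", "x_mm", "y_mm", "z_mm")) {
    v <- suppressWarnings(as.numeric(df[[cl]]))
    bad <- which(is.na(v))
    if (length(bad))
      stop("parse error: non-numeric ", cl, " at line ", bad[1] + 1L)
    df[[cl]] <- v
  }
  frames <- sort(unique(df$frame))
  labels <- df$marker[df$frame == frames[1]]   # declared label order
  k <- length(labels)
  tab <- table(df$frame, df$marker)
  if (any(tab != 1L)) {
    bad <- which(tab != 1L, arr.ind = TRUE)[1, ]
    stop("schema error: frame ", rownames(tab)[bad[1]],
      ifelse(tab[bad[1], bad[2]] == 0, " is missing marker ",
        " duplicates marker "), colnames(tab)[bad[2]])
  }
  if (any(diff(frames) != diff(frames)[1]))
    stop("schema error: missing frames (non-constant frame numbering)")
  T <- length(frames)
  coords <- array(NA_real_, c(T, k, 3))
  mIdx <- match(df$marker, labels)
  fIdx <- match(df$frame, frames)
  coords[cbind(fIdx, mIdx, 1L)] <- df$x_mm
  coords[cbind(fIdx, mIdx, 2L)] <- df$y_mm
  coords[cbind(fIdx, mIdx, 3L)] <- df$z_mm
  times <- df$time_s[!duplicated(df$frame)][order(frames[rank(frames)])]
  times <- df$time_s[match(frames, df$frame)]
  new("MarkerTimeSeries", coords = coords, times = times, labels = labels,
    condition = df$condition[1], individual = df$individual[1])
}

.configKeys <- c(stroke_frequency_hz = "strokeFrequency",
  stroke_amplitude_deg = "strokeAmplitude",
  elevation_amplitude_deg = "elevationAmplitude",
  stroke_plane_angle_deg = "strokePlaneAngle",
  noise_sd_mm = "noiseSd", sampling_rate_hz = "samplingRate",
  n_cycles = "nCycles", seed = "seed")

#' Serialize a simulation configuration to a flat key:value file
#'
#' YAML with documented keys matching the configuration fields:
#' \code{stroke_frequency_hz, stroke_amplitude_deg,
#' elevation_amplitude_deg, stroke_plane_angle_deg, mode_amplitudes,
#' mode_phases, noise_sd_mm, sampling_rate_hz, n_cycles, seed}.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @param path file path.
#' @return \code{readSimulationConfig} returns a
#'   \linkS4class{SimulationConfig}.
#' @export
writeSimulationConfig <- function(config, path) {
  x <- lapply(.configKeys, function(sl) unname(slot(config, sl)))
  x$mode_amplitudes <- as.list(config@modeAmplitudes)
  x$mode_phases <- as.numeric(config@modePhases)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname writeSimulationConfig
#' @export
readSimulationConfig <- function(path) {
  x <- yaml::read_yaml(path)
  missingKeys <- setdiff(c(names(.configKeys), "mode_amplitudes",
    "mode_phases"), names(x))
  if (length(missingKeys))
    stop("configuration is missing keys: ",
      paste(missingKeys, collapse = ", "))
  ma <- unlist(x$mode_amplitudes)[.modeNames]
  names(ma) <- .modeNames
  simulationConfig(strokeFrequency = x$stroke_frequency_hz,
    strokeAmplitude = x$stroke_amplitude_deg,
    elevationAmplitude = x$elevation_amplitude_deg,
    strokePlaneAngle = x$stroke_plane_angle_deg,
    modeAmplitudes = ma, modePhases = unlist(x$mode_phases),
    noiseSd = x$noise_sd_mm, samplingRate = x$sampling_rate_hz,
    nCycles = x$n_cycles, seed = x$seed)
}

#' Read a trial manifest
#'
#' A manifest CSV lists one trial per row with columns \code{path} (to a
#' landmark CSV), \code{individual}, \code{condition} and
#' \code{sampling_rate_hz}. Exactly one condition is designated as the
#' reference (default \code{"typical"}); it must be present.
#'
#' @param path manifest CSV path.
#' @param referenceCondition the reference condition label.
#' @return data.frame of validated trial entries with attribute
#'   \code{"referenceCondition"}.
#' @export
readTrialManifest <- function(path, referenceCondition = "typical") {
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("path", "individual", "condition", "sampling_rate_hz")
  missingCols <- setdiff(need, names(m))
  if (length(missingCols))
    stop("manifest is missing columns ", paste(missingCols, collapse = ", "))
  m$path <- ifelse(file.exists(m$path), m$path,
    file.path(dirname(path), m$path))
  bad <- !file.exists(m$path)
  if (any(bad)) stop("manifest paths do not exist: ",
    paste(m$path[bad], collapse = ", "))
  if (!any(m$condition == referenceCondition))
    stop("configuration error: no trial has the reference condition '",
      referenceCondition, "'")
  attr(m, "referenceCondition") <- referenceCondition
  m
}

#' Export a wing mesh as a Wavefront OBJ file
#'
#' @param mesh a \linkS4class{WingMesh}.
#' @param path output path.
#' @export
writeMeshOBJ <- function(mesh, path) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("v %.6f %.6f %.6f", mesh@vertices[, 1],
    mesh@vertices[, 2], mesh@vertices[, 3]), con)
  writeLines(sprintf("f %d %d %d", mesh@faces[, 1], mesh@faces[, 2],
    mesh@faces[, 3]), con)
  invisible(path)
}

#' Run the full analysis pipeline over a trial manifest
#'
#' Reads every trial, computes per-frame descriptors and stroke cycles,
#' constructs the shape basis from the reference-condition trials only,
#' projects every trial onto that basis, and runs the downstream analyses:
#' periodogram peaks, score-descriptor cross-correlations, standardized
#' regressions, and (when non-reference conditions are present) the cyclic
#' spline comparison of treatments against the reference smooth. All
#' results are written as tidy CSV files plus a plain-text run log; the
#' run is deterministic for fixed inputs and seed.
#'
#' @param manifest data.frame from \code{\link{readTrialManifest}}.
#' @param planform the \linkS4class{WingPlanform} describing the marker
#'   layout.
#' @param outputDir output directory, created if needed.
#' @param scale logical, scale configurations during alignment.
#' @param nShapeVars number of shape variables analysed downstream.
#' @param nPhasePoints phase-grid resolution of the cycle normalization.
#' @param internalSpacing mesh fill spacing (mm).
#' @param nBasisSmooth cyclic spline basis dimension.
#' @param seed seed recorded in the log (analysis stages are
#'   deterministic).
#' @return invisibly, a list with the in-memory results.
#' @export
runPipeline <- function(manifest, planform, outputDir, scale = TRUE,
    nShapeVars = 4L, nPhasePoints = 50L, internalSpacing = 0.5,
    nBasisSmooth = 20L, seed = 1L) {
  refCond <- attr(manifest, "referenceCondition")
  if (is.null(refCond)) refCond <- "typical"
  if (!any(manifest$condition == refCond))
    stop("configuration error: manifest has no '", refCond, "' trial")
  dir.create(outputDir, showWarnings = FALSE, recursive = TRUE)
  logLines <- c(paste("wingmorph", as.character(utils::packageVersion("wingmorph"))),
    paste("seed:", seed), paste("reference condition:", refCond),
    paste("scaled alignment:", scale),
    paste("trials:", nrow(manifest)))

  stage <- function(name, trial, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed for trial '", trial, "': ",
        conditionMessage(e)))
  }

  trials <- lapply(seq_len(nrow(manifest)), function(i) {
    id <- paste0(manifest$individual[i], "_", manifest$condition[i], "_", i)
    series <- stage("read", id, readLandmarks(manifest$path[i]))
    dsc <- stage("descriptors", id, computeDescriptors(series, planform,
      internalSpacing = internalSpacing))
    utils::write.csv(cbind(frame = seq_len(nFrames(series)),
      dsc$descriptors@frame),
      file.path(outputDir, paste0("descriptors_", id, ".csv")),
      row.names = FALSE)
    list(id = id, series = series, descriptors = dsc$descriptors,
      cycles = dsc$cycles, condition = manifest$condition[i])
  })

  # shape basis from the reference condition only
  refTrials <- Filter(function(tr) tr$condition == refCond, trials)
  refCoords <- do.call(abind3, lapply(refTrials, function(tr)
    tr$series@coords))
  al <- gpaAlign(refCoords, scale = scale)
  tc <- tangentProject(al$aligned, al$template)
  dec <- svdDecompose(tc, al$template)
  basis <- dec$basis
  k <- nrow(al$template@coords)
  Vdf <- data.frame(landmark = rep(seq_len(k), 3),
    axis = rep(c("x", "y", "z"), each = k), basis@V)
  names(Vdf)[-(1:2)] <- paste0("sv", seq_len(ncol(basis@V)))
  utils::write.csv(Vdf, file.path(outputDir, "shape_variables.csv"),
    row.names = FALSE)
  yaml::write_yaml(list(scaled = basis@scaled, k = k,
    singular_values = as.numeric(basis@d),
    variance_proportions = as.numeric(basis@varianceProportions)),
    file.path(outputDir, "shape_basis_meta.yaml"))

  # per-trial scores on the common basis
  for (tr in trials) {
    tr$scores <- projectOntoBasis(tr$series, basis)
    sc <- tr$scores@scores[, seq_len(min(nShapeVars, ncol(tr$scores@scores))),
      drop = FALSE]
    utils::write.csv(data.frame(frame = seq_len(nrow(sc)),
      phase = tr$cycles@phase, sc),
      file.path(outputDir, paste0("scores_", tr$id, ".csv")),
      row.names = FALSE)
  }
  trials <- lapply(trials, function(tr) {
    tr$scores <- projectOntoBasis(tr$series, basis); tr })

  # spectra, cross-correlations and regressions on the reference trials
  fs <- samplingRate(refTrials[[1]]$series)
  refScores <- do.call(rbind, lapply(trials, function(tr)
    if (tr$condition == refCond)
      tr$scores@scores[, seq_len(nShapeVars), drop = FALSE]))
  spec <- peakFrequency(refScores, fs)
  utils::write.csv(spec@peaks, file.path(outputDir, "spectra.csv"),
    row.names = FALSE)

  tr1 <- Filter(function(tr) tr$condition == refCond, trials)[[1]]
  descCols <- c("azimuth_deg", "elevation_deg", "twist_deg", "area_mm2",
    "second_moment", "midspan_camber", "span_camber")
  xc <- list()
  for (m in seq_len(nShapeVars)) for (dc in descCols) {
    cco <- crossCorrelation(tr1$scores@scores[, m],
      tr1$descriptors@frame[[dc]], tr1$cycles)
    xc[[paste(m, dc)]] <- cbind(variable = m, descriptor = dc, cco@table)
  }
  utils::write.csv(do.call(rbind, xc),
    file.path(outputDir, "cross_correlations.csv"), row.names = FALSE)

  refDesc <- do.call(rbind, lapply(trials, function(tr)
    if (tr$condition == refCond) tr$descriptors@frame[descCols]))
  reg <- standardizedRegression(refScores, refDesc)
  utils::write.csv(reg@coefficients,
    file.path(outputDir, "regression_coefficients.csv"), row.names = FALSE)
  utils::write.csv(reg@r2, file.path(outputDir, "regression_r2.csv"),
    row.names = FALSE)

  # cyclic spline comparison of treatments against the reference
  comparison <- NULL
  conds <- unique(manifest$condition)
  if (length(setdiff(conds, refCond))) {
    pooled <- function(cond, m) {
      dfs <- lapply(Filter(function(tr) tr$condition == cond, trials),
        function(tr) normalizeCycles(tr$scores@scores[, m], tr$cycles,
          nPhasePoints))
      for (i in seq_along(dfs))
        dfs[[i]]$cycle <- dfs[[i]]$cycle + i * 1000   # unique cycle ids
      df <- do.call(rbind, dfs)
      names(df)[3] <- "value"
      df
    }
    comparison <- lapply(seq_len(nShapeVars), function(m) {
      treatments <- lapply(setdiff(conds, refCond), pooled, m = m)
      names(treatments) <- setdiff(conds, refCond)
      compareShapeScores(pooled(refCond, m), treatments,
        nBasis = nBasisSmooth)
    })
    for (m in seq_along(comparison)) {
      cmp <- comparison[[m]]
      utils::write.csv(cmp@reference,
        file.path(outputDir, sprintf("reference_smooth_sv%d.csv", m)),
        row.names = FALSE)
      for (nm in names(cmp@differences))
        utils::write.csv(cmp@differences[[nm]],
          file.path(outputDir,
            sprintf("difference_smooth_sv%d_%s.csv", m, nm)),
          row.names = FALSE)
      utils::write.csv(cmp@intercepts,
        file.path(outputDir, sprintf("intercepts_sv%d.csv", m)),
        row.names = FALSE)
      logLines <- c(logLines, sprintf("sv%d AR(1) coefficient: %.2f", m,
        cmp@arCoefficient))
    }
  } else {
    message("single condition: spline comparison skipped")
    logLines <- c(logLines, "spline comparison skipped (single condition)")
  }

  logLines <- c(logLines,
    "defaults applied: GPA tol 1e-9; tangent projection orthogonal;",
    "SVD sign convention largest-|loading| positive;",
    sprintf("mesh spacing %.2f mm; spline basis %d (cyclic cubic);",
      internalSpacing, nBasisSmooth),
    "periodogram Hann taper, zero-padded to next power of two")
  writeLines(logLines, file.path(outputDir, "run_log.txt"))
  invisible(list(trials = trials, basis = basis, spectrum = spec,
    regression = reg, comparison = comparison))
}

## bind T x k x 3 arrays along frames
abind3 <- function(...) {
  arrs <- list(...)
  T <- sum(vapply(arrs, function(a) dim(a)[1], numeric(1)))
  out <- array(NA_real_, c(T, dim(arrs[[1]])[2], 3))
  at <- 0L
  for (a in arrs) {
    out[at + seq_len(dim(a)[1]), , ] <- a
    at <- at + dim(a)[1]
  }
  out
}
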