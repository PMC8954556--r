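#' @include AllClasses.R synthetic.R
NULL

.SCENE_MAGIC <- "UWBRSCN"
.SCENE_VERSION <- 1L

#' Write a fast-slow time matrix to a binary scene container
#'
#' Stores the complex matrix as separate real and imaginary planes (double
#' precision) behind a small versioned header with the sampling rate, bin
#' spacing and bin indices. The round trip through [readScene()] is
#' lossless.
#'
#' @param x A [RangeBinMatrix-class].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
writeScene <- function(x, path) {
  stopifnot(is(x, "RangeBinMatrix"))
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(.SCENE_MAGIC, con, eos = NULL)
  writeBin(.SCENE_VERSION, con, size = 4L, endian = "little")
  writeBin(c(x@rate, x@binSpacing), con, size = 8L, endian = "little")
  writeBin(c(nrow(x@values), ncol(x@values)), con, size = 4L,
           endian = "little")
  writeBin(x@bins, con, size = 4L, endian = "little")
  writeBin(as.numeric(Re(x@values)), con, size = 8L, endian = "little")
  writeBin(as.numeric(Im(x@values)), con, size = 8L, endian = "little")
  invisible(path)
}

#' Read a binary scene container
#'
#' @param path File written by [writeScene()].
#' @return A [RangeBinMatrix-class].
#' @export
readScene <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readChar(con, nchars = nchar(.SCENE_MAGIC), useBytes = TRUE)
  if (!identical(magic, .SCENE_MAGIC)) stop("not a scene container: ", path)
  ver <- readBin(con, integer(), 1L, size = 4L, endian = "little")
  if (ver != .SCENE_VERSION) stop("unsupported scene version ", ver)
  hd <- readBin(con, numeric(), 2L, size = 8L, endian = "little")
  dims <- readBin(con, integer(), 2L, size = 4L, endian = "little")
  bins <- readBin(con, integer(), dims[1L], size = 4L, endian = "little")
  re <- readBin(con, numeric(), prod(dims), size = 8L, endian = "little")
  im <- readBin(con, numeric(), prod(dims), size = 8L, endian = "little")
  vals <- matrix(complex(real = re, imaginary = im), dims[1L], dims[2L])
  rangeBinMatrix(vals, rate = hd[1L], binSpacing = hd[2L], bins = bins)
}

#' Write / read a per-sample label track
#'
#' Delimited text with columns `time_s` and `label`.
#'
#' @param x A [DisplacementTrace-class], or a character label vector.
#' @param path File path.
#' @param rate Sampling rate when `x` is a plain vector.
#' @return `path` invisibly; [readLabels()] returns a data frame.
#' @export
writeLabels <- function(x, path, rate = 17) {
  if (is(x, "DisplacementTrace")) {
    labels <- x@labels; rate <- x@rate
  } else labels <- as.character(x)
  df <- data.frame(time_s = (seq_along(labels) - 1L) / rate, label = labels)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeLabels
#' @export
readLabels <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write a recovered signal as delimited text
#'
#' Columns `time_s`, `value`.
#'
#' @param x A [RecoveredSignal-class].
#' @param path File path.
#' @return `path`, invisibly.
#' @export
writeRecoveredSignal <- function(x, path) {
  stopifnot(is(x, "RecoveredSignal"))
  df <- data.frame(time_s = (seq_along(x@samples) - 1L) / x@rate,
                   value = x@samples)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write / read bin weights as delimited text
#'
#' Columns `bin_index`, `weight`, `polarity`, plus the complex projection
#' axis and centre split into real and imaginary parts.
#'
#' @param w A [BinWeights-class].
#' @param path File path.
#' @return `path` invisibly; [readWeights()] returns a
#'   [BinWeights-class].
#' @export
writeWeights <- function(w, path) {
  stopifnot(is(w, "BinWeights"))
  df <- data.frame(bin_index = w@bins, weight = w@weights,
                   polarity = w@polarity,
                   axis_re = Re(w@axes), axis_im = Im(w@axes),
                   center_re = Re(w@centers), center_im = Im(w@centers),
                   reference_bin = w@referenceBin)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeWeights
#' @export
readWeights <- function(path) {
  df <- utils::read.csv(path)
  new("BinWeights", bins = as.integer(df$bin_index), weights = df$weight,
      polarity = df$polarity,
      axes = complex(real = df$axis_re, imaginary = df$axis_im),
      centers = complex(real = df$center_re, imaginary = df$center_im),
      referenceBin = as.integer(df$reference_bin[1L]))
}

# ---------------------------------------------------------------------------
# model / profile serialization (RDS payload with explicit format+version)
# ---------------------------------------------------------------------------

.modelToList <- function(m) {
  list(arch = list(nInputs = m@architecture@nInputs,
                   hidden = m@architecture@hidden,
                   nOutputs = m@architecture@nOutputs),
       weights = m@weights, normalization = m@normalization,
       referenceBins = m@referenceBins, targetBins = m@targetBins,
       trainingMse = m@trainingMse, validationMse = m@validationMse,
       testMse = m@testMse, converged = m@converged, control = m@control,
       seed = m@seed)
}

.modelFromList <- function(l) {
  new("NoiseEstimatorModel",
      architecture = new("EstimatorArchitecture",
                         nInputs = l$arch$nInputs, hidden = l$arch$hidden,
                         nOutputs = l$arch$nOutputs),
      weights = l$weights, normalization = l$normalization,
      referenceBins = l$referenceBins, targetBins = l$targetBins,
      trainingMse = l$trainingMse, validationMse = l$validationMse,
      testMse = l$testMse, converged = l$converged, control = l$control,
      seed = l$seed)
}

#' Serialize an interference estimator
#'
#' Single portable file holding the architecture, normalization statistics
#' and weights behind a versioned header; the round trip is lossless.
#'
#' @param model A [NoiseEstimatorModel-class].
#' @param path File path.
#' @return `path` invisibly; [readEstimator()] returns the model.
#' @export
writeEstimator <- function(model, path) {
  stopifnot(is(model, "NoiseEstimatorModel"))
  saveRDS(c(list(format = "uwbreath-noise-estimator", version = 1L),
            .modelToList(model)), path)
  invisible(path)
}

#' @rdname writeEstimator
#' @export
readEstimator <- function(path) {
  l <- readRDS(path)
  if (!is.list(l) || !identical(l$format, "uwbreath-noise-estimator"))
    stop("not an estimator file: ", path)
  if (l$version != 1L) stop("unsupported estimator version ", l$version)
  .modelFromList(l)
}

.weightsToList <- function(w) {
  list(bins = w@bins, weights = w@weights, polarity = w@polarity,
       axes = w@axes, centers = w@centers, referenceBin = w@referenceBin)
}

.weightsFromList <- function(l) {
  new("BinWeights", bins = l$bins, weights = l$weights,
      polarity = l$polarity, axes = l$axes, centers = l$centers,
      referenceBin = l$referenceBin)
}

#' Serialize a radar or detection profile
#'
#' One portable file per profile; the class is recorded in the header and
#' restored by [readProfile()]. Round trips are lossless.
#'
#' @param x A [RadarProfile-class] or [DetectionProfile-class].
#' @param path File path.
#' @return `path` invisibly; [readProfile()] returns the profile.
#' @export
writeProfile <- function(x, path) {
  if (is(x, "RadarProfile")) {
    payload <- list(format = "uwbreath-radar-profile", version = 1L,
                    id = x@id, referenceBins = x@referenceBins,
                    model = .modelToList(x@model), created = x@created)
  } else if (is(x, "DetectionProfile")) {
    payload <- list(format = "uwbreath-detection-profile", version = 1L,
                    radar = list(id = x@radar@id,
                                 referenceBins = x@radar@referenceBins,
                                 model = .modelToList(x@radar@model),
                                 created = x@radar@created),
                    targetBins = x@targetBins,
                    weights = .weightsToList(x@weights),
                    maWindow = x@maWindow,
                    classifier = list(thresholds = x@classifier@thresholds,
                                      classes = x@classifier@classes,
                                      windowSamples =
                                        x@classifier@windowSamples,
                                      logEpsilon = x@classifier@logEpsilon,
                                      centersLog = x@classifier@centersLog))
  } else stop("unsupported profile class: ", class(x))
  saveRDS(payload, path)
  invisible(path)
}

#' @rdname writeProfile
#' @export
readProfile <- function(path) {
  l <- readRDS(path)
  if (!is.list(l) || is.null(l$format)) stop("not a profile file: ", path)
  if (identical(l$format, "uwbreath-radar-profile")) {
    if (l$version != 1L) stop("unsupported profile version")
    new("RadarProfile", id = l$id, referenceBins = l$referenceBins,
        model = .modelFromList(l$model), created = l$created)
  } else if (identical(l$format, "uwbreath-detection-profile")) {
    if (l$version != 1L) stop("unsupported profile version")
    radar <- new("RadarProfile", id = l$radar$id,
                 referenceBins = l$radar$referenceBins,
                 model = .modelFromList(l$radar$model),
                 created = l$radar$created)
    new("DetectionProfile", radar = radar, targetBins = l$targetBins,
        weights = .weightsFromList(l$weights), maWindow = l$maWindow,
        classifier = new("ClassifierModel",
                         thresholds = l$classifier$thresholds,
                         classes = l$classifier$classes,
                         windowSamples = l$classifier$windowSamples,
                         logEpsilon = l$classifier$logEpsilon,
                         centersLog = l$classifier$centersLog))
  } else stop("not a profile file: ", path)
}

#' Write a metrics report
#'
#' Delimited per-class table (sensitivity, specificity) plus a
#' machine-readable YAML key-value file with the overall accuracy and the
#' confusion matrix.
#'
#' @param m A [ClassMetrics-class].
#' @param path CSV report path.
#' @param kvPath Optional YAML key-value path.
#' @return `path`, invisibly.
#' @export
writeMetricsReport <- function(m, path, kvPath = NULL) {
  stopifnot(is(m, "ClassMetrics"))
  df <- data.frame(class = names(m@sensitivity),
                   sensitivity = m@sensitivity,
                   specificity = m@specificity)
  df <- rbind(df, data.frame(class = "overall_accuracy",
                             sensitivity = m@accuracy, specificity = NA))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  if (!is.null(kvPath)) {
    yaml::write_yaml(list(
      overall_accuracy = m@accuracy,
      sensitivity = as.list(m@sensitivity),
      specificity = as.list(m@specificity),
      confusion = lapply(seq_len(nrow(m@confusion)), function(i)
        as.list(stats::setNames(m@confusion[i, ], colnames(m@confusion))))),
      kvPath)
  }
  invisible(path)
}

# ---------------------------------------------------------------------------
# scene configuration files
# ---------------------------------------------------------------------------

.traceFromSpec <- function(spec, rate) {
  trs <- lapply(spec, function(s) {
    type <- s$type
    if (is.null(type)) stop("trace segment without a type")
    switch(type,
      sinusoid = generateSinusoidTrace(
        freq = s$freq %||% 0.25, amplitudeMm = s$amplitude_mm %||% 4,
        duration = s$duration, rate = rate),
      idle = generateIdleTrace(s$duration, rate = rate),
      dibh = generateDibhTrace(
        baseAmp = s$base_amp %||% 4, deepAmp = s$deep_amp %||% 12,
        holdS = s$hold_s %||% 30, breathFreq = s$breath_freq %||% 0.25,
        duration = s$duration, rate = rate, freeS = s$free_s %||% 20,
        residualAmp = s$residual_amp %||% 0.9,
        residualFreq = s$residual_freq %||% 0.3),
      stop("unknown trace segment type: ", type))
  })
  concatTraces(trs)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a scene configuration file
#'
#' YAML description of a synthetic scene: scalar scene parameters, a
#' `trace` list of segments (`sinusoid`, `idle`, `dibh`) and an optional
#' `speed_profile` list of `{duration, speed}` entries. The scene duration
#' is the total trace duration.
#'
#' @param path YAML file path.
#' @return A list with `config` ([SceneConfig-class]), `trace`
#'   ([DisplacementTrace-class]) and `profile` (speed profile data frame or
#'   `NULL`).
#' @export
readSceneConfig <- function(path) {
  y <- yaml::read_yaml(path)
  rate <- y$rate %||% 17
  if (is.null(y$trace)) stop("scene configuration needs a trace section")
  trace <- .traceFromSpec(y$trace, rate)
  duration <- sampleCount(trace) / rate
  cfg <- sceneConfig(
    duration = duration, rate = rate, nBins = y$n_bins %||% 128L,
    targetCenter = y$target_center %||% 25L,
    nTargetBins = y$n_target_bins %||% 11L,
    referenceBins = unlist(y$reference_bins %||%
                             c(15L, 18L, 123L, 45L, 60L, 85L, 105L)),
    phaseGain = y$phase_gain %||% 0.1,
    interferencePowerRatio = y$interference_power_ratio %||% 5,
    siteSeed = y$site_seed %||% 1L, seed = y$seed %||% 1L)
  profile <- NULL
  if (!is.null(y$speed_profile)) {
    profile <- speedProfile(
      vapply(y$speed_profile, function(s) s$duration, numeric(1)),
      vapply(y$speed_profile, function(s) s$speed, numeric(1)))
  }
  list(config = cfg, trace = trace, profile = profile)
}

#' Compose a scene from a configuration file
#'
#' @param path YAML file from [readSceneConfig()]'s schema.
#' @return A [RadarScene-class].
#' @export
sceneFromConfigFile <- function(path) {
  sc <- readSceneConfig(path)
  composeScene(sc$config, sc$trace, sc$profile)
}
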