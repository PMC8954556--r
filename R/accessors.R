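#' @include AllClasses.R
NULL

#' @describeIn sampleRate rate of a displacement trace
#' @export
setMethod("sampleRate", "DisplacementTrace", function(x) x@rate)

#' @describeIn sampleRate slow-time rate of a radar matrix
#' @export
setMethod("sampleRate", "RangeBinMatrix", function(x) x@rate)

#' @describeIn sampleRate rate of a recovered signal
#' @export
setMethod("sampleRate", "RecoveredSignal", function(x) x@rate)

#' @describeIn sampleRate configured rate of a scene
#' @export
setMethod("sampleRate", "SceneConfig", function(x) x@rate)

#' @describeIn sampleCount samples of a displacement trace
#' @export
setMethod("sampleCount", "DisplacementTrace", function(x) length(x@samples))

#' @describeIn sampleCount slow-time samples of a radar matrix
#' @export
setMethod("sampleCount", "RangeBinMatrix", function(x) ncol(x@values))

#' @describeIn sampleCount samples of a recovered signal
#' @export
setMethod("sampleCount", "RecoveredSignal", function(x) length(x@samples))

#' @describeIn binIndices rows of a radar matrix
#' @export
setMethod("binIndices", "RangeBinMatrix", function(x) x@bins)

#' @describeIn binIndices target bins of a scene configuration
#' @export
setMethod("binIndices", "SceneConfig", function(x) x@targetBins)

#' @describeIn binIndices bins of a weight set
#' @export
setMethod("binIndices", "BinWeights", function(x) x@bins)

#' @describeIn classLabels labels of a displacement trace
#' @export
setMethod("classLabels", "DisplacementTrace", function(x) x@labels)

#' @describeIn classLabels ground-truth labels of a composed scene
#' @export
setMethod("classLabels", "RadarScene", function(x)
  x@truth@displacement@labels)

#' @describeIn classLabels predicted per-window labels of a monitoring run
#' @export
setMethod("classLabels", "MonitoringResult", function(x) x@windowLabels)

#' Displacement samples of a trace
#' @param x A [DisplacementTrace-class].
#' @return Numeric vector (mm).
#' @export
displacement <- function(x) {
  stopifnot(is(x, "DisplacementTrace") || is(x, "RadarScene"))
  if (is(x, "RadarScene")) x@truth@displacement@samples else x@samples
}

#' Complex values of a radar matrix
#' @param x A [RangeBinMatrix-class].
#' @return Complex matrix, bins x samples.
#' @export
binValues <- function(x) {
  stopifnot(is(x, "RangeBinMatrix"))
  x@values
}

#' Samples of a recovered signal
#' @param x A [RecoveredSignal-class].
#' @return Numeric vector.
#' @export
signalSamples <- function(x) {
  stopifnot(is(x, "RecoveredSignal"))
  x@samples
}

#' Power values of a PowerSeries
#' @param x A [PowerSeries-class].
#' @return Numeric vector.
#' @export
powerValues <- function(x) {
  stopifnot(is(x, "PowerSeries"))
  x@values
}

#' Thresholds of a fitted power classifier
#' @param x A [ClassifierModel-class].
#' @return Numeric vector of length 3 (power domain).
#' @export
classifierThresholds <- function(x) {
  stopifnot(is(x, "ClassifierModel"))
  x@thresholds
}

#' Confusion matrix of a metrics object
#' @param x A [ClassMetrics-class].
#' @return Integer matrix, truth in rows.
#' @export
confusionMatrix <- function(x) {
  stopifnot(is(x, "ClassMetrics"))
  x@confusion
}

#' Per-class sensitivity / specificity and accuracy
#' @param x A [ClassMetrics-class].
#' @return Named numeric vector.
#' @name metrics-accessors
NULL

#' @rdname metrics-accessors
#' @export
sensitivity <- function(x) { stopifnot(is(x, "ClassMetrics")); x@sensitivity }

#' @rdname metrics-accessors
#' @export
specificity <- function(x) { stopifnot(is(x, "ClassMetrics")); x@specificity }

#' @rdname metrics-accessors
#' @export
accuracy <- function(x) { stopifnot(is(x, "ClassMetrics")); x@accuracy }

setMethod("show", "DisplacementTrace", function(object) {
  cat(sprintf("DisplacementTrace: %d samples at %g Hz (%.1f s)\n",
              length(object@samples), object@rate,
              length(object@samples) / object@rate))
  tb <- table(factor(object@labels, breathingClasses()))
  cat("  classes:", paste(sprintf("%s=%d", names(tb), tb), collapse = ", "),
      "\n")
})

setMethod("show", "RangeBinMatrix", function(object) {
  cat(sprintf(
    "RangeBinMatrix: %d bins x %d samples at %g Hz (bin spacing %.3g m)\n",
    nrow(object@values), ncol(object@values), object@rate,
    object@binSpacing))
  cat("  bins:", paste(range(object@bins), collapse = ".."), "\n")
})

setMethod("show", "SceneConfig", function(object) {
  cat(sprintf("SceneConfig: %.1f s at %g Hz, %d bins, seed %d\n",
              object@duration, object@rate, object@nBins, object@seed))
  cat("  target bins:", paste(range(object@targetBins), collapse = ".."),
      sprintf(" reference bins: %s\n",
              paste(object@referenceBins, collapse = ",")))
  cat(sprintf("  interference/breathing power ratio: %g, phase gain: %g\n",
              object@interferencePowerRatio, object@phaseGain))
})

setMethod("show", "RadarScene", function(object) {
  cat("RadarScene\n  ")
  show(object@scene)
  cat("  ")
  show(object@truth@displacement)
})

setMethod("show", "EstimatorArchitecture", function(object) {
  cat(sprintf("EstimatorArchitecture: %d -> %s -> %d\n", object@nInputs,
              paste(object@hidden, collapse = " -> "), object@nOutputs))
})

setMethod("show", "NoiseEstimatorModel", function(object) {
  cat("NoiseEstimatorModel\n  ")
  show(object@architecture)
  cat(sprintf("  reference bins: %s\n  target bins: %s\n",
              paste(object@referenceBins, collapse = ","),
              paste(range(object@targetBins), collapse = "..")))
  cat(sprintf("  MSE train/val/test: %.3g / %.3g / %.3g%s\n",
              object@trainingMse, object@validationMse, object@testMse,
              if (!object@converged) "  [NOT CONVERGED]" else ""))
})

setMethod("show", "BinWeights", function(object) {
  cat(sprintf("BinWeights over %d bins (reference bin %d)\n",
              length(object@bins), object@referenceBin))
  cat("  weights:", paste(sprintf("%.3f", object@weights), collapse = " "),
      "\n  polarity:", paste(sprintf("%+d", as.integer(object@polarity)),
                             collapse = " "), "\n")
})

setMethod("show", "RecoveredSignal", function(object) {
  cat(sprintf("RecoveredSignal: %d samples at %g Hz\n",
              length(object@samples), object@rate))
})

setMethod("show", "PowerSeries", function(object) {
  cat(sprintf("PowerSeries: %d windows of %d samples (hop %d)\n",
              length(object@values), object@windowSamples, object@hop))
})

setMethod("show", "ClassifierModel", function(object) {
  cat("ClassifierModel (windowed-power thresholds)\n")
  cat("  thresholds:", paste(signif(object@thresholds, 4), collapse = " < "),
      "\n  classes:", paste(object@classes, collapse = " < "), "\n")
})

setMethod("show", "ClassMetrics", function(object) {
  cat(sprintf("ClassMetrics: overall accuracy %.4f\n", object@accuracy))
  df <- data.frame(sensitivity = round(object@sensitivity, 4),
                   specificity = round(object@specificity, 4))
  print(df)
})

setMethod("show", "RadarProfile", function(object) {
  cat(sprintf("RadarProfile '%s' (created %s)\n", object@id, object@created))
  cat("  reference bins:", paste(object@referenceBins, collapse = ","), "\n")
})

setMethod("show", "DetectionProfile", function(object) {
  cat("DetectionProfile\n  ")
  show(object@radar)
  cat("  target bins:", paste(range(object@targetBins), collapse = ".."),
      sprintf(" MA window: %d classifier window: %d\n", object@maWindow,
              object@classifier@windowSamples))
})

setMethod("show", "MonitoringResult", function(object) {
  cat(sprintf("MonitoringResult: %d samples, %d classified windows\n",
              length(object@recovered@samples), length(object@windowLabels)))
  tb <- table(factor(object@windowLabels, breathingClasses()))
  cat("  predicted:", paste(sprintf("%s=%d", names(tb), tb), collapse = ", "),
      "\n")
})
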