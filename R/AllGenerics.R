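#' @include AllGenerics.R
NULL

#' Sampling rate accessor
#'
#' Returns the slow-time sampling rate (Hz) of a radar or displacement object.
#'
#' @param x A [RangeBinMatrix-class], [DisplacementTrace-class],
#'   [RecoveredSignal-class] or [SceneConfig-class] object.
#' @return Sampling rate in Hz.
#' @export
setGeneric("sampleRate", function(x) standardGeneric("sampleRate"))

#' Number of slow-time samples
#'
#' @param x An object holding a slow-time axis.
#' @return Integer sample count.
#' @export
setGeneric("sampleCount", function(x) standardGeneric("sampleCount"))

#' Range-bin indices accessor
#'
#' Global radar bin indices carried by an object (rows of a fast-slow time
#' matrix, or the bins a model was trained on).
#'
#' @param x An object carrying bin indices.
#' @return Integer vector of bin indices.
#' @export
setGeneric("binIndices", function(x) standardGeneric("binIndices"))

#' Per-sample breathing-class labels
#'
#' @param x An object carrying a per-sample label track.
#' @return Character vector of class labels (see [breathingClasses()]).
#' @export
setGeneric("classLabels", function(x) standardGeneric("classLabels"))
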