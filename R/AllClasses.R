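#' @include AllGenerics.R
NULL

#' The four breathing classes
#'
#' Ordered vocabulary of breathing states used throughout the package, from
#' smallest to largest chest-wall motion amplitude: no subject / no breathing,
#' breath hold, free (regular) breathing, and deep inspiration/exhalation.
#'
#' @return Character vector of the four class names, in increasing amplitude
#'   order.
#' @export
#' @examples
#' breathingClasses()
breathingClasses <- function() {
  c("no_breathing", "breath_hold", "free_breathing", "deep_inspiration")
}

## run-length segments of a label track; internal
.labelSegments <- function(labels) {
  r <- rle(labels)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  data.frame(label = r$values, start = starts, end = ends,
             stringsAsFactors = FALSE)
}

# ---------------------------------------------------------------------------
# DisplacementTrace
# ---------------------------------------------------------------------------

#' DisplacementTrace: labelled chest displacement over time
#'
#' Chest-wall displacement in millimetres sampled at a fixed slow-time rate,
#' with a per-sample ground-truth breathing-class label. Samples labelled
#' `no_breathing` are identically zero, and breath-hold segments have strictly
#' smaller peak-to-peak excursion than free-breathing segments of the same
#' trace.
#'
#' @slot samples Numeric vector, displacement in mm.
#' @slot rate Sampling rate in Hz.
#' @slot labels Character vector of per-sample classes, see
#'   [breathingClasses()].
#'
#' @aliases DisplacementTrace
#' @export
setClass("DisplacementTrace",
  representation(samples = "numeric", rate = "numeric", labels = "character"),
  validity = function(object) {
    msg <- NULL
    if (length(object@samples) != length(object@labels))
      msg <- c(msg, "samples and labels must have equal length")
    if (!all(object@labels %in% breathingClasses()))
      msg <- c(msg, "unknown breathing class label")
    if (any(!is.finite(object@samples)))
      msg <- c(msg, "displacement samples must be finite")
    if (length(object@rate) != 1L || object@rate <= 0)
      msg <- c(msg, "rate must be a single positive number")
    zb <- object@labels == "no_breathing"
    if (any(zb) && any(object@samples[zb] != 0))
      msg <- c(msg, "no_breathing samples must be identically zero")
    seg <- .labelSegments(object@labels)
    pp <- function(lab) {
      s <- seg[seg$label == lab, , drop = FALSE]
      if (nrow(s) == 0L) return(NULL)
      vapply(seq_len(nrow(s)), function(i) {
        v <- object@samples[s$start[i]:s$end[i]]
        diff(range(v))
      }, numeric(1))
    }
    hpp <- pp("breath_hold"); fpp <- pp("free_breathing")
    if (!is.null(hpp) && !is.null(fpp) && max(hpp) >= max(fpp))
      msg <- c(msg, "breath_hold peak-to-peak must be below free_breathing")
    if (is.null(msg)) TRUE else msg
  })

#' Construct a DisplacementTrace
#'
#' @param samples Displacement samples (mm).
#' @param rate Sampling rate (Hz), default 17.
#' @param labels Per-sample class labels; defaults to `free_breathing` for
#'   nonzero traces and `no_breathing` for an all-zero trace.
#' @return A [DisplacementTrace-class] object.
#' @export
displacementTrace <- function(samples, rate = 17,
                              labels = NULL) {
  if (is.null(labels)) {
    labels <- rep(if (all(samples == 0)) "no_breathing" else "free_breathing",
                  length(samples))
  }
  new("DisplacementTrace", samples = as.numeric(samples), rate = rate,
      labels = labels)
}

# ---------------------------------------------------------------------------
# RangeBinMatrix
# ---------------------------------------------------------------------------

#' RangeBinMatrix: complex fast-slow time matrix
#'
#' The radar recording: a rectangular complex matrix indexed `[bin, time]`
#' (fast time = range-bin index, slow time = pulse index), with the slow-time
#' sampling rate and physical bin spacing attached. Rows may be a subset of
#' the radar's bins (e.g. the target bins only); the `bins` slot keeps the
#' global bin indices.
#'
#' @slot values Complex matrix, bins x samples.
#' @slot rate Slow-time sampling rate (Hz).
#' @slot binSpacing Physical bin spacing in metres (about 0.05).
#' @slot bins Integer vector of global bin indices, one per row.
#'
#' @aliases RangeBinMatrix
#' @export
setClass("RangeBinMatrix",
  representation(values = "matrix", rate = "numeric", binSpacing = "numeric",
                 bins = "integer"),
  validity = function(object) {
    msg <- NULL
    if (!is.complex(object@values))
      msg <- c(msg, "values must be a complex matrix")
    else if (any(!is.finite(Re(object@values))) ||
             any(!is.finite(Im(object@values))))
      msg <- c(msg, "values must be finite")
    if (length(object@bins) != nrow(object@values))
      msg <- c(msg, "bins must have one entry per row")
    if (anyDuplicated(object@bins))
      msg <- c(msg, "bin indices must be unique")
    if (is.null(msg)) TRUE else msg
  })

#' Construct a RangeBinMatrix
#'
#' @param values Complex (or numeric, coerced) matrix, bins x samples.
#' @param rate Slow-time sampling rate in Hz.
#' @param binSpacing Bin spacing in metres.
#' @param bins Global bin indices of the rows.
#' @return A [RangeBinMatrix-class] object.
#' @export
rangeBinMatrix <- function(values, rate = 17, binSpacing = 0.05,
                           bins = seq_len(nrow(values))) {
  storage.mode(values) <- "complex"
  new("RangeBinMatrix", values = values, rate = rate,
      binSpacing = binSpacing, bins = as.integer(bins))
}

#' Restrict a RangeBinMatrix to a subset of bins
#'
#' @param x A [RangeBinMatrix-class].
#' @param bins Global bin indices to keep (must be present in `x`).
#' @return A [RangeBinMatrix-class] holding only the requested bins.
#' @export
restrictBins <- function(x, bins) {
  idx <- match(as.integer(bins), x@bins)
  if (any(is.na(idx)))
    stop("requested bins not present in matrix: ",
         paste(bins[is.na(idx)], collapse = ", "))
  rangeBinMatrix(x@values[idx, , drop = FALSE], rate = x@rate,
                 binSpacing = x@binSpacing, bins = bins)
}

# ---------------------------------------------------------------------------
# SceneConfig
# ---------------------------------------------------------------------------

#' SceneConfig: parameters of a synthetic radar scene
#'
#' Describes the geometry and signal levels of a simulated treatment-room
#' scene: which bins hold the breathing target, which interference-only bins
#' serve as noise references, per-bin complex gains and displacement coupling,
#' the interference-to-breathing power ratio, and the thermal noise floor.
#'
#' The per-bin response model for a target bin \eqn{b} at displacement
#' \eqn{d} (mm) is
#' \deqn{x_b = g_b (1 + \beta_b d / A_{ref})
#'       \exp(j \eta 4\pi d / (1000\lambda))}
#' where \eqn{g_b} is the complex static gain (`targetGains`), \eqn{\beta_b}
#' the signed displacement coupling (`couplingSlopes`; a negative sign is a
#' polarity-inverted bin), \eqn{A_{ref}} the reference amplitude
#' (`displacementRef`, mm), \eqn{\lambda} the carrier wavelength (m) and
#' \eqn{\eta} the carrier-phase gain (`phaseGain`). At `phaseGain = 1` the
#' phase term is the full two-way carrier phase \eqn{4\pi d/\lambda}.
#'
#' @slot duration Scene duration in seconds.
#' @slot rate Sampling rate (Hz).
#' @slot nBins Total number of range bins.
#' @slot targetBins Contiguous target bin indices (default 11 centred on 25).
#' @slot referenceBins Interference-only reference bins (>= 7, disjoint from
#'   the target bins).
#' @slot targetGains Complex static gain per target bin.
#' @slot couplingSlopes Signed displacement coupling per target bin.
#' @slot wavelength Carrier wavelength in metres.
#' @slot phaseGain Carrier-phase gain (dimensionless).
#' @slot displacementRef Reference displacement amplitude in mm.
#' @slot interferencePowerRatio Interference power over breathing power in the
#'   target bins during gantry motion.
#' @slot noiseFloorPower Thermal noise power per bin.
#' @slot nLatentSources Number of latent broadband interference processes.
#' @slot siteSeed Integer seed fixing the site geometry: per-bin gains,
#'   coupling slopes and the interference mixing gains. Recordings taken at
#'   the same location share a `siteSeed`.
#' @slot seed Integer seed for the per-recording realizations (latent
#'   interference processes and thermal noise).
#'
#' @aliases SceneConfig
#' @export
setClass("SceneConfig",
  representation(duration = "numeric", rate = "numeric", nBins = "integer",
                 targetBins = "integer", referenceBins = "integer",
                 targetGains = "complex", couplingSlopes = "numeric",
                 wavelength = "numeric", phaseGain = "numeric",
                 displacementRef = "numeric",
                 interferencePowerRatio = "numeric",
                 noiseFloorPower = "numeric", nLatentSources = "integer",
                 siteSeed = "integer", seed = "integer"),
  validity = function(object) {
    msg <- NULL
    if (length(intersect(object@targetBins, object@referenceBins)) > 0L)
      msg <- c(msg, "target and reference bins must be disjoint")
    if (length(object@referenceBins) < 1L)
      msg <- c(msg, "at least one reference bin required")
    if (object@interferencePowerRatio < 0)
      msg <- c(msg, "interferencePowerRatio must be >= 0")
    if (any(c(object@targetBins, object@referenceBins) > object@nBins) ||
        any(c(object@targetBins, object@referenceBins) < 1L))
      msg <- c(msg, "bin indices out of range")
    n <- object@duration * object@rate
    if (abs(n - round(n)) > 1e-8)
      msg <- c(msg, "duration * rate must be an integer sample count")
    if (length(object@targetGains) != length(object@targetBins) ||
        length(object@couplingSlopes) != length(object@targetBins))
      msg <- c(msg, "per-bin gains/slopes must match the target bins")
    if (is.null(msg)) TRUE else msg
  })

## evaluate fn with a private RNG stream, leaving the global stream untouched
.withSeed <- function(seed, fn) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  fn()
}

#' Construct a SceneConfig
#'
#' Default bin layout matches the emulated setup: 128 bins of ~5 cm covering
#' 2 m at 17 Hz, an 11-bin target zone centred on bin 25, and seven
#' interference reference bins (including 15, 18 and 123). Per-bin gains,
#' phases and coupling slopes are drawn deterministically from `siteSeed`
#' (the fixed radar/room geometry, shared by every recording at a
#' location); one target bin is polarity-inverted by default. The latent
#' interference processes and thermal noise of a particular recording are
#' drawn from `seed`.
#'
#' @param duration Scene duration (s); `duration * rate` must be an integer.
#' @param rate Sampling rate (Hz).
#' @param nBins Total bins.
#' @param targetCenter Centre bin of the target zone.
#' @param nTargetBins Number of contiguous target bins.
#' @param targetBins Explicit target bins (overrides centre/width).
#' @param referenceBins Reference bin indices.
#' @param wavelength Carrier wavelength (m); default is the 5.9-10.3 GHz band
#'   centre, c / 8.1 GHz.
#' @param phaseGain Carrier-phase gain, default 0.1 (see
#'   [SceneConfig-class]).
#' @param displacementRef Reference displacement amplitude (mm), default 4.
#' @param interferencePowerRatio Interference-to-breathing power ratio,
#'   default 5.
#' @param noiseFloorPower Thermal noise power per bin; default 20 dB below
#'   the reference breathing power.
#' @param nLatentSources Latent broadband interference processes, default 3.
#' @param siteSeed Integer geometry seed (default 1), shared across
#'   recordings from the same location.
#' @param seed Integer realization seed for this recording.
#' @param targetGains,couplingSlopes Optional explicit per-bin parameters.
#' @param invertedBins Which target bins (global indices) receive inverted
#'   polarity; default the third bin of the target run.
#' @return A [SceneConfig-class] object.
#' @export
#' @examples
#' cfg <- sceneConfig(duration = 60, seed = 7)
#' binIndices(cfg)
sceneConfig <- function(duration, rate = 17, nBins = 128L,
                        targetCenter = 25L, nTargetBins = 11L,
                        targetBins = NULL,
                        referenceBins = c(15L, 18L, 123L, 45L, 60L, 85L, 105L),
                        wavelength = 299792458 / 8.1e9,
                        phaseGain = 0.1, displacementRef = 4,
                        interferencePowerRatio = 5,
                        noiseFloorPower = NULL, nLatentSources = 3L,
                        siteSeed = 1L, seed = 1L, targetGains = NULL,
                        couplingSlopes = NULL, invertedBins = NULL) {
  if (is.null(targetBins)) {
    half <- (nTargetBins - 1L) %/% 2L
    targetBins <- seq(targetCenter - half, length.out = nTargetBins)
  }
  targetBins <- as.integer(targetBins)
  nt <- length(targetBins)
  if (is.null(invertedBins) && nt >= 3L) invertedBins <- targetBins[3L]
  drawn <- .withSeed(as.integer(siteSeed) + 101L, function() {
    taper <- 0.4 + 0.6 * cos(pi * (seq_len(nt) - (nt + 1) / 2) / nt)^2
    phases <- runif(nt, 0, 2 * pi)
    slopes <- runif(nt, 0.6, 1.0)
    list(gains = taper * exp(1i * phases), slopes = slopes)
  })
  if (is.null(targetGains)) targetGains <- drawn$gains
  if (is.null(couplingSlopes)) {
    couplingSlopes <- drawn$slopes
    inv <- targetBins %in% invertedBins
    couplingSlopes[inv] <- -couplingSlopes[inv]
    targetGains[inv] <- targetGains[inv] * exp(1i * pi)
  }
  if (is.null(noiseFloorPower)) {
    pb <- mean(Mod(targetGains)^2 * couplingSlopes^2) / 2
    noiseFloorPower <- pb / 100
  }
  new("SceneConfig", duration = duration, rate = rate,
      nBins = as.integer(nBins), targetBins = targetBins,
      referenceBins = as.integer(referenceBins),
      targetGains = as.complex(targetGains),
      couplingSlopes = as.numeric(couplingSlopes),
      wavelength = wavelength, phaseGain = phaseGain,
      displacementRef = displacementRef,
      interferencePowerRatio = interferencePowerRatio,
      noiseFloorPower = noiseFloorPower,
      nLatentSources = as.integer(nLatentSources),
      siteSeed = as.integer(siteSeed), seed = as.integer(seed))
}

#' Reference breathing power of a scene configuration
#'
#' Mean-removed power, averaged over the target bins, that a sinusoid of
#' amplitude `displacementRef` injects under the configured gains and
#' coupling slopes. This is the denominator of the interference-to-breathing
#' power ratio.
#'
#' @param cfg A [SceneConfig-class].
#' @return Scalar power.
#' @export
referenceBreathingPower <- function(cfg) {
  mean(Mod(cfg@targetGains)^2 * cfg@couplingSlopes^2) / 2
}

# ---------------------------------------------------------------------------
# Ground truth and composed scene
# ---------------------------------------------------------------------------

#' SceneGroundTruth: the addends of a composed scene
#'
#' Mirrors the separate recordings of the emulated experiment (isolated
#' phantom motion, isolated gantry motion, combined): the composed scene
#' equals `cleanTarget + interferenceOnly + thermalNoise` exactly by
#' construction on the target bins.
#'
#' @slot displacement The ground-truth [DisplacementTrace-class].
#' @slot cleanTarget [RangeBinMatrix-class] of the breathing echo only,
#'   restricted to the target bins.
#' @slot interferenceOnly [RangeBinMatrix-class] of the gantry interference
#'   (plus its own measurement floor), all bins.
#' @slot thermalNoise [RangeBinMatrix-class] of the additional thermal noise,
#'   all bins.
#'
#' @aliases SceneGroundTruth
#' @export
setClass("SceneGroundTruth",
  representation(displacement = "DisplacementTrace",
                 cleanTarget = "RangeBinMatrix",
                 interferenceOnly = "RangeBinMatrix",
                 thermalNoise = "RangeBinMatrix"))

#' RadarScene: a composed scene with its ground truth
#'
#' @slot scene The combined [RangeBinMatrix-class] (all bins).
#' @slot truth The [SceneGroundTruth-class] addends.
#' @slot config The generating [SceneConfig-class].
#'
#' @aliases RadarScene
#' @export
setClass("RadarScene",
  representation(scene = "RangeBinMatrix", truth = "SceneGroundTruth",
                 config = "SceneConfig"))

# ---------------------------------------------------------------------------
# Estimator
# ---------------------------------------------------------------------------

#' EstimatorArchitecture: MLP layer widths
#'
#' @slot nInputs Number of inputs (2 per reference bin: real and imaginary).
#' @slot hidden Integer vector of hidden-layer widths.
#' @slot nOutputs Number of outputs (2 per target bin).
#'
#' @aliases EstimatorArchitecture
#' @export
setClass("EstimatorArchitecture",
  representation(nInputs = "integer", hidden = "integer",
                 nOutputs = "integer"),
  validity = function(object) {
    if (any(c(object@nInputs, object@hidden, object@nOutputs) < 1L))
      "layer widths must be positive" else TRUE
  })

#' Single-bin (SB) estimator architecture
#'
#' The single-bin interference estimator: 14 inputs (7 reference bins, real
#' and imaginary), hidden layers of 56 and 28 tanh units, and 2 linear
#' outputs (one complex target bin).
#'
#' @param nReferenceBins Number of reference bins, default 7.
#' @return An [EstimatorArchitecture-class].
#' @export
sbArchitecture <- function(nReferenceBins = 7L) {
  new("EstimatorArchitecture", nInputs = 2L * as.integer(nReferenceBins),
      hidden = c(56L, 28L), nOutputs = 2L)
}

#' Range-bin (RB) estimator architecture
#'
#' The multi-bin interference estimator: 14 inputs, hidden layers of 126 and
#' 22 tanh units, and 22 linear outputs (11 complex target bins).
#'
#' @param nReferenceBins Number of reference bins, default 7.
#' @param nTargetBins Number of target bins, default 11.
#' @return An [EstimatorArchitecture-class].
#' @export
rbArchitecture <- function(nReferenceBins = 7L, nTargetBins = 11L) {
  new("EstimatorArchitecture", nInputs = 2L * as.integer(nReferenceBins),
      hidden = c(126L, 22L), nOutputs = 2L * as.integer(nTargetBins))
}

#' TrainingSplit: train/validation/test fractions
#'
#' @slot fractions Named numeric vector `(train, validation, test)` summing
#'   to 1; defaults 0.70 / 0.15 / 0.15.
#'
#' @aliases TrainingSplit
#' @export
setClass("TrainingSplit",
  representation(fractions = "numeric"),
  validity = function(object) {
    if (length(object@fractions) != 3L) return("need 3 fractions")
    if (abs(sum(object@fractions) - 1) > 1e-8) return("fractions must sum to 1")
    if (any(object@fractions < 0)) return("fractions must be >= 0")
    TRUE
  })

#' Construct a TrainingSplit
#'
#' @param train,validation,test Fractions summing to 1.
#' @return A [TrainingSplit-class].
#' @export
trainingSplit <- function(train = 0.70, validation = 0.15, test = 0.15) {
  new("TrainingSplit",
      fractions = c(train = train, validation = validation, test = test))
}

#' NoiseEstimatorModel: a trained interference estimator
#'
#' A multilayer perceptron mapping the instantaneous complex samples of the
#' reference bins to the interference component of the target bins, together
#' with its input/output z-score normalization statistics and training
#' diagnostics. Mean-square errors are complex MSEs: mean of squared complex
#' error magnitudes over samples and target bins.
#'
#' @slot architecture The [EstimatorArchitecture-class].
#' @slot weights List of weight matrices `W` and bias vectors `b` per layer.
#' @slot normalization List with `xMean`, `xSd`, `yMean`, `ySd`.
#' @slot referenceBins,targetBins Global bin indices.
#' @slot trainingMse,validationMse,testMse Complex MSEs on the three splits.
#' @slot converged FALSE when training failed to reduce the loss.
#' @slot control Training control parameters actually used.
#' @slot seed Training seed.
#'
#' @aliases NoiseEstimatorModel
#' @export
setClass("NoiseEstimatorModel",
  representation(architecture = "EstimatorArchitecture", weights = "list",
                 normalization = "list", referenceBins = "integer",
                 targetBins = "integer", trainingMse = "numeric",
                 validationMse = "numeric", testMse = "numeric",
                 converged = "logical", control = "list", seed = "integer"))

# ---------------------------------------------------------------------------
# Enhancement
# ---------------------------------------------------------------------------

#' BinWeights: averaging weights, polarities and projection axes
#'
#' Per-target-bin fusion parameters for range-bin weighted averaging: a
#' non-negative weight (normalized to sum 1), a polarity sign relative to the
#' reference bin, and the fixed complex projection axis and centre used to
#' turn each complex bin into a real series. Storing the axes makes the
#' projection causal and reproducible at monitoring time.
#'
#' @slot bins Global target bin indices.
#' @slot weights Non-negative weights summing to 1.
#' @slot polarity +1 / -1 per bin; the reference bin is +1.
#' @slot axes Unit complex projection direction per bin.
#' @slot centers Complex centre subtracted before projection.
#' @slot referenceBin Global index of the polarity reference bin.
#'
#' @aliases BinWeights
#' @export
setClass("BinWeights",
  representation(bins = "integer", weights = "numeric", polarity = "numeric",
                 axes = "complex", centers = "complex",
                 referenceBin = "integer"),
  validity = function(object) {
    msg <- NULL
    n <- length(object@bins)
    if (length(object@weights) != n || length(object@polarity) != n ||
        length(object@axes) != n || length(object@centers) != n)
      msg <- c(msg, "all per-bin slots must have equal length")
    if (any(object@weights < 0) || abs(sum(object@weights) - 1) > 1e-8)
      msg <- c(msg, "weights must be >= 0 and sum to 1")
    if (!all(object@polarity %in% c(-1, 1)))
      msg <- c(msg, "polarity must be +1 or -1")
    i <- match(object@referenceBin, object@bins)
    if (!is.na(i) && object@polarity[i] != 1)
      msg <- c(msg, "reference bin polarity must be +1")
    if (is.null(msg)) TRUE else msg
  })

#' RecoveredSignal: a real-valued recovered breathing signal
#'
#' @slot samples Real-valued series.
#' @slot rate Sampling rate (Hz).
#' @slot provenance List describing how the signal was produced.
#'
#' @aliases RecoveredSignal
#' @export
setClass("RecoveredSignal",
  representation(samples = "numeric", rate = "numeric",
                 provenance = "list"))

recoveredSignal <- function(samples, rate = 17, provenance = list()) {
  new("RecoveredSignal", samples = as.numeric(samples), rate = rate,
      provenance = provenance)
}

# ---------------------------------------------------------------------------
# Classification
# ---------------------------------------------------------------------------

#' PowerSeries: sliding-window signal power
#'
#' Mean-removed power of a moving window over a recovered signal. With hop 1
#' there are `length(signal) - window + 1` values; value `i` covers samples
#' `i .. i + window - 1`.
#'
#' @slot values Non-negative power values.
#' @slot windowSamples Window length in samples (default 68).
#' @slot hop Hop between windows in samples (default 1).
#' @slot rate Sampling rate of the underlying signal (Hz).
#'
#' @aliases PowerSeries
#' @export
setClass("PowerSeries",
  representation(values = "numeric", windowSamples = "integer",
                 hop = "integer", rate = "numeric"),
  validity = function(object) {
    if (any(object@values < -1e-12)) "power must be non-negative" else TRUE
  })

#' ClassifierModel: power thresholds for the four breathing classes
#'
#' Three strictly increasing power thresholds splitting windowed power into
#' the four breathing classes, obtained from 1-D k-means in the log-power
#' domain. A power on a threshold is assigned to the upper class.
#'
#' @slot thresholds Strictly increasing numeric vector of length 3 (power
#'   domain).
#' @slot classes The four class names in increasing power order.
#' @slot windowSamples Window length the thresholds were fitted for.
#' @slot logEpsilon Offset used in `log(power + eps)`.
#' @slot centersLog Fitted cluster centres in the log domain.
#'
#' @aliases ClassifierModel
#' @export
setClass("ClassifierModel",
  representation(thresholds = "numeric", classes = "character",
                 windowSamples = "integer", logEpsilon = "numeric",
                 centersLog = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (length(object@thresholds) != 3L || any(diff(object@thresholds) <= 0))
      msg <- c(msg, "need 3 strictly increasing thresholds")
    if (length(object@classes) != 4L)
      msg <- c(msg, "need exactly 4 classes")
    if (is.null(msg)) TRUE else msg
  })

#' ClassMetrics: per-class sensitivity/specificity and overall accuracy
#'
#' One-vs-rest sensitivity `TP/(TP+FN)` and specificity `TN/(TN+FP)` per
#' breathing class, the overall accuracy, and the raw confusion matrix
#' (truth in rows, prediction in columns). Sensitivity of a class absent
#' from the truth is `NA` (undefined), never 0.
#'
#' @slot confusion Integer confusion matrix, truth x predicted.
#' @slot sensitivity Named per-class sensitivity.
#' @slot specificity Named per-class specificity.
#' @slot accuracy Overall accuracy.
#'
#' @aliases ClassMetrics
#' @export
setClass("ClassMetrics",
  representation(confusion = "matrix", sensitivity = "numeric",
                 specificity = "numeric", accuracy = "numeric"))

# ---------------------------------------------------------------------------
# Pipeline profiles
# ---------------------------------------------------------------------------

#' RadarProfile: the noise profile of a radar location
#'
#' Result of the pre-treatment, no-patient phase: the selected interference
#' reference bins and the trained interference estimator for this radar
#' placement.
#'
#' @slot id Location identifier.
#' @slot referenceBins Selected interference reference bins.
#' @slot model The trained [NoiseEstimatorModel-class].
#' @slot created Creation timestamp (ISO string).
#'
#' @aliases RadarProfile
#' @export
setClass("RadarProfile",
  representation(id = "character", referenceBins = "integer",
                 model = "NoiseEstimatorModel", created = "character"),
  validity = function(object) {
    if (!all(object@model@referenceBins %in% object@referenceBins))
      "estimator reference bins must be a subset of the profile's" else TRUE
  })

#' DetectionProfile: the breathing-rate detection profile
#'
#' Combines a [RadarProfile-class] with the localized target bins, the
#' range-bin averaging weights, the filter windows and the fitted power
#' classifier -- everything needed to run monitoring.
#'
#' @slot radar The [RadarProfile-class].
#' @slot targetBins Localized contiguous target bins.
#' @slot weights The [BinWeights-class] for fusion.
#' @slot maWindow Moving-average window (samples) applied to the fused
#'   signal, default 17.
#' @slot classifier The fitted [ClassifierModel-class].
#'
#' @aliases DetectionProfile
#' @export
setClass("DetectionProfile",
  representation(radar = "RadarProfile", targetBins = "integer",
                 weights = "BinWeights", maWindow = "integer",
                 classifier = "ClassifierModel"),
  validity = function(object) {
    if (length(intersect(object@targetBins, object@radar@referenceBins)) > 0L)
      "target bins must be disjoint from reference bins" else TRUE
  })

#' MonitoringResult: aligned outputs of the monitoring phase
#'
#' @slot recovered The [RecoveredSignal-class] after fusion and filtering.
#' @slot powers The [PowerSeries-class] used for classification.
#' @slot windowLabels Predicted class per window (aligned with `powers`).
#' @slot windowStarts First sample index of each window.
#' @slot rateSeries Data frame `time_s`, `bpm` of breathing-rate estimates.
#'
#' @aliases MonitoringResult
#' @export
setClass("MonitoringResult",
  representation(recovered = "RecoveredSignal", powers = "PowerSeries",
                 windowLabels = "character", windowStarts = "integer",
                 rateSeries = "data.frame"))
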