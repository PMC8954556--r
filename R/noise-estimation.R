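#' @include AllClasses.R mlp.R
NULL

## complex (bins x time) -> real (time x 2*bins), interleaved (re, im) per bin
.interleaveComplex <- function(values) {
  nb <- nrow(values); n <- ncol(values)
  out <- matrix(0, n, 2L * nb)
  for (k in seq_len(nb)) {
    out[, 2L * k - 1L] <- Re(values[k, ])
    out[, 2L * k] <- Im(values[k, ])
  }
  out
}

## real (time x 2*bins) -> complex (bins x time)
.deinterleaveComplex <- function(mat) {
  nb <- ncol(mat) %/% 2L
  vals <- matrix(0 + 0i, nb, nrow(mat))
  for (k in seq_len(nb))
    vals[k, ] <- complex(real = mat[, 2L * k - 1L],
                         imaginary = mat[, 2L * k])
  vals
}

#' Build a training set from an interference-only recording
#'
#' One training row per slow-time sample: the inputs are the interleaved
#' real and imaginary parts of the reference bins, the labels those of the
#' target bin(s). With 7 reference bins this gives 14 inputs; with 1 target
#' bin 2 outputs (single-bin estimator), with 11 target bins 22 outputs
#' (range-bin estimator).
#'
#' @param x A [RangeBinMatrix-class] recorded without a breathing target.
#' @param referenceBins Reference bin indices (interference only).
#' @param targetBins Target bin indices whose interference is to be learned.
#' @return A list with matrices `inputs` (n x 2*nRef) and `labels`
#'   (n x 2*nTarget).
#' @export
buildTrainingSet <- function(x, referenceBins, targetBins) {
  referenceBins <- as.integer(referenceBins)
  targetBins <- as.integer(targetBins)
  if (length(intersect(referenceBins, targetBins)) > 0L)
    stop("reference and target bins must not overlap")
  ref <- restrictBins(x, referenceBins)
  tgt <- restrictBins(x, targetBins)
  list(inputs = .interleaveComplex(ref@values),
       labels = .interleaveComplex(tgt@values))
}

.normStats <- function(mat) {
  mu <- colMeans(mat)
  sd <- apply(mat, 2L, stats::sd)
  sd[!is.finite(sd) | sd < 1e-12] <- 1
  list(mean = mu, sd = sd)
}

.normApply <- function(mat, st) sweep(sweep(mat, 2L, st$mean), 2L, st$sd, "/")
.normInvert <- function(mat, st) sweep(sweep(mat, 2L, st$sd, "*"), 2L, st$mean, "+")

## complex MSE: mean squared complex-error magnitude over samples and bins,
## computed from interleaved real matrices
.complexMse <- function(pred, truth) {
  if (length(pred) == 0L) return(NA_real_)
  2 * mean((pred - truth)^2)
}

#' Train an interference estimator
#'
#' Fits the multilayer perceptron of `arch` (tanh hidden layers, linear
#' outputs) to map reference-bin samples to target-bin interference, using
#' z-score input/output normalization computed on the training split,
#' full-batch Adam, and early stopping when the validation MSE stops
#' improving. Training is deterministic for a fixed seed.
#'
#' @param inputs,labels Matrices from [buildTrainingSet()].
#' @param arch An [EstimatorArchitecture-class]; widths must match the data.
#' @param split A [TrainingSplit-class] (default 0.70 / 0.15 / 0.15).
#' @param seed Integer seed for the split and weight initialisation.
#' @param referenceBins,targetBins Bin indices recorded in the model.
#' @param control List of optimizer settings: `maxEpochs` (default 1500),
#'   `learningRate` (0.01), `patience` (100, epochs of non-improvement
#'   before stopping), `decayPatience` (40, epochs without meaningful
#'   improvement before the learning rate is halved), and `optimizer`
#'   (`"adam"`, the default, or `"lbfgs"` for full-batch quasi-Newton).
#' @return A [NoiseEstimatorModel-class]. `converged` is `FALSE` when the
#'   monitored MSE never decreased from its initial value.
#' @export
trainEstimator <- function(inputs, labels, arch = NULL,
                           split = trainingSplit(), seed = 1L,
                           referenceBins = integer(), targetBins = integer(),
                           control = list()) {
  if (nrow(inputs) != nrow(labels))
    stop("inputs and labels must have the same number of rows")
  if (any(!is.finite(inputs)) || any(!is.finite(labels)))
    stop("non-finite training data")
  if (is.null(arch)) {
    arch <- new("EstimatorArchitecture", nInputs = ncol(inputs),
                hidden = c(56L, 28L), nOutputs = ncol(labels))
  }
  if (arch@nInputs != ncol(inputs) || arch@nOutputs != ncol(labels))
    stop("architecture does not match the training data widths")
  ctrl <- utils::modifyList(list(maxEpochs = 1500L, learningRate = 0.01,
                                 patience = 100L, decayPatience = 40L,
                                 optimizer = "adam"), control)
  n <- nrow(inputs)
  fr <- split@fractions
  perm <- .withSeed(as.integer(seed), function() sample.int(n))
  nTrain <- max(1L, floor(fr[1L] * n))
  nVal <- floor(fr[2L] * n)
  iTrain <- perm[seq_len(nTrain)]
  iVal <- if (nVal > 0L) perm[nTrain + seq_len(nVal)] else integer(0)
  iTest <- if (nTrain + nVal < n) perm[(nTrain + nVal + 1L):n] else integer(0)

  xs <- .normStats(inputs[iTrain, , drop = FALSE])
  ys <- .normStats(labels[iTrain, , drop = FALSE])
  Xn <- .normApply(inputs, xs)
  Yn <- .normApply(labels, ys)

  fit <- .mlpTrain(Xn[iTrain, , drop = FALSE], Yn[iTrain, , drop = FALSE],
                   hidden = arch@hidden, seed = as.integer(seed) + 7L,
                   Xval = if (length(iVal)) Xn[iVal, , drop = FALSE],
                   Tval = if (length(iVal)) Yn[iVal, , drop = FALSE],
                   maxEpochs = ctrl$maxEpochs,
                   learningRate = ctrl$learningRate,
                   patience = ctrl$patience,
                   decayPatience = ctrl$decayPatience,
                   optimizer = ctrl$optimizer)
  converged <- length(fit$trace) > 0 &&
    min(fit$trace) < fit$trace[1L] + 1e-15

  predAll <- .normInvert(.mlpPredict(fit$layers, Xn), ys)
  mseOf <- function(idx) .complexMse(predAll[idx, , drop = FALSE],
                                     labels[idx, , drop = FALSE])
  norm <- list(xMean = xs$mean, xSd = xs$sd, yMean = ys$mean, ySd = ys$sd)
  new("NoiseEstimatorModel", architecture = arch, weights = fit$layers,
      normalization = norm, referenceBins = as.integer(referenceBins),
      targetBins = as.integer(targetBins),
      trainingMse = mseOf(iTrain), validationMse = mseOf(iVal),
      testMse = mseOf(iTest), converged = converged,
      control = ctrl, seed = as.integer(seed))
}

#' Train an estimator directly from an interference-only recording
#'
#' Convenience wrapper around [buildTrainingSet()] and [trainEstimator()]
#' using the architecture presets.
#'
#' @param x Interference-only [RangeBinMatrix-class].
#' @param referenceBins,targetBins Bin indices.
#' @param arch `"sb"`, `"rb"` or an [EstimatorArchitecture-class]; by
#'   default chosen from the number of target bins.
#' @param ... Passed to [trainEstimator()].
#' @return A [NoiseEstimatorModel-class].
#' @export
trainEstimatorFromRecording <- function(x, referenceBins, targetBins,
                                        arch = NULL, ...) {
  ds <- buildTrainingSet(x, referenceBins, targetBins)
  if (is.character(arch)) {
    arch <- switch(match.arg(arch, c("sb", "rb")),
                   sb = sbArchitecture(length(referenceBins)),
                   rb = rbArchitecture(length(referenceBins),
                                       length(targetBins)))
  }
  if (is.null(arch)) {
    arch <- if (length(targetBins) == 1L)
      sbArchitecture(length(referenceBins))
    else rbArchitecture(length(referenceBins), length(targetBins))
  }
  trainEstimator(ds$inputs, ds$labels, arch = arch,
                 referenceBins = referenceBins, targetBins = targetBins, ...)
}

#' Estimate the interference in the target bins
#'
#' Applies the trained estimator sample by sample: only the current
#' slow-time sample of the reference bins is used, so the estimate is causal
#' and real-time capable.
#'
#' @param model A [NoiseEstimatorModel-class].
#' @param x A [RangeBinMatrix-class] containing the model's reference bins.
#' @return A [RangeBinMatrix-class] of complex interference estimates over
#'   the model's target bins.
#' @export
estimateNoise <- function(model, x) {
  ref <- restrictBins(x, model@referenceBins)
  X <- .interleaveComplex(ref@values)
  Xn <- .normApply(X, list(mean = model@normalization$xMean,
                           sd = model@normalization$xSd))
  Yn <- .mlpPredict(model@weights, Xn)
  Y <- .normInvert(Yn, list(mean = model@normalization$yMean,
                            sd = model@normalization$ySd))
  rangeBinMatrix(.deinterleaveComplex(Y), rate = x@rate,
                 binSpacing = x@binSpacing, bins = model@targetBins)
}

#' Subtract the estimated interference from the target bins
#'
#' @param model A [NoiseEstimatorModel-class].
#' @param x A [RangeBinMatrix-class] containing both the model's reference
#'   and target bins.
#' @return A [RangeBinMatrix-class] of denoised target bins, sample-aligned
#'   with the input.
#' @export
denoise <- function(model, x) {
  est <- estimateNoise(model, x)
  tgt <- restrictBins(x, model@targetBins)
  rangeBinMatrix(tgt@values - est@values, rate = x@rate,
                 binSpacing = x@binSpacing, bins = model@targetBins)
}

#' Mean-square error of the interference estimate against ground truth
#'
#' @param model A [NoiseEstimatorModel-class].
#' @param x Interference-only [RangeBinMatrix-class] (model inputs).
#' @param truth Ground-truth interference: a [RangeBinMatrix-class]
#'   containing the model's target bins, or a complex matrix with one row
#'   per target bin.
#' @return A list with `perBin` (named numeric, mean squared complex-error
#'   magnitude per target bin) and `pooled` (mean over all bins and
#'   samples).
#' @export
evaluateMse <- function(model, x, truth) {
  est <- estimateNoise(model, x)
  tv <- if (is(truth, "RangeBinMatrix"))
    restrictBins(truth, model@targetBins)@values
  else truth
  if (!all(dim(tv) == dim(est@values)))
    stop("truth dimensions do not match the estimate")
  err2 <- Mod(est@values - tv)^2
  perBin <- rowMeans(err2)
  names(perBin) <- as.character(model@targetBins)
  list(perBin = perBin, pooled = mean(err2))
}
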