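#' @include AllClasses.R
NULL

## First principal axis of a complex series in the complex plane.
## Returns a unit complex direction with a canonical sign (so repeated
## computation on equivalent data yields the same orientation) and the
## complex centre. A (near-)constant series gets the real axis.
.principalAxis <- function(z) {
  mu <- mean(z)
  zc <- z - mu
  sxx <- mean(Re(zc)^2); syy <- mean(Im(zc)^2); sxy <- mean(Re(zc) * Im(zc))
  if (sxx + syy < 1e-30)
    return(list(axis = 1 + 0i, center = mu, power = 0))
  ## leading eigenvector of the 2x2 covariance [[sxx, sxy], [sxy, syy]]
  tr <- sxx + syy
  det <- sxx * syy - sxy^2
  lam <- tr / 2 + sqrt(max(tr^2 / 4 - det, 0))
  v <- if (abs(sxy) > 1e-30) c(lam - syy, sxy) else
    if (sxx >= syy) c(1, 0) else c(0, 1)
  v <- v / sqrt(sum(v^2))
  ## canonical sign: larger component positive; tie-break on the real part
  if (abs(v[1]) >= abs(v[2])) { if (v[1] < 0) v <- -v } else
    if (v[2] < 0) v <- -v
  axis <- complex(real = v[1], imaginary = v[2])
  score <- Re(Conj(axis) * zc)
  list(axis = axis, center = mu, power = mean(score^2))
}

## project complex bins to real series using fixed axes/centres
.projectWith <- function(values, axes, centers) {
  out <- matrix(0, nrow(values), ncol(values))
  for (k in seq_len(nrow(values)))
    out[k, ] <- Re(Conj(axes[k]) * (values[k, ] - centers[k]))
  out
}

#' Project complex range bins onto fixed real axes
#'
#' Applies the per-bin principal-axis projection stored in a
#' [BinWeights-class] object: each complex bin is centred and projected
#' onto its stored axis, yielding one real series per bin. Because the axes
#' are fixed at calibration time, the projection is causal at monitoring
#' time.
#'
#' @param x A [RangeBinMatrix-class] (or complex matrix) over the weight
#'   object's bins.
#' @param w A [BinWeights-class].
#' @return Numeric matrix, bins x samples.
#' @export
projectBins <- function(x, w) {
  vals <- if (is(x, "RangeBinMatrix")) restrictBins(x, w@bins)@values else x
  if (nrow(vals) != length(w@bins))
    stop("bin count does not match the weights")
  .projectWith(vals, w@axes, w@centers)
}

#' Compute averaging weights and polarities for the target bins
#'
#' Each denoised complex bin is projected onto its first principal axis in
#' the complex plane (maximum-variance direction). Weights are proportional
#' to the projected signal power of each bin; the polarity is the sign of
#' the zero-lag correlation of each projected series with the reference
#' bin's (ties broken toward +1), so bins whose breathing waveform appears
#' inverted are flipped back before averaging.
#'
#' @param x A [RangeBinMatrix-class] (or complex matrix) of denoised target
#'   bins.
#' @param referenceBin Global index of the polarity reference bin; defaults
#'   to the highest-power bin.
#' @return A [BinWeights-class]. All-zero input yields uniform weights and
#'   +1 polarities with a warning.
#' @export
computeWeightsAndPolarity <- function(x, referenceBin = NULL) {
  if (!is(x, "RangeBinMatrix"))
    x <- rangeBinMatrix(x)
  vals <- x@values
  nb <- nrow(vals)
  if (nb < 1L) stop("need at least one bin")
  pcs <- lapply(seq_len(nb), function(k) .principalAxis(vals[k, ]))
  axes <- vapply(pcs, function(p) p$axis, complex(1))
  centers <- vapply(pcs, function(p) p$center, complex(1))
  powers <- vapply(pcs, function(p) p$power, numeric(1))
  scores <- .projectWith(vals, axes, centers)
  if (all(powers < 1e-30)) {
    warning("all bins are (near) zero; using uniform weights")
    return(new("BinWeights", bins = x@bins, weights = rep(1 / nb, nb),
               polarity = rep(1, nb), axes = axes, centers = centers,
               referenceBin = x@bins[1L]))
  }
  if (is.null(referenceBin)) referenceBin <- x@bins[which.max(powers)]
  iref <- match(as.integer(referenceBin), x@bins)
  if (is.na(iref)) stop("reference bin not present")
  refScore <- scores[iref, ]
  polarity <- vapply(seq_len(nb), function(k) {
    cc <- sum(scores[k, ] * refScore)
    if (cc < 0) -1 else 1      # ties toward +1
  }, numeric(1))
  weights <- powers / sum(powers)
  new("BinWeights", bins = x@bins, weights = weights, polarity = polarity,
      axes = axes, centers = centers,
      referenceBin = as.integer(referenceBin))
}

#' Range-bin weighted averaging (RBWA)
#'
#' Coherently fuses the projected target bins into a single real breathing
#' signal: `output[n] = sum_b w_b * polarity_b * proj_b[n]`. For bins
#' carrying the same waveform with independent equal-power noise, coherent
#' averaging raises the SNR roughly with the square root of the number of
#' bins.
#'
#' @param x A [RangeBinMatrix-class] (or complex matrix) of denoised target
#'   bins.
#' @param w A [BinWeights-class] matching the bins of `x`.
#' @return A [RecoveredSignal-class].
#' @export
rangeBinWeightedAverage <- function(x, w) {
  scores <- projectBins(x, w)
  out <- as.numeric(crossprod(scores, w@weights * w@polarity))
  rate <- if (is(x, "RangeBinMatrix")) x@rate else 17
  recoveredSignal(out, rate = rate,
                  provenance = list(stage = "rbwa", bins = w@bins,
                                    referenceBin = w@referenceBin))
}

#' Moving-average filter
#'
#' Causal (trailing) moving mean: sample `n` is the mean of the most recent
#' `window` samples; the first `window - 1` outputs average the partial
#' window, so the length is preserved. A centred variant is available for
#' offline analysis.
#'
#' @param x Numeric vector or [RecoveredSignal-class].
#' @param window Window length in samples (>= 1, at most the signal
#'   length).
#' @param sides `"causal"` (default) or `"centered"`.
#' @return Same type as the input.
#' @export
movingAverage <- function(x, window, sides = c("causal", "centered")) {
  sides <- match.arg(sides)
  v <- if (is(x, "RecoveredSignal")) x@samples else x
  n <- length(v)
  window <- as.integer(window)
  if (window < 1L) stop("window must be >= 1")
  if (window > n) stop("window exceeds the signal length")
  cs <- cumsum(v)
  if (sides == "causal") {
    lo <- pmax(seq_len(n) - window + 1L, 1L)
    out <- (cs - c(0, cs)[lo]) / (seq_len(n) - lo + 1L)
  } else {
    half <- (window - 1L) %/% 2L
    lo <- pmax(seq_len(n) - half, 1L)
    hi <- pmin(seq_len(n) + (window - 1L - half), n)
    out <- (cs[hi] - c(0, cs)[lo]) / (hi - lo + 1L)
  }
  if (is(x, "RecoveredSignal")) {
    prov <- x@provenance
    prov$maWindow <- window
    recoveredSignal(out, rate = x@rate, provenance = prov)
  } else out
}

## zero-padded periodogram; returns freq grid and power
.periodogram <- function(v, rate, padFactor = 4L) {
  v <- v - mean(v)
  n <- length(v)
  nfft <- 2^ceiling(log2(max(n * padFactor, 2)))
  P <- Mod(stats::fft(c(v, rep(0, nfft - n))))^2 / n
  k <- seq_len(nfft %/% 2L)          # positive frequencies, DC excluded
  list(freq = k * rate / nfft, power = P[k + 1L])
}

#' Dominant in-band periodogram frequency
#'
#' Frequency of the periodogram maximum within a band, using a zero-padded
#' FFT of the mean-removed signal.
#'
#' @param x Numeric vector or [RecoveredSignal-class].
#' @param rate Sampling rate in Hz (taken from the signal if available).
#' @param band Frequency band searched, default `c(0, 0.5)` Hz.
#' @param padFactor Zero-padding factor for the FFT grid, default 4.
#' @return Frequency in Hz, or `NA` for a constant signal.
#' @export
dominantFrequency <- function(x, rate = NULL, band = c(0, 0.5),
                              padFactor = 4L) {
  v <- if (is(x, "RecoveredSignal")) x@samples else x
  if (is.null(rate)) rate <- if (is(x, "RecoveredSignal")) x@rate else
    stop("rate required")
  if (stats::var(v) < 1e-30) return(NA_real_)
  pg <- .periodogram(v, rate, padFactor)
  sel <- pg$freq > band[1L] & pg$freq <= band[2L]
  if (!any(sel)) return(NA_real_)
  pg$freq[sel][which.max(pg$power[sel])]
}

#' Estimate the breathing rate from a recovered signal
#'
#' Takes the trailing `windowS` seconds of the signal and returns the
#' dominant periodogram frequency in the breathing band, converted to
#' breaths per minute. When no spectral peak stands sufficiently proud of
#' the in-band noise floor (breath hold, or no subject), the rate is 0.
#'
#' @param x Numeric vector or [RecoveredSignal-class].
#' @param windowS Analysis window in seconds (default 30); must span at
#'   least two periods of the fastest in-band breath and fit in the signal.
#' @param rate Sampling rate (Hz), taken from the signal if available.
#' @param band Breathing band in Hz, default `c(0, 0.5)` (0-30 breaths/min).
#' @param prominence Peak-to-median power ratio required to report a
#'   nonzero rate, default 8.
#' @return Breathing rate in breaths per minute (0 when no peak).
#' @export
#' @examples
#' x <- sin(2 * pi * 0.25 * (0:509) / 17)
#' estimateBreathingRate(x, windowS = 30, rate = 17)   # 15
estimateBreathingRate <- function(x, windowS = 30, rate = NULL,
                                  band = c(0, 0.5), prominence = 8) {
  v <- if (is(x, "RecoveredSignal")) x@samples else x
  if (is.null(rate)) rate <- if (is(x, "RecoveredSignal")) x@rate else
    stop("rate required")
  nw <- as.integer(round(windowS * rate))
  if (windowS < 2 / band[2L] || nw < 4L)
    stop("window too short: must span at least two breathing periods")
  if (nw > length(v)) stop("window exceeds the signal length")
  v <- v[(length(v) - nw + 1L):length(v)]
  if (stats::var(v) < 1e-30) return(0)
  pg <- .periodogram(v, rate)
  sel <- pg$freq > band[1L] & pg$freq <= band[2L]
  pk <- which.max(pg$power[sel])
  if (pg$power[sel][pk] <= prominence * stats::median(pg$power[sel]))
    return(0)
  60 * pg$freq[sel][pk]
}
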