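#' @include AllClasses.R
NULL

#' Windowed signal power
#'
#' Mean-removed power of a sliding window: for each window the mean is
#' subtracted and the mean of the squared residuals taken, so constant
#' offsets (e.g. a breath-hold plateau) carry no power. Window `i` covers
#' samples `i .. i + window - 1`; with hop 1 there are
#' `length(x) - window + 1` windows.
#'
#' @param x Numeric vector or [RecoveredSignal-class].
#' @param window Window length in samples, default 68.
#' @param hop Hop between consecutive windows, default 1.
#' @param rate Sampling rate (Hz), taken from the signal if available.
#' @return A [PowerSeries-class].
#' @export
#' @examples
#' x <- 4 * sin(2 * pi * 0.25 * (0:135) / 17)
#' powerValues(windowedPower(x, 68))[1]   # 8 = A^2 / 2
windowedPower <- function(x, window = 68L, hop = 1L, rate = NULL) {
  v <- if (is(x, "RecoveredSignal")) x@samples else x
  if (is.null(rate)) rate <- if (is(x, "RecoveredSignal")) x@rate else 17
  n <- length(v)
  window <- as.integer(window); hop <- as.integer(hop)
  if (window > n) stop("window exceeds the signal length")
  if (window < 2L) stop("window must be >= 2")
  if (hop < 1L) stop("hop must be >= 1")
  starts <- seq.int(1L, n - window + 1L, by = hop)
  cs <- c(0, cumsum(v)); cs2 <- c(0, cumsum(v^2))
  sm <- cs[starts + window] - cs[starts]
  sq <- cs2[starts + window] - cs2[starts]
  p <- pmax(sq / window - (sm / window)^2, 0)
  new("PowerSeries", values = p, windowSamples = window, hop = hop,
      rate = rate)
}

#' Majority ground-truth label per window
#'
#' Reduces a per-sample label track to one label per sliding window (the
#' majority label inside the window; ties go to the later-appearing label),
#' aligned with [windowedPower()].
#'
#' @param labels Character vector of per-sample labels.
#' @param window Window length in samples.
#' @param hop Hop between windows, default 1.
#' @return Character vector, one label per window.
#' @export
windowMajorityLabels <- function(labels, window = 68L, hop = 1L) {
  n <- length(labels)
  window <- as.integer(window); hop <- as.integer(hop)
  if (window > n) stop("window exceeds the label track length")
  lev <- unique(labels)
  num <- match(labels, lev)
  counts <- vapply(seq_along(lev), function(l) {
    cs <- c(0L, cumsum(num == l))
    starts <- seq.int(1L, n - window + 1L, by = hop)
    cs[starts + window] - cs[starts]
  }, integer(length(seq.int(1L, n - window + 1L, by = hop))))
  counts <- matrix(counts, ncol = length(lev))
  ## ties toward the label seen later in the window: prefer the class of the
  ## window's last sample when counts tie
  starts <- seq.int(1L, n - window + 1L, by = hop)
  lastLab <- num[starts + window - 1L]
  pick <- vapply(seq_along(starts), function(i) {
    mx <- max(counts[i, ])
    cand <- which(counts[i, ] == mx)
    if (length(cand) > 1L && lastLab[i] %in% cand) lastLab[i] else cand[1L]
  }, integer(1))
  lev[pick]
}

#' Fit breathing-class power thresholds by k-means
#'
#' Runs 1-D k-means (k = 4) on `log(power + eps)`, orders the cluster
#' centres, and places each threshold at the midpoint between adjacent
#' centres in the log domain (mapped back to the power domain). Classes are
#' assigned to clusters in increasing power order: no breathing, breath
#' hold, free breathing, deep inspiration. Deterministic for a fixed seed.
#'
#' @param powers A [PowerSeries-class] or numeric vector of window powers
#'   (a calibration segment containing all four classes).
#' @param k Number of clusters, default 4.
#' @param seed Seed for the k-means restarts.
#' @param logEpsilon Offset inside the log, default `1e-12`.
#' @param nstart Number of k-means restarts, default 25.
#' @return A [ClassifierModel-class].
#' @export
fitThresholds <- function(powers, k = 4L, seed = 1L, logEpsilon = 1e-12,
                          nstart = 25L) {
  p <- if (is(powers, "PowerSeries")) powers@values else powers
  window <- if (is(powers, "PowerSeries")) powers@windowSamples else 68L
  if (length(unique(p)) < k)
    stop("need at least ", k, " distinct power values")
  lp <- log(p + logEpsilon)
  km <- .withSeed(as.integer(seed), function()
    stats::kmeans(lp, centers = k, nstart = nstart, iter.max = 100L))
  cen <- sort(as.numeric(km$centers))
  thrLog <- (cen[-k] + cen[-1L]) / 2
  thr <- exp(thrLog) - logEpsilon
  new("ClassifierModel", thresholds = thr, classes = breathingClasses(),
      windowSamples = as.integer(window), logEpsilon = logEpsilon,
      centersLog = cen)
}

#' Classify window powers into breathing classes
#'
#' Assigns each power to the class of the interval it falls in; a power
#' exactly on a threshold goes to the upper class. This induces the same
#' partition as nearest-cluster-centre assignment in the log domain.
#'
#' @param powers A [PowerSeries-class] or numeric vector.
#' @param model A fitted [ClassifierModel-class].
#' @return Character vector of class labels, one per window.
#' @export
classifyPowers <- function(powers, model) {
  p <- if (is(powers, "PowerSeries")) powers@values else powers
  idx <- 1L + (p >= model@thresholds[1L]) + (p >= model@thresholds[2L]) +
    (p >= model@thresholds[3L])
  model@classes[idx]
}

#' Classification metrics against ground truth
#'
#' Builds the 4-class confusion matrix and computes one-vs-rest sensitivity
#' `TP/(TP+FN)` and specificity `TN/(TN+FP)` per class, and the overall
#' accuracy (correct windows over total windows). A class absent from the
#' truth has undefined (`NA`) sensitivity and is excluded from any
#' averaging by the caller.
#'
#' @param predicted,truth Character vectors of equal length with labels
#'   from [breathingClasses()] (or any common label set via `classes`).
#' @param classes Label set, default [breathingClasses()].
#' @return A [ClassMetrics-class].
#' @export
evaluateClassification <- function(predicted, truth,
                                   classes = breathingClasses()) {
  if (length(predicted) != length(truth))
    stop("predicted and truth must have equal length")
  bad <- setdiff(unique(c(predicted, truth)), classes)
  if (length(bad) > 0L)
    stop("labels outside the class set: ", paste(bad, collapse = ", "))
  cm <- table(factor(truth, classes), factor(predicted, classes))
  cm <- matrix(as.integer(cm), nrow = length(classes),
               dimnames = list(truth = classes, predicted = classes))
  total <- sum(cm)
  sens <- vapply(seq_along(classes), function(i) {
    tp <- cm[i, i]; fn <- sum(cm[i, -i])
    if (tp + fn == 0L) NA_real_ else tp / (tp + fn)
  }, numeric(1))
  spec <- vapply(seq_along(classes), function(i) {
    tn <- sum(cm[-i, -i]); fp <- sum(cm[-i, i])
    if (tn + fp == 0L) NA_real_ else tn / (tn + fp)
  }, numeric(1))
  names(sens) <- names(spec) <- classes
  new("ClassMetrics", confusion = cm, sensitivity = sens,
      specificity = spec, accuracy = sum(diag(cm)) / total)
}
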