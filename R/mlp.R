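## Internal multilayer-perceptron engine: tanh hidden layers, linear output,
## full-batch Adam with early stopping on a validation set. Deliberately
## minimal -- the estimators need a deterministic, dependency-free trainer for
## networks of at most a few hundred units.

.mlpInit <- function(sizes, seed) {
  ## Glorot-uniform initialisation; deterministic for a fixed seed.
  .withSeed(seed, function() {
    lapply(seq_len(length(sizes) - 1L), function(l) {
      nin <- sizes[l]; nout <- sizes[l + 1L]
      lim <- sqrt(6 / (nin + nout))
      list(W = matrix(runif(nin * nout, -lim, lim), nin, nout),
           b = rep(0, nout))
    })
  })
}

.mlpForward <- function(layers, X) {
  nl <- length(layers)
  acts <- vector("list", nl + 1L)
  acts[[1L]] <- X
  for (l in seq_len(nl)) {
    Z <- acts[[l]] %*% layers[[l]]$W
    Z <- sweep(Z, 2L, layers[[l]]$b, "+")
    acts[[l + 1L]] <- if (l < nl) tanh(Z) else Z
  }
  acts
}

.mlpPredict <- function(layers, X) {
  acts <- .mlpForward(layers, X)
  acts[[length(acts)]]
}

## gradient of mean((Y - T)^2) over all entries
.mlpGradient <- function(layers, acts, Tgt) {
  nl <- length(layers)
  n <- nrow(Tgt)
  grads <- vector("list", nl)
  delta <- 2 * (acts[[nl + 1L]] - Tgt) / (n * ncol(Tgt))
  for (l in rev(seq_len(nl))) {
    grads[[l]] <- list(W = crossprod(acts[[l]], delta),
                       b = colSums(delta))
    if (l > 1L)
      delta <- (delta %*% t(layers[[l]]$W)) * (1 - acts[[l]]^2)
  }
  grads
}

.mlpLoss <- function(layers, X, Tgt) {
  Y <- .mlpPredict(layers, X)
  mean((Y - Tgt)^2)
}

.mlpPack <- function(layers) {
  unlist(lapply(layers, function(l) c(l$W, l$b)))
}

.mlpUnpack <- function(par, sizes) {
  layers <- vector("list", length(sizes) - 1L)
  off <- 0L
  for (l in seq_len(length(sizes) - 1L)) {
    nw <- sizes[l] * sizes[l + 1L]
    W <- matrix(par[off + seq_len(nw)], sizes[l], sizes[l + 1L])
    off <- off + nw
    b <- par[off + seq_len(sizes[l + 1L])]
    off <- off + sizes[l + 1L]
    layers[[l]] <- list(W = W, b = b)
  }
  layers
}

## full-batch quasi-Newton training via optim(); deterministic
.mlpTrainLbfgs <- function(X, Tgt, hidden, seed, Xval = NULL, Tval = NULL,
                           maxEpochs = 1000L) {
  sizes <- c(ncol(X), hidden, ncol(Tgt))
  init <- .mlpInit(sizes, seed)
  initLoss <- .mlpLoss(init, X, Tgt)
  fn <- function(p) .mlpLoss(.mlpUnpack(p, sizes), X, Tgt)
  gr <- function(p) {
    layers <- .mlpUnpack(p, sizes)
    acts <- .mlpForward(layers, X)
    .mlpPack(.mlpGradient(layers, acts, Tgt))
  }
  opt <- stats::optim(.mlpPack(init), fn, gr, method = "L-BFGS-B",
                      control = list(maxit = maxEpochs, factr = 10))
  layers <- .mlpUnpack(opt$par, sizes)
  useVal <- !is.null(Xval) && nrow(Xval) > 0L
  monitor <- if (useVal) .mlpLoss(layers, Xval, Tval) else opt$value
  list(layers = layers, monitorLoss = monitor,
       trace = c(initLoss, opt$value), epochs = opt$counts[["function"]])
}

## Adam on the full batch. Returns layers plus loss traces.
.mlpTrain <- function(X, Tgt, hidden, seed,
                      Xval = NULL, Tval = NULL,
                      maxEpochs = 1500L, learningRate = 0.01,
                      patience = 100L, decayPatience = 40L,
                      decayFactor = 0.5, minLearningRate = 1e-6,
                      beta1 = 0.9, beta2 = 0.999,
                      epsilon = 1e-8, tol = 0, optimizer = "adam") {
  if (identical(optimizer, "lbfgs"))
    return(.mlpTrainLbfgs(X, Tgt, hidden, seed, Xval, Tval, maxEpochs))
  sizes <- c(ncol(X), hidden, ncol(Tgt))
  layers <- .mlpInit(sizes, seed)
  nl <- length(layers)
  m <- lapply(layers, function(l) list(W = l$W * 0, b = l$b * 0))
  v <- m
  best <- layers
  useVal <- !is.null(Xval) && nrow(Xval) > 0L
  bestLoss <- if (useVal) .mlpLoss(layers, Xval, Tval) else
    .mlpLoss(layers, X, Tgt)
  sinceBest <- 0L
  sinceCheck <- 0L
  checkLoss <- bestLoss
  trainTrace <- numeric(0)
  for (epoch in seq_len(maxEpochs)) {
    acts <- .mlpForward(layers, X)
    grads <- .mlpGradient(layers, acts, Tgt)
    for (l in seq_len(nl)) {
      for (p in c("W", "b")) {
        g <- grads[[l]][[p]]
        m[[l]][[p]] <- beta1 * m[[l]][[p]] + (1 - beta1) * g
        v[[l]][[p]] <- beta2 * v[[l]][[p]] + (1 - beta2) * g^2
        mhat <- m[[l]][[p]] / (1 - beta1^epoch)
        vhat <- v[[l]][[p]] / (1 - beta2^epoch)
        layers[[l]][[p]] <- layers[[l]][[p]] -
          learningRate * mhat / (sqrt(vhat) + epsilon)
      }
    }
    curLoss <- if (useVal) .mlpLoss(layers, Xval, Tval) else
      .mlpLoss(layers, X, Tgt)
    trainTrace <- c(trainTrace, curLoss)
    if (curLoss < bestLoss - tol) {
      bestLoss <- curLoss
      best <- layers
      sinceBest <- 0L
    } else {
      sinceBest <- sinceBest + 1L
      if (sinceBest >= patience) break
    }
    ## reduce-on-plateau: Adam's steady-state jitter scales with the
    ## learning rate, so halve it (restarting from the best weights) unless
    ## the monitored loss improved meaningfully over the last check period
    sinceCheck <- sinceCheck + 1L
    if (sinceCheck >= decayPatience) {
      if (bestLoss > checkLoss * 0.98) {
        learningRate <- learningRate * decayFactor
        if (learningRate < minLearningRate) break
        layers <- best
        m <- lapply(layers, function(l) list(W = l$W * 0, b = l$b * 0))
        v <- m
      }
      checkLoss <- bestLoss
      sinceCheck <- 0L
    }
  }
  list(layers = best, monitorLoss = bestLoss, trace = trainTrace,
       epochs = length(trainTrace))
}
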