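## Single-hidden-layer perceptron for per-segment classification.
##
## One ReLU hidden layer, logistic output, minibatch Adam with L2 penalty
## (the `alpha` hyperparameter) and an epoch cap (`max_iter`). Training
## stops early when the epoch loss has not improved by more than `tol` for
## `patience` consecutive epochs. Deterministic given the RNG state: weight
## initialization and minibatch shuffling are the only stochastic parts.
## All heavy operations are BLAS matrix products, so fits at the study
## sizes (thousands of rows, hundreds of hidden units) take seconds.

mlpFit <- function(x, y, hidden, alpha = 1, maxIter = 1000, lr = 1e-3,
                   batchSize = 200, tol = 1e-4, patience = 10) {
  n <- nrow(x); p <- ncol(x)
  ## He-style initialization for the ReLU layer, Glorot for the output
  W1 <- matrix(rnorm(p * hidden, 0, sqrt(2 / p)), p, hidden)
  b1 <- numeric(hidden)
  W2 <- matrix(rnorm(hidden, 0, sqrt(1 / hidden)), hidden, 1)
  b2 <- 0
  ## Adam state
  mW1 <- vW1 <- matrix(0, p, hidden); mb1 <- vb1 <- numeric(hidden)
  mW2 <- vW2 <- matrix(0, hidden, 1); mb2 <- vb2 <- 0
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  step <- 0
  best <- Inf; bad <- 0
  batchSize <- min(batchSize, n)

  for (epoch in seq_len(maxIter)) {
    perm <- sample.int(n)
    lossSum <- 0
    for (s in seq(1, n, by = batchSize)) {
      idx <- perm[s:min(s + batchSize - 1, n)]
      nb <- length(idx)
      xb <- x[idx, , drop = FALSE]
      yb <- y[idx]
      ## forward
      h <- xb %*% W1
      h <- sweep(h, 2, b1, "+")
      a <- pmax(h, 0)
      z <- drop(a %*% W2) + b2
      prob <- 1 / (1 + exp(-z))
      lossSum <- lossSum + sum(-yb * log(pmax(prob, 1e-12)) -
                                 (1 - yb) * log(pmax(1 - prob, 1e-12)))
      ## backward (mean gradient over the batch, L2 on weights)
      dz <- (prob - yb) / nb
      gW2 <- crossprod(a, dz) + (alpha / nb) * W2
      gb2 <- sum(dz)
      da <- tcrossprod(dz, W2)
      da[h <= 0] <- 0
      gW1 <- crossprod(xb, da) + (alpha / nb) * W1
      gb1 <- colSums(da)
      ## Adam updates
      step <- step + 1
      c1 <- 1 - beta1^step; c2 <- 1 - beta2^step
      upd <- function(m, v, g) {
        m <- beta1 * m + (1 - beta1) * g
        v <- beta2 * v + (1 - beta2) * g^2
        list(m = m, v = v, d = lr * (m / c1) / (sqrt(v / c2) + eps))
      }
      u <- upd(mW1, vW1, gW1); mW1 <- u$m; vW1 <- u$v; W1 <- W1 - u$d
      u <- upd(mb1, vb1, gb1); mb1 <- u$m; vb1 <- u$v; b1 <- b1 - u$d
      u <- upd(mW2, vW2, gW2); mW2 <- u$m; vW2 <- u$v; W2 <- W2 - u$d
      u <- upd(mb2, vb2, gb2); mb2 <- u$m; vb2 <- u$v; b2 <- b2 - u$d
    }
    loss <- lossSum / n +
      alpha / (2 * batchSize) * (sum(W1^2) + sum(W2^2))
    if (loss < best - tol) {
      best <- loss; bad <- 0
    } else {
      bad <- bad + 1
      if (bad >= patience) break
    }
  }
  structure(list(W1 = W1, b1 = b1, W2 = W2, b2 = b2, hidden = hidden,
                 epochs = epoch, loss = best), class = "apnea_mlp")
}

mlpPredict <- function(fit, x) {
  a <- pmax(sweep(x %*% fit$W1, 2, fit$b1, "+"), 0)
  z <- drop(a %*% fit$W2) + fit$b2
  1 / (1 + exp(-z))
}
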