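#' Signed logistic squashing to (-1, 1)
#'
#' `2 / (1 + exp(-x)) - 1`, identically `tanh(x / 2)`: the logistic
#' function rescaled so that the +/-1 class labels are attainable targets
#' and a zero decision threshold separates the classes.
#'
#' @param x numeric.
#' @return values in (-1, 1).
#' @export
signedLogistic <- function(x) tanh(x / 2)

.logisticCost <- function(theta, X, y, lambda) {
  z <- theta[1L] + drop(X %*% theta[-1L])
  r <- signedLogistic(z) - y
  sum(r^2) + lambda * sum(theta[-1L]^2)
}

.logisticGrad <- function(theta, X, y, lambda) {
  z <- theta[1L] + drop(X %*% theta[-1L])
  s <- signedLogistic(z)
  common <- 2 * (s - y) * (1 - s^2) / 2
  c(sum(common), drop(crossprod(X, common)) + 2 * lambda * theta[-1L])
}

#' Single-neuron perceptron (ridge-regularized logistic regression)
#'
#' Fits the squared-error logistic cost
#' `sum_p [sigma(b + f_p . w) - y_p]^2 + lambda ||w||^2` with
#' `sigma` the signed logistic (range (-1, 1)) and labels `y = +/-1`, by
#' deterministic gradient descent from zero initialization
#' (Barzilai-Borwein adaptive step with backtracking), stopping when the
#' gradient norm falls below `tol` or the iteration budget is exhausted.
#'
#' @param trainX training matrix, patients x features.
#' @param y labels in -1/+1 (both classes required).
#' @param fTest test feature vector.
#' @param lambda ridge regularization (default 0.1).
#' @param maxIter iteration budget.
#' @param tol gradient-norm convergence tolerance.
#' @return list with prediction `P` in (-1, 1), `b`, `w`, `converged`.
#' @export
logisticClassifier <- function(trainX, y, fTest, lambda = 0.1,
                               maxIter = 5000L, tol = 1e-8) {
  if (length(unique(y)) < 2L) stop("both classes required in training set")
  if (any(!is.finite(trainX)) || any(!is.finite(fTest)))
    stop("features must be finite")
  d <- ncol(trainX)
  theta <- numeric(d + 1L)
  g <- .logisticGrad(theta, trainX, y, lambda)
  cost <- .logisticCost(theta, trainX, y, lambda)
  step <- 1e-2
  converged <- FALSE
  for (it in seq_len(maxIter)) {
    if (sqrt(sum(g^2)) < tol) { converged <- TRUE; break }
    # backtracking on the current step
    repeat {
      thetaNew <- theta - step * g
      costNew <- .logisticCost(thetaNew, trainX, y, lambda)
      if (costNew <= cost - 1e-4 * step * sum(g^2) || step < 1e-14) break
      step <- step / 2
    }
    gNew <- .logisticGrad(thetaNew, trainX, y, lambda)
    # Barzilai-Borwein step proposal for the next iteration
    sVec <- thetaNew - theta
    yVec <- gNew - g
    bb <- sum(sVec * yVec)
    step <- if (bb > 0) sum(sVec^2) / bb else 1e-2
    theta <- thetaNew; g <- gNew; cost <- costNew
  }
  if (!converged && sqrt(sum(g^2)) < tol) converged <- TRUE
  if (!converged)
    warning("logistic classifier did not reach gradient tolerance; ",
            "returning best iterate")
  list(P = signedLogistic(theta[1L] + sum(fTest * theta[-1L])),
       b = theta[1L], w = theta[-1L], converged = converged)
}

#' Continuous-valued recurrent network classifier (Gibbs sampling)
#'
#' Relaxes the test vector onto the training manifold by Gibbs sampling:
#' at each iteration a training vector is drawn with probability
#' proportional to its (non-negatively clamped) inner product with the
#' working vector, one uniformly chosen coordinate of the working vector is
#' replaced by that training vector's value, and the chain's running mean
#' is tracked. The relaxed vector `f'` is the running mean at convergence
#' (stabilized over a 50-iteration window). The prediction is the
#' clamped-weight label average
#' `P = sum_p y_p max(f_p . f', 0) / sum_p max(f_p . f', 0)`, so
#' `P` lies in [-1, 1]. Feature vectors are mean-centered on the training
#' set before any inner product so that the clamping is informative.
#'
#' Uses R's current RNG stream; seed with [set.seed()] for determinism.
#'
#' @param trainX training matrix, patients x features.
#' @param y labels in -1/+1.
#' @param fTest test feature vector.
#' @param maxIter maximum Gibbs iterations (default 500).
#' @param tol running-mean max-norm convergence tolerance.
#' @return list with `P`, the relaxed vector `fRelaxed`, and `converged`.
#' @export
gibbsRnnClassifier <- function(trainX, y, fTest, maxIter = 500L,
                               tol = 1e-4) {
  mu <- colMeans(trainX)
  Fc <- sweep(trainX, 2L, mu)
  g0 <- fTest - mu
  gWork <- g0
  d <- length(g0)
  nTrain <- nrow(Fc)
  runMean <- numeric(d)
  window <- matrix(NA_real_, 50L, d)
  converged <- FALSE
  fellBack <- FALSE
  for (it in seq_len(maxIter)) {
    w <- pmax(drop(Fc %*% gWork), 0)
    if (all(w == 0)) { fellBack <- TRUE; break }
    p <- sample.int(nTrain, 1L, prob = w)
    a <- sample.int(d, 1L)
    gWork[a] <- Fc[p, a]
    runMean <- (runMean * (it - 1L) + gWork) / it
    slot <- ((it - 1L) %% 50L) + 1L
    if (it > 50L && max(abs(runMean - window[slot, ])) < tol) {
      converged <- TRUE
      break
    }
    window[slot, ] <- runMean
  }
  fRelaxed <- if (fellBack && all(runMean == 0)) g0 else runMean
  if (fellBack)
    warning("all Gibbs weights clamped to zero; using unrelaxed vector")
  wOut <- pmax(drop(Fc %*% fRelaxed), 0)
  if (all(wOut == 0)) {
    wOut <- pmax(drop(Fc %*% g0), 0)
    fRelaxed <- g0
  }
  P <- if (all(wOut == 0)) {
    warning("degenerate Gibbs weights; returning neutral prediction")
    0
  } else sum(y * wOut) / sum(wOut)
  list(P = P, fRelaxed = fRelaxed, converged = converged)
}

#' Log-likelihood (Gaussian mixture) classifier
#'
#' Models each feature independently per class by a Gaussian with the
#' class training mean and variance (floored at `1e-6` of the pooled
#' variance), scores the test vector by the summed per-feature log-density
#' difference `sum_a [L_1(f^a) - L_{-1}(f^a)]`, and squashes the raw score
#' through the signed logistic for comparability with the other ensemble
#' members.
#'
#' @param trainX training matrix, patients x features.
#' @param y labels in -1/+1, at least 2 members per class.
#' @param fTest test feature vector.
#' @return list with `P` in (-1, 1) and the unsquashed `raw` score.
#' @export
loglikClassifier <- function(trainX, y, fTest) {
  Xr <- trainX[y == -1, , drop = FALSE]
  Xs <- trainX[y == +1, , drop = FALSE]
  if (nrow(Xr) < 2L || nrow(Xs) < 2L)
    stop("log-likelihood classifier needs >= 2 training members per class")
  pooled <- apply(trainX, 2L, stats::var)
  floorVar <- pmax(1e-6 * pooled, 1e-12)
  vR <- pmax(apply(Xr, 2L, stats::var), floorVar)
  vS <- pmax(apply(Xs, 2L, stats::var), floorVar)
  raw <- sum(stats::dnorm(fTest, colMeans(Xs), sqrt(vS), log = TRUE) -
             stats::dnorm(fTest, colMeans(Xr), sqrt(vR), log = TRUE))
  list(P = signedLogistic(raw), raw = raw)
}

#' Binary network classifier (k-neighbor label vote)
#'
#' Computes correlation-contrast similarities from the test vector to every
#' training vector, links to the top `k`, and predicts the mean of the
#' linked labels: `P = sum_p y_p A(j, l_p) / sum_p A(j, l_p)`.
#'
#' @param trainX training matrix, patients x features.
#' @param y labels in -1/+1.
#' @param fTest nonzero test feature vector.
#' @param k number of neighbors (default 3, at most the training size).
#' @return list with `P` in [-1, 1] and the neighbor indices.
#' @export
networkClassifier <- function(trainX, y, fTest, k = 3L) {
  n <- nrow(trainX)
  if (k > n) stop("k must not exceed the number of training patients")
  if (sum(fTest^2) == 0) stop("zero test vector")
  sims <- apply(trainX, 1L, correlationContrast, b = fTest)
  nb <- order(sims, decreasing = TRUE)[seq_len(k)]
  list(P = mean(y[nb]), neighbors = nb)
}

#' Ensemble chemosensitivity prediction
#'
#' Runs the four binary classifiers (perceptron, Gibbs recurrent network,
#' log-likelihood, k-neighbor network) and averages their predictions. The
#' standard error combines the across-classifier sample SE
#' (`sd / sqrt(4)`) in quadrature with the root-variance of ensemble means
#' over resampled training subsets (stratified 80% subsets, refitting the
#' classifiers only).
#'
#' Uses R's current RNG stream (Gibbs sampling and subset resampling);
#' seed with [set.seed()] for determinism.
#'
#' @param trainX training matrix, patients x features.
#' @param y labels in -1/+1.
#' @param fTest test feature vector.
#' @param k network-classifier neighbors.
#' @param lambda perceptron ridge regularization.
#' @param resamples number of training-subset resamples for the quadrature
#'   SE term (0 disables).
#' @param resampleFrac fraction of each class retained per resample.
#' @return list with `P` (ensemble mean), `se`, `perClassifier` (named
#'   numeric of the four predictions) and `failed` (names of classifiers
#'   that errored, excluded from the average).
#' @export
ensemblePredict <- function(trainX, y, fTest, k = 3L, lambda = 0.1,
                            resamples = 8L, resampleFrac = 0.8) {
  runAll <- function(X, yy) {
    kk <- min(k, nrow(X))
    c(logistic = tryCatch(logisticClassifier(X, yy, fTest, lambda)$P,
                          error = function(e) NA_real_),
      rnn = tryCatch(gibbsRnnClassifier(X, yy, fTest)$P,
                     error = function(e) NA_real_),
      loglik = tryCatch(loglikClassifier(X, yy, fTest)$P,
                        error = function(e) NA_real_),
      network = tryCatch(networkClassifier(X, yy, fTest, kk)$P,
                         error = function(e) NA_real_))
  }
  per <- runAll(trainX, y)
  ok <- !is.na(per)
  if (!any(ok)) stop("all ensemble classifiers failed")
  P <- mean(per[ok])
  se <- if (sum(ok) > 1L) stats::sd(per[ok]) / sqrt(sum(ok)) else 0

  if (resamples > 0L) {
    idxR <- which(y == -1); idxS <- which(y == +1)
    means <- vapply(seq_len(resamples), function(r) {
      nR <- min(length(idxR), max(2L, ceiling(resampleFrac * length(idxR))))
      nS <- min(length(idxS), max(2L, ceiling(resampleFrac * length(idxS))))
      sub <- c(idxR[sample.int(length(idxR), nR)],
               idxS[sample.int(length(idxS), nS)])
      pr <- runAll(trainX[sub, , drop = FALSE], y[sub])
      mean(pr[!is.na(pr)])
    }, numeric(1L))
    se <- sqrt(se^2 + stats::var(means))
  }
  list(P = P, se = se, perClassifier = per,
       failed = names(per)[!ok])
}
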