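test_that("perceptron optimum matches an independent optimizer on the same cost", {
  set.seed(41)
  worst <- 0
  for (i in 1:20) {
    n <- 12L; d <- 3L
    X <- matrix(rnorm(n * d), n, d) +
      outer(rep(c(-1, 1), each = n / 2), rnorm(d))
    y <- rep(c(-1, 1), each = n / 2)
    ft <- rnorm(d)
    mine <- suppressWarnings(logisticClassifier(X, y, ft))
    cost <- function(th) {
      z <- th[1L] + drop(X %*% th[-1L])
      sum((tanh(z / 2) - y)^2) + 0.1 * sum(th[-1L]^2)
    }
    o <- stats::optim(rep(0, d + 1L), cost, method = "BFGS",
                      control = list(maxit = 2000, reltol = 1e-14))
    oracle <- tanh((o$par[1L] + sum(ft * o$par[-1L])) / 2)
    worst <- max(worst, abs(mine$P - oracle))
  }
  expect_lt(worst, 1e-4)
})

test_that("perceptron separates a 1-D separable toy problem and obeys limits", {
  tr <- separableTrainingSet(n = 10L, d = 1L, gap = 2, sd = 0.15,
                             seed = 2L)
  for (i in seq_len(nrow(tr$X))) {
    P <- suppressWarnings(
      logisticClassifier(tr$X, tr$y, tr$X[i, ])$P)
    expect_equal(sign(P), tr$y[i])
  }
  # symmetric balanced data, zero test vector -> P ~ 0
  Xs <- matrix(c(-2, -1, -1.5, 1, 2, 1.5), ncol = 1)
  ys <- c(-1, -1, -1, 1, 1, 1)
  expect_lt(abs(suppressWarnings(
    logisticClassifier(Xs, ys, 0)$P)), 0.05)
  # infinite ridge shrinks the weights to zero
  fit <- suppressWarnings(
    logisticClassifier(tr$X, tr$y, tr$X[1L, ], lambda = 1e9))
  expect_lt(max(abs(fit$w)), 1e-3)
  expect_error(logisticClassifier(Xs, rep(1, 6), 0), "both classes")
})

test_that("Gibbs classifier is seed-deterministic and resolves orthogonal class subspaces", {
  # classes living on orthogonal coordinate blocks after centering
  Xr <- cbind(matrix(rnorm(8, 5, 0.1), 4, 2), matrix(0, 4, 2))
  Xs <- cbind(matrix(0, 4, 2), matrix(rnorm(8, 5, 0.1), 4, 2))
  X <- rbind(Xr, Xs)
  y <- rep(c(-1, 1), each = 4)

  set.seed(50)
  p1 <- gibbsRnnClassifier(X, y, X[1L, ])
  set.seed(50)
  p2 <- gibbsRnnClassifier(X, y, X[1L, ])
  expect_identical(p1$P, p2$P)
  # test vector aligned with the resistant block -> pure resistant weight
  expect_equal(p1$P, -1)
  set.seed(51)
  expect_equal(gibbsRnnClassifier(X, y, X[5L, ])$P, 1)

  # degenerate single-class training set
  set.seed(52)
  expect_equal(gibbsRnnClassifier(Xr, rep(-1, 4), Xr[1L, ] + 0.05)$P, -1)

  # bounded output on random data
  set.seed(53)
  for (i in 1:5) {
    Xr <- matrix(rnorm(30), 10, 3)
    P <- gibbsRnnClassifier(Xr, sample(c(-1, 1), 10, TRUE),
                            rnorm(3))$P
    expect_lte(abs(P), 1)
  }
})

test_that("log-likelihood classifier respects symmetry, dominance and affine invariance", {
  tr <- separableTrainingSet(n = 10L, d = 2L, gap = 3, seed = 7L)
  muR <- colMeans(tr$X[tr$y == -1, ]); muS <- colMeans(tr$X[tr$y == 1, ])

  # class-mean test vectors are confidently classified
  expect_gt(loglikClassifier(tr$X, tr$y, muS)$P, 0.5)
  expect_lt(loglikClassifier(tr$X, tr$y, muR)$P, -0.5)

  # exactly symmetric classes, midpoint test vector -> raw score 0
  Xsym <- rbind(c(-1, -2), c(-2, -1), c(-3, -3), c(1, 2), c(2, 1), c(3, 3))
  ysym <- rep(c(-1, 1), each = 3)
  expect_equal(loglikClassifier(Xsym, ysym, c(0, 0))$raw, 0)

  # joint rescaling of features and test vector leaves P unchanged
  p0 <- loglikClassifier(tr$X, tr$y, muS)
  p2 <- loglikClassifier(2 * tr$X, tr$y, 2 * muS)
  expect_equal(p2$raw, p0$raw, tolerance = 1e-10)

  expect_error(loglikClassifier(tr$X[c(1, 11:20), ], tr$y[c(1, 11:20)],
                                muS), ">= 2")
})

test_that("network classifier equals a brute-force k-NN vote on exhaustive small instances", {
  set.seed(60)
  for (n in 3:6) {
    X <- matrix(rnorm(n * 3), n, 3)
    ft <- rnorm(3)
    labelGrids <- expand.grid(rep(list(c(-1, 1)), n))
    for (li in seq_len(nrow(labelGrids))) {
      y <- as.numeric(labelGrids[li, ])
      for (k in 1:n) {
        mine <- networkClassifier(X, y, ft, k)$P
        # independent path: rank all similarities, average the top-k labels
        sims <- vapply(seq_len(n), function(i) {
          a <- X[i, ]; b <- ft
          beta <- sqrt(sum(a^2)) / sqrt(sum(b^2))
          (2 * sqrt(beta) / (1 + beta)) * sum(a * b) /
            sqrt(sum(a^2) * sum(b^2))
        }, numeric(1L))
        brute <- mean(y[order(-sims)[1:k]])
        expect_equal(mine, brute)
      }
    }
  }
  expect_equal(networkClassifier(matrix(1:8, 4, 2), c(1, 1, -1, -1),
                                 c(1, 1), k = 4L)$P, 0)
  expect_error(networkClassifier(matrix(1:8, 4, 2), c(1, 1, -1, -1),
                                 c(0, 0)), "zero")
})

test_that("ensemble averaging and its standard error follow the contracts", {
  tr <- separableTrainingSet(n = 6L, d = 3L, gap = 5, seed = 9L)
  set.seed(70)
  ens <- suppressWarnings(
    ensemblePredict(tr$X, tr$y, colMeans(tr$X[tr$y == 1, ]),
                    resamples = 0L))
  expect_equal(ens$P, mean(ens$perClassifier))
  expect_equal(ens$se, sd(ens$perClassifier) / 2)
  expect_true(all(abs(ens$perClassifier) <= 1))

  # hand check of the SE rule on fixed predictions {1, 1, -1, -1}
  expect_equal(sd(c(1, 1, -1, -1)) / 2, (2 / sqrt(3)) / 2)

  # resampling only adds variance
  set.seed(71)
  ens2 <- suppressWarnings(
    ensemblePredict(tr$X, tr$y, colMeans(tr$X[tr$y == 1, ]),
                    resamples = 4L))
  expect_gte(ens2$se, ens$se - 1e-12)
})

test_that("label swap negates every classifier prediction", {
  tr <- separableTrainingSet(n = 8L, d = 3L, gap = 3, seed = 13L)
  ft <- rnorm(3)
  pLog <- suppressWarnings(logisticClassifier(tr$X, tr$y, ft)$P)
  nLog <- suppressWarnings(logisticClassifier(tr$X, -tr$y, ft)$P)
  expect_equal(nLog, -pLog, tolerance = 1e-6)
  expect_equal(loglikClassifier(tr$X, -tr$y, ft)$P,
               -loglikClassifier(tr$X, tr$y, ft)$P)
  expect_equal(networkClassifier(tr$X, -tr$y, ft)$P,
               -networkClassifier(tr$X, tr$y, ft)$P)
  # Gibbs: antisymmetric for a fixed seed (weights do not involve labels)
  set.seed(80); pG <- gibbsRnnClassifier(tr$X, tr$y, ft)$P
  set.seed(80); nG <- gibbsRnnClassifier(tr$X, -tr$y, ft)$P
  expect_equal(nG, -pG)
})
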