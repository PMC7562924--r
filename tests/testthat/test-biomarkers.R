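test_that("global masks are 9 orthonormal tensor polynomials", {
  g <- timeFrequencyGrid()  # 13 loops x 50 frequencies
  masks <- buildGlobalMasks(g)
  expect_length(masks, 9L)

  # order-(0,0) mask is constant over the grid
  w00 <- masks[["glob.t0f0"]]$weights
  expect_equal(max(w00) - min(w00), 0)

  # Gram matrix is the identity under the grid inner product
  G <- outer(seq_along(masks), seq_along(masks),
             Vectorize(function(i, j)
               sum(masks[[i]]$weights * masks[[j]]$weights)))
  expect_lt(max(abs(G - diag(9))), 1e-6)

  expect_error(buildGlobalMasks(timeFrequencyGrid(postDoseLoops = 2L)),
               ">= 3")
})

test_that("local masks are band-disjoint with zero-sum odd time order", {
  g <- timeFrequencyGrid()
  masks <- buildLocalMasks(g)
  expect_length(masks, 9L)

  # masks from different bands are orthogonal (disjoint support)
  bands <- vapply(masks, function(m) m$band, character(1L))
  for (i in 1:8) for (j in (i + 1):9)
    if (bands[i] != bands[j])
      expect_equal(sum(masks[[i]]$weights * masks[[j]]$weights), 0)

  # order-1 time mask columns sum to zero over loops
  w1 <- masks[["loc.low.t1"]]$weights
  expect_lt(max(abs(colSums(w1))), 1e-12)

  expect_error(buildLocalMasks(g, c(0.01, 0.1, 0.05, 10)),
               "increasing")
})

test_that("projection is the grid inner product and is linear", {
  g <- timeFrequencyGrid()
  masks <- c(buildGlobalMasks(g), buildLocalMasks(g))
  nP <- postDoseLoops(g); nF <- length(frequencies(g))

  expect_equal(projectSpectrogram(matrix(0, nP, nF), masks),
               setNames(rep(0, 18), names(masks)))

  # constant spectrogram: only order-0-in-both masks respond
  pc <- projectSpectrogram(matrix(2, nP, nF), masks)
  zeroOrders <- c("glob.t0f0", "loc.low.t0", "loc.mid.t0", "loc.high.t0")
  expect_true(all(abs(pc[setdiff(names(pc), zeroOrders)]) < 1e-10))
  expect_true(all(abs(pc[zeroOrders]) > 1e-8))

  # linear time ramp against a brute-force double sum
  ramp <- matrix(rep(seq_len(nP), nF), nP, nF)
  m <- masks[["glob.t1f0"]]
  brute <- 0
  for (t in seq_len(nP)) for (w in seq_len(nF))
    brute <- brute + m$weights[t, w] * ramp[t, w]
  expect_equal(projectSpectrogram(ramp, masks)[["glob.t1f0"]], brute)

  # linearity on random spectrograms
  set.seed(21)
  D1 <- matrix(rnorm(nP * nF), nP, nF)
  D2 <- matrix(rnorm(nP * nF), nP, nF)
  expect_equal(projectSpectrogram(2.5 * D1 - 3 * D2, masks),
               2.5 * projectSpectrogram(D1, masks) -
                 3 * projectSpectrogram(D2, masks))

  expect_error(projectSpectrogram(matrix(0, 2, 2), masks), "dimensions")
})

test_that("precondition fits recover the generating spectral parameters", {
  g <- timeFrequencyGrid()
  f <- frequencies(g)
  p <- phenotypeParams(A = 100, kneeHz = 0.3, slope = 1.6, nyFloor = 1)
  fit <- fitPreconditions(baselineDopplerSpectrum(p, g), f)
  expect_true(all(fit$converged))
  expect_lt(abs(fit$values[["KNEE"]] - 0.3) / 0.3, 0.05)
  expect_lt(abs(fit$values[["S"]] - 1.6) / 1.6, 0.05)
  # for this model the half-width equals the knee frequency
  expect_equal(fit$values[["HW"]], fit$values[["KNEE"]])

  # DR = log10((A + NY) / NY) = 2 for A = 99 NY
  p2 <- phenotypeParams(A = 99, nyFloor = 1)
  fit2 <- fitPreconditions(baselineDopplerSpectrum(p2, g), f)
  expect_equal(fit2$values[["DR"]], 2, tolerance = 0.01)

  expect_error(fitPreconditions(c(-1, 1, 1), f[1:3]), "positive")
})

test_that("precondition recovery is accurate over random parameter draws", {
  g <- timeFrequencyGrid()
  f <- frequencies(g)
  set.seed(33)
  relErr <- replicate(100, {
    A <- runif(1, 20, 500); K <- runif(1, 0.05, 2)
    s <- runif(1, 0.8, 3); NY <- runif(1, 0.2, 5)
    sp <- A / (1 + (f / K)^s) + NY
    v <- fitPreconditions(sp, f)$values
    c(abs(v[["KNEE"]] - K) / K, abs(v[["S"]] - s) / s)
  })
  expect_lt(median(relErr[1, ]), 0.01)
  expect_lt(median(relErr[2, ]), 0.01)
})

test_that("precondition deltas use the documented ratio/difference conventions", {
  g <- timeFrequencyGrid()
  f <- frequencies(g)
  p <- phenotypeParams()
  pre <- fitPreconditions(baselineDopplerSpectrum(p, g), f,
                          nsd = 0.5, bsb = 1000, ncnt = 300)
  expect_equal(as.numeric(preconditionDeltas(pre, pre)), rep(0, 9))

  # halved knee -> log10(0.5)
  pHalf <- phenotypeParams(kneeHz = 0.15)
  post <- fitPreconditions(baselineDopplerSpectrum(pHalf, g), f,
                           nsd = 0.5, bsb = 1000, ncnt = 300)
  d <- preconditionDeltas(pre, post)
  expect_equal(d[["dKNEE"]], log10(0.5), tolerance = 1e-3)

  # unfit precondition imputes 0 with a flag
  broken <- pre
  broken$values[["KNEE"]] <- NA_real_
  broken$converged[["KNEE"]] <- FALSE
  d2 <- preconditionDeltas(broken, post)
  expect_equal(d2[["dKNEE"]], 0)
  expect_true(attr(d2, "imputed")[["dKNEE"]])
})

test_that("feature vectors assemble to the fixed 81-element layout", {
  block <- setNames(rnorm(27), c(sprintf("glob.t%df%d",
                                         rep(0:2, each = 3), rep(0:2, 3)),
                                 sprintf("loc.%s.t%d",
                                         rep(c("low", "mid", "high"),
                                             each = 3), rep(0:2, 3)),
                                 paste0("pre.d", c("NSD", "BSB", "NCNT",
                                                   "DR", "NY", "KNEE",
                                                   "HW", "S", "SF"))))
  blocks <- list(carboplatin = block, paclitaxel = block,
                 combination = block)
  fv <- assembleFeatureVector(blocks, "P1", +1)
  expect_length(fv$values, 81L)
  expect_equal(sum(startsWith(names(fv$values), "carb.")), 27L)
  # fixed block order: carboplatin, paclitaxel, combination
  expect_true(startsWith(names(fv$values)[1L], "carb."))
  expect_true(startsWith(names(fv$values)[81L], "combo."))

  expect_error(assembleFeatureVector(blocks[1:2], "P1"), "missing")
  expect_error(assembleFeatureVector(
    list(carboplatin = block[1:5], paclitaxel = block,
         combination = block), "P1"), "27")
})

test_that("Doppler conversion matches the backscattering relation", {
  # 1 micron/s at 840 nm, n = 1.33 -> ~3 Hz to one significant figure
  f1 <- dopplerShift(1e-6)
  expect_equal(f1, 2 * 1.33 * 1e-6 / 840e-9)
  expect_equal(signif(f1, 1), 3)

  # Nyquist band: 12.5 Hz -> ~4 microns/s
  expect_equal(signif(dopplerSpeed(12.5) * 1e6, 1), 4)
  # 1 Hz band edge -> ~300 nm/s
  expect_equal(signif(dopplerSpeed(1) * 1e9, 1), 300)

  # exact inverse round trip
  v <- c(0, 1e-7, 3.3e-6)
  expect_equal(dopplerSpeed(dopplerShift(v)), v)
  expect_error(dopplerShift(-1), "non-negative")
})
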