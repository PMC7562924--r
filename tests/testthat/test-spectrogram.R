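test_that("power spectrum localizes a tone and respects Parseval and scaling", {
  g <- timeFrequencyGrid()
  fs <- 25; n <- 4096
  t <- (0:(n - 1)) / fs

  # single tone: spectral mass concentrated at the 1 Hz grid bin
  tone <- sin(2 * pi * 1 * t)
  psd <- powerSpectrum(tone, fs, g)
  f <- frequencies(g)
  expect_equal(f[which.max(psd)], 1, tolerance = 0.12)

  # white noise: integrated raw periodogram equals the variance (Parseval);
  # check via a flat-spectrum series on the grid's own binning
  set.seed(4)
  x <- rnorm(n)
  X <- fft(x - mean(x))
  half <- floor(n / 2)
  praw <- 2 * Mod(X[2:(half + 1)])^2 / n^2 * n / fs
  praw[half] <- praw[half] / 2
  df <- fs / n
  expect_equal(sum(praw) * df, mean((x - mean(x))^2), tolerance = 1e-10)

  # quadratic scaling
  expect_equal(powerSpectrum(3 * x, fs, g), 9 * powerSpectrum(x, fs, g))

  # degenerate inputs
  expect_error(powerSpectrum(numeric(1L), fs, g), "length")
  expect_equal(powerSpectrum(rep(2, 128), fs, g, floor = 0.5),
               rep(0.5, length(f)))
})

test_that("baseline average is the geometric mean of the last four pre-dose loops", {
  g <- timeFrequencyGrid()
  nF <- length(frequencies(g))
  base <- rep(10, nF)
  S <- matrix(rep(base, nLoops(g)), nLoops(g), nF, byrow = TRUE)
  expect_equal(baselineAverage(S, g), base)

  # two loops at S and two at 100 S -> geometric mean 10 S
  S2 <- S
  S2[3:4, ] <- 100 * S2[3:4, ]
  expect_equal(baselineAverage(S2, g), 10 * base)

  gShort <- timeFrequencyGrid(preDoseLoops = 3L)
  expect_error(baselineAverage(S[1:12, ], gShort), "4 pre-dose")
})

test_that("drug-response spectrogram implements the log10 ratio", {
  g <- timeFrequencyGrid()
  w <- noiselessWell("sensitive", "control", g)
  d <- drugResponseSpectrogram(w)
  expect_equal(max(abs(responseMatrix(d))), 0)

  wTen <- w
  post <- (doseLoop(g) + 1):nLoops(g)
  wTen@spectra[post, ] <- 10 * wTen@spectra[post, ]
  dTen <- drugResponseSpectrogram(wTen)
  expect_equal(responseMatrix(dTen),
               matrix(1, length(post), length(frequencies(g))))
})

test_that("spectrograms are gauge invariant under global rescaling of a well", {
  g <- timeFrequencyGrid()
  set.seed(8)
  for (rep in 1:5) {
    w <- simulateWell(phenotypeParams(), g, "resistant", "paclitaxel",
                      violationProbs = c())
    wScaled <- w
    c0 <- runif(1, 0.1, 50)
    wScaled@spectra <- c0 * w@spectra
    expect_equal(responseMatrix(drugResponseSpectrogram(wScaled)),
                 responseMatrix(drugResponseSpectrogram(w)))
  }
})

test_that("data quality halves per violation and detects brightness jumps", {
  g <- timeFrequencyGrid()
  w <- noiselessWell("sensitive", "control", g)
  expect_equal(assessDataQuality(w)$dq, 1)

  wj <- w
  wj@brightness[6L] <- wj@brightness[6L] * 2
  expect_equal(assessDataQuality(wj)$dq, 0.5)

  # injected flags count, and a detected duplicate is not double-counted
  wf <- wj
  wf@violations <- c("brightness_jump", "low_activity")
  expect_equal(assessDataQuality(wf)$dq, 0.25)
  wf3 <- wj
  wf3@violations <- c("low_activity", "speckle_decorrelation")
  expect_equal(assessDataQuality(wf3)$dq, 0.125)

  # low-activity criterion needs a cohort reference
  thr <- dqThresholds(activityReference = 1e9)
  expect_equal(assessDataQuality(w, thr)$dq, 0.5)
})

test_that("DQ-weighted averaging reduces to the arithmetic mean for equal weights", {
  g <- timeFrequencyGrid()
  set.seed(10)
  ws <- lapply(1:3, function(i)
    simulateWell(phenotypeParams(), g, "resistant", "carboplatin",
                 violationProbs = c()))
  ds <- lapply(ws, drugResponseSpectrogram)

  avgEq <- weightedAverageSpectrograms(ds, dqs = rep(0.5, 3))
  manual <- Reduce(`+`, lapply(ds, responseMatrix)) / 3
  expect_equal(responseMatrix(avgEq), manual)
  expect_equal(dataQuality(avgEq), 0.5)

  # vanishing weight removes a replicate's contribution
  avgDrop <- weightedAverageSpectrograms(ds, dqs = c(1, 1, 1e-12))
  avg2 <- weightedAverageSpectrograms(ds[1:2], dqs = c(1, 1))
  expect_equal(responseMatrix(avgDrop), responseMatrix(avg2),
               tolerance = 1e-9)

  expect_equal(responseMatrix(weightedAverageSpectrograms(ds[1])),
               responseMatrix(ds[[1]]))
  expect_error(weightedAverageSpectrograms(ds, dqs = c(0, 0, 0)),
               "usable")
})

test_that("control subtraction is exact and invertible", {
  g <- timeFrequencyGrid()
  set.seed(12)
  w1 <- simulateWell(phenotypeParams(), g, "resistant", "carboplatin",
                     violationProbs = c())
  wc <- simulateWell(phenotypeParams(), g, "resistant", "control",
                     violationProbs = c())
  d1 <- drugResponseSpectrogram(w1)
  dc <- drugResponseSpectrogram(wc)

  self <- subtractControl(dc, dc)
  expect_equal(max(abs(responseMatrix(self))), 0)

  sub <- subtractControl(d1, dc)
  back <- sub
  back@D <- sub@D + dc@D
  expect_equal(responseMatrix(back), responseMatrix(d1))
  expect_identical(treatment(sub), "carboplatin")

  expect_error(subtractControl(d1, NULL), "missing")
  expect_warning(out <- subtractControl(d1, NULL, missing = "passthrough"),
                 "missing")
  expect_equal(responseMatrix(out), responseMatrix(d1))
})
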