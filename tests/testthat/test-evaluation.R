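test_that("mixture PDF matches the normal density and integrates to one", {
  m <- mixturePdf(0.5, 0.1)
  expect_equal(m$density(0.5), 1 / (0.1 * sqrt(2 * pi)))
  expect_equal(stats::integrate(m$density, -3, 3,
                                rel.tol = 1e-10)$value, 1,
               tolerance = 1e-6)

  # two identical components equal one component everywhere
  m2 <- mixturePdf(c(0.5, 0.5), c(0.1, 0.1))
  x <- seq(-2, 2, length.out = 101)
  expect_equal(m2$density(x), m$density(x))

  # the sigma floor prevents delta components
  mf <- mixturePdf(c(0, 1), c(0, 0))
  expect_true(all(mf$sigma == 0.02))
  expect_error(mixturePdf(numeric(0)), "at least one")
})

test_that("mixture ROC covers the degenerate and separated limits", {
  mA <- mixturePdf(c(-0.1, 0.1), c(0.2, 0.2))
  same <- rocFromMixture(mA, mA)
  expect_equal(same$auc, 0.5, tolerance = 1e-6)

  far <- rocFromMixture(mixturePdf(-0.9, 0.02), mixturePdf(0.9, 0.02))
  expect_equal(far$auc, 1, tolerance = 1e-6)

  # translation invariance of the AUC
  mR <- mixturePdf(c(-0.5, -0.3), c(0.1, 0.15))
  mS <- mixturePdf(c(0.2, 0.6), c(0.1, 0.2))
  aucShift <- rocFromMixture(
    mixturePdf(mR$mu + 0.4, mR$sigma),
    mixturePdf(mS$mu + 0.4, mS$sigma),
    thresholds = seq(-3.5, 3.5, length.out = 2401))$auc
  expect_equal(rocFromMixture(mR, mS)$auc, aucShift, tolerance = 1e-4)

  # curves are monotone in the threshold
  roc <- rocFromMixture(mR, mS)
  expect_true(all(diff(roc$sensitivity) >= 0))
  expect_true(all(diff(roc$specificity) <= 0))
})

test_that("mixture AUC agrees with a Monte-Carlo oracle", {
  set.seed(90)
  mR <- mixturePdf(rnorm(8, -0.5, 0.3), runif(8, 0.02, 0.3))
  mS <- mixturePdf(rnorm(8, 0.5, 0.3), runif(8, 0.02, 0.3))
  auc <- rocFromMixture(mR, mS,
                        thresholds = seq(-6, 6, length.out = 4801))$auc
  nMc <- 1e6
  drawMix <- function(m, n) {
    i <- sample.int(length(m$mu), n, replace = TRUE)
    rnorm(n, m$mu[i], m$sigma[i])
  }
  # AUC = P(resistant draw < sensitive draw)
  aucMc <- mean(drawMix(mR, nMc) < drawMix(mS, nMc))
  expect_lt(abs(auc - aucMc), 0.01)
})

test_that("decision metrics implement the clinical formulas", {
  # engineered mixtures with known masses at threshold 0:
  # sens = 0.9 (R mass below 0), spec = 0.8
  mR <- mixturePdf(qnorm(0.9, lower.tail = FALSE) * -0.1 / 1, 0.1)
  # component with P(X < 0) = 0.9: mu = -0.1 * qnorm(0.9)... build directly
  mR <- mixturePdf(-0.1 * qnorm(0.9), 0.1)
  expect_equal(mR$cdf(0), 0.9)
  mS <- mixturePdf(0.2 * qnorm(0.8), 0.2)
  m <- decisionMetrics(mR, mS, nR = 10, nS = 10, threshold = 0)
  expect_equal(m$sensitivity, 0.9)
  expect_equal(m$specificity, 0.8)
  expect_equal(m$plr, 4.5)
  expect_equal(m$nlr, 0.125)
  expect_equal(m$accuracy, 0.85)
  expect_equal(m$ppv, 0.9 * 10 / (0.9 * 10 + 0.2 * 10))

  # a representative clinical operating point: sens 93%, spec 89% -> NLR ~ 0.08
  mR2 <- mixturePdf(-0.1 * qnorm(0.93), 0.1)
  mS2 <- mixturePdf(0.1 * qnorm(0.89), 0.1)
  m2 <- decisionMetrics(mR2, mS2, 10, 10, 0)
  expect_equal(m2$nlr, (1 - 0.93) / 0.89, tolerance = 1e-10)
  expect_equal(round(m2$nlr, 2), 0.08)

  # perfect separation
  m3 <- decisionMetrics(mixturePdf(-1, 0.01), mixturePdf(1, 0.01), 5, 5, 0)
  expect_equal(m3$accuracy, 1, tolerance = 1e-9)
  expect_equal(m3$nlr, 0, tolerance = 1e-9)
  expect_equal(m3$plr, Inf)
})

test_that("mean separation recovers a designed class gap within its error", {
  expect_equal(meanSeparation(c(-1, -1), c(1, 1))$separation, 2)
  expect_equal(meanSeparation(c(0.3, 0.3), c(0.3, 0.3))$separation, 0)

  # designed separation 0.8 with n = 10 per class
  set.seed(95)
  mR <- rnorm(10, -0.4, 0.1); mS <- rnorm(10, +0.4, 0.1)
  ms <- meanSeparation(mR, mS, rep(0.05, 10), rep(0.05, 10))
  expect_lt(abs(ms$separation - 0.8), 3 * ms$se)
  expect_equal(diff(ms$ci), 2 * 1.96 * ms$se)
  expect_true(meanSeparation(-0.5, c(0.4, 0.6))$singleClassFlag)
})

test_that("LOOCV covers every patient, keeps metastatic data out of training, and is seeded", {
  co <- tinyCohort(seed = 3L)
  ft <- extractFeatures(co)
  cfg <- tinyCohortConfig()
  preds <- suppressWarnings(loocv(ft, cfg, seed = 21L))
  expect_equal(nrow(preds), nrow(ft))
  expect_setequal(preds$patientId, ft$patientId)
  expect_true(all(abs(preds[, c("P_logistic", "P_rnn", "P_loglik",
                                "P_network")]) <= 1))

  # metastatic feature perturbation cannot change training patients'
  # predictions (metastatic rows are never in a fold's training set)
  ft2 <- ft
  metRow <- which(ft2$cohortTag == "metastatic")
  featCols <- spectrogramFeatureNames(ft2)
  ft2[metRow, featCols] <- ft2[metRow, featCols] * 2 + 5
  preds2 <- suppressWarnings(loocv(ft2, cfg, seed = 21L))
  trRows <- preds$cohortTag == "training"
  expect_equal(preds2$P[trRows], preds$P[trRows])

  # determinism under the seed
  preds3 <- suppressWarnings(loocv(ft, cfg, seed = 21L))
  expect_identical(preds3, preds)
})

test_that("evaluation report assigns metastatic specimens to the R-class", {
  co <- tinyCohort(seed = 3L)
  ft <- extractFeatures(co)
  preds <- suppressWarnings(loocv(ft, tinyCohortConfig(), seed = 22L))
  rep <- evaluatePredictions(preds)
  expect_true(rep$auc >= 0 && rep$auc <= 1)
  expect_equal(rep$n_metastatic, 1L)
  expect_named(rep$thresholds, c("fixed", "optimal"))
  expect_equal(rep$thresholds$fixed$threshold, 0)
  # Youden threshold is at least as good as the fixed one
  youden <- function(m) m$sensitivity + m$specificity
  expect_gte(youden(rep$thresholds$optimal) + 1e-9,
             youden(rep$thresholds$fixed))
})
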