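#' Leave-one-out cross-validated ensemble predictions
#'
#' Predicts each training patient with an ensemble trained on all other
#' training patients, refitting the column standardization, the SVD
#' orthogonalization and the z-factor biomarker selection inside every
#' fold. Metastatic and test patients are predicted by the model trained on
#' the full training cohort and never appear in any training fold or in
#' feature selection.
#'
#' @param featureTable feature table from [extractFeatures()].
#' @param config a [bdiConfig()] list (uses `nSelect`, `k`, `lambda`,
#'   `subsetResamples`).
#' @param seed integer seed driving the Gibbs sampler and subset
#'   resampling; each fold gets its own derived substream.
#' @return data.frame with one row per patient: `patientId`, `cohortTag`,
#'   `label`, the four per-classifier predictions, ensemble `P` and `se`.
#' @export
loocv <- function(featureTable, config = bdiConfig(), seed = 1L) {
  trainIdx <- which(featureTable$cohortTag == "training")
  if (length(unique(featureTable$clinicalLabel[trainIdx])) < 2L)
    stop("training cohort must contain both classes")
  holdIdx <- which(featureTable$cohortTag != "training")

  set.seed(seed)
  foldSeeds <- sample.int(.Machine$integer.max,
                          length(trainIdx) + length(holdIdx))

  predictOne <- function(i, foldTrainIdx, foldSeed) {
    foldTable <- featureTable
    foldTable$cohortTag[-foldTrainIdx] <- "heldout"
    labels <- foldTable$clinicalLabel[foldTrainIdx]
    if (length(unique(labels)) < 2L) {
      warning(sprintf("fold for %s has a single class; skipped",
                      featureTable$patientId[i]))
      return(NULL)
    }
    sel <- selectBiomarkers(foldTable, nSelect = config$nSelect)
    trainX <- sel$scores[foldTrainIdx, , drop = FALSE]
    fTest <- sel$scores[i, ]
    set.seed(foldSeed)
    ens <- ensemblePredict(trainX, labels, fTest, k = config$k,
                           lambda = config$lambda,
                           resamples = config$subsetResamples)
    data.frame(patientId = featureTable$patientId[i],
               cohortTag = featureTable$cohortTag[i],
               label = featureTable$clinicalLabel[i],
               P_logistic = ens$perClassifier[["logistic"]],
               P_rnn = ens$perClassifier[["rnn"]],
               P_loglik = ens$perClassifier[["loglik"]],
               P_network = ens$perClassifier[["network"]],
               P = ens$P, se = ens$se,
               stringsAsFactors = FALSE)
  }

  out <- list()
  for (j in seq_along(trainIdx)) {
    i <- trainIdx[j]
    out[[length(out) + 1L]] <-
      predictOne(i, setdiff(trainIdx, i), foldSeeds[j])
  }
  for (j in seq_along(holdIdx)) {
    i <- holdIdx[j]
    out[[length(out) + 1L]] <-
      predictOne(i, trainIdx, foldSeeds[length(trainIdx) + j])
  }
  do.call(rbind, out)
}

#' Equal-weight Gaussian mixture over patient predictions
#'
#' One Gaussian component per patient with that patient's ensemble mean
#' and standard error; standard errors are floored so that exactly
#' agreeing classifiers do not produce delta functions.
#'
#' @param means per-patient ensemble means.
#' @param ses per-patient standard errors.
#' @param sigmaFloor minimum component standard deviation (default 0.02).
#' @return object of class `MixturePDF` with fields `mu`, `sigma` and
#'   closures `density(x)` and `cdf(x)`.
#' @export
mixturePdf <- function(means, ses = rep(0, length(means)),
                       sigmaFloor = 0.02) {
  if (!length(means)) stop("mixture requires at least one prediction")
  stopifnot(length(ses) == length(means), sigmaFloor > 0)
  mu <- as.numeric(means)
  sigma <- pmax(as.numeric(ses), sigmaFloor)
  mixEval <- function(x, fn) {
    acc <- numeric(length(x))
    for (i in seq_along(mu)) acc <- acc + fn(x, mu[i], sigma[i])
    acc / length(mu)
  }
  density <- function(x) mixEval(x, stats::dnorm)
  cdf <- function(x) mixEval(x, stats::pnorm)
  structure(list(mu = mu, sigma = sigma, density = density, cdf = cdf),
            class = "MixturePDF")
}

#' ROC curve from class mixture PDFs
#'
#' Sweeps a dense threshold grid over the continuous class PDFs. The
#' resistant class (R-class) is the "positive" class and lies at negative
#' predicted chemosensitivity, so sensitivity at threshold `t` is the
#' R-mixture mass below `t` and specificity is the S-mixture mass above
#' `t`. The AUC is the trapezoidal integral of sensitivity against false
#' positive rate.
#'
#' @param mixR,mixS [mixturePdf()] objects for the R- and S-class.
#' @param thresholds threshold grid (default 1201 points on [-3, 3]).
#' @return list with `thresholds`, `sensitivity`, `specificity`, `auc`.
#' @export
rocFromMixture <- function(mixR, mixS,
                           thresholds = seq(-3, 3, length.out = 1201L)) {
  sens <- mixR$cdf(thresholds)
  spec <- 1 - mixS$cdf(thresholds)
  fpr <- 1 - spec
  auc <- sum(diff(fpr) * (sens[-1L] + sens[-length(sens)]) / 2)
  list(thresholds = thresholds, sensitivity = sens, specificity = spec,
       auc = auc)
}

#' Clinical decision metrics at a threshold
#'
#' Sensitivity and specificity are the continuous mixture masses on the
#' correct side of the threshold; accuracy, likelihood ratios and
#' predictive values follow the standard definitions with prevalence taken
#' from the cohort class counts. A specificity of 1 reports an infinite
#' positive likelihood ratio.
#'
#' @param mixR,mixS [mixturePdf()] objects.
#' @param nR,nS class sizes.
#' @param threshold decision threshold (R-class below).
#' @return named list: `threshold`, `sensitivity`, `specificity`,
#'   `accuracy`, `plr`, `nlr`, `ppv`, `npv`.
#' @export
decisionMetrics <- function(mixR, mixS, nR, nS, threshold = 0) {
  sens <- mixR$cdf(threshold)
  spec <- 1 - mixS$cdf(threshold)
  acc <- (sens * nR + spec * nS) / (nR + nS)
  plr <- if (spec == 1) Inf else sens / (1 - spec)
  nlr <- if (spec == 0) Inf else (1 - sens) / spec
  ppv <- sens * nR / (sens * nR + (1 - spec) * nS)
  npv <- spec * nS / (spec * nS + (1 - sens) * nR)
  list(threshold = threshold, sensitivity = sens, specificity = spec,
       accuracy = acc, plr = plr, nlr = nlr, ppv = ppv, npv = npv)
}

#' Youden-optimal decision threshold
#'
#' @param mixR,mixS [mixturePdf()] objects.
#' @param thresholds candidate grid.
#' @return threshold maximizing sensitivity + specificity.
#' @export
optimalThreshold <- function(mixR, mixS,
                             thresholds = seq(-3, 3, length.out = 1201L)) {
  youden <- mixR$cdf(thresholds) + 1 - mixS$cdf(thresholds)
  thresholds[which.max(youden)]
}

#' Mean class separation with confidence interval
#'
#' Difference of the S-class and R-class mean predicted chemosensitivities
#' with a Gaussian 95% interval. Each class-mean standard error combines
#' the between-patient variance with the per-patient ensemble standard
#' errors: `se_c^2 = var(mu_i) / n + sum(se_i^2) / n^2`. For a
#' single-patient class the between-patient term is unavailable and the
#' per-patient term alone is used (flagged).
#'
#' @param meansR,sesR R-class per-patient means and standard errors.
#' @param meansS,sesS S-class per-patient means and standard errors.
#' @return list with `separation`, `ci` (length-2), `se`, and
#'   `singleClassFlag`.
#' @export
meanSeparation <- function(meansR, meansS, sesR = rep(0, length(meansR)),
                           sesS = rep(0, length(meansS))) {
  if (!length(meansR) || !length(meansS))
    stop("both classes must be non-empty")
  classSe <- function(m, s) {
    n <- length(m)
    between <- if (n > 1L) stats::var(m) / n else 0
    sqrt(between + sum(s^2) / n^2)
  }
  seR <- classSe(meansR, sesR)
  seS <- classSe(meansS, sesS)
  sep <- mean(meansS) - mean(meansR)
  se <- sqrt(seR^2 + seS^2)
  list(separation = sep, ci = sep + c(-1, 1) * 1.96 * se, se = se,
       singleClassFlag = length(meansR) == 1L || length(meansS) == 1L)
}

#' Evaluate ensemble predictions: ROC, decision points, separation
#'
#' Assigns each patient to the R-class (resistant training patients and
#' all metastatic specimens) or S-class (sensitive non-metastatic), builds
#' the per-class Gaussian mixtures, and reports the mixture ROC, the
#' fixed-zero and Youden-optimal decision metrics, the mean class
#' separation, the discrete LOOCV accuracy over training patients
#' (sign of the ensemble mean against the clinical label) and the count of
#' metastatic specimens assigned to the R-class at the zero threshold.
#'
#' @param preds prediction table from [loocv()].
#' @param sigmaFloor mixture component floor (default 0.02).
#' @return report list (see Details) suitable for JSON serialization.
#' @export
evaluatePredictions <- function(preds, sigmaFloor = 0.02) {
  rClass <- preds$cohortTag == "metastatic" | preds$label == -1
  if (!any(rClass) || all(rClass))
    stop("both classes required")
  mixR <- mixturePdf(preds$P[rClass], preds$se[rClass], sigmaFloor)
  mixS <- mixturePdf(preds$P[!rClass], preds$se[!rClass], sigmaFloor)
  roc <- rocFromMixture(mixR, mixS)
  thrOpt <- optimalThreshold(mixR, mixS)
  nR <- sum(rClass); nS <- sum(!rClass)

  train <- preds$cohortTag == "training"
  loocvAccuracy <- mean(sign(preds$P[train]) == preds$label[train])
  met <- preds$cohortTag == "metastatic"
  sep <- meanSeparation(preds$P[rClass], preds$P[!rClass],
                        preds$se[rClass], preds$se[!rClass])

  list(auc = roc$auc,
       thresholds = list(
         fixed = decisionMetrics(mixR, mixS, nR, nS, 0),
         optimal = decisionMetrics(mixR, mixS, nR, nS, thrOpt)),
       mean_separation = sep$separation,
       ci = sep$ci,
       loocv_accuracy = loocvAccuracy,
       n_metastatic = sum(met),
       metastatic_r_class = sum(preds$P[met] < 0),
       per_patient = preds,
       roc = roc)
}
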