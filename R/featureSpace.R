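#' z-factor class separation of a score vector
#'
#' Signal-to-noise separation statistic of a feature between the resistant
#' (-1) and sensitive (+1) classes: the difference of class means divided
#' by the root sum of the class sample variances,
#' `z = (mean_R - mean_S) / sqrt(var_R + var_S)`.
#'
#' @param x numeric scores.
#' @param labels class labels in -1/+1 with at least 2 members per class.
#' @return numeric z-factor.
#' @export
#' @examples
#' zFactor(c(1, 1, 3, 3, -1, -1, -3, -3), c(-1, -1, -1, -1, 1, 1, 1, 1))
zFactor <- function(x, labels) {
  r <- x[labels == -1]
  s <- x[labels == +1]
  if (length(r) < 2L || length(s) < 2L)
    stop("z-factor requires at least 2 members per class")
  (mean(r) - mean(s)) / sqrt(stats::var(r) + stats::var(s))
}

# column standardization frozen on training rows; zero-variance columns are
# excluded from scaling (divisor 1) and flagged
.standardizer <- function(Xtrain) {
  mu <- colMeans(Xtrain)
  sd <- apply(Xtrain, 2L, stats::sd)
  zeroVar <- !is.finite(sd) | sd == 0
  sd[zeroVar] <- 1
  list(mu = mu, sd = sd, zeroVar = zeroVar)
}

.applyStandardizer <- function(X, st)
  sweep(sweep(X, 2L, st$mu), 2L, st$sd, `/`)

#' SVD orthogonalization of a spectrogram-biomarker block
#'
#' Z-scores the columns over the training rows, decomposes the training
#' matrix by singular value decomposition and returns orthonormal loadings
#' (descending singular value) plus the scores of all rows in the frozen
#' standardization. The sign of each component is fixed so that its
#' largest-magnitude loading element is positive.
#'
#' @param X numeric matrix, patients x biomarkers.
#' @param trainRows logical or integer index of training rows (standardization
#'   and decomposition use only these).
#' @return list with `loadings` (biomarkers x components, orthonormal),
#'   `d` (singular values), `scores` (all rows x components),
#'   `standardizer`.
#' @export
svdTransform <- function(X, trainRows = seq_len(nrow(X))) {
  Xtr <- X[trainRows, , drop = FALSE]
  if (nrow(Xtr) < 2L) stop("need at least 2 training patients")
  st <- .standardizer(Xtr)
  Ztr <- .applyStandardizer(Xtr, st)
  sv <- svd(Ztr)
  V <- sv$v
  for (j in seq_len(ncol(V))) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  Zall <- .applyStandardizer(X, st)
  list(loadings = V, d = sv$d, scores = Zall %*% V, standardizer = st)
}

.svdSuffix <- c(carboplatin = "carb", paclitaxel = "tax",
                combination = "tax+carb")

#' Select the top orthogonal biomarkers by z-factor
#'
#' Per drug treatment, orthogonalizes the 18 spectrogram-based biomarkers by
#' SVD over the training patients, ranks every component of every treatment
#' by the magnitude of its z-factor between the resistant and sensitive
#' training classes, and keeps the top `nSelect`. Metastatic and test
#' patients never enter the standardization, the decomposition or the
#' z-factors; their scores are computed in the frozen training frame.
#'
#' @param featureTable feature table from [extractFeatures()].
#' @param nSelect number of components to keep (default 5).
#' @return list with `scores` (all patients x nSelect, rownames patient
#'   ids), `selected` (data.frame: component name e.g. `BM3carb`,
#'   treatment, component index, z-factor), `models` (per-treatment
#'   [svdTransform()] fits), `zTable` (all components and z-factors).
#' @export
selectBiomarkers <- function(featureTable, nSelect = 5L) {
  train <- featureTable$cohortTag == "training"
  if (sum(train) < 4L)
    stop("need at least 4 training patients")
  labels <- featureTable$clinicalLabel[train]

  models <- list()
  zRows <- list()
  scoreCols <- list()
  for (tr in names(.treatmentPrefix)) {
    cols <- grep(sprintf("^%s\\.(glob|loc)\\.", .treatmentPrefix[[tr]]),
                 names(featureTable), value = TRUE)
    X <- as.matrix(featureTable[, cols])
    m <- svdTransform(X, trainRows = which(train))
    models[[tr]] <- m
    for (j in seq_len(ncol(m$scores))) {
      nm <- sprintf("BM%d%s", j, .svdSuffix[[tr]])
      zRows[[nm]] <- data.frame(component = nm, treatment = tr, index = j,
                                z = zFactor(m$scores[train, j], labels),
                                stringsAsFactors = FALSE)
      scoreCols[[nm]] <- m$scores[, j]
    }
  }
  zTable <- do.call(rbind, zRows)
  rownames(zTable) <- NULL
  if (nSelect > nrow(zTable))
    stop("nSelect exceeds the number of available components")
  # stable tie-break: treatments in block order, then component index
  ord <- order(-abs(zTable$z),
               match(zTable$treatment, names(.treatmentPrefix)),
               zTable$index)
  sel <- zTable[ord[seq_len(nSelect)], ]
  scores <- do.call(cbind, scoreCols[sel$component])
  colnames(scores) <- sel$component
  rownames(scores) <- featureTable$patientId
  list(scores = scores, selected = sel, models = models, zTable = zTable)
}
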