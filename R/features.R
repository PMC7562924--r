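.treatmentPrefix <- c(carboplatin = "carb", paclitaxel = "tax",
                      combination = "combo")

#' Assemble the 81-element patient feature vector
#'
#' Concatenates the three per-drug blocks of 27 drug-response features
#' (18 spectrogram projections + 9 precondition deltas) in the fixed order
#' carboplatin, paclitaxel, combination. Blocks must be supplied as a named
#' list keyed by treatment; the vehicle control is consumed earlier by
#' spectrogram subtraction and is not a block.
#'
#' @param blocks named list with elements `carboplatin`, `paclitaxel`,
#'   `combination`, each a numeric vector of length 27.
#' @param patientId patient identifier.
#' @param label clinical label, +1 sensitive or -1 resistant.
#' @param cohortTag `"training"`, `"metastatic"` or `"test"`.
#' @return named list with `patientId`, `label`, `cohortTag` and `values`
#'   (named numeric of length 81, names prefixed `carb.`, `tax.`,
#'   `combo.`).
#' @export
assembleFeatureVector <- function(blocks, patientId, label = NA_real_,
                                  cohortTag = "training") {
  need <- names(.treatmentPrefix)
  if (!all(need %in% names(blocks)))
    stop("blocks must be named by treatment: ",
         paste(setdiff(need, names(blocks)), collapse = ", "),
         " missing")
  values <- unlist(lapply(need, function(tr) {
    b <- blocks[[tr]]
    if (length(b) != 27L)
      stop(sprintf("block '%s' must have 27 features, got %d",
                   tr, length(b)))
    stats::setNames(b, paste(.treatmentPrefix[[tr]], names(b), sep = "."))
  }))
  stopifnot(length(values) == 81L)
  list(patientId = patientId, label = label, cohortTag = cohortTag,
       values = values)
}

# DQ-weighted mean helper
.wmean <- function(x, w) sum(x * w) / sum(w)

#' Extract per-patient biomarker feature vectors from a cohort
#'
#' Runs the full spectrogram-to-feature pipeline: per-well data-quality
#' assessment (with the cohort median activity as low-activity reference),
#' per-well drug-response spectrograms, DQ-weighted replicate averaging per
#' treatment, optional vehicle-control subtraction, projection onto the 9
#' global and 9 local filter masks, and precondition deltas from the fitted
#' baseline and endpoint spectra. Precondition fits use the un-subtracted
#' treatment average so that spectral-shape parameters remain physical.
#'
#' @param cohort a [WellCohort-class].
#' @param config a [bdiConfig()] list.
#' @return data.frame with columns `patientId`, `clinicalLabel`,
#'   `phenotype`, `cohortTag` and the 81 named feature columns.
#' @export
#' @examples
#' co <- simulateCohort(assayDesign(2, 2, 0,
#'         wellsPerTreatment = c(control = 2, carboplatin = 2,
#'                               paclitaxel = 2, combination = 2)))
#' ft <- extractFeatures(co)
#' dim(ft)
extractFeatures <- function(cohort, config = bdiConfig()) {
  stopifnot(is(cohort, "WellCohort"))
  g <- cohort@grid
  man <- cohort@manifest
  masks <- c(buildGlobalMasks(g), buildLocalMasks(g, config$bandEdges))

  activity <- vapply(cohort@wells, .wellActivity, numeric(1L))
  thr <- dqThresholds(config$brightnessJumpRatio, config$lowActivityFrac,
                      activityReference = stats::median(activity))

  patientWells <- split(cohort@wells,
                        vapply(cohort@wells, function(w) w@patientId,
                               character(1L)))
  rows <- vector("list", nrow(man))
  for (p in seq_len(nrow(man))) {
    pid <- man$patientId[p]
    pw <- patientWells[[pid]]
    byTr <- split(pw, vapply(pw, treatment, character(1L)))

    avg <- list()
    for (tr in names(byTr)) {
      dqs <- vapply(byTr[[tr]],
                    function(w) assessDataQuality(w, thr)$dq, numeric(1L))
      spgms <- Map(function(w, q) drugResponseSpectrogram(w, dq = q),
                   byTr[[tr]], dqs)
      avg[[tr]] <- weightedAverageSpectrograms(spgms, dqs)
    }
    ctrl <- avg[["control"]]

    blocks <- list()
    for (tr in names(.treatmentPrefix)) {
      if (is.null(avg[[tr]]))
        stop(sprintf("patient %s has no '%s' wells", pid, tr))
      raw <- avg[[tr]]
      spgm <- if (config$dmsoSubtract)
        subtractControl(raw, ctrl) else raw
      proj <- projectSpectrogram(spgm, masks)

      trWells <- byTr[[tr]]
      dqs <- vapply(trWells,
                    function(w) assessDataQuality(w, thr)$dq, numeric(1L))
      nsdPre <- .wmean(vapply(trWells, function(w) w@meta$nsdPre,
                              numeric(1L)), dqs)
      nsdPost <- .wmean(vapply(trWells, function(w) w@meta$nsdPost,
                               numeric(1L)), dqs)
      ncnt <- .wmean(vapply(trWells, function(w) w@meta$ncnt,
                            numeric(1L)), dqs)
      dl <- doseLoop(g)
      bsbPre <- .wmean(vapply(trWells, function(w)
        mean(w@brightness[(dl - 3L):dl]), numeric(1L)), dqs)
      bsbPost <- .wmean(vapply(trWells, function(w)
        w@brightness[nLoops(g)], numeric(1L)), dqs)

      endpoint <- raw@baseline * 10^raw@D[nrow(raw@D), ]
      pre <- fitPreconditions(raw@baseline, frequencies(g),
                              nsd = nsdPre, bsb = bsbPre, ncnt = ncnt)
      post <- fitPreconditions(endpoint, frequencies(g),
                               nsd = nsdPost, bsb = bsbPost, ncnt = ncnt)
      deltas <- preconditionDeltas(pre, post)
      blocks[[tr]] <- c(proj, stats::setNames(as.numeric(deltas),
                                              paste0("pre.", names(deltas))))
    }
    fv <- assembleFeatureVector(blocks, pid, man$clinicalLabel[p],
                                man$cohortTag[p])
    rows[[p]] <- fv$values
  }
  out <- data.frame(patientId = man$patientId,
                    clinicalLabel = man$clinicalLabel,
                    phenotype = man$phenotype,
                    cohortTag = man$cohortTag,
                    stringsAsFactors = FALSE)
  cbind(out, do.call(rbind, rows))
}

#' Names of the spectrogram-projection feature columns
#'
#' @param featureTable a feature table from [extractFeatures()].
#' @return character vector of the 54 spectrogram-based column names (18
#'   per drug), in block order.
#' @export
spectrogramFeatureNames <- function(featureTable) {
  nm <- names(featureTable)
  nm[grepl("^(carb|tax|combo)\\.(glob|loc)\\.", nm)]
}
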