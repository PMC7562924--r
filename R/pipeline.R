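#' Run the full chemosensitivity pipeline
#'
#' Chains every stage from a single configuration and master seed:
#' synthetic cohort simulation, feature extraction, biomarker selection,
#' similarity network, leave-one-out ensemble classification and
#' Gaussian-mixture ROC evaluation. All randomness flows from the master
#' seed through named per-stage substreams, so identical seeds give
#' identical outputs. When `outDir` is given, every stage's artifacts are
#' written there (per-well spectra, feature table, selected biomarkers,
#' similarity matrix and edge list, predictions, `report.json`).
#'
#' @param config a [bdiConfig()] list.
#' @param seed master seed (default: the config seed).
#' @param outDir optional output directory.
#' @param writeSpectra also write the (large) per-well spectra table when
#'   `outDir` is given.
#' @return list with `cohort`, `features`, `selection`, `similarity`,
#'   `network`, `predictions` and `report`.
#' @export
#' @examples
#' cfg <- bdiConfig(nResistant = 3, nSensitive = 3, nMetastatic = 1,
#'                  wellsPerTreatment = c(control = 3, carboplatin = 3,
#'                                        paclitaxel = 3, combination = 3),
#'                  subsetResamples = 2)
#' \donttest{res <- runPipeline(cfg, seed = 1)}
runPipeline <- function(config = bdiConfig(), seed = config$seed,
                        outDir = NULL, writeSpectra = FALSE) {
  set.seed(seed)
  stageSeeds <- sample.int(.Machine$integer.max, 2L)

  grid <- timeFrequencyGrid(config$nFrequencies, config$freqMin,
                            config$nyquist, config$preDoseLoops,
                            config$postDoseLoops, config$loopPeriod)
  design <- assayDesign(config$nResistant, config$nSensitive,
                        config$nMetastatic, config$wellsPerTreatment,
                        seed = stageSeeds[1L])
  cohort <- simulateCohort(design, grid = grid)

  features <- extractFeatures(cohort, config)
  selection <- selectBiomarkers(features, nSelect = config$nSelect)

  groups <- ifelse(features$cohortTag == "metastatic", "metastatic",
                   ifelse(features$clinicalLabel == -1, "resistant",
                          "sensitive"))
  S <- similarityMatrix(selection$scores, groups = groups)
  network <- kNeighborAdjacency(S, k = config$k)

  predictions <- loocv(features, config, seed = stageSeeds[2L])
  report <- evaluatePredictions(predictions, config$sigmaFloor)

  if (!is.null(outDir)) {
    if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
    if (writeSpectra)
      writeSpectraTable(cohort, file.path(outDir, "spectra"))
    writeFeatureTable(features, file.path(outDir, "features.tsv"))
    data.table::fwrite(selection$selected,
                       file.path(outDir, "selected_biomarkers.tsv"),
                       sep = "\t")
    writeSimilarity(S, network,
                    file.path(outDir, "similarity.tsv"),
                    file.path(outDir, "network_edges.tsv"))
    writePredictions(predictions, file.path(outDir, "predictions.tsv"))
    data.table::fwrite(data.table::data.table(
      threshold = report$roc$thresholds,
      sensitivity = report$roc$sensitivity,
      specificity = report$roc$specificity),
      file.path(outDir, "roc_curve.tsv"), sep = "\t")
    writeReport(report, file.path(outDir, "report.json"))
  }
  list(cohort = cohort, features = features, selection = selection,
       similarity = S, network = network, predictions = predictions,
       report = report)
}
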