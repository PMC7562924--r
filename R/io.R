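#' Write a cohort's per-well spectra and manifest to delimited text
#'
#' Writes `wells.tsv` (long format: one row per well, loop and frequency,
#' columns patient_id, well_id, treatment, immobilization, loop,
#' loop_time_h, frequency_hz, spectral_density, brightness, violations),
#' `manifest.tsv` (patient_id, clinical_label, cohort_tag, seed) and
#' `grid.yaml` describing the sampling grid.
#'
#' @param cohort a [WellCohort-class].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
writeSpectraTable <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  g <- cohort@grid
  nF <- length(frequencies(g)); nL <- nLoops(g)
  tabs <- lapply(cohort@wells, function(w) {
    data.table::data.table(
      patient_id = w@patientId, well_id = w@wellId,
      treatment = w@treatment,
      immobilization = w@meta$immobilization,
      loop = rep(seq_len(nL), each = nF),
      loop_time_h = rep(loopTimes(g), each = nF),
      frequency_hz = rep(frequencies(g), nL),
      spectral_density = as.vector(t(w@spectra)),
      brightness = rep(w@brightness, each = nF),
      violations = paste(w@violations, collapse = ";"),
      nsd_pre = w@meta$nsdPre, nsd_post = w@meta$nsdPost,
      ncnt = w@meta$ncnt)
  })
  data.table::fwrite(data.table::rbindlist(tabs),
                     file.path(dir, "wells.tsv"), sep = "\t")
  man <- cohort@manifest
  data.table::fwrite(data.table::data.table(
    patient_id = man$patientId, phenotype = man$phenotype,
    clinical_label = man$clinicalLabel, cohort_tag = man$cohortTag,
    immobilization = man$immobilization, seed = cohort@seed),
    file.path(dir, "manifest.tsv"), sep = "\t")
  yaml::write_yaml(list(frequencies = frequencies(g),
                        loopPeriod = g@loopPeriod,
                        doseLoop = doseLoop(g), nLoops = nLoops(g)),
                   file.path(dir, "grid.yaml"))
  invisible(dir)
}

#' Read a cohort written by [writeSpectraTable()]
#'
#' @param dir directory holding `wells.tsv`, `manifest.tsv`, `grid.yaml`.
#' @return a [WellCohort-class].
#' @export
readSpectraTable <- function(dir) {
  gy <- yaml::read_yaml(file.path(dir, "grid.yaml"))
  f <- as.numeric(gy$frequencies)
  grid <- new("TimeFrequencyGrid", frequencies = f,
              loopTimes = (seq_len(gy$nLoops) - 1L) * gy$loopPeriod / 60,
              doseLoop = as.integer(gy$doseLoop),
              loopPeriod = gy$loopPeriod)
  tab <- data.table::fread(file.path(dir, "wells.tsv"))
  manTab <- data.table::fread(file.path(dir, "manifest.tsv"))
  nF <- length(f); nL <- gy$nLoops
  wellsList <- lapply(split(tab, by = "well_id", sorted = FALSE),
                      function(wt) {
    wt <- wt[order(wt$loop, wt$frequency_hz), ]
    S <- matrix(wt$spectral_density, nL, nF, byrow = TRUE)
    v <- wt$violations[1L]
    new("WellRecord", wellId = wt$well_id[1L],
        patientId = wt$patient_id[1L], treatment = wt$treatment[1L],
        grid = grid, spectra = S,
        brightness = wt$brightness[seq(1L, nrow(wt), by = nF)],
        violations = if (nzchar(v)) strsplit(v, ";")[[1L]] else character(),
        meta = list(nsdPre = wt$nsd_pre[1L], nsdPost = wt$nsd_post[1L],
                    ncnt = wt$ncnt[1L],
                    immobilization = wt$immobilization[1L]))
  })
  man <- data.frame(patientId = manTab$patient_id,
                    phenotype = manTab$phenotype,
                    clinicalLabel = manTab$clinical_label,
                    cohortTag = manTab$cohort_tag,
                    immobilization = manTab$immobilization,
                    stringsAsFactors = FALSE)
  new("WellCohort", wells = unname(wellsList), manifest = man,
      grid = grid, seed = as.integer(manTab$seed[1L]))
}

#' Write a drug-response spectrogram to wide delimited text
#'
#' Writes the response matrix as a tab-separated wide table (rows =
#' post-dose loops, header row = frequencies in Hz) plus a YAML sidecar
#' with treatment, DQ, patient and the baseline spectrum.
#'
#' @param spgm a [DrugResponseSpectrogram-class].
#' @param path output path for the matrix; the sidecar gets `.meta.yaml`
#'   appended.
#' @return `path`, invisibly.
#' @export
writeSpectrogram <- function(spgm, path) {
  D <- spgm@D
  colnames(D) <- formatC(frequencies(spgm), format = "g", digits = 10)
  data.table::fwrite(data.table::as.data.table(D), path, sep = "\t")
  yaml::write_yaml(list(treatment = spgm@treatment, dq = spgm@dq,
                        patientId = spgm@patientId,
                        baseline = spgm@baseline),
                   paste0(path, ".meta.yaml"))
  invisible(path)
}

#' Read a spectrogram written by [writeSpectrogram()]
#'
#' @param path matrix path (expects the `.meta.yaml` sidecar next to it).
#' @param grid the [TimeFrequencyGrid-class] the matrix lives on.
#' @return a [DrugResponseSpectrogram-class].
#' @export
readSpectrogram <- function(path, grid) {
  D <- as.matrix(data.table::fread(path, header = TRUE))
  dimnames(D) <- NULL
  meta <- yaml::read_yaml(paste0(path, ".meta.yaml"))
  new("DrugResponseSpectrogram", grid = grid, D = D,
      treatment = meta$treatment, dq = meta$dq,
      baseline = as.numeric(meta$baseline), patientId = meta$patientId)
}

#' Write / read the patient feature table
#'
#' Tab-separated with columns `patientId`, `clinicalLabel`, `phenotype`,
#' `cohortTag` followed by the 81 named feature columns.
#'
#' @param featureTable table from [extractFeatures()].
#' @param path file path.
#' @return `path` invisibly (writer); the table (reader).
#' @export
writeFeatureTable <- function(featureTable, path) {
  data.table::fwrite(featureTable, path, sep = "\t")
  invisible(path)
}

#' @rdname writeFeatureTable
#' @export
readFeatureTable <- function(path) {
  as.data.frame(data.table::fread(path))
}

#' Write a similarity matrix and its k-neighbor edge list
#'
#' The matrix goes to a square tab-separated file with header ids; the
#' network goes to an edge-list file (source, target, similarity) readable
#' by standard graph tools.
#'
#' @param S similarity matrix with dimnames.
#' @param adj adjacency list from [kNeighborAdjacency()] (for the edge
#'   list; `NULL` skips it).
#' @param matrixPath,edgePath output paths.
#' @return `matrixPath`, invisibly.
#' @export
writeSimilarity <- function(S, adj = NULL, matrixPath,
                            edgePath = NULL) {
  dt <- data.table::data.table(id = rownames(S))
  dt <- cbind(dt, data.table::as.data.table(S))
  data.table::fwrite(dt, matrixPath, sep = "\t")
  if (!is.null(adj) && !is.null(edgePath)) {
    A <- adj$directed
    idx <- which(A == 1L, arr.ind = TRUE)
    data.table::fwrite(data.table::data.table(
      source = rownames(A)[idx[, 1L]],
      target = colnames(A)[idx[, 2L]],
      similarity = S[idx]), edgePath, sep = "\t")
  }
  invisible(matrixPath)
}

#' Write / read the ensemble prediction table
#'
#' @param preds prediction table from [loocv()].
#' @param path file path.
#' @return `path` invisibly (writer); the table (reader).
#' @export
writePredictions <- function(preds, path) {
  data.table::fwrite(preds, path, sep = "\t")
  invisible(path)
}

#' @rdname writePredictions
#' @export
readPredictions <- function(path) {
  as.data.frame(data.table::fread(path))
}

#' Write the evaluation report as JSON
#'
#' @param report report list from [evaluatePredictions()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeReport <- function(report, path) {
  report$roc <- NULL  # curve goes to its own table, not the JSON
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  invisible(path)
}
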