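#' @import methods
NULL

#' Time-frequency sampling grid for fluctuation spectroscopy
#'
#' Shared grid on which all per-well fluctuation spectra and drug-response
#' spectrograms are defined. Frequencies are log-spaced between the lowest
#' resolved Doppler frequency and the Nyquist frequency of the camera; loops
#' are the repeating plate-scan cycles, a fixed number of which precede the
#' drug dose.
#'
#' @slot frequencies strictly increasing frequency axis in Hz.
#' @slot loopTimes strictly increasing loop start times in hours.
#' @slot doseLoop index of the last pre-dose loop.
#' @slot loopPeriod loop period in minutes.
#'
#' @seealso [timeFrequencyGrid()]
#' @exportClass TimeFrequencyGrid
setClass("TimeFrequencyGrid",
  representation(
    frequencies = "numeric",
    loopTimes   = "numeric",
    doseLoop    = "integer",
    loopPeriod  = "numeric"
  )
)

setValidity("TimeFrequencyGrid", function(object) {
  msg <- character()
  f <- object@frequencies
  if (length(f) < 3L || any(diff(f) <= 0))
    msg <- c(msg, "frequencies must be strictly increasing with length >= 3")
  if (length(f) && f[1L] <= 0)
    msg <- c(msg, "frequencies must be positive")
  tl <- object@loopTimes
  if (length(tl) < 2L || any(diff(tl) <= 0))
    msg <- c(msg, "loopTimes must be strictly increasing with length >= 2")
  if (length(tl) >= 2L &&
      max(abs(diff(tl) - object@loopPeriod / 60)) > 1e-8)
    msg <- c(msg, "loopTimes spacing must equal loopPeriod")
  if (object@doseLoop < 1L || object@doseLoop >= length(tl))
    msg <- c(msg, "doseLoop must leave at least one post-dose loop")
  if (object@loopPeriod <= 0)
    msg <- c(msg, "loopPeriod must be positive")
  if (length(msg)) msg else TRUE
})

#' Single-well fluctuation spectrum time series
#'
#' Container for one well of a multiwell biodynamic assay: the fluctuation
#' power spectral density sampled at every loop of the measurement cycle,
#' the per-loop image brightness, and any quality-control violation flags
#' attached during acquisition or simulation.
#'
#' @slot wellId well identifier.
#' @slot patientId patient identifier.
#' @slot treatment one of `"control"`, `"carboplatin"`, `"paclitaxel"`,
#'   `"combination"`.
#' @slot grid the [TimeFrequencyGrid-class] the spectra live on.
#' @slot spectra strictly positive matrix, loops x frequencies.
#' @slot brightness positive per-loop mean image brightness.
#' @slot violations character vector of named quality-control violations.
#' @slot meta list of scalar well metadata (speckle contrast `nsdPre`/
#'   `nsdPost`, sample pixel count `ncnt`, immobilization).
#'
#' @exportClass WellRecord
setClass("WellRecord",
  representation(
    wellId     = "character",
    patientId  = "character",
    treatment  = "character",
    grid       = "TimeFrequencyGrid",
    spectra    = "matrix",
    brightness = "numeric",
    violations = "character",
    meta       = "list"
  )
)

setValidity("WellRecord", function(object) {
  msg <- character()
  g <- object@grid
  s <- object@spectra
  if (!is.numeric(s) || any(!is.finite(s)) || any(s <= 0))
    msg <- c(msg, "spectra must be strictly positive and finite")
  if (nrow(s) != length(g@loopTimes))
    msg <- c(msg, "spectra row count must match grid loop count")
  if (ncol(s) != length(g@frequencies))
    msg <- c(msg, "spectra column count must match grid frequency count")
  if (length(object@brightness) != length(g@loopTimes) ||
      any(object@brightness <= 0))
    msg <- c(msg, "brightness must be positive with one value per loop")
  if (!object@treatment %in% bdiTreatments())
    msg <- c(msg, sprintf("unknown treatment '%s'", object@treatment))
  if (length(msg)) msg else TRUE
})

#' Cohort of simulated or measured wells with patient manifest
#'
#' @slot wells list of [WellRecord-class] objects.
#' @slot manifest data.frame with columns `patientId`, `phenotype` (response
#'   parameterization actually simulated), `clinicalLabel` (+1 sensitive,
#'   -1 resistant), `cohortTag` (`"training"`, `"metastatic"` or `"test"`)
#'   and `immobilization`.
#' @slot grid shared [TimeFrequencyGrid-class].
#' @slot seed integer seed the cohort was generated from (NA for measured
#'   data).
#'
#' @exportClass WellCohort
setClass("WellCohort",
  representation(
    wells    = "list",
    manifest = "data.frame",
    grid     = "TimeFrequencyGrid",
    seed     = "integer"
  )
)

setValidity("WellCohort", function(object) {
  msg <- character()
  if (!all(vapply(object@wells, is, logical(1L), "WellRecord")))
    msg <- c(msg, "wells must all be WellRecord objects")
  need <- c("patientId", "phenotype", "clinicalLabel", "cohortTag",
            "immobilization")
  if (!all(need %in% names(object@manifest)))
    msg <- c(msg, paste("manifest must have columns:",
                        paste(need, collapse = ", ")))
  else {
    wp <- unique(vapply(object@wells, function(w) w@patientId, character(1L)))
    if (!all(wp %in% object@manifest$patientId))
      msg <- c(msg, "every well's patient must appear in the manifest")
  }
  if (length(msg)) msg else TRUE
})

#' Baseline-referenced drug-response spectrogram
#'
#' The drug response of one well (or a replicate-averaged treatment) as the
#' log10 ratio of post-dose spectral density to the pre-dose baseline,
#' `D(omega, t) = log10 S(omega, t) - log10 S(omega, 0)`, with rows indexed
#' by post-dose loop and columns by frequency. Positive entries mean gained
#' spectral density relative to baseline, negative entries mean loss.
#'
#' @slot grid the [TimeFrequencyGrid-class].
#' @slot D finite matrix, post-dose loops x frequencies, log10 units.
#' @slot treatment treatment label.
#' @slot dq data-quality weight in (0, 1]; per-well values are `2^(-m)`
#'   after `m` quality violations, replicate averages carry the mean DQ.
#' @slot baseline the positive pre-dose baseline spectrum `S(omega, 0)`.
#' @slot patientId patient identifier ("" when not applicable).
#'
#' @exportClass DrugResponseSpectrogram
setClass("DrugResponseSpectrogram",
  representation(
    grid      = "TimeFrequencyGrid",
    D         = "matrix",
    treatment = "character",
    dq        = "numeric",
    baseline  = "numeric",
    patientId = "character"
  )
)

setValidity("DrugResponseSpectrogram", function(object) {
  msg <- character()
  g <- object@grid
  nPost <- length(g@loopTimes) - g@doseLoop
  if (any(!is.finite(object@D)))
    msg <- c(msg, "D must be finite")
  if (nrow(object@D) != nPost)
    msg <- c(msg, "D row count must equal the number of post-dose loops")
  if (ncol(object@D) != length(g@frequencies))
    msg <- c(msg, "D column count must match grid frequencies")
  if (object@dq <= 0 || object@dq > 1)
    msg <- c(msg, "dq must lie in (0, 1]")
  if (length(object@baseline) != length(g@frequencies) ||
      any(object@baseline <= 0))
    msg <- c(msg, "baseline must be positive on the grid frequencies")
  if (length(msg)) msg else TRUE
})
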