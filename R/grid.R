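#' Construct the assay time-frequency grid
#'
#' Builds the sampling grid of the biodynamic assay: a log-spaced Doppler
#' frequency axis running from the lowest resolved frequency up to the
#' camera Nyquist frequency, and a loop (plate-cycle) time axis. The default
#' layout is 50 frequencies from 10 mHz to 12.5 Hz and 13 loops of 82 min:
#' 4 pre-dose loops (a 5.5 h baseline) followed by 9 post-dose loops
#' (12.3 h of drug response).
#'
#' @param nFrequencies number of log-spaced frequency points.
#' @param freqMin lowest frequency in Hz.
#' @param nyquist Nyquist frequency in Hz (half the camera frame rate).
#' @param preDoseLoops number of loops recorded before the dose.
#' @param postDoseLoops number of loops recorded after the dose.
#' @param loopPeriod loop period in minutes.
#' @return a [TimeFrequencyGrid-class] object.
#' @export
#' @examples
#' g <- timeFrequencyGrid()
#' nLoops(g)
#' range(frequencies(g))
timeFrequencyGrid <- function(nFrequencies = 50L, freqMin = 0.01,
                              nyquist = 12.5, preDoseLoops = 4L,
                              postDoseLoops = 9L, loopPeriod = 82) {
  stopifnot(nFrequencies >= 3L, freqMin > 0, nyquist > freqMin,
            preDoseLoops >= 1L, postDoseLoops >= 1L, loopPeriod > 0)
  nL <- as.integer(preDoseLoops + postDoseLoops)
  new("TimeFrequencyGrid",
      frequencies = 10^seq(log10(freqMin), log10(nyquist),
                           length.out = nFrequencies),
      loopTimes   = (seq_len(nL) - 1L) * loopPeriod / 60,
      doseLoop    = as.integer(preDoseLoops),
      loopPeriod  = loopPeriod)
}

#' @describeIn timeFrequencyGrid frequency axis in Hz.
#' @param x a grid-bearing object.
setMethod("frequencies", "TimeFrequencyGrid", function(x) x@frequencies)

#' @describeIn timeFrequencyGrid loop start times in hours.
setMethod("loopTimes", "TimeFrequencyGrid", function(x) x@loopTimes)

#' @describeIn timeFrequencyGrid index of the last pre-dose loop.
setMethod("doseLoop", "TimeFrequencyGrid", function(x) x@doseLoop)

#' @describeIn timeFrequencyGrid total number of loops.
setMethod("nLoops", "TimeFrequencyGrid", function(x) length(x@loopTimes))

#' @describeIn timeFrequencyGrid number of post-dose loops.
setMethod("postDoseLoops", "TimeFrequencyGrid",
          function(x) length(x@loopTimes) - x@doseLoop)

#' @rdname frequencies-WellRecord-method
#' @name frequencies,WellRecord-method
#' @aliases frequencies,WellRecord-method
#'   frequencies,DrugResponseSpectrogram-method spectra,WellRecord-method
#'   treatment,WellRecord-method treatment,DrugResponseSpectrogram-method
#'   dataQuality,DrugResponseSpectrogram-method
#'   responseMatrix,DrugResponseSpectrogram-method
#'   manifest,WellCohort-method wells,WellCohort-method
#' @title Accessors for wells, cohorts and spectrograms
#' @param x a [WellRecord-class], [WellCohort-class] or
#'   [DrugResponseSpectrogram-class].
#' @return the accessed component.
NULL

setMethod("frequencies", "WellRecord", function(x) x@grid@frequencies)
setMethod("frequencies", "DrugResponseSpectrogram",
          function(x) x@grid@frequencies)
setMethod("spectra", "WellRecord", function(x) x@spectra)
setMethod("treatment", "WellRecord", function(x) x@treatment)
setMethod("treatment", "DrugResponseSpectrogram", function(x) x@treatment)
setMethod("dataQuality", "DrugResponseSpectrogram", function(x) x@dq)
setMethod("responseMatrix", "DrugResponseSpectrogram", function(x) x@D)
setMethod("manifest", "WellCohort", function(x) x@manifest)
setMethod("wells", "WellCohort", function(x) x@wells)

setMethod("show", "TimeFrequencyGrid", function(object) {
  cat(sprintf(
    "TimeFrequencyGrid: %d frequencies [%.3g, %.3g] Hz, %d loops (%d pre-dose) @ %.0f min\n",
    length(object@frequencies), min(object@frequencies),
    max(object@frequencies), length(object@loopTimes), object@doseLoop,
    object@loopPeriod))
})

setMethod("show", "WellRecord", function(object) {
  cat(sprintf(
    "WellRecord %s (patient %s, %s): %d loops x %d frequencies, %d violation(s)\n",
    object@wellId, object@patientId, object@treatment,
    nrow(object@spectra), ncol(object@spectra), length(object@violations)))
})

setMethod("show", "WellCohort", function(object) {
  m <- object@manifest
  cat(sprintf(
    "WellCohort: %d wells, %d patients (%d training, %d metastatic, %d test), seed %s\n",
    length(object@wells), nrow(m), sum(m$cohortTag == "training"),
    sum(m$cohortTag == "metastatic"), sum(m$cohortTag == "test"),
    object@seed))
})

setMethod("show", "DrugResponseSpectrogram", function(object) {
  cat(sprintf(
    "DrugResponseSpectrogram (%s%s): %d post-dose loops x %d frequencies, DQ = %.3g\n",
    object@treatment,
    if (nzchar(object@patientId)) paste0(", patient ", object@patientId) else "",
    nrow(object@D), ncol(object@D), object@dq))
})
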