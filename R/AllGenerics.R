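#' Treatment arms of the biodynamic assay
#'
#' The four treatment arms of the standard plate layout: DMSO vehicle
#' control, the two monotherapies, and the combination.
#'
#' @param drugsOnly if `TRUE`, drop the vehicle control.
#' @return character vector of treatment names in canonical order.
#' @export
#' @examples
#' bdiTreatments()
bdiTreatments <- function(drugsOnly = FALSE) {
  x <- c("control", "carboplatin", "paclitaxel", "combination")
  if (drugsOnly) x[-1L] else x
}

#' Frequency axis of a grid-bearing object
#' @param x a [TimeFrequencyGrid-class], [WellRecord-class] or
#'   [DrugResponseSpectrogram-class].
#' @return numeric vector of frequencies in Hz.
#' @export
setGeneric("frequencies", function(x) standardGeneric("frequencies"))

#' Loop start times in hours
#' @param x a [TimeFrequencyGrid-class].
#' @return numeric vector of loop times (h).
#' @export
setGeneric("loopTimes", function(x) standardGeneric("loopTimes"))

#' Index of the last pre-dose loop
#' @param x a [TimeFrequencyGrid-class].
#' @return integer loop index.
#' @export
setGeneric("doseLoop", function(x) standardGeneric("doseLoop"))

#' Total number of loops
#' @param x a [TimeFrequencyGrid-class].
#' @return integer.
#' @export
setGeneric("nLoops", function(x) standardGeneric("nLoops"))

#' Number of post-dose loops
#' @param x a [TimeFrequencyGrid-class].
#' @return integer.
#' @export
setGeneric("postDoseLoops", function(x) standardGeneric("postDoseLoops"))

#' Spectra matrix of a well
#' @param x a [WellRecord-class].
#' @return loops x frequencies matrix of spectral densities.
#' @export
setGeneric("spectra", function(x) standardGeneric("spectra"))

#' Treatment label
#' @param x a [WellRecord-class] or [DrugResponseSpectrogram-class].
#' @return character scalar.
#' @export
setGeneric("treatment", function(x) standardGeneric("treatment"))

#' Data-quality weight
#' @param x a [DrugResponseSpectrogram-class].
#' @return numeric in (0, 1].
#' @export
setGeneric("dataQuality", function(x) standardGeneric("dataQuality"))

#' Drug-response matrix D(omega, t)
#' @param x a [DrugResponseSpectrogram-class].
#' @return post-dose loops x frequencies matrix (log10 units).
#' @export
setGeneric("responseMatrix", function(x) standardGeneric("responseMatrix"))

#' Patient manifest of a cohort
#' @param x a [WellCohort-class].
#' @return data.frame with one row per patient.
#' @export
setGeneric("manifest", function(x) standardGeneric("manifest"))

#' Well list of a cohort
#' @param x a [WellCohort-class].
#' @return list of [WellRecord-class] objects.
#' @export
setGeneric("wells", function(x) standardGeneric("wells"))
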