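#' Pipeline configuration with assay defaults
#'
#' All tunable parameters of the pipeline in one validated list. Defaults
#' are the standard assay values: 25 fps camera (12.5 Hz Nyquist), 82-min
#' loops with the dose after loop 4, 17/18/18/18 well replicates, network
#' neighbors `k = 3`, ridge regularization `lambda = 0.1`, 5 selected
#' biomarkers.
#'
#' @param nFrequencies,freqMin,nyquist,preDoseLoops,postDoseLoops,loopPeriod
#'   grid layout, see [timeFrequencyGrid()].
#' @param frameRate camera frame rate in Hz.
#' @param bandEdges local-mask band edges in Hz.
#' @param brightnessJumpRatio,lowActivityFrac data-quality thresholds, see
#'   [dqThresholds()].
#' @param dmsoSubtract subtract the vehicle-control spectrogram before
#'   feature extraction.
#' @param nSelect number of SVD biomarkers kept by [selectBiomarkers()].
#' @param k network-classifier neighbors.
#' @param lambda perceptron ridge regularization.
#' @param sigmaFloor Gaussian-mixture component floor.
#' @param subsetResamples training-subset resamples for the ensemble SE.
#' @param nResistant,nSensitive,nMetastatic default synthetic cohort
#'   composition.
#' @param wellsPerTreatment named replicate counts.
#' @param seed master seed.
#' @return validated list of class `BDIConfig`.
#' @export
#' @examples
#' cfg <- bdiConfig()
#' cfg$k
bdiConfig <- function(nFrequencies = 50L, freqMin = 0.01, nyquist = 12.5,
                      preDoseLoops = 4L, postDoseLoops = 9L,
                      loopPeriod = 82, frameRate = 25,
                      bandEdges = c(0.01, 0.1, 1, 10),
                      brightnessJumpRatio = 1.5, lowActivityFrac = 0.05,
                      dmsoSubtract = TRUE, nSelect = 5L, k = 3L,
                      lambda = 0.1, sigmaFloor = 0.02,
                      subsetResamples = 8L, nResistant = 10L,
                      nSensitive = 10L, nMetastatic = 4L,
                      wellsPerTreatment = c(control = 17L,
                                            carboplatin = 18L,
                                            paclitaxel = 18L,
                                            combination = 18L),
                      seed = 1L) {
  cfg <- list(nFrequencies = as.integer(nFrequencies), freqMin = freqMin,
              nyquist = nyquist, preDoseLoops = as.integer(preDoseLoops),
              postDoseLoops = as.integer(postDoseLoops),
              loopPeriod = loopPeriod, frameRate = frameRate,
              bandEdges = bandEdges,
              brightnessJumpRatio = brightnessJumpRatio,
              lowActivityFrac = lowActivityFrac,
              dmsoSubtract = isTRUE(dmsoSubtract),
              nSelect = as.integer(nSelect), k = as.integer(k),
              lambda = lambda, sigmaFloor = sigmaFloor,
              subsetResamples = as.integer(subsetResamples),
              nResistant = as.integer(nResistant),
              nSensitive = as.integer(nSensitive),
              nMetastatic = as.integer(nMetastatic),
              wellsPerTreatment = wellsPerTreatment,
              seed = as.integer(seed))
  .validateConfig(cfg)
  structure(cfg, class = "BDIConfig")
}

.validateConfig <- function(cfg) {
  check <- function(ok, key, why)
    if (!ok) stop(sprintf("invalid config value for '%s': %s", key, why),
                  call. = FALSE)
  check(cfg$nFrequencies >= 3L, "nFrequencies", "must be >= 3")
  check(cfg$freqMin > 0, "freqMin", "must be positive")
  check(cfg$nyquist > cfg$freqMin, "nyquist", "must exceed freqMin")
  check(abs(cfg$nyquist - cfg$frameRate / 2) < 1e-9, "nyquist",
        "must equal frameRate / 2")
  check(cfg$preDoseLoops >= 4L, "preDoseLoops",
        "must be >= 4 (baseline uses the last 4 pre-dose loops)")
  check(cfg$postDoseLoops >= 3L, "postDoseLoops",
        "must be >= 3 (quadratic time masks)")
  check(cfg$loopPeriod > 0, "loopPeriod", "must be positive")
  check(length(cfg$bandEdges) == 4L && all(diff(cfg$bandEdges) > 0),
        "bandEdges", "must be 4 strictly increasing values")
  check(cfg$brightnessJumpRatio > 1, "brightnessJumpRatio",
        "must exceed 1")
  check(cfg$lowActivityFrac > 0 && cfg$lowActivityFrac < 1,
        "lowActivityFrac", "must lie in (0, 1)")
  check(cfg$nSelect >= 1L, "nSelect", "must be >= 1")
  check(cfg$k >= 1L, "k", "must be >= 1")
  check(cfg$lambda >= 0, "lambda", "must be non-negative")
  check(cfg$sigmaFloor > 0, "sigmaFloor", "must be positive")
  check(cfg$subsetResamples >= 0L, "subsetResamples",
        "must be non-negative")
  check(cfg$nResistant >= 1L && cfg$nSensitive >= 1L, "nResistant",
        "both training classes need >= 1 patient")
  check(all(bdiTreatments() %in% names(cfg$wellsPerTreatment)) &&
          all(cfg$wellsPerTreatment >= 1L), "wellsPerTreatment",
        "must name all four treatments with counts >= 1")
  invisible(cfg)
}

#' Load a pipeline configuration from a YAML file
#'
#' Reads `key: value` pairs, rejects unknown keys, fills unspecified keys
#' with the [bdiConfig()] defaults and validates the result. An empty file
#' yields the full default configuration.
#'
#' @param path path to a YAML configuration file.
#' @return validated `BDIConfig` list.
#' @export
loadConfig <- function(path) {
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  if (!is.list(user)) stop("config file must contain key: value pairs")
  known <- names(formals(bdiConfig))
  unknown <- setdiff(names(user), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  if (!is.null(user$wellsPerTreatment))
    user$wellsPerTreatment <- unlist(user$wellsPerTreatment)
  do.call(bdiConfig, user)
}
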