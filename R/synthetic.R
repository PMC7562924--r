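#' Default phenotype response table
#'
#' Endpoint modifier factors of the spectral model per (phenotype,
#' treatment). Each entry gives the knee-shift factor and the amplitude
#' factor reached at the final post-dose loop; both ramp linearly in loop
#' number from 1 at the dose. Resistant tissue under monotherapy slides its
#' knee frequency down while slightly gaining plateau amplitude — the
#' spectral red shift (slowed intracellular motion). The combination
#' produces broadband amplitude inhibition for both phenotypes. Sensitive
#' tissue shows only a mild blue shift under monotherapy. Vehicle control is
#' identically (1, 1).
#'
#' @return nested list `response[[phenotype]][[treatment]] = c(knee, amp)`.
#' @export
defaultResponseTable <- function() {
  list(
    resistant = list(
      control     = c(knee = 1.00, amp = 1.00),
      carboplatin = c(knee = 0.60, amp = 1.20),
      paclitaxel  = c(knee = 0.62, amp = 1.15),
      combination = c(knee = 0.90, amp = 0.60)
    ),
    sensitive = list(
      control     = c(knee = 1.00, amp = 1.00),
      carboplatin = c(knee = 1.08, amp = 1.00),
      paclitaxel  = c(knee = 1.10, amp = 1.02),
      combination = c(knee = 1.00, amp = 0.50)
    )
  )
}

#' Spectral-model and response parameters of the synthetic generator
#'
#' Parameterizes the baseline Doppler fluctuation spectrum
#' `S(omega) = A / (1 + (omega / kneeHz)^slope) + nyFloor`
#' (low-frequency plateau, knee, power-law roll-off, Nyquist noise floor)
#' and the phenotype-dependent drug-response trajectories applied to it.
#'
#' @param A plateau amplitude of the baseline spectrum (spectral-density
#'   units).
#' @param kneeHz knee (corner) frequency in Hz.
#' @param slope roll-off exponent above the knee (dimensionless).
#' @param nyFloor Nyquist noise-floor spectral density.
#' @param sigmaLog multiplicative measurement noise, standard deviation in
#'   log10 units per (frequency, loop) bin.
#' @param response endpoint modifier table, see [defaultResponseTable()].
#' @param patientSdKnee between-patient spread of the knee-shift endpoint
#'   (standard deviation of its natural log).
#' @param patientSdAmp between-patient spread of the amplitude endpoint
#'   (standard deviation of its natural log).
#' @return object of class `PhenotypeParams` (validated list).
#' @export
#' @examples
#' p <- phenotypeParams()
#' p$kneeHz
phenotypeParams <- function(A = 100, kneeHz = 0.3, slope = 1.6, nyFloor = 1,
                            sigmaLog = 0.08,
                            response = defaultResponseTable(),
                            patientSdKnee = 0.18, patientSdAmp = 0.10) {
  if (A <= 0) stop("plateau amplitude A must be positive")
  if (nyFloor <= 0) stop("Nyquist floor must be positive")
  if (kneeHz <= 0) stop("knee frequency must be positive")
  if (slope <= 0) stop("roll-off slope must be positive")
  if (sigmaLog < 0) stop("sigmaLog must be non-negative")
  for (ph in names(response))
    if (any(abs(response[[ph]]$control - 1) > 0))
      stop("control response trajectories must be identically (1, 1)")
  structure(list(A = A, kneeHz = kneeHz, slope = slope, nyFloor = nyFloor,
                 sigmaLog = sigmaLog, response = response,
                 patientSdKnee = patientSdKnee, patientSdAmp = patientSdAmp),
            class = "PhenotypeParams")
}

#' Baseline Doppler fluctuation spectrum
#'
#' Evaluates the noiseless baseline spectral model on the grid frequencies:
#' a low-frequency plateau rolling off as a power law above the knee
#' frequency, on top of a flat detection-noise floor.
#'
#' @param params a [phenotypeParams()] object.
#' @param grid a [TimeFrequencyGrid-class].
#' @return strictly positive, monotone non-increasing spectral-density
#'   vector on `frequencies(grid)`.
#' @export
#' @examples
#' s <- baselineDopplerSpectrum(phenotypeParams(), timeFrequencyGrid())
#' all(diff(s) <= 0)
baselineDopplerSpectrum <- function(params, grid) {
  stopifnot(inherits(params, "PhenotypeParams"))
  f <- frequencies(grid)
  params$A / (1 + (f / params$kneeHz)^params$slope) + params$nyFloor
}

#' Drug-response modifier factors at a given loop
#'
#' Returns the (knee factor, amplitude factor) pair applied to the baseline
#' spectral model at a given loop. Factors are 1 on and before the dose loop
#' and ramp linearly in loop number to the endpoint values of the response
#' table at the final loop.
#'
#' @param phenotype `"resistant"` or `"sensitive"` (response
#'   parameterization, not the clinical label).
#' @param treatment one of [bdiTreatments()].
#' @param loop loop index (1-based).
#' @param grid a [TimeFrequencyGrid-class].
#' @param params a [phenotypeParams()] object.
#' @return named numeric `c(knee, amp)`.
#' @export
drugResponseModifier <- function(phenotype, treatment, loop, grid,
                                 params = phenotypeParams()) {
  resp <- params$response[[phenotype]]
  if (is.null(resp))
    stop(sprintf("unknown phenotype '%s'", phenotype))
  endp <- resp[[treatment]]
  if (is.null(endp))
    stop(sprintf("unknown treatment '%s'", treatment))
  ramp <- max(0, (loop - doseLoop(grid)) / postDoseLoops(grid))
  c(knee = 1 + (endp[["knee"]] - 1) * ramp,
    amp  = 1 + (endp[["amp"]]  - 1) * ramp)
}

# Model spectrum at one loop under the modifier factors; the noise floor is
# detection noise and is not modified by the drug.
.modelSpectrum <- function(params, grid, kneeFac, ampFac) {
  f <- frequencies(grid)
  ampFac * params$A /
    (1 + (f / (params$kneeHz * kneeFac))^params$slope) + params$nyFloor
}

#' Default quality-violation injection probabilities
#'
#' Per-well probabilities of injecting each named quality-control
#' violation. The defaults put the expected data-quality weight
#' `E[2^(-m)] = prod(1 - p/2)` near 0.25, the typical value of the assay.
#'
#' @return named numeric vector of probabilities.
#' @export
defaultViolationProbs <- function() {
  c(brightness_jump = 0.55, low_activity = 0.45,
    speckle_decorrelation = 0.65, sample_drift = 0.70)
}

#' Simulate one assay well
#'
#' Generates a [WellRecord-class]: the modified model spectrum at every
#' loop multiplied by i.i.d. log-normal measurement noise
#' `10^(sigmaLog * eps)`, a per-loop brightness trace, and injected
#' quality-control violations. An injected `brightness_jump` also doubles
#' the brightness of one random post-dose loop so that the trace itself
#' carries the artifact.
#'
#' Randomness comes from R's current RNG stream; seed with [set.seed()]
#' (or use [simulateCohort()], which manages seeding).
#'
#' @param params a [phenotypeParams()] object.
#' @param grid a [TimeFrequencyGrid-class].
#' @param phenotype response parameterization, `"resistant"` or
#'   `"sensitive"`.
#' @param treatment one of [bdiTreatments()].
#' @param patientId,wellId identifiers.
#' @param violationProbs named injection probabilities, see
#'   [defaultViolationProbs()].
#' @param immobilization immobilization tag stored in the metadata.
#' @return a [WellRecord-class].
#' @export
#' @examples
#' set.seed(7)
#' w <- simulateWell(phenotypeParams(sigmaLog = 0), timeFrequencyGrid(),
#'                   "resistant", "carboplatin", violationProbs = c())
simulateWell <- function(params, grid, phenotype, treatment,
                         patientId = "P1", wellId = "W1",
                         violationProbs = defaultViolationProbs(),
                         immobilization = "poly-lysine") {
  nL <- nLoops(grid)
  nF <- length(frequencies(grid))
  S <- matrix(NA_real_, nL, nF)
  for (l in seq_len(nL)) {
    fac <- drugResponseModifier(phenotype, treatment, l, grid, params)
    S[l, ] <- .modelSpectrum(params, grid, fac[["knee"]], fac[["amp"]])
  }
  if (params$sigmaLog > 0)
    S <- S * 10^(params$sigmaLog * matrix(stats::rnorm(nL * nF), nL, nF))

  brightness <- 1000 * exp(stats::rnorm(nL, 0, 0.03))
  injected <- character()
  if (length(violationProbs)) {
    u <- stats::runif(length(violationProbs))
    injected <- names(violationProbs)[u < violationProbs]
  }
  if ("brightness_jump" %in% injected) {
    l <- doseLoop(grid) + sample.int(postDoseLoops(grid), 1L)
    brightness[l] <- brightness[l] * 2
  }
  meta <- list(nsdPre = 0.5 + stats::rnorm(1, 0, 0.02),
               nsdPost = 0.5 + stats::rnorm(1, 0, 0.02),
               ncnt = 200 + sample.int(200, 1L),
               immobilization = immobilization)
  new("WellRecord", wellId = wellId, patientId = patientId,
      treatment = treatment, grid = grid, spectra = S,
      brightness = brightness, violations = injected, meta = meta)
}

#' Assay plate design for a synthetic cohort
#'
#' @param nResistant,nSensitive number of training patients with resistant /
#'   sensitive clinical outcome (both must be >= 1 for downstream training).
#' @param nMetastatic number of metastatic specimens; these always carry the
#'   resistant-type response parameterization, whatever their clinical
#'   label, and are excluded from training and feature selection.
#' @param wellsPerTreatment named well replicate counts; the standard plate
#'   uses 17 vehicle-control and 18 wells per drug arm.
#' @param immobilization immobilization tag applied to all patients.
#' @param seed integer seed.
#' @return object of class `AssayDesign` (validated list).
#' @export
assayDesign <- function(nResistant = 10L, nSensitive = 10L,
                        nMetastatic = 4L,
                        wellsPerTreatment = c(control = 17L,
                                              carboplatin = 18L,
                                              paclitaxel = 18L,
                                              combination = 18L),
                        immobilization = "poly-lysine", seed = 1L) {
  if (nResistant < 1L || nSensitive < 1L)
    stop("both training classes must have at least one patient")
  if (nMetastatic < 0L) stop("nMetastatic must be non-negative")
  if (!all(bdiTreatments() %in% names(wellsPerTreatment)))
    stop("wellsPerTreatment must name all four treatments")
  if (any(wellsPerTreatment < 1L))
    stop("well counts must be >= 1")
  structure(list(nResistant = as.integer(nResistant),
                 nSensitive = as.integer(nSensitive),
                 nMetastatic = as.integer(nMetastatic),
                 wellsPerTreatment = wellsPerTreatment[bdiTreatments()],
                 immobilization = immobilization,
                 seed = as.integer(seed)),
            class = "AssayDesign")
}

# Per-patient response table: endpoint factors jittered on the log scale so
# patients differ in effect size (between-patient biological variability).
.patientResponse <- function(params) {
  resp <- params$response
  for (ph in names(resp)) {
    for (tr in names(resp[[ph]])) {
      if (tr == "control") next
      e <- resp[[ph]][[tr]]
      e[["knee"]] <- exp(log(e[["knee"]]) + stats::rnorm(1, 0, params$patientSdKnee))
      e[["amp"]]  <- exp(log(e[["amp"]])  + stats::rnorm(1, 0, params$patientSdAmp))
      resp[[ph]][[tr]] <- e
    }
  }
  resp
}

#' Simulate a seeded synthetic cohort
#'
#' Generates the full multiwell cohort: for each patient, a per-patient
#' response parameterization (population endpoints jittered on the log
#' scale) and the designed number of replicate wells per treatment arm.
#' Metastatic specimens receive the resistant-type response
#' parameterization regardless of their clinical label, and are tagged
#' `"metastatic"` so that downstream feature selection and training exclude
#' them.
#'
#' @param design an [assayDesign()].
#' @param params a [phenotypeParams()].
#' @param grid a [TimeFrequencyGrid-class].
#' @param seed integer seed (defaults to the design seed).
#' @param violationProbs see [defaultViolationProbs()].
#' @return a [WellCohort-class].
#' @export
#' @examples
#' co <- simulateCohort(assayDesign(2, 2, 1,
#'         wellsPerTreatment = c(control = 2, carboplatin = 2,
#'                               paclitaxel = 2, combination = 2)))
#' manifest(co)
simulateCohort <- function(design = assayDesign(),
                           params = phenotypeParams(),
                           grid = timeFrequencyGrid(),
                           seed = design$seed,
                           violationProbs = defaultViolationProbs()) {
  stopifnot(inherits(design, "AssayDesign"),
            inherits(params, "PhenotypeParams"))
  set.seed(seed)
  man <- data.frame(
    patientId = c(sprintf("R%02d", seq_len(design$nResistant)),
                  sprintf("S%02d", seq_len(design$nSensitive)),
                  if (design$nMetastatic)
                    sprintf("M%02d", seq_len(design$nMetastatic))),
    phenotype = c(rep("resistant", design$nResistant),
                  rep("sensitive", design$nSensitive),
                  rep("resistant", design$nMetastatic)),
    clinicalLabel = c(rep(-1, design$nResistant),
                      rep(+1, design$nSensitive),
                      # metastatic implants from clinically sensitive and
                      # resistant patients alike carry the resistant
                      # parameterization
                      rep_len(c(+1, -1), design$nMetastatic)),
    cohortTag = c(rep("training", design$nResistant + design$nSensitive),
                  rep("metastatic", design$nMetastatic)),
    immobilization = design$immobilization,
    stringsAsFactors = FALSE
  )

  wellList <- vector("list",
                     nrow(man) * sum(design$wellsPerTreatment))
  i <- 0L
  for (p in seq_len(nrow(man))) {
    pParams <- params
    pParams$response <- .patientResponse(params)
    for (tr in bdiTreatments()) {
      for (r in seq_len(design$wellsPerTreatment[[tr]])) {
        i <- i + 1L
        wellList[[i]] <- simulateWell(
          pParams, grid, man$phenotype[p], tr,
          patientId = man$patientId[p],
          wellId = sprintf("%s_%s_%02d", man$patientId[p],
                           substr(tr, 1, 4), r),
          violationProbs = violationProbs,
          immobilization = design$immobilization)
      }
    }
  }
  new("WellCohort", wells = wellList, manifest = man, grid = grid,
      seed = as.integer(seed))
}
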