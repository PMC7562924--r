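# small fixtures shared across test files; everything is generated in code

smallGrid <- function() {
  timeFrequencyGrid(nFrequencies = 20L, preDoseLoops = 4L,
                    postDoseLoops = 5L)
}

# minimal cohort: fast enough for whole-pipeline tests
tinyCohortConfig <- function(...) {
  bdiConfig(nResistant = 3L, nSensitive = 3L, nMetastatic = 1L,
            wellsPerTreatment = c(control = 3L, carboplatin = 3L,
                                  paclitaxel = 3L, combination = 3L),
            subsetResamples = 2L, ...)
}

tinyCohort <- function(seed = 1L, sigmaLog = 0.08, ...) {
  simulateCohort(
    assayDesign(3L, 3L, 1L,
                wellsPerTreatment = c(control = 3L, carboplatin = 3L,
                                      paclitaxel = 3L, combination = 3L),
                seed = seed),
    params = phenotypeParams(sigmaLog = sigmaLog, ...))
}

noiselessWell <- function(phenotype = "resistant",
                          treatment = "carboplatin",
                          grid = timeFrequencyGrid(), seed = 1L) {
  set.seed(seed)
  simulateWell(phenotypeParams(sigmaLog = 0), grid, phenotype, treatment,
               violationProbs = c())
}

# well-separated 2-class training set in d dimensions
separableTrainingSet <- function(n = 10L, d = 3L, gap = 4, sd = 1,
                                 seed = 1L) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(n * d, -gap / 2, sd), n, d),
             matrix(rnorm(n * d, +gap / 2, sd), n, d))
  list(X = X, y = rep(c(-1, 1), each = n))
}
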