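#' One-sided power spectral density on the log-frequency grid
#'
#' Fourier transforms an intensity time series into a one-sided power
#' spectral density and resamples it onto the log-spaced grid frequencies by
#' averaging the periodogram within geometrically spaced bins (which
#' preserves band-integrated power). Grid bins narrower than the Fourier
#' resolution are filled by interpolating the periodogram in log frequency.
#'
#' Before binning, the periodogram satisfies Parseval's identity: the PSD
#' integrated over frequency equals the series variance.
#'
#' @param x numeric intensity time series (length >= 2).
#' @param frameRate sampling rate in Hz (camera frame rate, default 25).
#' @param grid a [TimeFrequencyGrid-class] whose frequencies must not
#'   exceed the Nyquist frequency `frameRate / 2`.
#' @param floor additive spectral-density floor (default 0); a constant
#'   series returns zeros plus this floor.
#' @return spectral-density vector on `frequencies(grid)`.
#' @export
#' @examples
#' g <- timeFrequencyGrid()
#' s <- powerSpectrum(sin(2 * pi * 1 * (0:4095) / 25), 25, g)
powerSpectrum <- function(x, frameRate = 25, grid, floor = 0) {
  if (length(x) < 2L) stop("intensity series must have length >= 2")
  fGrid <- frequencies(grid)
  if (max(fGrid) > frameRate / 2 + 1e-9)
    stop("grid frequencies exceed the Nyquist frequency")
  n <- length(x)
  xc <- x - mean(x)
  if (all(xc == 0)) return(rep(floor, length(fGrid)))
  X <- stats::fft(xc)
  nHalf <- floor(n / 2)
  # one-sided PSD: sum(psd) * df = population variance
  psd <- 2 * Mod(X[2:(nHalf + 1L)])^2 / (n^2) * n / frameRate
  if (n %% 2L == 0L) psd[nHalf] <- psd[nHalf] / 2  # Nyquist bin not doubled
  fFour <- (1:nHalf) * frameRate / n

  # geometric bin edges around the log-spaced grid points
  lg <- log10(fGrid)
  mid <- (lg[-1L] + lg[-length(lg)]) / 2
  edges <- 10^c(2 * lg[1L] - mid[1L], mid,
                2 * lg[length(lg)] - mid[length(mid)])
  bin <- findInterval(fFour, edges, rightmost.closed = TRUE)
  out <- rep(NA_real_, length(fGrid))
  for (k in seq_along(fGrid)) {
    inBin <- bin == k
    if (any(inBin)) out[k] <- mean(psd[inBin])
  }
  empty <- is.na(out)
  if (any(empty))
    out[empty] <- stats::approx(log10(fFour), psd, xout = lg[empty],
                                rule = 2)$y
  out + floor
}

#' Pre-dose baseline spectrum
#'
#' The baseline spectrum `S(omega, 0)` is the per-frequency geometric mean
#' (arithmetic mean of the log10 spectra) over the last 4 loops before the
#' dose.
#'
#' @param x a [WellRecord-class], or a positive loops x frequencies matrix.
#' @param grid required when `x` is a bare matrix.
#' @return positive baseline spectral-density vector.
#' @export
baselineAverage <- function(x, grid = NULL) {
  if (is(x, "WellRecord")) {
    grid <- x@grid
    x <- x@spectra
  }
  if (is.null(grid)) stop("grid required when x is a matrix")
  if (any(x <= 0)) stop("spectral densities must be strictly positive")
  dl <- doseLoop(grid)
  if (dl < 4L)
    stop("baseline requires at least 4 pre-dose loops")
  rows <- (dl - 3L):dl
  10^colMeans(log10(x[rows, , drop = FALSE]))
}

#' Baseline-referenced drug-response spectrogram of a well
#'
#' Computes `D(omega, t) = log10 S(omega, t) - log10 S(omega, 0)` over the
#' post-dose loops, referenced to the geometric-mean pre-dose baseline.
#'
#' @param well a [WellRecord-class].
#' @param baseline optional baseline spectrum; computed by
#'   [baselineAverage()] when omitted.
#' @param dq data-quality weight to attach (default 1).
#' @return a [DrugResponseSpectrogram-class].
#' @export
#' @examples
#' set.seed(1)
#' w <- simulateWell(phenotypeParams(sigmaLog = 0), timeFrequencyGrid(),
#'                   "resistant", "carboplatin", violationProbs = c())
#' d <- drugResponseSpectrogram(w)
drugResponseSpectrogram <- function(well, baseline = NULL, dq = 1) {
  stopifnot(is(well, "WellRecord"))
  g <- well@grid
  if (is.null(baseline)) baseline <- baselineAverage(well)
  if (length(baseline) != length(frequencies(g)))
    stop("baseline length must match grid frequencies")
  if (any(baseline <= 0) || any(well@spectra <= 0))
    stop("spectral densities must be strictly positive")
  post <- (doseLoop(g) + 1L):nLoops(g)
  D <- sweep(log10(well@spectra[post, , drop = FALSE]), 2L, log10(baseline))
  new("DrugResponseSpectrogram", grid = g, D = D,
      treatment = well@treatment, dq = dq, baseline = baseline,
      patientId = well@patientId)
}

#' Data-quality thresholds
#'
#' @param brightnessJumpRatio consecutive-loop brightness ratio above which
#'   a brightness jump (immobilization shift) is flagged.
#' @param lowActivityFrac fraction of the cohort-median band-integrated
#'   baseline power (above the noise floor) below which a well is flagged
#'   as low cell activity.
#' @param activityReference cohort median of the activity statistic; the
#'   low-activity criterion is only evaluated when a reference is supplied.
#' @return named list of thresholds.
#' @export
dqThresholds <- function(brightnessJumpRatio = 1.5, lowActivityFrac = 0.05,
                         activityReference = NA_real_) {
  stopifnot(brightnessJumpRatio > 1, lowActivityFrac > 0)
  list(brightnessJumpRatio = brightnessJumpRatio,
       lowActivityFrac = lowActivityFrac,
       activityReference = activityReference)
}

# band-integrated baseline power above the noise floor (trapezoid in Hz);
# the floor is estimated as the density in the top (Nyquist) bin
.wellActivity <- function(well) {
  sb <- baselineAverage(well)
  f <- frequencies(well@grid)
  y <- pmax(sb - sb[length(sb)], 0)
  sum(diff(f) * (y[-1L] + y[-length(y)]) / 2)
}

#' Assess the data quality of a well
#'
#' The data-quality factor DQ starts at unity and is halved for each
#' violated quality-control criterion: a sudden jump in brightness between
#' consecutive loops (immobilization shift), low cell activity (baseline
#' band power above the noise floor under a small fraction of the cohort
#' median), plus any violations already flagged on the record. Detected and
#' pre-flagged violations with the same name count once.
#'
#' @param well a [WellRecord-class].
#' @param thresholds a [dqThresholds()] list.
#' @return list with `dq` (`2^(-m)`) and `violations` (character).
#' @export
#' @examples
#' set.seed(1)
#' w <- simulateWell(phenotypeParams(), timeFrequencyGrid(),
#'                   "sensitive", "control", violationProbs = c())
#' assessDataQuality(w)$dq
assessDataQuality <- function(well, thresholds = dqThresholds()) {
  stopifnot(is(well, "WellRecord"))
  detected <- character()
  b <- well@brightness
  ratio <- pmax(b[-1L] / b[-length(b)], b[-length(b)] / b[-1L])
  if (max(ratio) > thresholds$brightnessJumpRatio)
    detected <- c(detected, "brightness_jump")
  if (is.finite(thresholds$activityReference) &&
      .wellActivity(well) <
        thresholds$lowActivityFrac * thresholds$activityReference)
    detected <- c(detected, "low_activity")
  v <- union(well@violations, detected)
  list(dq = 2^(-length(v)), violations = v)
}

#' DQ-weighted replicate average of spectrograms
#'
#' Element-wise average of replicate drug-response spectrograms weighted by
#' their data-quality factors; the baselines are combined as the weighted
#' geometric mean and the result carries the mean DQ of its inputs.
#'
#' @param spgms list of [DrugResponseSpectrogram-class] objects sharing
#'   grid and treatment.
#' @param dqs data-quality weights; defaults to the spectrograms' own.
#' @return a [DrugResponseSpectrogram-class].
#' @export
weightedAverageSpectrograms <- function(spgms,
                                        dqs = vapply(spgms, dataQuality,
                                                     numeric(1L))) {
  if (!length(spgms)) stop("need at least one spectrogram")
  if (length(dqs) != length(spgms))
    stop("one DQ per spectrogram required")
  if (all(dqs == 0)) stop("no usable replicates: all DQ weights are zero")
  tr <- unique(vapply(spgms, treatment, character(1L)))
  if (length(tr) != 1L)
    stop("replicate spectrograms must share a treatment")
  w <- dqs / sum(dqs)
  D <- Reduce(`+`, Map(function(s, wi) wi * s@D, spgms, w))
  logBase <- Reduce(`+`, Map(function(s, wi) wi * log10(s@baseline),
                             spgms, w))
  new("DrugResponseSpectrogram", grid = spgms[[1L]]@grid, D = D,
      treatment = tr, dq = mean(dqs), baseline = 10^logBase,
      patientId = spgms[[1L]]@patientId)
}

#' Subtract the vehicle-control spectrogram
#'
#' Element-wise subtraction of the DMSO vehicle-control average from a
#' treatment spectrogram, removing drug-independent drift. The treatment
#' label is preserved.
#'
#' @param spgm treatment [DrugResponseSpectrogram-class].
#' @param control control [DrugResponseSpectrogram-class], or `NULL`.
#' @param missing what to do when `control` is `NULL`: `"error"` (default)
#'   or `"passthrough"` (return `spgm` with a warning).
#' @return a [DrugResponseSpectrogram-class].
#' @export
subtractControl <- function(spgm, control,
                            missing = c("error", "passthrough")) {
  missing <- match.arg(missing)
  if (is.null(control)) {
    if (missing == "error") stop("control spectrogram is missing")
    warning("control spectrogram missing; returning unsubtracted spectrogram")
    return(spgm)
  }
  if (!identical(dim(spgm@D), dim(control@D)))
    stop("treatment and control spectrograms must share a grid")
  out <- spgm
  out@D <- spgm@D - control@D
  out
}
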