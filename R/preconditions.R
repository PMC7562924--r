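#' Fit spectral-shape preconditions of a baseline spectrum
#'
#' Fits the plateau-knee-power-law-floor model
#' `S(omega) = A / (1 + (omega / KNEE)^S) + NY` to a spectrum by least
#' squares on log10 densities and derives the precondition set: the Nyquist
#' floor NY (density in the top frequency bin), knee frequency KNEE,
#' roll-off slope S, half-width HW (frequency where the density above the
#' floor falls to half the plateau), dynamic range
#' `DR = log10((A + NY) / NY)`, and the secondary high-frequency slope SF
#' (log-log slope over the top half-decade). Speckle contrast NSD,
#' brightness BSB and sample size NCNT are not derivable from the spectrum
#' and are passed through from well metadata.
#'
#' @param spectrum positive spectral-density vector.
#' @param freqs frequency axis in Hz.
#' @param nsd,bsb,ncnt pass-through metadata values.
#' @return object of class `PreconditionSet`: list with `values` (named
#'   numeric: NSD, BSB, NCNT, DR, NY, KNEE, HW, S, SF) and `converged`
#'   (named logical flags for KNEE, S, HW). Non-convergent fits leave
#'   KNEE, S, HW as `NA` with flags `FALSE`.
#' @export
#' @examples
#' g <- timeFrequencyGrid()
#' s <- baselineDopplerSpectrum(phenotypeParams(), g)
#' fitPreconditions(s, frequencies(g))$values[c("KNEE", "S")]
fitPreconditions <- function(spectrum, freqs, nsd = NA_real_,
                             bsb = NA_real_, ncnt = NA_real_) {
  if (any(spectrum <= 0)) stop("spectrum must be strictly positive")
  if (length(spectrum) != length(freqs))
    stop("spectrum and freqs must have equal length")
  nF <- length(freqs)
  nyObs <- spectrum[nF]

  # fit in log-parameters (positivity) on log10 densities
  resid <- function(par)
    log10(10^par[1L] / (1 + (freqs / 10^par[2L])^par[3L]) + 10^par[4L]) -
      log10(spectrum)
  start <- c(log10(max(spectrum[1L] - nyObs, nyObs)),
             log10(sqrt(freqs[1L] * freqs[nF])), 1.5, log10(nyObs))
  fit <- tryCatch(
    minpack.lm::nls.lm(par = start, fn = resid,
                       control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)

  values <- c(NSD = nsd, BSB = bsb, NCNT = ncnt, DR = NA_real_, NY = nyObs,
              KNEE = NA_real_, HW = NA_real_, S = NA_real_, SF = NA_real_)
  converged <- c(KNEE = FALSE, S = FALSE, HW = FALSE)
  if (!is.null(fit) && fit$info %in% 1:4) {
    cf <- fit$par
    A <- 10^cf[1L]; K <- 10^cf[2L]
    s <- cf[3L]; NYfit <- 10^cf[4L]
    ok <- is.finite(K) && K >= freqs[1L] / 10 && K <= freqs[nF] * 10 &&
      is.finite(s) && s > 0
    if (ok) {
      values[["KNEE"]] <- K
      values[["S"]] <- s
      # for this model S(HW) - NY = A/2 exactly at HW = KNEE
      values[["HW"]] <- K
      values[["DR"]] <- log10((A + NYfit) / NYfit)
      converged[] <- TRUE
    }
  }
  if (is.na(values[["DR"]]))
    values[["DR"]] <- log10(max(spectrum) / nyObs)

  # secondary slope: log-log fit over the top half-decade below Nyquist
  top <- freqs >= freqs[nF] / 10^0.5
  if (sum(top) >= 2L)
    values[["SF"]] <- unname(stats::coef(
      stats::lm(log10(spectrum[top]) ~ log10(freqs[top])))[2L])

  structure(list(values = values, converged = converged),
            class = "PreconditionSet")
}

#' Drug-induced precondition changes
#'
#' Differences between the post-treatment (assay endpoint) and baseline
#' precondition sets: scale-type quantities (KNEE, HW, NY, BSB) as log10
#' ratios post/pre, the dimensionless or already-logarithmic quantities
#' (NSD, DR, S, SF, NCNT) as arithmetic differences. Preconditions whose
#' fit did not converge on either side yield an imputed delta of 0, marked
#' in the `imputed` attribute.
#'
#' @param pre,post `PreconditionSet` objects from [fitPreconditions()].
#' @return named numeric vector of 9 deltas (`dNSD`, `dBSB`, `dNCNT`,
#'   `dDR`, `dNY`, `dKNEE`, `dHW`, `dS`, `dSF`) with logical attribute
#'   `imputed`.
#' @export
preconditionDeltas <- function(pre, post) {
  stopifnot(inherits(pre, "PreconditionSet"),
            inherits(post, "PreconditionSet"))
  vPre <- pre$values; vPost <- post$values
  ratio <- c("KNEE", "HW", "NY", "BSB")
  diffs <- c("NSD", "DR", "S", "SF", "NCNT")
  out <- c(
    stats::setNames(vPost[diffs] - vPre[diffs], paste0("d", diffs)),
    stats::setNames(log10(vPost[ratio] / vPre[ratio]), paste0("d", ratio)))
  ord <- paste0("d", c("NSD", "BSB", "NCNT", "DR", "NY", "KNEE", "HW",
                       "S", "SF"))
  out <- out[ord]
  imputed <- !is.finite(out)
  out[imputed] <- 0
  attr(out, "imputed") <- imputed
  out
}
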