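#' Discrete orthonormal (Gram) polynomials on a point set
#'
#' Orthonormalizes the monomials 1, x, ..., x^maxOrder against the discrete
#' inner product on the supplied points — the discrete analogue of the
#' Legendre polynomials, exactly orthonormal on the grid. Sign convention:
#' each polynomial is positive at the largest point.
#'
#' @param x evaluation points (length > maxOrder).
#' @param maxOrder highest polynomial order.
#' @return matrix `length(x) x (maxOrder + 1)`, column `j` holding order
#'   `j - 1`.
#' @keywords internal
discreteLegendre <- function(x, maxOrder = 2L) {
  if (length(x) <= maxOrder)
    stop("need more points than the polynomial order")
  # map to [-1, 1] for conditioning
  xm <- 2 * (x - min(x)) / (max(x) - min(x)) - 1
  V <- outer(xm, 0:maxOrder, `^`)
  Q <- qr.Q(qr(V))
  for (j in seq_len(ncol(Q)))
    if (Q[length(xm), j] < 0) Q[, j] <- -Q[, j]
  Q
}

.newMask <- function(name, family, weights, timeOrder, freqOrder = NA,
                     band = NA) {
  structure(list(name = name, family = family, weights = weights,
                 timeOrder = timeOrder, freqOrder = freqOrder, band = band),
            class = "FilterMask")
}

#' Global time-frequency filter masks
#'
#' Builds the 9 global biomarker filters: tensor products of low-order
#' (0, 1, 2) discrete Legendre polynomials along the post-dose loop axis and
#' along the log10-frequency axis, each normalized to unit norm under the
#' grid inner product. Because the discrete polynomials are exactly
#' orthonormal on the grid, the 9 masks have an identity Gram matrix.
#'
#' @param grid a [TimeFrequencyGrid-class] with at least 3 post-dose loops
#'   and 3 frequencies.
#' @return list of 9 `FilterMask` objects named `glob.t{i}f{j}`.
#' @export
#' @examples
#' length(buildGlobalMasks(timeFrequencyGrid()))
buildGlobalMasks <- function(grid) {
  nP <- postDoseLoops(grid)
  f <- frequencies(grid)
  if (nP < 3L || length(f) < 3L)
    stop("grid must have >= 3 post-dose loops and >= 3 frequencies")
  Pt <- discreteLegendre(seq_len(nP), 2L)
  Pf <- discreteLegendre(log10(f), 2L)
  masks <- list()
  for (i in 0:2) for (j in 0:2) {
    w <- Pt[, i + 1L] %o% Pf[, j + 1L]
    nm <- sprintf("glob.t%df%d", i, j)
    masks[[nm]] <- .newMask(nm, "global", w, i, j)
  }
  masks
}

#' Local band filter masks
#'
#' Builds the 9 local biomarker filters: indicator functions of the low
#' (rheology), mid and high (organelle-transport) frequency bands crossed
#' with order 0, 1, 2 discrete Legendre time dependence, unit-normalized.
#' Masks from different bands have disjoint frequency support and are
#' therefore mutually orthogonal.
#'
#' @param grid a [TimeFrequencyGrid-class].
#' @param bandEdges increasing edges of the three bands in Hz; defaults to
#'   the named spectral bands 10-100 mHz, 100 mHz-1 Hz and 1-10 Hz.
#' @return list of 9 `FilterMask` objects named `loc.{low,mid,high}.t{i}`.
#' @export
buildLocalMasks <- function(grid, bandEdges = c(0.01, 0.1, 1, 10)) {
  if (length(bandEdges) != 4L || any(diff(bandEdges) <= 0))
    stop("bandEdges must be 4 strictly increasing values (non-overlapping bands)")
  nP <- postDoseLoops(grid)
  f <- frequencies(grid)
  if (nP < 3L) stop("grid must have >= 3 post-dose loops")
  Pt <- discreteLegendre(seq_len(nP), 2L)
  bandNames <- c("low", "mid", "high")
  masks <- list()
  for (b in 1:3) {
    inBand <- f >= bandEdges[b] & f < bandEdges[b + 1L]
    if (sum(inBand) < 1L)
      stop(sprintf("band '%s' contains no grid frequencies", bandNames[b]))
    ind <- as.numeric(inBand)
    for (i in 0:2) {
      w <- Pt[, i + 1L] %o% ind
      w <- w / sqrt(sum(w^2))
      nm <- sprintf("loc.%s.t%d", bandNames[b], i)
      masks[[nm]] <- .newMask(nm, "local", w, i, band = bandNames[b])
    }
  }
  masks
}

#' Project a spectrogram onto filter masks
#'
#' Grid inner product of the drug-response matrix with each filter mask:
#' `feature_k = sum_{t, omega} mask_k(t, omega) * D(t, omega)`.
#'
#' @param spgm a [DrugResponseSpectrogram-class] or a bare post-dose loops
#'   x frequencies matrix.
#' @param masks list of `FilterMask` objects from [buildGlobalMasks()] /
#'   [buildLocalMasks()].
#' @return named numeric vector, one coefficient per mask.
#' @export
projectSpectrogram <- function(spgm, masks) {
  D <- if (is(spgm, "DrugResponseSpectrogram")) spgm@D else spgm
  vapply(masks, function(m) {
    if (!identical(dim(m$weights), dim(D)))
      stop("mask and spectrogram dimensions do not match")
    sum(m$weights * D)
  }, numeric(1L))
}
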