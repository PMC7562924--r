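#' Correlation contrast between two feature vectors
#'
#' Cosine similarity down-weighted when the two vectors' magnitudes
#' mismatch: `S_AB = (2 sqrt(beta) / (1 + beta)) * (A.B) / (|A| |B|)` with
#' `beta = |A| / |B|`. The prefactor is invariant under `beta -> 1/beta`,
#' so the measure is symmetric, lies in [-1, 1], and equals the cosine only
#' when the magnitudes match (`beta = 1`). Motivated by fringe contrast in
#' interferometry.
#'
#' @param a,b nonzero numeric vectors of equal length.
#' @return similarity in [-1, 1].
#' @export
#' @examples
#' correlationContrast(1:4, 1:4)        # 1
#' correlationContrast(1:4, -(1:4))     # -1
#' correlationContrast(1:4, (1:4) / 2)  # 2*sqrt(2)/3
correlationContrast <- function(a, b) {
  if (length(a) != length(b)) stop("vectors must have equal length")
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0)
    stop("correlation contrast is undefined for a zero vector")
  beta <- na / nb
  (2 * sqrt(beta) / (1 + beta)) * sum(a * b) / (na * nb)
}

#' Pairwise correlation-contrast similarity matrix
#'
#' All pairwise correlation contrasts between patient feature vectors, with
#' unit diagonal. When `groups` is supplied the rows are ordered
#' resistant, metastatic, sensitive, and clustered within each group by
#' average-linkage agglomeration on the dissimilarity `1 - S`.
#'
#' @param X numeric matrix, patients x features, rownames = patient ids.
#' @param groups optional character vector per patient with values
#'   `"resistant"`, `"metastatic"`, `"sensitive"` controlling display
#'   order.
#' @return symmetric similarity matrix with entries in [-1, 1].
#' @export
similarityMatrix <- function(X, groups = NULL) {
  n <- nrow(X)
  if (n < 2L) stop("need at least 2 vectors")
  S <- diag(1, n)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n)
    S[i, j] <- S[j, i] <- correlationContrast(X[i, ], X[j, ])
  dimnames(S) <- list(rownames(X), rownames(X))

  if (!is.null(groups)) {
    ord <- integer()
    for (gLevel in c("resistant", "metastatic", "sensitive")) {
      idx <- which(groups == gLevel)
      if (length(idx) > 2L) {
        d <- stats::as.dist(1 - S[idx, idx])
        idx <- idx[stats::hclust(d, method = "average")$order]
      }
      ord <- c(ord, idx)
    }
    ord <- c(ord, setdiff(seq_len(n), ord))
    S <- S[ord, ord]
  }
  S
}

#' k-neighbor adjacency network from a similarity matrix
#'
#' Links each node to the `k` nodes with which it shares the highest
#' similarity (self excluded; ties broken stably by node order). The
#' directed adjacency retains each node's out-links; the undirected view is
#' the union symmetrization.
#'
#' @param S symmetric similarity matrix.
#' @param k number of neighbors (default 3; must be < number of nodes).
#' @return list with `directed` and `undirected` binary adjacency matrices
#'   and `k`.
#' @export
kNeighborAdjacency <- function(S, k = 3L) {
  n <- nrow(S)
  if (k >= n) stop("k must be smaller than the number of nodes")
  A <- matrix(0L, n, n, dimnames = dimnames(S))
  for (i in seq_len(n)) {
    sims <- S[i, ]
    sims[i] <- -Inf
    nb <- order(sims, decreasing = TRUE)[seq_len(k)]
    A[i, nb] <- 1L
  }
  list(directed = A, undirected = pmax(A, t(A)), k = as.integer(k))
}
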