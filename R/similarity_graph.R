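#' Metric-weighted squared distance between two mutation profiles
#'
#' Computes `(a - b)' diag(feature_weights) (a - b)`: a squared Euclidean
#' distance in which each coordinate (here, each tumor sample) contributes
#' proportionally to its weight. With unit weights on binary vectors this is
#' the Hamming distance.
#'
#' @param a,b numeric vectors of equal length.
#' @param feature_weights nonnegative weights, one per coordinate; default
#'   all ones.
#' @return nonnegative scalar.
#' @export
weighted_sq_distance <- function(a, b, feature_weights = rep(1, length(a))) {
  if (length(a) != length(b) || length(a) != length(feature_weights)) {
    stop("a, b and feature_weights must have equal lengths", call. = FALSE)
  }
  if (any(feature_weights < 0)) {
    stop("feature_weights must be nonnegative", call. = FALSE)
  }
  d <- a - b
  sum(feature_weights * d * d)
}

#' Gaussian kernel similarity from a squared distance
#'
#' `exp(-sq_dist / (2 * sigma^2))`: 1 at zero distance, decaying
#' monotonically with distance at a rate set by the bandwidth `sigma`.
#'
#' @param sq_dist nonnegative squared distance (vectorized).
#' @param sigma positive bandwidth.
#' @return similarity in (0, 1].
#' @export
gaussian_similarity <- function(sq_dist, sigma) {
  if (!is.numeric(sigma) || length(sigma) != 1 || sigma <= 0) {
    stop("sigma must be a positive scalar", call. = FALSE)
  }
  if (any(sq_dist < 0)) stop("sq_dist must be nonnegative", call. = FALSE)
  exp(-sq_dist / (2 * sigma^2))
}

# All pairwise weighted squared distances between gene columns of X.
# t(X) diag(w) X via a crossprod; clip tiny negatives from cancellation.
pairwise_sq_dist <- function(X, feature_weights) {
  G <- crossprod(sqrt(feature_weights) * X)
  q <- diag(G)
  D2 <- outer(q, q, `+`) - 2 * G
  D2[D2 < 0] <- 0
  D2
}

#' Build the gene similarity graph and its Laplacian
#'
#' Genes are the nodes: similarity between two genes is the Gaussian kernel
#' of the sample-weighted squared distance between their mutation profiles
#' (columns of `X`). The graph Laplacian `L = diag(D) - S`, with `D` the row
#' sums of `S`, supplies the smoothness penalty `Tr(Z' L Z)` that encourages
#' similar genes to receive similar low-dimensional coefficients.
#'
#' When the factorization's adaptive sample weights are available they are
#' passed as `feature_weights`, so that down-weighted (outlier) samples also
#' contribute less to gene-gene similarity.
#'
#' @param X a [mutation_matrix()] or samples-by-genes numeric matrix with at
#'   least 2 gene columns.
#' @param feature_weights nonnegative per-sample weights; default all ones.
#' @param sigma positive bandwidth, or `"median"` (default) for the median
#'   heuristic: sigma is the square root of the median nonzero pairwise
#'   weighted squared distance. If every pairwise distance is zero the
#'   bandwidth falls back to 1 with a warning.
#' @param self_loops keep unit self-similarity on the diagonal (default
#'   TRUE). The Laplacian is unchanged either way because the diagonal
#'   contributes equally to `D` and `S`.
#' @return a `similarity_graph`: list with `S` (p x p similarity), `degrees`
#'   (row sums of `S`), `laplacian` (`diag(degrees) - S`) and `sigma`.
#' @export
build_graph <- function(X, feature_weights = NULL, sigma = "median",
                        self_loops = TRUE) {
  X <- mm_values(X)
  p <- ncol(X)
  if (p < 2) stop("need at least 2 genes to build a graph", call. = FALSE)
  if (is.null(feature_weights)) feature_weights <- rep(1, nrow(X))
  if (length(feature_weights) != nrow(X) || any(feature_weights < 0)) {
    stop("feature_weights must be nonnegative with one entry per sample",
         call. = FALSE)
  }
  D2 <- pairwise_sq_dist(X, feature_weights)
  if (identical(sigma, "median")) {
    nz <- D2[upper.tri(D2)]
    nz <- nz[nz > 0]
    if (length(nz) == 0) {
      warning("all pairwise distances are zero; falling back to sigma = 1")
      sigma <- 1
    } else {
      sigma <- sqrt(stats::median(nz))
    }
  }
  S <- gaussian_similarity(D2, sigma)
  if (!self_loops) diag(S) <- 0
  degrees <- rowSums(S)
  L <- diag(degrees, nrow = p) - S
  dimnames(S) <- dimnames(L) <- list(colnames(X), colnames(X))
  names(degrees) <- colnames(X)
  structure(list(S = S, degrees = degrees, laplacian = L, sigma = sigma),
            class = "similarity_graph")
}

#' @export
print.similarity_graph <- function(x, ...) {
  cat(sprintf("similarity_graph: %d genes, sigma = %.4g, mean similarity = %.4g\n",
              nrow(x$S), x$sigma, mean(x$S[upper.tri(x$S)])))
  invisible(x)
}
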