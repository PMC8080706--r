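#' Construct a binary somatic mutation matrix
#'
#' A `mutation_matrix` is a samples-by-genes 0/1 matrix: entry `(s, g)` is 1
#' iff gene `g` carries at least one qualifying somatic mutation in sample
#' `s`. Rows are named by sample identifiers, columns by gene symbols. With
#' this orientation each gene's mutation profile across the cohort is a
#' column vector, which is the object the factorization embeds.
#'
#' @param values numeric or logical matrix with entries in \{0, 1\}.
#' @param samples character vector of unique sample identifiers (defaults to
#'   `rownames(values)`).
#' @param genes character vector of unique gene symbols (defaults to
#'   `colnames(values)`).
#' @return an integer matrix of class `mutation_matrix` with `samples` as row
#'   names and `genes` as column names.
#' @examples
#' X <- mutation_matrix(matrix(c(1, 0, 0, 1), 2, 2),
#'                      samples = c("S1", "S2"), genes = c("TP53", "PIK3CA"))
#' @export
mutation_matrix <- function(values, samples = rownames(values),
                            genes = colnames(values)) {
  values <- as.matrix(values)
  if (is.logical(values)) storage.mode(values) <- "integer"
  if (!is.numeric(values)) {
    stop("mutation matrix values must be numeric 0/1", call. = FALSE)
  }
  bad <- which(!(values %in% c(0, 1)))
  if (length(bad) > 0) {
    i <- arrayInd(bad[1], dim(values))
    stop(sprintf("non-binary value %s at row %d, column %d",
                 format(values[bad[1]]), i[1], i[2]), call. = FALSE)
  }
  if (is.null(samples)) samples <- paste0("S", seq_len(nrow(values)))
  if (is.null(genes)) genes <- paste0("G", seq_len(ncol(values)))
  samples <- as.character(samples)
  genes <- as.character(genes)
  if (length(samples) != nrow(values) || length(genes) != ncol(values)) {
    stop("identifier lengths do not match matrix dimensions", call. = FALSE)
  }
  if (anyDuplicated(samples)) {
    stop(sprintf("duplicate sample identifier: %s",
                 samples[duplicated(samples)][1]), call. = FALSE)
  }
  if (anyDuplicated(genes)) {
    stop(sprintf("duplicate gene symbol: %s",
                 genes[duplicated(genes)][1]), call. = FALSE)
  }
  storage.mode(values) <- "integer"
  dimnames(values) <- list(samples, genes)
  class(values) <- c("mutation_matrix", class(matrix()))
  values
}

#' @export
print.mutation_matrix <- function(x, ...) {
  cat(sprintf("mutation_matrix: %d samples x %d genes, %d mutated entries (%.2f%%)\n",
              nrow(x), ncol(x), sum(x), 100 * mean(x)))
  invisible(x)
}

# Strip the class so linear algebra sees a plain numeric matrix.
mm_values <- function(X) {
  X <- unclass(X)
  storage.mode(X) <- "double"
  X
}

#' Drop genes with too few mutated samples
#'
#' Filtering is an explicit preprocessing step, never silent: genes mutated
#' in fewer than `min_count` samples (default: genes never mutated) are
#' removed and the removal is reported via a message.
#'
#' @param X a [mutation_matrix()].
#' @param min_count minimum number of mutated samples a gene must have to be
#'   kept (default 1, i.e. drop all-zero gene columns).
#' @return the filtered `mutation_matrix`.
#' @export
filter_genes <- function(X, min_count = 1) {
  stopifnot(min_count >= 0)
  counts <- colSums(unclass(X))
  keep <- counts >= min_count
  if (!all(keep)) {
    message(sprintf("filter_genes: dropped %d of %d genes with < %d mutated samples",
                    sum(!keep), length(keep), min_count))
  }
  if (sum(keep) == 0) stop("no genes left after filtering", call. = FALSE)
  mutation_matrix(unclass(X)[, keep, drop = FALSE])
}
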