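#' Per-gene mutation scores from the coefficient matrix
#'
#' Each gene's learned coefficient vector (a row of `Z`) summarizes how
#' strongly the gene loads on each latent subgroup dimension. The default
#' score is the maximum coordinate: under the sparsity pressure of the
#' model a driver gene loads dominantly on one dimension, so the dominant
#' coordinate carries both its strength (score) and its subgroup identity.
#' The L2 norm and the coordinate sum are available as alternatives.
#'
#' @param Z nonnegative genes-by-k coefficient matrix.
#' @param method `"max"` (default), `"l2"` or `"sum"`.
#' @return named nonnegative score vector, one per gene.
#' @export
gene_scores <- function(Z, method = c("max", "l2", "sum")) {
  method <- match.arg(method)
  Z <- as.matrix(Z)
  if (any(Z < 0)) stop("Z must be nonnegative", call. = FALSE)
  s <- switch(method,
              max = apply(Z, 1, max),
              l2  = sqrt(rowSums(Z^2)),
              sum = rowSums(Z))
  stats::setNames(s, rownames(Z))
}

#' Rank genes by descending mutation score
#'
#' Ties are broken by ascending gene symbol (C-locale byte order) so output
#' is deterministic.
#'
#' @param genes character vector of gene symbols.
#' @param scores matching numeric scores.
#' @param subgroups optional matching integer subgroup labels (e.g. from
#'   [assign_subgroups()]); defaults to `NA`.
#' @return a `gene_ranking` data frame with columns `gene`, `score`,
#'   `rank`, `subgroup`, ordered by rank.
#' @export
rank_genes <- function(genes, scores, subgroups = NULL) {
  if (length(genes) != length(scores)) {
    stop("genes and scores must have equal lengths", call. = FALSE)
  }
  if (is.null(subgroups)) subgroups <- rep(NA_integer_, length(genes))
  if (length(subgroups) != length(genes)) {
    stop("subgroups must match genes in length", call. = FALSE)
  }
  ord <- order(-scores, genes, method = "radix")
  structure(data.frame(gene = as.character(genes)[ord],
                       score = as.numeric(scores)[ord],
                       rank = seq_along(genes),
                       subgroup = as.integer(subgroups)[ord],
                       stringsAsFactors = FALSE),
            class = c("gene_ranking", "data.frame"))
}

#' Top-n candidate driver genes
#'
#' The first `n` genes of a ranking. The pipeline's standard candidate list
#' sizes are 100, 200 and 500, with 500 the default.
#'
#' @param ranking a `gene_ranking` from [rank_genes()].
#' @param n positive candidate list size, at most the number of genes.
#' @return character vector of `n` gene symbols in rank order.
#' @export
top_candidates <- function(ranking, n = 500) {
  stopifnot(inherits(ranking, "gene_ranking"), n >= 1)
  if (n > nrow(ranking)) {
    stop(sprintf("n = %d exceeds the number of ranked genes (%d)",
                 n, nrow(ranking)), call. = FALSE)
  }
  ranking$gene[order(ranking$rank)][seq_len(n)]
}

#' Assign each gene to a latent subgroup
#'
#' A gene's subgroup is the subspace dimension on which its coefficient
#' vector loads most strongly (`argmax` over the row of `Z`); ties go to the
#' lowest dimension index. Genes with an all-zero coefficient vector are
#' unassigned and labelled 0.
#'
#' @param Z nonnegative genes-by-k coefficient matrix.
#' @return integer labels in `0..k`, named by gene when `Z` has row names.
#' @export
assign_subgroups <- function(Z) {
  Z <- as.matrix(Z)
  if (any(Z < 0)) stop("Z must be nonnegative", call. = FALSE)
  labels <- max.col(Z, ties.method = "first")
  labels[rowSums(Z) == 0] <- 0L
  stats::setNames(as.integer(labels), rownames(Z))
}
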