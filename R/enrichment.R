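#' Upper-tail hypergeometric probability
#'
#' `P(X >= x)` when `n` genes are drawn without replacement from a universe
#' of `N` genes of which `K` belong to the benchmark set:
#' `sum_{j=x}^{min(K,n)} C(K,j) C(N-K, n-j) / C(N,n)`. Terms are accumulated
#' in log space (via `lchoose` and a log-sum-exp) so the tail is stable for
#' genome-scale universes.
#'
#' @param N universe size.
#' @param K benchmark-set size within the universe.
#' @param n candidate-list size.
#' @param x observed overlap.
#' @return probability in (0, 1].
#' @export
hypergeom_upper_tail <- function(N, K, n, x) {
  if (K < 0 || K > N || n < 0 || n > N || x < 0 || x > min(K, n)) {
    stop(sprintf("infeasible counts: N=%d K=%d n=%d x=%d", N, K, n, x),
         call. = FALSE)
  }
  if (x == 0) return(1)
  j <- x:min(K, n)
  j <- j[n - j <= N - K]          # terms with impossible complements vanish
  if (length(j) == 0) return(0)
  logs <- lchoose(K, j) + lchoose(N - K, n - j) - lchoose(N, n)
  mx <- max(logs)
  exp(mx) * sum(exp(logs - mx))
}

#' Test the overlap of a candidate list with one benchmark set
#'
#' The benchmark set is first intersected with the universe (genes absent
#' from the mutation matrix cannot be recovered by any candidate list, so
#' counting them would only deflate power), then the upper-tail
#' hypergeometric probability of the observed overlap is computed.
#'
#' @param candidates character vector of candidate driver genes, a subset of
#'   `universe`.
#' @param benchmark character vector of benchmark genes.
#' @param universe character vector of all genes eligible for selection
#'   (the genes of the filtered mutation matrix).
#' @param set_name optional label carried into the result.
#' @return an `overlap_result`: list with `set_name`, `universe_size`,
#'   `set_size`, `candidates_size`, `overlap`, `p_value`, `overlap_genes`.
#' @export
test_overlap <- function(candidates, benchmark, universe, set_name = NA) {
  universe <- unique(as.character(universe))
  if (length(universe) == 0) stop("universe must be non-empty", call. = FALSE)
  candidates <- unique(as.character(candidates))
  if (!all(candidates %in% universe)) {
    stop("candidates must be a subset of the universe", call. = FALSE)
  }
  bench <- intersect(unique(as.character(benchmark)), universe)
  hit <- intersect(candidates, bench)
  structure(list(set_name = set_name,
                 universe_size = length(universe),
                 set_size = length(bench),
                 candidates_size = length(candidates),
                 overlap = length(hit),
                 p_value = hypergeom_upper_tail(length(universe),
                                                length(bench),
                                                length(candidates),
                                                length(hit)),
                 overlap_genes = sort(hit, method = "radix")),
            class = "overlap_result")
}

#' Benchmark a candidate list against a gene-set collection
#'
#' Runs [test_overlap()] for every set and summarizes the per-set p-values.
#' The headline summary is the unadjusted arithmetic mean of the per-set
#' p-values (the conventional "average p-value" comparison statistic for
#' candidate driver lists); the minimum p-value and Benjamini–Hochberg
#' adjusted p-values are reported alongside but never folded into the mean.
#'
#' @param candidates character vector of candidate genes.
#' @param collection a `gene_set_collection` from [read_gene_sets()].
#' @param universe character vector of eligible genes.
#' @return list with `results` (data frame: one row per set with columns
#'   `set_name`, `universe_size`, `set_size`, `candidates_size`, `overlap`,
#'   `p_value`, `p_adjusted`, `overlap_genes`) and `summary` (list with
#'   `mean_p`, `min_p`, `n_sets`).
#' @export
benchmark_report <- function(candidates, collection, universe) {
  stopifnot(inherits(collection, "gene_set_collection"))
  if (length(collection$sets) == 0) {
    stop("gene-set collection is empty", call. = FALSE)
  }
  rows <- lapply(names(collection$sets), function(nm) {
    r <- test_overlap(candidates, collection$sets[[nm]], universe,
                      set_name = nm)
    data.frame(set_name = nm, universe_size = r$universe_size,
               set_size = r$set_size, candidates_size = r$candidates_size,
               overlap = r$overlap, p_value = r$p_value,
               overlap_genes = paste(r$overlap_genes, collapse = ","),
               stringsAsFactors = FALSE)
  })
  results <- do.call(rbind, rows)
  results$p_adjusted <- stats::p.adjust(results$p_value, method = "BH")
  results <- results[c("set_name", "universe_size", "set_size",
                       "candidates_size", "overlap", "p_value",
                       "p_adjusted", "overlap_genes")]
  list(results = results,
       summary = list(mean_p = mean(results$p_value),
                      min_p = min(results$p_value),
                      n_sets = nrow(results)))
}

#' Count genes shared between two candidate lists
#'
#' Used to compare the candidate lists of different prioritization methods.
#'
#' @param list_a,list_b character vectors of gene symbols.
#' @return list with `n_shared` and the sorted `shared_genes`.
#' @export
pairwise_overlap_count <- function(list_a, list_b) {
  shared <- sort(intersect(unique(as.character(list_a)),
                           unique(as.character(list_b))), method = "radix")
  list(n_shared = length(shared), shared_genes = shared)
}
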