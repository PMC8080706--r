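#' Specification of a synthetic heterogeneous cohort
#'
#' The generator emulates the setting the method targets: a cohort split
#' into latent subgroups, each with its own driver genes mutated at an
#' elevated rate within the subgroup, on top of a low background passenger
#' rate; a fraction of outlier samples whose mutations ignore gene identity
#' entirely; and a fraction of noisy genes mutated at a high rate across all
#' subgroups (mimicking long or hypermutable passenger genes).
#'
#' @param n_samples number of tumor samples (default 120).
#' @param n_genes number of genes (default 400).
#' @param k_subgroups number of latent subgroups (default 4).
#' @param drivers_per_subgroup planted drivers per subgroup (default 10).
#' @param driver_rate_in within-subgroup mutation probability of a driver
#'   (default 0.5).
#' @param background_rate passenger / out-of-subgroup mutation probability
#'   (default 0.02).
#' @param outlier_sample_fraction fraction of samples that are outliers
#'   (default 0.05).
#' @param outlier_sample_rate mutation probability of every gene in an
#'   outlier sample (default 0.3).
#' @param noisy_gene_fraction fraction of non-driver genes that are noisy
#'   (default 0.05).
#' @param noisy_gene_rate mutation probability of a noisy gene in every
#'   non-outlier sample (default 0.3).
#' @param seed integer seed; the cohort is fully determined by it.
#' @return a list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_samples = 120, n_genes = 400, k_subgroups = 4,
                        drivers_per_subgroup = 10, driver_rate_in = 0.5,
                        background_rate = 0.02,
                        outlier_sample_fraction = 0.05,
                        outlier_sample_rate = 0.3,
                        noisy_gene_fraction = 0.05,
                        noisy_gene_rate = 0.3, seed = 1) {
  rates <- c(driver_rate_in, background_rate, outlier_sample_fraction,
             outlier_sample_rate, noisy_gene_fraction, noisy_gene_rate)
  if (any(rates < 0) || any(rates > 1)) {
    stop("all rates and fractions must lie in [0, 1]", call. = FALSE)
  }
  if (driver_rate_in <= background_rate) {
    stop("driver_rate_in must exceed background_rate", call. = FALSE)
  }
  stopifnot(n_samples >= 1, n_genes >= 1, k_subgroups >= 1,
            drivers_per_subgroup >= 0)
  if (k_subgroups * drivers_per_subgroup > n_genes) {
    stop("k_subgroups * drivers_per_subgroup exceeds n_genes", call. = FALSE)
  }
  structure(list(n_samples = as.integer(n_samples),
                 n_genes = as.integer(n_genes),
                 k_subgroups = as.integer(k_subgroups),
                 drivers_per_subgroup = as.integer(drivers_per_subgroup),
                 driver_rate_in = driver_rate_in,
                 background_rate = background_rate,
                 outlier_sample_fraction = outlier_sample_fraction,
                 outlier_sample_rate = outlier_sample_rate,
                 noisy_gene_fraction = noisy_gene_fraction,
                 noisy_gene_rate = noisy_gene_rate,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Simulate a heterogeneous mutation cohort with known truth
#'
#' Samples are partitioned near-evenly into `k_subgroups`; each subgroup
#' owns a disjoint block of driver genes. Entry `(s, g)` is Bernoulli with
#' probability `outlier_sample_rate` if `s` is an outlier (overriding gene
#' identity), else `noisy_gene_rate` if `g` is noisy, else `driver_rate_in`
#' if `g` drives `s`'s subgroup, else `background_rate`. The same seed
#' always yields the same cohort.
#'
#' @param spec a [cohort_spec()].
#' @return list with `matrix` (a [mutation_matrix()]) and `truth` (list with
#'   `sample_subgroups`, `driver_genes` — one character vector per
#'   subgroup —, `noisy_genes`, `outlier_samples`).
#' @export
simulate_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  m <- spec$n_samples; p <- spec$n_genes; k <- spec$k_subgroups
  samples <- sprintf("S%03d", seq_len(m))
  genes <- sprintf("G%04d", seq_len(p))
  subgroups <- rep(seq_len(k), length.out = m)
  driver_idx <- seq_len(k * spec$drivers_per_subgroup)
  driver_genes <- if (spec$drivers_per_subgroup > 0) {
    split(genes[driver_idx],
          rep(seq_len(k), each = spec$drivers_per_subgroup))
  } else {
    rep(list(character(0)), k)
  }
  names(driver_genes) <- paste0("subgroup", seq_len(k))

  withr::with_seed(spec$seed, {
    non_driver <- setdiff(seq_len(p), driver_idx)
    n_noisy <- min(round(spec$noisy_gene_fraction * p), length(non_driver))
    noisy_idx <- sort(non_driver[sample.int(length(non_driver), n_noisy)])
    n_out <- round(spec$outlier_sample_fraction * m)
    outlier_idx <- sort(sample.int(m, n_out))

    rates <- matrix(spec$background_rate, m, p)
    for (g in seq_len(k)) {
      rows <- which(subgroups == g)
      cols <- match(driver_genes[[g]], genes)
      rates[rows, cols] <- spec$driver_rate_in
    }
    if (length(noisy_idx) > 0) rates[, noisy_idx] <- spec$noisy_gene_rate
    if (length(outlier_idx) > 0) rates[outlier_idx, ] <- spec$outlier_sample_rate
    vals <- matrix(stats::rbinom(m * p, 1L, as.vector(rates)), m, p)
  })

  truth <- list(sample_subgroups = stats::setNames(subgroups, samples),
                driver_genes = driver_genes,
                noisy_genes = genes[noisy_idx],
                outlier_samples = samples[outlier_idx])
  list(matrix = mutation_matrix(vals, samples = samples, genes = genes),
       truth = truth)
}

#' Write a simulated cohort to disk
#'
#' Emits the mutation matrix as TSV, the planted truth as JSON, and the
#' per-subgroup driver sets as a GMT file so the enrichment step can be
#' exercised end-to-end against known positives.
#'
#' @param cohort a [simulate_cohort()] result.
#' @param dir output directory (created if needed).
#' @return the paths written, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(matrix = file.path(dir, "mutation_matrix.tsv"),
             truth = file.path(dir, "truth.json"),
             gmt = file.path(dir, "driver_sets.gmt"))
  write_matrix_tsv(cohort$matrix, paths[["matrix"]])
  jsonlite::write_json(cohort$truth, paths[["truth"]],
                       auto_unbox = FALSE, digits = NA)
  write_gene_sets(cohort$truth$driver_genes, paths[["gmt"]])
  invisible(paths)
}

#' Driver-recovery metrics against the planted truth
#'
#' Precision and recall of the top `n_top` ranked genes against the union of
#' planted drivers, plus the adjusted Rand index (ARI) between the ranking's
#' subgroup labels — restricted to the planted drivers — and the planted
#' driver-subgroup membership. The ARI is chance-corrected: 1 means perfect
#' subgroup recovery, 0 is the expectation under random labelling.
#'
#' @param ranking a `gene_ranking` from [rank_genes()], covering the
#'   cohort's (filtered) genes with subgroup labels.
#' @param truth the `truth` element of a [simulate_cohort()] result.
#' @param n_top size of the candidate list to evaluate.
#' @return list with `precision`, `recall`, `ari`, `n_top`, `n_drivers`.
#' @export
recovery_metrics <- function(ranking, truth, n_top) {
  stopifnot(inherits(ranking, "gene_ranking"))
  if (n_top > nrow(ranking)) {
    stop(sprintf("n_top = %d exceeds the number of ranked genes (%d)",
                 n_top, nrow(ranking)), call. = FALSE)
  }
  drivers <- unlist(truth$driver_genes, use.names = FALSE)
  top <- top_candidates(ranking, n_top)
  hit <- intersect(top, drivers)
  true_labels <- rep(seq_along(truth$driver_genes),
                     lengths(truth$driver_genes))
  names(true_labels) <- drivers
  present <- drivers[drivers %in% ranking$gene]
  pred_labels <- ranking$subgroup[match(present, ranking$gene)]
  ari <- if (length(present) >= 2 && !anyNA(pred_labels)) {
    mclust::adjustedRandIndex(true_labels[present], pred_labels)
  } else NA_real_
  list(precision = length(hit) / n_top,
       recall = length(hit) / length(drivers),
       ari = ari, n_top = n_top, n_drivers = length(drivers))
}
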