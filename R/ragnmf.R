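#' Solver configuration
#'
#' Collects the hyperparameters of the factorization. Notation used
#' throughout the package (the literature is inconsistent, so names follow
#' roles): `U` is the samples-by-k basis, `Z` the genes-by-k coefficients,
#' `W` the diagonal per-gene instance weights and `M` the diagonal
#' per-sample feature weights. `W` and `M` live on scaled simplices: they
#' are nonnegative and sum to the budgets `C_w` and `C_m`.
#'
#' @param k subspace dimension (default 4, the pipeline's standard setting
#'   for breast-cancer cohorts).
#' @param lambda_graph nonnegative weight of the graph smoothness penalty
#'   `Tr(Z' L Z)`. The default 0.01 makes the penalty commensurate with the
#'   residual term for a dense Gaussian gene graph, whose degrees grow with
#'   the number of genes.
#' @param alpha positive ridge on the instance weights `W`, or `NULL`
#'   (default) for scale calibration: `alpha` is frozen at `auto_scale`
#'   times the mean per-gene residual cost at the first weight update.
#'   Small values let the weights concentrate on low-residual genes and
#'   zero out the hard-to-fit ones (drivers included); large values keep
#'   the weights uniform and the robustness inert. Calibrating to the cost
#'   scale keeps informative genes weighted while noisy genes are
#'   suppressed, analogous to the median heuristic for the kernel
#'   bandwidth.
#' @param beta positive ridge on the feature weights `M`, or `NULL` for the
#'   same calibration against per-sample costs; same role for samples.
#' @param auto_scale multiplier used when `alpha` or `beta` is `NULL`
#'   (default 2).
#' @param C_w,C_m positive weight budgets; `NULL` (default) means the number
#'   of genes / samples respectively, so uniform weights equal 1 and the
#'   unweighted objective is recovered as a special case.
#' @param max_iter maximum outer iterations.
#' @param tol relative-objective convergence tolerance:
#'   `|f_t - f_(t-1)| / max(f_(t-1), 1e-12) < tol` stops the loop.
#' @param seed integer seed for the random initialization of `U` and `Z`.
#' @param mode `"ragnmf"` (default, adaptive weights), `"gnmf"` (weights
#'   frozen uniform; plain graph-regularized NMF) or `"driversub"` (weights
#'   frozen uniform plus an L1 sparsity penalty `lambda_z * sum|Z|` and a
#'   Frobenius penalty `lambda_w * ||U||^2`).
#' @param lambda_z,lambda_w nonnegative penalties used only in
#'   `mode = "driversub"`.
#' @param sigma graph bandwidth, or `"median"` (default) for the median
#'   heuristic; see [build_graph()].
#' @param refresh_graph rebuild the gene graph with the current feature
#'   weights at the start of every outer iteration (default TRUE). With
#'   FALSE the iteration-0 graph is reused, which fixes the objective
#'   function and makes the outer loop provably non-increasing.
#' @param accelerate use Nesterov-style extrapolation on `U` and `Z` with
#'   restart on objective increase (default FALSE: plain alternating
#'   updates).
#' @return a list of class `ragnmf_config`.
#' @export
ragnmf_config <- function(k = 4, lambda_graph = 0.01, alpha = NULL,
                          beta = NULL, auto_scale = 2,
                          C_w = NULL, C_m = NULL, max_iter = 500,
                          tol = 1e-6, seed = 1,
                          mode = c("ragnmf", "gnmf", "driversub"),
                          lambda_z = 0.1, lambda_w = 0.1,
                          sigma = "median", refresh_graph = TRUE,
                          accelerate = FALSE) {
  mode <- match.arg(mode)
  stopifnot(k >= 1, k == as.integer(k), lambda_graph >= 0,
            max_iter >= 1, tol > 0, lambda_z >= 0, lambda_w >= 0,
            auto_scale > 0)
  if (!is.null(alpha) && alpha <= 0) {
    stop("alpha must be positive (or NULL for auto calibration)",
         call. = FALSE)
  }
  if (!is.null(beta) && beta <= 0) {
    stop("beta must be positive (or NULL for auto calibration)",
         call. = FALSE)
  }
  if (!is.null(C_w)) stopifnot(C_w > 0)
  if (!is.null(C_m)) stopifnot(C_m > 0)
  structure(list(k = as.integer(k), lambda_graph = lambda_graph,
                 alpha = alpha, beta = beta, auto_scale = auto_scale,
                 C_w = C_w, C_m = C_m,
                 max_iter = as.integer(max_iter), tol = tol,
                 seed = as.integer(seed), mode = mode,
                 lambda_z = lambda_z, lambda_w = lambda_w, sigma = sigma,
                 refresh_graph = isTRUE(refresh_graph),
                 accelerate = isTRUE(accelerate)),
            class = "ragnmf_config")
}

EPS_DENOM <- 1e-12

check_factor_shapes <- function(X, U, Z, W, M) {
  m <- nrow(X); p <- ncol(X)
  if (nrow(U) != m || nrow(Z) != p || ncol(U) != ncol(Z) ||
      length(W) != p || length(M) != m) {
    stop("inconsistent factor shapes", call. = FALSE)
  }
  invisible(TRUE)
}

#' Evaluate the weighted factorization objective
#'
#' `sum_{s,g} M_s W_g (X - U Z')_{sg}^2 + lambda_graph * Tr(Z' L Z)
#'  + alpha * sum(W^2) + beta * sum(M^2)`, i.e. a doubly weighted squared
#' residual in which gene weights `W` and sample weights `M` modulate each
#' entry's contribution, plus the graph smoothness penalty and ridge terms
#' on the weights. In `mode = "driversub"` the L1 and Frobenius penalties
#' `lambda_z * sum|Z| + lambda_w * sum(U^2)` are added.
#'
#' @param X samples-by-genes matrix (a [mutation_matrix()] or plain matrix).
#' @param U,Z,W,M factors and weights; see [ragnmf_config()] for roles.
#' @param graph a [build_graph()] result, required when `lambda_graph > 0`.
#' @param config a [ragnmf_config()].
#' @return nonnegative scalar.
#' @export
ragnmf_objective <- function(X, U, Z, W, M, graph = NULL,
                             config = ragnmf_config()) {
  X <- mm_values(X)
  check_factor_shapes(X, U, Z, W, M)
  if (anyNA(U) || anyNA(Z) || anyNA(W) || anyNA(M)) {
    stop("NaN in factorization state", call. = FALSE)
  }
  if (is.null(config$alpha) || is.null(config$beta)) {
    stop("alpha and beta must be numeric here; auto calibration is resolved by ragnmf_fit()",
         call. = FALSE)
  }
  R <- X - tcrossprod(U, Z)
  value <- sum(M * drop((R * R) %*% W)) +
    config$alpha * sum(W^2) + config$beta * sum(M^2)
  if (config$lambda_graph > 0) {
    if (is.null(graph)) stop("graph required when lambda_graph > 0",
                             call. = FALSE)
    value <- value + config$lambda_graph * sum(Z * (graph$laplacian %*% Z))
  }
  if (config$mode == "driversub") {
    value <- value + config$lambda_z * sum(Z) + config$lambda_w * sum(U^2)
  }
  value
}

#' Multiplicative update of the basis U
#'
#' `U <- U * (diag(M) X diag(W) Z) / (diag(M) U Z' diag(W) Z)`, elementwise,
#' with the denominator floored at 1e-12. This is the weighted analogue of
#' the classical NMF basis update; at an exact factorization the ratio is 1
#' and `U` is a fixed point. `lambda_w > 0` adds the gradient of a Frobenius
#' penalty to the denominator (used by the driversub mode).
#'
#' @inheritParams ragnmf_objective
#' @param lambda_w nonnegative Frobenius penalty on `U` (default 0).
#' @return updated basis, same shape as `U`, nonnegative.
#' @export
update_basis <- function(X, U, Z, W, M, lambda_w = 0) {
  X <- mm_values(X)
  check_factor_shapes(X, U, Z, W, M)
  WZ <- W * Z
  num <- M * (X %*% WZ)
  den <- M * (U %*% crossprod(Z, WZ))
  if (lambda_w > 0) den <- den + lambda_w * U
  U * num / pmax(den, EPS_DENOM)
}

#' Multiplicative update of the coefficients Z
#'
#' `Z <- Z * (diag(W) X' diag(M) U + lambda S Z) /
#'          (diag(W) Z U' diag(M) U + lambda diag(D) Z)`, elementwise, with
#' the denominator floored at 1e-12. The Laplacian `L = D - S` is split so
#' that the similarity matrix `S` lands in the numerator and the degree
#' matrix `D` in the denominator, keeping every factor nonnegative — the
#' standard multiplicative form for a `Tr(Z' L Z)` penalty.
#'
#' @inheritParams ragnmf_objective
#' @param lambda_graph nonnegative graph-penalty weight.
#' @return updated coefficients, same shape as `Z`, nonnegative.
#' @export
update_coefficients <- function(X, U, Z, W, M, graph = NULL,
                                lambda_graph = 0) {
  X <- mm_values(X)
  check_factor_shapes(X, U, Z, W, M)
  MU <- M * U
  num <- W * (crossprod(X, MU))
  den <- W * (Z %*% crossprod(U, MU))
  if (lambda_graph > 0) {
    if (is.null(graph)) stop("graph required when lambda_graph > 0",
                             call. = FALSE)
    num <- num + lambda_graph * (graph$S %*% Z)
    den <- den + lambda_graph * (graph$degrees * Z)
  }
  Z * num / pmax(den, EPS_DENOM)
}

#' Per-gene weighted residual costs
#'
#' `E_g = sum_s M_s (X - U Z')_{sg}^2`: the diagonal of
#' `R' diag(M) R`. These costs drive the instance-weight update — genes the
#' current factorization explains poorly get large costs and hence small
#' weights.
#'
#' @inheritParams ragnmf_objective
#' @return nonnegative vector of length `ncol(X)`.
#' @export
instance_weight_costs <- function(X, U, Z, M) {
  X <- mm_values(X)
  R <- X - tcrossprod(U, Z)
  drop(crossprod(R * R, M))
}

#' Per-sample weighted residual costs
#'
#' `E_s = sum_g W_g (X - U Z')_{sg}^2`: the diagonal of `R diag(W) R'`,
#' mirroring [instance_weight_costs()] with genes and samples swapped.
#'
#' @inheritParams ragnmf_objective
#' @return nonnegative vector of length `nrow(X)`.
#' @export
feature_weight_costs <- function(X, U, Z, W) {
  X <- mm_values(X)
  R <- X - tcrossprod(U, Z)
  drop((R * R) %*% W)
}

#' Euclidean projection onto a scaled simplex
#'
#' Returns `argmin_{w >= 0, sum(w) = budget} ||w - v||^2` by the exact
#' sorting algorithm: sort `v` decreasingly, find the largest support size
#' whose water-filling threshold keeps all retained entries positive, and
#' clip the rest to zero.
#'
#' @param v numeric vector.
#' @param budget positive sum constraint.
#' @return nonnegative vector summing to `budget`.
#' @export
project_to_scaled_simplex <- function(v, budget) {
  if (!is.numeric(budget) || length(budget) != 1 || budget <= 0) {
    stop("budget must be a positive scalar", call. = FALSE)
  }
  u <- sort(v, decreasing = TRUE)
  css <- cumsum(u)
  idx <- seq_along(u)
  rho <- max(which(u + (budget - css) / idx > 0))
  theta <- (css[rho] - budget) / rho
  pmax(v - theta, 0)
}

#' Update the instance (gene) weights
#'
#' Solves `min_W sum_g E_g W_g + alpha * sum(W^2)` subject to `W >= 0`,
#' `sum(W) = C_w` exactly: completing the square reduces it to the Euclidean
#' projection of `-E / (2 alpha)` onto the scaled simplex. Genes with larger
#' residual costs receive smaller weights.
#'
#' @param costs per-gene residual costs from [instance_weight_costs()].
#' @param alpha positive ridge parameter.
#' @param budget weight budget `C_w`.
#' @return new weight vector on the scaled simplex.
#' @export
update_instance_weights <- function(costs, alpha, budget = length(costs)) {
  stopifnot(alpha > 0)
  project_to_scaled_simplex(-costs / (2 * alpha), budget)
}

#' Update the feature (sample) weights
#'
#' Same subproblem as [update_instance_weights()] with samples in place of
#' genes and `beta`, `C_m` in place of `alpha`, `C_w`.
#'
#' @param costs per-sample residual costs from [feature_weight_costs()].
#' @param beta positive ridge parameter.
#' @param budget weight budget `C_m`.
#' @return new weight vector on the scaled simplex.
#' @export
update_feature_weights <- function(costs, beta, budget = length(costs)) {
  stopifnot(beta > 0)
  project_to_scaled_simplex(-costs / (2 * beta), budget)
}

#' Fit the robust adaptive graph-regularized factorization
#'
#' Alternating outer loop: (1) optionally rebuild the gene graph with the
#' current sample weights, (2) multiplicative update of the basis `U`,
#' (3) multiplicative update of the coefficients `Z`, (4) exact
#' simplex-constrained update of the gene weights `W`, (5) exact update of
#' the sample weights `M`, (6) record the objective. The loop stops when the
#' relative objective change (against the previous iteration, or against the
#' initial state for the first iteration) drops below `tol` or after
#' `max_iter` iterations. `U` and `Z` are initialized uniform(0, 1) + 0.1 under the
#' configured seed so multiplicative updates stay strictly positive; `W`
#' and `M` start uniform on their budgets.
#'
#' In `mode = "gnmf"` steps 4–5 are skipped and the weights stay uniform; in
#' `mode = "driversub"` the weights also stay uniform, the coefficient
#' update is followed by soft-thresholding at `lambda_z`, and `lambda_w`
#' enters the basis-update denominator.
#'
#' @param X a [mutation_matrix()] (binary, filtered) or plain
#'   samples-by-genes matrix.
#' @param config a [ragnmf_config()].
#' @return a list of class `ragnmf_fit` with elements `U`, `Z`, `W`, `M`,
#'   `objective_history`, `n_iter`, `converged`, `graph`, `config`,
#'   `samples`, `genes`.
#' @examples
#' cohort <- simulate_cohort(cohort_spec(n_samples = 30, n_genes = 60,
#'                                       k_subgroups = 2, seed = 7))
#' fit <- ragnmf_fit(cohort$matrix, ragnmf_config(k = 2, max_iter = 30))
#' head(gene_scores(fit$Z))
#' @export
ragnmf_fit <- function(X, config = ragnmf_config()) {
  Xv <- mm_values(X)
  m <- nrow(Xv); p <- ncol(Xv); k <- config$k
  if (k >= min(m, p)) {
    stop(sprintf("k = %d must be smaller than min(samples, genes) = %d",
                 k, min(m, p)), call. = FALSE)
  }
  C_w <- if (is.null(config$C_w)) p else config$C_w
  C_m <- if (is.null(config$C_m)) m else config$C_m
  adapt <- config$mode == "ragnmf"
  alpha <- config$alpha
  beta <- config$beta
  if (!adapt) {
    # weights stay uniform: the ridge terms are additive constants, so the
    # calibration scale is immaterial
    if (is.null(alpha)) alpha <- 1
    if (is.null(beta)) beta <- 1
  }

  init <- withr::with_seed(config$seed, list(
    U = matrix(stats::runif(m * k), m, k) + 0.1,
    Z = matrix(stats::runif(p * k), p, k) + 0.1
  ))
  U <- init$U; Z <- init$Z
  W <- rep(C_w / p, p)
  M <- rep(C_m / m, m)
  graph <- if (config$lambda_graph > 0) {
    build_graph(Xv, feature_weights = M, sigma = config$sigma)
  } else NULL

  history <- numeric(0)
  converged <- FALSE
  U_prev <- U; Z_prev <- Z
  t_prev <- 1
  # baseline objective at the initial state, used by the first convergence
  # check (not recorded in the history)
  cfg0 <- config
  cfg0$alpha <- if (is.null(alpha)) 0 else alpha
  cfg0$beta <- if (is.null(beta)) 0 else beta
  obj_prev <- ragnmf_objective(Xv, U, Z, W, M, graph = graph, config = cfg0)

  for (it in seq_len(config$max_iter)) {
    if (it > 1 && adapt && config$refresh_graph && config$lambda_graph > 0) {
      graph <- build_graph(Xv, feature_weights = M, sigma = config$sigma)
    }
    if (config$accelerate && it > 1) {
      t_cur <- (1 + sqrt(1 + 4 * t_prev^2)) / 2
      gamma <- (t_prev - 1) / t_cur
      U_in <- pmax(U + gamma * (U - U_prev), EPS_DENOM)
      Z_in <- pmax(Z + gamma * (Z - Z_prev), EPS_DENOM)
    } else {
      t_cur <- 1
      U_in <- U; Z_in <- Z
    }
    U_prev <- U; Z_prev <- Z

    lw <- if (config$mode == "driversub") config$lambda_w else 0
    U_new <- update_basis(Xv, U_in, Z_in, W, M, lambda_w = lw)
    Z_new <- update_coefficients(Xv, U_new, Z_in, W, M, graph = graph,
                                 lambda_graph = config$lambda_graph)
    if (config$mode == "driversub") {
      Z_new <- pmax(Z_new - config$lambda_z, 0)
    }
    if (adapt) {
      EM <- instance_weight_costs(Xv, U_new, Z_new, M)
      if (is.null(alpha)) alpha <- config$auto_scale * mean(EM)
      W <- update_instance_weights(EM, alpha, C_w)
      EW <- feature_weight_costs(Xv, U_new, Z_new, W)
      if (is.null(beta)) beta <- config$auto_scale * mean(EW)
      M <- update_feature_weights(EW, beta, C_m)
    }
    cfg_res <- config
    cfg_res$alpha <- alpha; cfg_res$beta <- beta
    obj <- ragnmf_objective(Xv, U_new, Z_new, W, M, graph = graph,
                            config = cfg_res)
    if (!is.finite(obj)) {
      stop(sprintf("objective is not finite at iteration %d", it),
           call. = FALSE)
    }
    if (config$accelerate && it > 1 && obj > obj_prev) {
      # restart: redo this iteration from the un-extrapolated point
      U_new <- update_basis(Xv, U_prev, Z_prev, W, M, lambda_w = lw)
      Z_new <- update_coefficients(Xv, U_new, Z_prev, W, M, graph = graph,
                                   lambda_graph = config$lambda_graph)
      if (config$mode == "driversub") Z_new <- pmax(Z_new - config$lambda_z, 0)
      if (adapt) {
        W <- update_instance_weights(instance_weight_costs(Xv, U_new, Z_new, M),
                                     alpha, C_w)
        M <- update_feature_weights(feature_weight_costs(Xv, U_new, Z_new, W),
                                    beta, C_m)
      }
      obj <- ragnmf_objective(Xv, U_new, Z_new, W, M, graph = graph,
                              config = cfg_res)
      t_cur <- 1
    }
    U <- U_new; Z <- Z_new
    t_prev <- t_cur
    history <- c(history, obj)
    if (abs(obj - obj_prev) / max(obj_prev, 1e-12) < config$tol) {
      converged <- TRUE
      break
    }
    obj_prev <- obj
  }

  dimnames(U) <- list(rownames(Xv), paste0("dim", seq_len(k)))
  dimnames(Z) <- list(colnames(Xv), paste0("dim", seq_len(k)))
  config$alpha <- alpha
  config$beta <- beta
  structure(list(U = U, Z = Z, W = stats::setNames(W, colnames(Xv)),
                 M = stats::setNames(M, rownames(Xv)),
                 objective_history = history, n_iter = length(history),
                 converged = converged, graph = graph, config = config,
                 samples = rownames(Xv), genes = colnames(Xv)),
            class = "ragnmf_fit")
}

#' @export
print.ragnmf_fit <- function(x, ...) {
  cat(sprintf(
    "ragnmf_fit (mode = %s): %d samples x %d genes, k = %d\n  %d iteration(s), %s, final objective %.6g\n",
    x$config$mode, nrow(x$U), nrow(x$Z), x$config$k, x$n_iter,
    if (x$converged) "converged" else "max_iter reached",
    x$objective_history[x$n_iter]))
  invisible(x)
}

#' Save a fitted model as a plain-text checkpoint
#'
#' Writes a directory with `U.tsv`, `Z.tsv`, `weights.tsv` (gene weights),
#' `sample_weights.tsv`, `config.json` and `history.json`, so a fit can be
#' archived and reloaded without binary serialization.
#'
#' @param fit a [ragnmf_fit()] result.
#' @param dir output directory (created if needed).
#' @export
save_model <- function(fit, dir) {
  stopifnot(inherits(fit, "ragnmf_fit"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_named_matrix <- function(mat, path, id) {
    df <- data.frame(rownames(mat), mat, check.names = FALSE)
    colnames(df) <- c(id, paste0("dim", seq_len(ncol(mat))))
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write_named_matrix(fit$U, file.path(dir, "U.tsv"), "sample")
  write_named_matrix(fit$Z, file.path(dir, "Z.tsv"), "gene")
  utils::write.table(data.frame(gene = names(fit$W), weight = fit$W),
                     file.path(dir, "weights.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(sample = names(fit$M), weight = fit$M),
                     file.path(dir, "sample_weights.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  cfg <- fit$config
  class(cfg) <- NULL
  jsonlite::write_json(cfg, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  jsonlite::write_json(list(objective_history = fit$objective_history,
                            n_iter = fit$n_iter, converged = fit$converged),
                       file.path(dir, "history.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Load a checkpoint written by [save_model()]
#'
#' @param dir checkpoint directory.
#' @return a list of class `ragnmf_fit` (without the graph, which is
#'   rebuildable from the data).
#' @export
load_model <- function(dir) {
  read_named_matrix <- function(path) {
    df <- utils::read.delim(path, check.names = FALSE,
                            colClasses = c("character"))
    mat <- as.matrix(df[, -1, drop = FALSE])
    storage.mode(mat) <- "double"
    rownames(mat) <- df[[1]]
    mat
  }
  U <- read_named_matrix(file.path(dir, "U.tsv"))
  Z <- read_named_matrix(file.path(dir, "Z.tsv"))
  wdf <- utils::read.delim(file.path(dir, "weights.tsv"),
                           colClasses = c("character", "numeric"))
  mdf <- utils::read.delim(file.path(dir, "sample_weights.tsv"),
                           colClasses = c("character", "numeric"))
  cfg <- jsonlite::read_json(file.path(dir, "config.json"),
                             simplifyVector = TRUE)
  cfg <- do.call(ragnmf_config, cfg[!vapply(cfg, is.null, logical(1))])
  hist <- jsonlite::read_json(file.path(dir, "history.json"),
                              simplifyVector = TRUE)
  structure(list(U = U, Z = Z,
                 W = stats::setNames(wdf$weight, wdf$gene),
                 M = stats::setNames(mdf$weight, mdf$sample),
                 objective_history = hist$objective_history,
                 n_iter = hist$n_iter, converged = hist$converged,
                 graph = NULL, config = cfg,
                 samples = rownames(U), genes = rownames(Z)),
            class = "ragnmf_fit")
}
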