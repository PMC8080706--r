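make_cfg <- function(...) ragnmf_config(...)

test_that("objective is zero at an exact factorization and matches the residual formula", {
  st <- random_state(4, 6, 2, seed = 1)
  X <- tcrossprod(st$U, st$Z)     # exact product, not binary: shapes only
  cfg <- make_cfg(k = 2, lambda_graph = 0, alpha = 0.4, beta = 0.6)
  ridge_const <- 0.4 * sum(st$W^2) + 0.6 * sum(st$M^2)
  expect_equal(ragnmf_objective(X, st$U, st$Z, st$W, st$M, config = cfg),
               ridge_const, tolerance = 1e-14)  # residual term is exactly 0

  # zero factors: residual is X itself
  Xb <- random_binary_matrix(4, 6, seed = 2)
  U0 <- matrix(0, 4, 2); Z0 <- matrix(0, 6, 2)
  cfg2 <- make_cfg(k = 2, lambda_graph = 0, alpha = 0.7, beta = 1.3)
  expect_equal(ragnmf_objective(Xb, U0, Z0, st$W, st$M, config = cfg2),
               sum(st$M * (unclass(Xb)^2 %*% st$W)) +
                 0.7 * sum(st$W^2) + 1.3 * sum(st$M^2))
})

test_that("objective equals the elementwise double-loop oracle", {
  X <- random_binary_matrix(4, 5, seed = 9)
  st <- random_state(4, 5, 2, seed = 10)
  g <- build_graph(X, sigma = 1)
  cfg <- make_cfg(k = 2, lambda_graph = 0.3, alpha = 0.5, beta = 0.25)
  got <- ragnmf_objective(X, st$U, st$Z, st$W, st$M, graph = g, config = cfg)
  want <- objective_oracle(X, st$U, st$Z, st$W, st$M, lambda = 0.3,
                           L = g$laplacian, alpha = 0.5, beta = 0.25)
  expect_equal(got, want, tolerance = 1e-10)
})

test_that("basis and coefficient updates are fixed points at an exact factorization", {
  st <- random_state(5, 7, 2, seed = 4)
  X <- tcrossprod(st$U, st$Z)
  U2 <- update_basis(X, st$U, st$Z, st$W, st$M)
  expect_equal(U2, st$U, tolerance = 1e-10)
  Z2 <- update_coefficients(X, st$U, st$Z, st$W, st$M, lambda_graph = 0)
  expect_equal(Z2, st$Z, tolerance = 1e-10)
})

test_that("uniform weights recover the classical unweighted NMF updates", {
  X <- random_binary_matrix(6, 8, seed = 21)
  st <- random_state(6, 8, 3, seed = 22)
  W1 <- rep(1, 8); M1 <- rep(1, 6)
  expect_equal(update_basis(X, st$U, st$Z, W1, M1),
               nmf_basis_update_oracle(X, st$U, st$Z), tolerance = 1e-12)
  expect_equal(update_coefficients(X, st$U, st$Z, W1, M1, lambda_graph = 0),
               nmf_coef_update_oracle(X, st$U, st$Z), tolerance = 1e-12)
})

test_that("single multiplicative steps never increase their objective terms", {
  worst_u <- worst_z <- -Inf
  for (seed in 1:50) {
    X <- random_binary_matrix(6, 8, density = 0.35, seed = seed)
    st <- random_state(6, 8, 2, seed = seed + 500)
    g <- build_graph(X, sigma = 1)
    resid <- function(U, Z) sum(st$M * ((unclass(X) - tcrossprod(U, Z))^2 %*% st$W))
    before_u <- resid(st$U, st$Z)
    U2 <- update_basis(X, st$U, st$Z, st$W, st$M)
    after_u <- resid(U2, st$Z)
    worst_u <- max(worst_u, (after_u - before_u) / before_u)

    lossg <- function(Z) resid(U2, Z) + 0.2 * sum(Z * (g$laplacian %*% Z))
    before_z <- lossg(st$Z)
    Z2 <- update_coefficients(X, U2, st$Z, st$W, st$M, graph = g,
                              lambda_graph = 0.2)
    worst_z <- max(worst_z, (lossg(Z2) - before_z) / before_z)
  }
  expect_lt(worst_u, 1e-9)
  expect_lt(worst_z, 1e-9)
})

test_that("instance and feature costs match double-loop oracles", {
  X <- random_binary_matrix(4, 5, seed = 31)
  st <- random_state(4, 5, 2, seed = 32)
  R <- unclass(X) - tcrossprod(st$U, st$Z)
  EM <- numeric(5); EW <- numeric(4)
  for (g in 1:5) EM[g] <- sum(st$M * R[, g]^2)
  for (s in 1:4) EW[s] <- sum(st$W * R[s, ]^2)
  expect_equal(unname(instance_weight_costs(X, st$U, st$Z, st$M)), EM,
               tolerance = 1e-12)
  expect_equal(unname(feature_weight_costs(X, st$U, st$Z, st$W)), EW,
               tolerance = 1e-12)
  expect_equal(instance_weight_costs(X, st$U, st$Z, st$M) * 0,
               rep(0, 5), ignore_attr = TRUE)
  Xe <- tcrossprod(st$U, st$Z)
  expect_equal(unname(instance_weight_costs(Xe, st$U, st$Z, st$M)),
               rep(0, 5), tolerance = 1e-14)
})

test_that("simplex projection matches the active-set enumeration oracle", {
  expect_equal(project_to_scaled_simplex(c(0.2, 0.3, 0.5), 1),
               c(0.2, 0.3, 0.5))
  expect_equal(project_to_scaled_simplex(c(2, 0), 1), c(1, 0))
  for (seed in 1:40) {
    v <- withr::with_seed(seed, rnorm(sample(2:5, 1), sd = 2))
    budget <- withr::with_seed(seed + 1000, runif(1, 0.5, 3))
    got <- project_to_scaled_simplex(v, budget)
    expect_equal(sum(got), budget, tolerance = 1e-10)
    expect_true(all(got >= 0))
    expect_equal(got, simplex_projection_oracle(v, budget), tolerance = 1e-8)
  }
})

test_that("weight updates solve their simplex subproblems", {
  # constant costs -> uniform weights
  expect_equal(update_instance_weights(rep(3.3, 5), alpha = 0.5, budget = 5),
               rep(1, 5))
  # a dominant cost with small ridge -> that weight goes to zero
  w <- update_instance_weights(c(100, 1, 1, 1), alpha = 0.1, budget = 4)
  expect_equal(w[1], 0)
  # matches a projected-gradient numeric minimizer
  costs <- withr::with_seed(77, runif(6, 0, 5))
  got <- update_instance_weights(costs, alpha = 0.8, budget = 6)
  num <- weight_subproblem_oracle(costs, 0.8, 6)
  expect_equal(got, num, tolerance = 1e-6)
  # feature update mirrors the instance update under transposition
  expect_equal(update_feature_weights(costs, beta = 0.8, budget = 6), got)
})

test_that("feature-weight update equals the instance update on transposed data", {
  X <- random_binary_matrix(5, 7, seed = 41)
  st <- random_state(5, 7, 2, seed = 42)
  EW <- feature_weight_costs(X, st$U, st$Z, st$W)
  EM_t <- instance_weight_costs(t(unclass(X)), st$Z, st$U, st$W)
  expect_equal(unname(EW), unname(EM_t), tolerance = 1e-12)
})

test_that("fit recovers planted low-rank structure", {
  errs <- vapply(1:5, function(seed) {
    withr::with_seed(seed, {
      A <- matrix(rbinom(30 * 2, 1, 0.5), 30, 2)
      B <- matrix(rbinom(2 * 40, 1, 0.4), 2, 40)
    })
    X <- mutation_matrix((A %*% B) > 0)   # Boolean product of planted factors
    X <- suppressMessages(filter_genes(X))
    fit <- ragnmf_fit(X, ragnmf_config(k = 2, seed = seed, lambda_graph = 0,
                                       max_iter = 300, mode = "gnmf"))
    R <- unclass(X) - tcrossprod(fit$U, fit$Z)
    sqrt(sum(R^2) / sum(unclass(X)^2))
  }, numeric(1))
  expect_lt(mean(errs), 0.15)
})

test_that("fit honors the stopping contract and determinism", {
  X <- random_binary_matrix(10, 12, seed = 55)
  cfg <- ragnmf_config(k = 2, tol = Inf, seed = 3)
  one <- ragnmf_fit(X, cfg)
  expect_equal(one$n_iter, 1)  # tol=Inf stops after one outer iteration
  expect_true(one$converged)

  cfg2 <- ragnmf_config(k = 2, max_iter = 25, seed = 9)
  f1 <- ragnmf_fit(X, cfg2)
  f2 <- ragnmf_fit(X, cfg2)
  expect_identical(f1$objective_history, f2$objective_history)
  expect_identical(f1$Z, f2$Z)

  expect_error(ragnmf_fit(X, ragnmf_config(k = 10)), "must be smaller")
})

test_that("factors stay nonnegative and weights stay on their budgets", {
  for (seed in 1:10) {
    X <- random_binary_matrix(8, 10, density = 0.3, seed = seed)
    fit <- ragnmf_fit(X, ragnmf_config(k = 2, max_iter = 15, seed = seed))
    expect_true(all(fit$U >= 0) && all(fit$Z >= 0))
    expect_true(all(fit$W >= 0) && all(fit$M >= 0))
    expect_equal(sum(fit$W), 10, tolerance = 1e-8)
    expect_equal(sum(fit$M), 8, tolerance = 1e-8)
    expect_true(all(is.finite(fit$objective_history)))
  }
})

test_that("objective history is non-increasing with a fixed graph", {
  for (seed in 1:6) {
    X <- random_binary_matrix(12, 15, density = 0.3, seed = seed)
    fit <- ragnmf_fit(X, ragnmf_config(k = 2, alpha = 8, beta = 8,
                                       max_iter = 40, seed = seed,
                                       refresh_graph = FALSE))
    h <- fit$objective_history
    expect_true(all(diff(h) <= 1e-6 * utils::head(h, -1)))
  }
})

test_that("gnmf mode reproduces the plain graph-regularized objective", {
  for (seed in 1:5) {
    X <- random_binary_matrix(9, 11, density = 0.35, seed = seed)
    cfg <- ragnmf_config(k = 2, lambda_graph = 0.05, mode = "gnmf",
                         max_iter = 12, seed = seed, refresh_graph = FALSE)
    fit <- ragnmf_fit(X, cfg)
    R <- unclass(X) - tcrossprod(fit$U, fit$Z)
    g <- fit$graph
    plain <- sum(R^2) + 0.05 * sum(fit$Z * (g$laplacian %*% fit$Z))
    frozen <- fit$config$alpha * sum(fit$W^2) + fit$config$beta * sum(fit$M^2)
    # uniform weights equal 1 under the default budgets, so the weighted
    # residual coincides with the unweighted one
    expect_equal(fit$objective_history[fit$n_iter], plain + frozen,
                 tolerance = 1e-10)
    expect_equal(unname(fit$W), rep(1, 11))
    expect_equal(unname(fit$M), rep(1, 9))
  }
})

test_that("driversub mode sparsifies coefficients via soft-thresholding", {
  X <- random_binary_matrix(12, 16, density = 0.25, seed = 70)
  dense <- ragnmf_fit(X, ragnmf_config(k = 3, mode = "gnmf", lambda_graph = 0,
                                       max_iter = 40, seed = 70))
  sparse <- ragnmf_fit(X, ragnmf_config(k = 3, mode = "driversub",
                                        lambda_graph = 0, lambda_z = 0.05,
                                        lambda_w = 0.1, max_iter = 40,
                                        seed = 70))
  expect_gt(mean(sparse$Z == 0), mean(dense$Z == 0))
  expect_true(all(sparse$Z >= 0))
  expect_true(all(is.finite(sparse$objective_history)))
})

test_that("accelerated fitting reaches at least as good an objective", {
  X <- random_binary_matrix(15, 20, density = 0.3, seed = 81)
  plain <- ragnmf_fit(X, ragnmf_config(k = 3, max_iter = 60, seed = 81,
                                       refresh_graph = FALSE, alpha = 10,
                                       beta = 10))
  accel <- ragnmf_fit(X, ragnmf_config(k = 3, max_iter = 60, seed = 81,
                                       refresh_graph = FALSE, alpha = 10,
                                       beta = 10, accelerate = TRUE))
  expect_lt(tail(accel$objective_history, 1),
            tail(plain$objective_history, 1) * 1.05)
})

test_that("model checkpoints round-trip through the plain-text layout", {
  X <- random_binary_matrix(8, 10, seed = 90)
  fit <- ragnmf_fit(X, ragnmf_config(k = 2, max_iter = 10, seed = 90))
  dir <- withr::local_tempdir()
  save_model(fit, dir)
  back <- load_model(dir)
  expect_equal(back$U, fit$U, tolerance = 1e-12)
  expect_equal(back$Z, fit$Z, tolerance = 1e-12)
  expect_equal(back$W, fit$W, tolerance = 1e-12)
  expect_equal(back$objective_history, fit$objective_history,
               tolerance = 1e-12)
  expect_equal(back$config$k, fit$config$k)
})

test_that("noisy planted genes receive lower instance weights than clean genes", {
  hits <- 0
  for (seed in 1:10) {
    cohort <- simulate_cohort(cohort_spec(n_samples = 40, n_genes = 80,
                                          k_subgroups = 2,
                                          drivers_per_subgroup = 5,
                                          noisy_gene_fraction = 0.1,
                                          seed = seed))
    X <- suppressMessages(filter_genes(cohort$matrix))
    fit <- ragnmf_fit(X, ragnmf_config(k = 2, max_iter = 60, seed = seed))
    noisy <- intersect(cohort$truth$noisy_genes, fit$genes)
    clean <- setdiff(fit$genes,
                     c(noisy, unlist(cohort$truth$driver_genes)))
    if (mean(fit$W[noisy]) < mean(fit$W[clean])) hits <- hits + 1
  }
  expect_gte(hits, 9)
})
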