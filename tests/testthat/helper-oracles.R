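# Independent oracles: deliberately naive implementations (double loops,
# exhaustive enumeration, external exact arithmetic) that the fast
# vectorized code is checked against.

# Elementwise double-loop evaluation of the weighted objective.
objective_oracle <- function(X, U, Z, W, M, lambda = 0, L = NULL,
                             alpha = 0, beta = 0) {
  X <- unclass(X)
  total <- 0
  for (s in seq_len(nrow(X))) {
    for (g in seq_len(ncol(X))) {
      r <- X[s, g] - sum(U[s, ] * Z[g, ])
      total <- total + M[s] * W[g] * r^2
    }
  }
  if (lambda > 0) {
    graph_term <- 0
    for (a in seq_len(nrow(Z))) for (b in seq_len(nrow(Z))) {
      graph_term <- graph_term + L[a, b] * sum(Z[a, ] * Z[b, ])
    }
    total <- total + lambda * graph_term
  }
  total + alpha * sum(W^2) + beta * sum(M^2)
}

# Entry-by-entry Laplacian construction from first principles.
laplacian_oracle <- function(X, feature_weights, sigma) {
  X <- unclass(X)
  p <- ncol(X)
  S <- matrix(0, p, p)
  for (i in seq_len(p)) for (j in seq_len(p)) {
    d2 <- sum(feature_weights * (X[, i] - X[, j])^2)
    S[i, j] <- exp(-d2 / (2 * sigma^2))
  }
  D <- rowSums(S)
  diag(D) - S
}

# Exact simplex projection by enumerating every support set (feasible for
# length <= ~10): on each candidate support the equality-constrained
# minimizer is a water-filling shift; keep the feasible candidate closest
# to v.
simplex_projection_oracle <- function(v, budget) {
  q <- length(v)
  best <- NULL
  best_d <- Inf
  for (mask in seq_len(2^q - 1)) {
    active <- which(bitwAnd(mask, 2^(seq_len(q) - 1)) > 0)
    w <- numeric(q)
    w[active] <- v[active] + (budget - sum(v[active])) / length(active)
    if (any(w[active] < -1e-12)) next
    w[w < 0] <- 0
    d <- sum((w - v)^2)
    if (d < best_d) {
      best_d <- d
      best <- w
    }
  }
  best
}

# Projected-gradient minimizer of sum(costs * w) + ridge * sum(w^2) on the
# scaled simplex; independent of the closed-form route.
weight_subproblem_oracle <- function(costs, ridge, budget,
                                     iters = 20000, lr = NULL) {
  q <- length(costs)
  w <- rep(budget / q, q)
  if (is.null(lr)) lr <- 0.5 / ridge
  for (i in seq_len(iters)) {
    grad <- costs + 2 * ridge * w
    w <- project_to_scaled_simplex(w - lr * grad, budget)
  }
  w
}

# Classical unweighted multiplicative NMF updates (Lee & Seung form).
nmf_basis_update_oracle <- function(X, U, Z) {
  X <- unclass(X)
  U * (X %*% Z) / pmax(U %*% crossprod(Z), 1e-12)
}
nmf_coef_update_oracle <- function(X, U, Z) {
  X <- unclass(X)
  Z * (crossprod(X, U)) / pmax(Z %*% crossprod(U), 1e-12)
}

# Exact rational-arithmetic hypergeometric upper tails computed with
# Python's fractions module (arbitrary-precision integers). Returns a data
# frame with columns N, K, n, x, p for every feasible tuple with N in Ns.
exact_hypergeom_tails <- function(Ns) {
  script <- '
import sys
from fractions import Fraction
from math import comb
for N in [int(t) for t in sys.argv[1:]]:
    for K in range(0, N + 1):
        for n in range(0, N + 1):
            lo = max(0, n - (N - K)); hi = min(K, n)
            denom = comb(N, n)
            pmf = [Fraction(comb(K, lo) * comb(N - K, n - lo), denom)]
            for j in range(lo, hi):
                pmf.append(pmf[-1] * Fraction((K - j) * (n - j),
                                              (j + 1) * (N - K - n + j + 1)))
            tail = Fraction(0)
            tails = []
            for q in reversed(pmf):
                tail += q
                tails.append(tail)
            tails.reverse()
            for x in range(0, hi + 1):
                t = Fraction(1) if x <= lo else tails[x - lo]
                print(N, K, n, x, float(t))
'
  script_file <- tempfile(fileext = ".py")
  writeLines(script, script_file)
  on.exit(unlink(script_file))
  out <- system2("python", c(script_file, as.character(Ns)), stdout = TRUE)
  df <- read.table(text = out, col.names = c("N", "K", "n", "x", "p"))
  df
}
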