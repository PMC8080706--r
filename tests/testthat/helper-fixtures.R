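# Small seeded fixtures shared across test files.

random_binary_matrix <- function(m, p, density = 0.3, seed = 1) {
  withr::with_seed(seed, {
    vals <- matrix(rbinom(m * p, 1L, density), m, p)
  })
  mutation_matrix(vals,
                  samples = sprintf("S%02d", seq_len(m)),
                  genes = sprintf("G%02d", seq_len(p)))
}

random_state <- function(m, p, k, seed = 1) {
  withr::with_seed(seed, list(
    U = matrix(runif(m * k, 0.1, 1), m, k),
    Z = matrix(runif(p * k, 0.1, 1), p, k),
    W = {w <- runif(p, 0.2, 1); w * p / sum(w)},
    M = {mm <- runif(m, 0.2, 1); mm * m / sum(mm)}
  ))
}

tiny_gmt <- function(lines) {
  path <- withr::local_tempfile(fileext = ".gmt",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}
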