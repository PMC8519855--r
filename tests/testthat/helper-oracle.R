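# Brute-force oracles, independent of the package's vectorized permutation
# path: per-subject correlations via stats::cor on raw rows, and exhaustive
# enumeration over all n! subject relabelings.

all_perms <- function(v) {
  n <- length(v)
  if (n == 1L) return(matrix(v, 1L, 1L))
  do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(v[i], all_perms(v[-i]), deparse.level = 0)
  }))
}

# Mean within-subject similarity when subject i's X map is paired with
# subject perm[i]'s Y map.
oracle_a_stat <- function(x, y, perm = seq_len(nrow(x)), method = "pearson") {
  mean(vapply(seq_len(nrow(x)), function(i) {
    stats::cor(x[i, ], y[perm[i], ], method = method)
  }, numeric(1)))
}

# Exact permutation p-value over all n! relabelings (identity included).
oracle_exact_p <- function(x, y, method = "pearson",
                           sidedness = "two_sided") {
  perms <- all_perms(seq_len(nrow(x)))
  a_all <- apply(perms, 1L, function(p) oracle_a_stat(x, y, p, method))
  a0 <- oracle_a_stat(x, y, method = method)
  if (sidedness == "two_sided") mean(abs(a0) <= abs(a_all)) else mean(a0 <= a_all)
}

# Small coupled dataset: y rows share the subject-specific signal of x rows.
toy_coupled_dataset <- function(n = 8, v = 40, noise = 0.3, seed = 1) {
  withr::with_seed(seed, {
    x <- matrix(stats::rnorm(n * v), n, v)
    y <- x + matrix(stats::rnorm(n * v, sd = noise), n, v)
  })
  modality_dataset(x, y)
}

toy_null_dataset <- function(n = 8, v = 40, seed = 1) {
  withr::with_seed(seed, {
    x <- matrix(stats::rnorm(n * v), n, v)
    y <- matrix(stats::rnorm(n * v), n, v)
  })
  modality_dataset(x, y)
}
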