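# Independent brute-force oracles, kept free of package internals.

# Spearman rho by definition: Pearson correlation of mid-ranks.
oracle_spearman_rho <- function(x, y) {
  stats::cor(rank(x), rank(y))
}

# Exhaustive two-sided permutation p-value for Spearman rho, enumerating
# every ordering of y (n! cases) via recursion.
oracle_spearman_p <- function(x, y) {
  n <- length(y)
  perm_all <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perm_all(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    }
    out
  }
  obs <- abs(oracle_spearman_rho(x, y))
  rhos <- vapply(perm_all(seq_len(n)),
                 function(p) oracle_spearman_rho(x, y[p]), numeric(1))
  mean(abs(rhos) >= obs - 1e-12)
}

# Mann-Whitney U (for x) from mid-ranks.
oracle_mwu_u <- function(x, y) {
  r <- rank(c(x, y))
  sum(r[seq_along(x)]) - length(x) * (length(x) + 1) / 2
}

# Exhaustive two-sided permutation p-value for U, enumerating all group
# assignments; deviation measured from the null mean n1*n2/2.
oracle_mwu_p <- function(x, y) {
  n1 <- length(x)
  pooled <- c(x, y)
  n <- length(pooled)
  mu <- n1 * (n - n1) / 2
  idx <- utils::combn(n, n1)
  us <- apply(idx, 2, function(i) {
    r <- rank(pooled)
    sum(r[i]) - n1 * (n1 + 1) / 2
  })
  obs <- abs(oracle_mwu_u(x, y) - mu)
  mean(abs(us - mu) >= obs - 1e-12)
}

# Small noiseless survey bundle shared by pipeline tests.
noiseless_design <- function(seed = 1L, ...) {
  survey_design(n_stations = 2, depths_m = c(2, 10, 30),
                irms_sd_pct = 0, nanosims_counts = 1e9, qpcr_cv = 0,
                a_enriched_range = c(24.7, 24.7), seed = seed, ...)
}
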