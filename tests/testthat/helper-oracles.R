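# Independent oracles and small fixture builders shared across tests.

# random positive relative-quantity matrix
rand_rq <- function(n_samples, n_genes, seed, sd = 1) {
  set.seed(seed)
  m <- matrix(2^rnorm(n_samples * n_genes, 0, sd), n_samples, n_genes,
              dimnames = list(paste0("s", seq_len(n_samples)),
                              paste0("g", seq_len(n_genes))))
  m
}

# random Cq matrix in a realistic cycle range
rand_cq <- function(n_samples, n_genes, seed) {
  set.seed(seed)
  m <- matrix(runif(n_samples * n_genes, 15, 30), n_samples, n_genes,
              dimnames = list(paste0("s", seq_len(n_samples)),
                              paste0("g", seq_len(n_genes))))
  m
}

# brute-force double loop over all gene pairs (definition of M)
m_brute <- function(rq, base = 2) {
  n <- ncol(rq)
  out <- vapply(seq_len(n), function(j) {
    mean(vapply(setdiff(seq_len(n), j), function(k) {
      sd(log(rq[, j] / rq[, k], base = base))
    }, numeric(1)))
  }, numeric(1))
  names(out) <- colnames(rq)
  out
}

# Pearson correlation from the covariance definition
cor_brute <- function(x, y) {
  n <- length(x)
  sum((x - mean(x)) * (y - mean(y))) / ((n - 1) * sd(x) * sd(y))
}

# exhaustive two-sided permutation p-value on |difference of means|
perm_p <- function(x, y) {
  pooled <- c(x, y)
  nx <- length(x)
  splits <- utils::combn(length(pooled), nx)
  obs <- abs(mean(x) - mean(y))
  stats <- apply(splits, 2L, function(i) {
    abs(mean(pooled[i]) - mean(pooled[-i]))
  })
  mean(stats >= obs - 1e-12)
}
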