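test_that("log quantities are plain log2 with positivity checking", {
  expect_equal(unname(log_quantities(cbind(a = c(1, 0.25, 0.7),
                                           b = c(2, 4, 8)))[, 1]),
               c(0, -2, log2(0.7)))
  expect_equal(log2(0.7), -0.5146, tolerance = 1e-4)
  expect_error(log_quantities(cbind(a = c(1, 0))), "positive")
})

test_that("variance decomposition is zero for constant data and unbiased", {
  y <- matrix(rep(c(1, 2, 3, 4), each = 5), 5, 4,
              dimnames = list(paste0("s", 1:5), paste0("g", 1:4)))
  expect_equal(unname(variance_decomposition(y)[, 1]), rep(0, 4))

  # Monte-Carlo consistency: 9 genes, sigma^2 in {0.01, 0.04, 0.25}
  truth <- rep(c(0.01, 0.04, 0.25), each = 3)
  set.seed(41)
  est <- rowMeans(replicate(20, {
    y <- sapply(sqrt(truth), function(s) rnorm(2000, 0, s)) +
      rnorm(2000, 0, 0.3)  # per-sample loading, absorbed by centering
    colnames(y) <- paste0("g", 1:9)
    rownames(y) <- paste0("s", 1:2000)
    variance_decomposition(y)[, 1]
  }))
  expect_true(all(abs(est - truth) / truth < 0.1))
})

test_that("centering correction rescues a near-constant gene", {
  # two genes with large equal noise inflate the centered variance of a
  # third, almost constant gene; the correction must undo that
  set.seed(42)
  y <- cbind(g1 = rnorm(3000, 0, 0.8),
             g2 = rnorm(3000, 0, 0.8),
             g3 = rnorm(3000, 0, 0.01))
  rownames(y) <- paste0("s", 1:3000)
  z <- y - rowMeans(y)
  naive <- apply(z, 2, var)
  corrected <- variance_decomposition(y)[, 1]
  expect_gt(naive[["g3"]], 0.1)          # centering inflates the naive value
  expect_lt(corrected[["g3"]], 0.02)     # correction recovers ~0
  expect_equal(corrected[["g1"]], 0.64, tolerance = 0.15)
})

test_that("group differences are exact on noise-free shifts and shrink", {
  # a +1 log2 shift of one gene in one of two balanced groups: after the
  # across-gene centering a share 1/n of the shift leaks into every other
  # gene, so d = +/- (1/2)(1 - 1/n) for the shifted gene and -/+ 1/(2n)
  # for the rest, approaching +/- 0.5 as the panel grows
  for (n in c(3L, 11L)) {
    y <- matrix(0, 8, n, dimnames = list(paste0("s", 1:8), paste0("g", 1:n)))
    y[, "g2"] <- 5  # per-gene constant, must not create differences
    groups <- rep(c("A", "B"), each = 4)
    y[groups == "B", "g1"] <- y[groups == "B", "g1"] + 1
    gd <- group_differences(y, groups,
                            sigma2 = matrix(0, n, 2,
                                            dimnames = list(colnames(y), c("A", "B"))))
    expect_equal(unname(gd$d["g1", ]), c(-0.5, 0.5) * (1 - 1 / n),
                 tolerance = 1e-12)
    expect_equal(unname(gd$d["g2", ]), c(0.5, -0.5) / n, tolerance = 1e-12)
    # with zero measurement noise there is nothing to shrink
    expect_equal(gd$d_shrunk, gd$d, tolerance = 1e-12)
  }
  expect_equal(unname(gd$d["g1", ]), c(-0.5, 0.5), tolerance = 0.1)

  # as sigma2 -> Inf with fixed d, the shrunken difference -> 0
  y <- matrix(rnorm(8 * 11), 8, 11,
              dimnames = list(paste0("s", 1:8), paste0("g", 1:11)))
  groups <- rep(c("A", "B"), each = 4)
  big <- matrix(1e12, 11, 2,
                dimnames = list(colnames(y), c("A", "B")))
  gd_big <- group_differences(y, groups, sigma2 = big)
  expect_true(all(abs(gd_big$d_shrunk) < 1e-6))
  expect_error(group_differences(y, rep("A", 8)), "at least 2 groups")
})

test_that("balanced group differences sum to zero within each gene", {
  y <- log_quantities(rand_rq(12, 5, seed = 43))
  groups <- rep(c("A", "B", "C"), each = 4)
  gd <- group_differences(y, groups)
  expect_equal(unname(rowSums(gd$d)), rep(0, 5), tolerance = 1e-12)
})

test_that("stability values are invariant to sample and gene offsets", {
  rq <- rand_rq(12, 5, seed = 44)
  groups <- rep(c("A", "B"), each = 6)
  base <- normfinder_stability(rq, groups)$rho
  # per-sample constant on the log scale = per-sample factor on quantities
  shifted_samples <- sweep(rq, 1, 2^rnorm(12), "*")
  # per-gene constant = expression-level change
  shifted_genes <- sweep(rq, 2, 2^c(1, -2, 0.5, 3, 0), "*")
  expect_equal(normfinder_stability(shifted_samples, groups)$rho, base,
               tolerance = 1e-9)
  expect_equal(normfinder_stability(shifted_genes, groups)$rho, base,
               tolerance = 1e-9)
})

test_that("noise-free data yields zero stability values", {
  rq <- matrix(2^rep(c(0, 1, -1, 2), each = 6), 6, 4,
               dimnames = list(paste0("s", 1:6), paste0("g", 1:4)))
  res <- normfinder_stability(rq)
  expect_equal(unname(res$rho), rep(0, 4))
})

test_that("a noisy gene and a group-shifted gene take the two worst ranks", {
  hits <- 0L
  for (seed in 1:100) {
    set.seed(seed)
    n_g <- 10
    groups <- rep(c("A", "B"), each = n_g)
    y <- sapply(1:11, function(i) rnorm(2 * n_g, 0, 0.1))
    colnames(y) <- paste0("g", 1:11)
    rownames(y) <- paste0("s", 1:(2 * n_g))
    y[, "g1"] <- rnorm(2 * n_g, 0, 0.8)              # unstable gene
    y[groups == "B", "g2"] <- y[groups == "B", "g2"] + 1  # group shift
    res <- normfinder_stability(2^y, groups)
    worst2 <- res$ranking$gene[res$ranking$rank >= 10]
    if (setequal(worst2, c("g1", "g2"))) hits <- hits + 1L
  }
  expect_gte(hits, 95L)
})

test_that("grouped mode ranks a group-shifted gene below its twin", {
  set.seed(45)
  groups <- rep(c("A", "B"), each = 8)
  y <- sapply(1:5, function(i) rnorm(16, 0, 0.1))
  colnames(y) <- paste0("g", 1:5)
  rownames(y) <- paste0("s", 1:16)
  y[, "g2"] <- y[, "g1"]                       # identical twin of g1 ...
  y[groups == "B", "g2"] <- y[groups == "B", "g2"] + 0.8  # ... plus a shift
  res <- normfinder_stability(2^y, groups)
  r <- setNames(res$ranking$rank, res$ranking$gene)
  expect_gt(r[["g2"]], r[["g1"]])
})

test_that("degenerate inputs are rejected", {
  y <- log_quantities(rand_rq(6, 2, seed = 46))
  expect_error(variance_decomposition(y), "at least 3 genes")
  y3 <- log_quantities(rand_rq(3, 4, seed = 46))
  expect_error(variance_decomposition(y3, groups = c("A", "A", "B")),
               "at least 2 samples")
})
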