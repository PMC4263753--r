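#' Log2 expression values for model-based stability analysis
#'
#' @param rq positive samples-by-genes matrix of relative quantities.
#' @return matrix `y = log2(rq)`.
#' @export
log_quantities <- function(rq) {
  rq <- as.matrix(rq)
  if (any(rq <= 0)) stop("relative quantities must be positive")
  log2(rq)
}

#' Intra-group variance decomposition (NormFinder model)
#'
#' Within each group, every sample (row) of the log-expression matrix is
#' centered by its across-gene mean, which absorbs sample-wide loading
#' effects but couples the genes' apparent variances. With `n` genes, `v_ig`
#' the sample variance of gene i's centered values in group g, and
#' `V_g = sum_i v_ig`, the unbiased solution of the induced linear system is
#'
#'   `sigma2_ig = max(0, n/(n-2) * (v_ig - V_g / (n (n-1))))`
#'
#' (negative estimates are a small-sample artifact and truncated at 0).
#'
#' @param y samples-by-genes matrix of log2 expression (>= 3 genes).
#' @param groups vector/factor of group labels, one per row of `y`; every
#'   group needs at least 2 samples. `NULL` treats all samples as one group.
#' @return genes-by-groups matrix of variance estimates.
#' @export
variance_decomposition <- function(y, groups = NULL) {
  y <- as.matrix(y)
  n <- ncol(y)
  if (n < 3L)
    stop("the variance decomposition needs at least 3 genes")
  if (is.null(groups)) groups <- rep("all", nrow(y))
  groups <- as.factor(groups)
  if (length(groups) != nrow(y))
    stop("'groups' must assign every sample")
  if (any(table(groups) < 2L))
    stop("every group needs at least 2 samples")

  z <- y - rowMeans(y)
  sig <- sapply(levels(groups), function(g) {
    v <- apply(z[groups == g, , drop = FALSE], 2L, var)
    pmax(0, n / (n - 2) * (v - sum(v) / (n * (n - 1))))
  })
  sig <- matrix(sig, nrow = n,
                dimnames = list(colnames(y), levels(groups)))
  sig
}

#' Inter-group expression differences with shrinkage
#'
#' Per gene and group: the group mean of the sample-centered log expression
#' minus the average of the group means, `d_ig`. Because small groups give
#' noisy differences, each `d_ig` is shrunk toward 0 by the empirical-Bayes
#' factor `gamma2 / (gamma2 + sigma2_ig / n_g)`, where
#' `gamma2 = max(0, mean(d^2) - mean(sigma2_ig / n_g))` estimates the true
#' between-group variance of the differences.
#'
#' @param y samples-by-genes matrix of log2 expression.
#' @param groups group labels, one per row; at least 2 groups.
#' @param sigma2 genes-by-groups matrix from [variance_decomposition()]
#'   (computed if omitted).
#' @return list with genes-by-groups matrices `d` and `d_shrunk`, and the
#'   scalar `gamma2`.
#' @export
group_differences <- function(y, groups, sigma2 = NULL) {
  y <- as.matrix(y)
  groups <- as.factor(groups)
  if (nlevels(groups) < 2L)
    stop("inter-group differences need at least 2 groups")
  if (is.null(sigma2)) sigma2 <- variance_decomposition(y, groups)

  z <- y - rowMeans(y)
  gm <- sapply(levels(groups), function(g)
    colMeans(z[groups == g, , drop = FALSE]))
  d <- gm - rowMeans(gm)
  n_g <- as.numeric(table(groups)[colnames(d)])
  noise <- sweep(sigma2[rownames(d), colnames(d), drop = FALSE], 2L, n_g, "/")
  gamma2 <- max(0, mean(d^2) - mean(noise))
  # when both the prior and the noise variance vanish there is nothing to
  # estimate: shrink fully to 0 rather than divide 0 by 0
  shrink <- ifelse(gamma2 + noise > 0, gamma2 / (gamma2 + noise), 0)
  d_shrunk <- d * shrink
  list(d = d, d_shrunk = d_shrunk, gamma2 = gamma2)
}

#' NormFinder stability values
#'
#' Model-based stability estimation on log2 relative quantities. In grouped
#' mode (>= 2 groups, each with >= 2 samples) the stability value combines
#' the shrunken inter-group difference with the intra-group standard error:
#'
#'   `rho_i = (1/G) * sum_g ( |d_shrunk_ig| + sqrt(sigma2_ig / n_g) )`
#'
#' In ungrouped mode (`groups = NULL`, the default) it is simply
#' `rho_i = sqrt(sigma2_i)`. Lower values indicate more stable genes; the
#' ranking uses competition ranks on the exact values.
#'
#' @param rq positive samples-by-genes matrix of relative quantities
#'   (>= 3 genes).
#' @param groups optional group labels (e.g. time points), one per sample.
#' @return an object of class `normfinder_result`: list with `ranking`
#'   (data frame `gene`, `rank`, `rho`), `rho`, `sigma2`, and in grouped mode
#'   `d`, `d_shrunk`, `gamma2`; `mode` is `"grouped"` or `"ungrouped"`.
#' @export
normfinder_stability <- function(rq, groups = NULL) {
  y <- log_quantities(rq)
  grouped <- !is.null(groups) && nlevels(as.factor(groups)) >= 2L
  sigma2 <- variance_decomposition(y, groups)

  if (grouped) {
    groups <- as.factor(groups)
    gd <- group_differences(y, groups, sigma2)
    n_g <- as.numeric(table(groups)[colnames(sigma2)])
    se <- sqrt(sweep(sigma2, 2L, n_g, "/"))
    rho <- rowMeans(abs(gd$d_shrunk) + se)
  } else {
    rho <- sqrt(sigma2[, 1L])
  }

  ranking <- data.frame(gene = names(rho),
                        rank = competition_ranks(rho),
                        rho = unname(rho), stringsAsFactors = FALSE)
  ranking <- ranking[order(ranking$rank), ]
  rownames(ranking) <- NULL

  out <- list(ranking = ranking, rho = rho, sigma2 = sigma2,
              mode = if (grouped) "grouped" else "ungrouped")
  if (grouped) out <- c(out, gd)
  structure(out, class = "normfinder_result")
}

#' @export
print.normfinder_result <- function(x, ...) {
  cat(sprintf("NormFinder stability (%s mode; lower rho = more stable):\n",
              x$mode))
  print(x$ranking, row.names = FALSE)
  invisible(x)
}
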