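#' Standard deviation of pairwise log expression ratios
#'
#' The geNorm pairwise variation of two genes: the sample standard deviation
#' (n-1 denominator) over samples of the log-transformed ratio of their
#' relative quantities. Log base 2 by convention; symmetric in its
#' arguments and invariant to rescaling either gene by a positive constant.
#'
#' @param q_j,q_k positive per-sample relative quantities of the two genes
#'   (same samples, length >= 2).
#' @param base logarithm base (2 by convention).
#' @return nonnegative scalar.
#' @export
pairwise_ratio_sd <- function(q_j, q_k, base = 2) {
  if (length(q_j) != length(q_k))
    stop("q_j and q_k must cover the same samples")
  if (length(q_j) < 2L) stop("at least 2 samples are required")
  if (any(q_j <= 0) || any(q_k <= 0))
    stop("relative quantities must be positive")
  sd(log(q_j / q_k, base = base))
}

#' geNorm gene-stability measure M
#'
#' For each gene, the average of its pairwise log-ratio standard deviations
#' with all other genes in the set: `M_j = sum_{k != j} V_jk / (N - 1)`.
#' Lower M means more stable expression relative to the rest of the panel.
#'
#' @param rq positive samples-by-genes matrix of relative quantities
#'   (>= 2 genes).
#' @param base logarithm base.
#' @return named numeric vector of M values.
#' @export
m_values <- function(rq, base = 2) {
  rq <- as.matrix(rq)
  n <- ncol(rq)
  if (n < 2L) stop("M values need at least 2 genes")
  if (any(rq <= 0)) stop("relative quantities must be positive")
  L <- log(rq, base = base)
  V <- matrix(0, n, n, dimnames = list(colnames(rq), colnames(rq)))
  for (j in seq_len(n - 1L))
    for (k in (j + 1L):n)
      V[j, k] <- V[k, j] <- sd(L[, j] - L[, k])
  colSums(V) / (n - 1L)
}

#' geNorm stepwise-exclusion stability ranking
#'
#' Repeatedly computes M over the surviving genes and removes the gene with
#' the highest M, until two genes remain. Excluded genes take positions
#' N, N-1, ..., 3; the terminal pair cannot be resolved by the algorithm and
#' shares position 1. The reported per-gene M is by default its M at the step
#' of its exclusion (the final pair reports the common last-step M); set
#' `report = "first_round"` to report every gene's M from the full panel
#' instead. Exact argmax ties are broken by input column order (the
#' first-listed gene is retained longer); steps where that happened are
#' recorded in the `ties` element.
#'
#' @param rq positive samples-by-genes matrix of relative quantities
#'   (>= 3 genes).
#' @param base logarithm base.
#' @param report `"stepwise"` (default) or `"first_round"`.
#' @param cutoff pairwise-variation cutoff passed to [optimal_rg_count()].
#' @return an object of class `genorm_result`: list with `ranking` (data
#'   frame `gene`, `rank`, `M`, ordered by rank), `exclusion_order` (least
#'   stable first), `v_series`, `recommended_count`, `ties`.
#' @export
genorm_rank <- function(rq, base = 2, report = c("stepwise", "first_round"),
                        cutoff = 0.15) {
  report <- match.arg(report)
  rq <- as.matrix(rq)
  n <- ncol(rq)
  if (n < 3L) stop("geNorm ranking needs at least 3 genes")
  first_round <- m_values(rq, base = base)

  survivors <- colnames(rq)
  excluded <- character(0)
  m_at_exclusion <- numeric(0)
  ties <- character(0)
  while (length(survivors) > 2L) {
    M <- m_values(rq[, survivors, drop = FALSE], base = base)
    top <- which(M == max(M))
    if (length(top) > 1L) {
      ties <- c(ties, sprintf("step with %d genes: argmax tie {%s}, excluded last-listed",
                              length(survivors),
                              paste(names(M)[top], collapse = ", ")))
      top <- top[length(top)]   # first-listed retained longer
    }
    out <- names(M)[top]
    excluded <- c(excluded, out)
    m_at_exclusion <- c(m_at_exclusion, M[[out]])
    survivors <- setdiff(survivors, out)
  }
  final_m <- m_values(rq[, survivors, drop = FALSE], base = base)

  gene <- c(survivors, rev(excluded))
  rank <- c(1L, 1L, seq(3L, n))
  M <- if (report == "stepwise") {
    c(final_m[survivors], rev(m_at_exclusion))
  } else {
    first_round[gene]
  }
  ranking <- data.frame(gene = gene, rank = rank, M = unname(M),
                        stringsAsFactors = FALSE)

  v <- pairwise_variation_series(rq, ranking$gene, base = base)
  res <- structure(list(ranking = ranking,
                        exclusion_order = excluded,
                        v_series = v,
                        recommended_count = optimal_rg_count(v, cutoff),
                        ties = ties),
                   class = "genorm_result")
  res
}

#' @export
print.genorm_result <- function(x, ...) {
  cat("geNorm stability ranking (lower M = more stable):\n")
  print(x$ranking, row.names = FALSE)
  cat("pairwise variation: ",
      paste(sprintf("%s=%.3f", names(x$v_series), x$v_series),
            collapse = ", "), "\n")
  cat("recommended number of reference genes:", x$recommended_count, "\n")
  invisible(x)
}

#' geNorm pairwise variation series V(n/n+1)
#'
#' For n = 2 .. N-1, the normalization factor `NF_n` is the per-sample
#' geometric mean of the n top-ranked genes' quantities; `V_n` is the sample
#' standard deviation over samples of `log2(NF_n / NF_(n+1))`. A small V
#' means adding the (n+1)-th gene hardly changes the normalization factor.
#'
#' @param rq positive samples-by-genes matrix of relative quantities.
#' @param ranking character vector of gene names in stability order (most
#'   stable first), e.g. `genorm_rank(rq)$ranking$gene`.
#' @param base logarithm base.
#' @return named numeric vector `V2/3`, `V3/4`, ...
#' @export
pairwise_variation_series <- function(rq, ranking, base = 2) {
  rq <- as.matrix(rq)
  n <- length(ranking)
  if (n < 3L) stop("the V series needs at least 3 ranked genes")
  miss <- setdiff(ranking, colnames(rq))
  if (length(miss))
    stop("ranked gene(s) not in table: ", paste(miss, collapse = ", "))
  L <- log(rq[, ranking, drop = FALSE], base = base)
  # log of NF_n = mean of the top-n log quantities
  v <- vapply(2:(n - 1L), function(k) {
    nf_k <- rowMeans(L[, seq_len(k), drop = FALSE])
    nf_k1 <- rowMeans(L[, seq_len(k + 1L), drop = FALSE])
    sd(nf_k - nf_k1)
  }, numeric(1))
  names(v) <- sprintf("V%d/%d", 2:(n - 1L), 3:n)
  v
}

#' Optimal number of reference genes from the V series
#'
#' The smallest n whose pairwise variation V(n/n+1) falls below the cutoff
#' (0.15 by convention), i.e. the point where including one more reference
#' gene is no longer required. If no value is below the cutoff, all N genes
#' are recommended with a warning.
#'
#' @param v_series output of [pairwise_variation_series()].
#' @param cutoff threshold (default 0.15).
#' @return integer count of reference genes.
#' @export
optimal_rg_count <- function(v_series, cutoff = 0.15) {
  if (length(v_series) == 0L) stop("empty pairwise variation series")
  below <- which(v_series < cutoff)
  if (length(below) == 0L) {
    n <- length(v_series) + 2L
    warning("no pairwise variation below ", cutoff,
            "; recommending all ", n, " genes")
    return(n)
  }
  unname(below[1L]) + 1L
}
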