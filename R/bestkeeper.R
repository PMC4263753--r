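#' BestKeeper per-gene Cq descriptive statistics
#'
#' Operates on raw Cq values (not relative quantities). For each gene:
#' geometric mean, arithmetic mean, minimum and maximum Cq, the BestKeeper
#' dispersion "SD (+/- Cq)" -- the mean absolute deviation of Cq from the
#' arithmetic mean, as published -- the coefficient of variation
#' `CV(%) = 100 * dispersion / arithmetic mean`, and the classic n-1 standard
#' deviation for comparison. Genes with dispersion above 1 cycle are flagged
#' as not acceptable (reported, never enforced).
#'
#' @param cq a [cq_table()] or samples-by-genes Cq matrix (>= 2 samples).
#' @param genes genes to describe (default all).
#' @param dispersion which estimate fills the `dispersion` column used for
#'   ranking: `"mad"` (mean absolute deviation, the BestKeeper convention,
#'   default) or `"sd"` (classic standard deviation).
#' @return data frame with one row per gene: `gene`, `n`, `geo_mean`,
#'   `ar_mean`, `min`, `max`, `mad_cq`, `sd_cq`, `dispersion`, `cv_pct`,
#'   `acceptable`.
#' @export
cq_descriptives <- function(cq, genes = NULL, dispersion = c("mad", "sd")) {
  dispersion <- match.arg(dispersion)
  m <- cq_values(cq, genes)
  if (nrow(m) < 2L) stop("descriptives need at least 2 samples")
  stats <- lapply(colnames(m), function(g) {
    x <- m[, g]
    mu <- mean(x)
    mad_cq <- mean(abs(x - mu))
    sd_cq <- sd(x)
    disp <- if (dispersion == "mad") mad_cq else sd_cq
    data.frame(gene = g, n = length(x),
               geo_mean = exp(mean(log(x))), ar_mean = mu,
               min = min(x), max = max(x),
               mad_cq = mad_cq, sd_cq = sd_cq, dispersion = disp,
               cv_pct = 100 * disp / mu,
               acceptable = disp <= 1,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, stats)
  rownames(out) <- NULL
  out
}

#' BestKeeper index
#'
#' Per-sample geometric mean of the candidate genes' raw Cq values.
#'
#' @param cq a [cq_table()] or Cq matrix (all values positive).
#' @param genes non-empty vector of genes entering the index (default all).
#' @return named numeric vector, one index value per sample.
#' @export
bestkeeper_index <- function(cq, genes = NULL) {
  m <- cq_values(cq, genes)
  if (ncol(m) == 0L) stop("the index needs at least one gene")
  if (any(m <= 0)) stop("Cq values must be positive")
  exp(rowMeans(log(m)))
}

#' Correlation of each gene with the BestKeeper index
#'
#' Pearson correlation of every gene's Cq column against the index, with a
#' two-sided p-value from `t = r * sqrt((N-2)/(1-r^2))` on N-2 degrees of
#' freedom. A zero-variance gene (or index) has no defined correlation and
#' is reported as missing with a warning.
#'
#' @param cq a [cq_table()] or Cq matrix (>= 3 samples for p-values).
#' @param index per-sample index from [bestkeeper_index()].
#' @param genes genes to correlate (default all).
#' @return data frame `gene`, `r`, `p_value`.
#' @export
index_correlations <- function(cq, index, genes = NULL) {
  m <- cq_values(cq, genes)
  if (nrow(m) != length(index))
    stop("index must cover the same samples as the Cq table")
  N <- nrow(m)
  res <- lapply(colnames(m), function(g) {
    x <- m[, g]
    if (sd(x) == 0 || sd(index) == 0) {
      warning("zero variance for gene '", g,
              "' or the index; correlation undefined")
      return(data.frame(gene = g, r = NA_real_, p_value = NA_real_,
                        stringsAsFactors = FALSE))
    }
    r <- cor(x, index)
    p <- if (N >= 3L && abs(r) < 1) {
      tstat <- r * sqrt((N - 2) / (1 - r^2))
      2 * pt(-abs(tstat), df = N - 2)
    } else if (N >= 3L) 0 else NA_real_
    data.frame(gene = g, r = r, p_value = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Full BestKeeper analysis
#'
#' Computes the per-gene descriptives, the index over the candidate panel,
#' the gene-vs-index correlations, and the stability ordering: ascending
#' dispersion, exact ties broken by larger absolute correlation, then input
#' order (recorded in `ties`). Consensus positions are competition ranks on
#' the full-precision dispersion.
#'
#' @inheritParams cq_descriptives
#' @return an object of class `bestkeeper_result`: list with `gene_stats`
#'   (descriptives joined with `r` and `p_value`), `index`, `ranking`
#'   (data frame `gene`, `rank`, `dispersion`, `r`, in stability order),
#'   `ties`.
#' @export
bestkeeper <- function(cq, genes = NULL, dispersion = c("mad", "sd")) {
  dispersion <- match.arg(dispersion)
  stats <- cq_descriptives(cq, genes, dispersion)
  idx <- bestkeeper_index(cq, genes)
  cors <- index_correlations(cq, idx, genes)
  stats <- merge(stats, cors, by = "gene", sort = FALSE)

  ord <- order(stats$dispersion, -abs(stats$r))
  ties <- character(0)
  dup <- duplicated(stats$dispersion) | duplicated(stats$dispersion, fromLast = TRUE)
  if (any(dup))
    ties <- sprintf("dispersion ties at full precision: %s",
                    paste(stats$gene[dup], collapse = ", "))
  ranking <- data.frame(gene = stats$gene[ord],
                        rank = competition_ranks(stats$dispersion)[ord],
                        dispersion = stats$dispersion[ord],
                        r = stats$r[ord], stringsAsFactors = FALSE)
  rownames(ranking) <- NULL
  structure(list(gene_stats = stats, index = idx, ranking = ranking,
                 ties = ties),
            class = "bestkeeper_result")
}

#' @export
print.bestkeeper_result <- function(x, ...) {
  cat("BestKeeper stability (ascending Cq dispersion):\n")
  print(x$ranking, row.names = FALSE)
  invisible(x)
}
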