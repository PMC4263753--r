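#' Efficiency-corrected relative quantities (delta-Cq method)
#'
#' Converts Cq values into relative quantities using each gene's own
#' amplification factor: `RQ[s, g] = E_g ^ (min_s' Cq[s', g] - Cq[s, g])`.
#' The sample with the lowest Cq of a gene (its most-expressing sample) gets
#' RQ exactly 1; all other samples fall in (0, 1]. The per-gene minimum is
#' taken over the full sample set supplied, so cold and heat assays should be
#' quantified separately.
#'
#' @param cq a [cq_table()] or samples-by-genes Cq matrix.
#' @param eff named numeric vector of per-gene amplification factors
#'   (see [efficiency_map()]); every gene in `genes` must be present.
#' @param genes genes to convert (default: all columns of `cq`).
#' @return numeric matrix of relative quantities, rows = samples.
#' @export
relative_quantities <- function(cq, eff, genes = NULL) {
  m <- cq_values(cq, genes)
  eff <- efficiency_map(eff)
  miss <- setdiff(colnames(m), names(eff))
  if (length(miss))
    stop("no amplification efficiency for gene(s): ",
         paste(miss, collapse = ", "))
  rq <- m
  for (g in colnames(m))
    rq[, g] <- eff[[g]]^(min(m[, g]) - m[, g])
  rq
}

#' Per-sample normalization factor
#'
#' Geometric mean of the selected reference genes' relative quantities,
#' sample by sample.
#'
#' @param rq relative-quantity matrix from [relative_quantities()].
#' @param reference_genes non-empty character vector of reference genes.
#' @return named numeric vector, one positive factor per sample.
#' @export
normalization_factor <- function(rq, reference_genes) {
  rq <- as.matrix(rq)
  if (length(reference_genes) == 0L)
    stop("at least one reference gene is required")
  miss <- setdiff(reference_genes, colnames(rq))
  if (length(miss))
    stop("reference gene(s) not in table: ", paste(miss, collapse = ", "))
  sub <- rq[, reference_genes, drop = FALSE]
  if (any(sub <= 0)) stop("relative quantities must be positive")
  exp(rowMeans(log(sub)))
}

#' Normalize target-gene quantities by a normalization factor
#'
#' `N[s, g] = RQ[s, g] / NF[s]`. Sample-wide loading artifacts shared by the
#' reference genes cancel in this ratio.
#'
#' @param rq relative-quantity matrix (target genes as columns).
#' @param nf named per-sample normalization factor covering all samples.
#' @return matrix of normalized expression values.
#' @export
normalize_targets <- function(rq, nf) {
  rq <- as.matrix(rq)
  miss <- setdiff(rownames(rq), names(nf))
  if (length(miss))
    stop("normalization factor missing for sample(s): ",
         paste(miss, collapse = ", "))
  nf <- nf[rownames(rq)]
  if (any(nf == 0)) stop("normalization factor must be nonzero")
  sweep(rq, 1L, nf, "/")
}

#' Fold-change report against a control time point
#'
#' For each target gene and time point, the mean and standard deviation of
#' the normalized expression over replicates, the fold change relative to the
#' control group mean (set to 1 at the control time point), and a two-sided
#' two-sample t-test of the time point's replicates against the control
#' replicates. Significance flags: `*` for p <= 0.05, `**` for p <= 0.01,
#' `ns` otherwise.
#'
#' If both groups have zero variance the t statistic is degenerate: equal
#' means report p = 1, separated means report p = 0 with a warning. A group
#' with fewer than 2 replicates yields a missing p-value (the fold change is
#' still reported).
#'
#' @param normalized matrix of normalized expression from
#'   [normalize_targets()].
#' @param design data frame with columns `sample_id` and `time_hours`
#'   covering every row of `normalized`.
#' @param control_time time (hours) of the control group (default 0).
#' @param test `"student"` (equal-variance, the default) or `"welch"`.
#' @param p_adjust multiple-testing adjustment applied per gene across time
#'   points (`"none"`, the default, or any [stats::p.adjust()] method such as
#'   `"BH"`).
#' @return data frame with one row per (gene, time point): `gene`,
#'   `time_hours`, `n`, `mean`, `sd`, `fold_change`, `p_value`, `signif`.
#' @export
fold_change_report <- function(normalized, design, control_time = 0,
                               test = c("student", "welch"),
                               p_adjust = "none") {
  test <- match.arg(test)
  normalized <- as.matrix(normalized)
  design <- as.data.frame(design)
  if (!all(c("sample_id", "time_hours") %in% names(design)))
    stop("design needs 'sample_id' and 'time_hours' columns")
  miss <- setdiff(rownames(normalized), design$sample_id)
  if (length(miss))
    stop("design missing sample(s): ", paste(miss, collapse = ", "))
  times <- design$time_hours[match(rownames(normalized), design$sample_id)]
  if (!control_time %in% times)
    stop("control time ", control_time, " not present in the design")
  tp <- sort(unique(times))

  rows <- lapply(colnames(normalized), function(g) {
    ctrl <- normalized[times == control_time, g]
    do.call(rbind, lapply(tp, function(t0) {
      x <- normalized[times == t0, g]
      fc <- if (t0 == control_time) 1 else mean(x) / mean(ctrl)
      p <- if (t0 == control_time) NA_real_ else two_sample_p(x, ctrl, test)
      data.frame(gene = g, time_hours = t0, n = length(x),
                 mean = mean(x), sd = if (length(x) > 1L) sd(x) else NA_real_,
                 fold_change = fc, p_value = p,
                 stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  if (p_adjust != "none") {
    for (g in unique(out$gene)) {
      i <- out$gene == g
      out$p_value[i] <- p.adjust(out$p_value[i], method = p_adjust)
    }
  }
  out$signif <- ifelse(is.na(out$p_value), "ns",
                       ifelse(out$p_value <= 0.01, "**",
                              ifelse(out$p_value <= 0.05, "*", "ns")))
  rownames(out) <- NULL
  out
}

two_sample_p <- function(x, y, test) {
  if (length(x) < 2L || length(y) < 2L) return(NA_real_)
  if (sd(x) == 0 && sd(y) == 0) {
    if (isTRUE(all.equal(mean(x), mean(y)))) return(1)
    warning("degenerate t-test: zero variance in both groups, p set to 0")
    return(0)
  }
  t.test(x, y, var.equal = (test == "student"))$p.value
}
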