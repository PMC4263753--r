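#' Competition ranks of stability scores
#'
#' The best score takes position 1; tied scores share the minimal position;
#' the next distinct score takes (number of strictly better genes) + 1.
#'
#' @param scores finite numeric scores, optionally named by gene.
#' @param direction `"ascending_is_best"` (default; lower score = better, as
#'   for M, rho and Cq dispersion) or `"descending_is_best"`.
#' @return integer vector of positions, named like `scores`.
#' @export
#' @examples
#' competition_ranks(c(0.147, 0.147, 0.166, 0.179))  # 1 1 3 4
competition_ranks <- function(scores,
                              direction = c("ascending_is_best",
                                            "descending_is_best")) {
  direction <- match.arg(direction)
  if (any(!is.finite(scores))) stop("scores must be finite")
  s <- if (direction == "ascending_is_best") scores else -scores
  r <- as.integer(rank(s, ties.method = "min"))
  names(r) <- names(scores)
  r
}

#' Geometric-mean consensus of three stability rankings
#'
#' Aggregates the per-algorithm positions of each gene into a single ranking
#' by their geometric mean, `gm_i = (p1_i * p2_i * p3_i)^(1/3)`, ordered
#' ascending. The three rankings must cover the identical gene set.
#'
#' @param rankings either a named list of three position vectors (each named
#'   by gene, e.g. from [competition_ranks()]), or a data frame with a `gene`
#'   column and three position columns.
#' @return an object of class `consensus_ranking`: a data frame with one row
#'   per gene, the three positions, `geom_mean`, and the final `rank`
#'   (competition ranks on the geometric mean), ordered by `rank`.
#' @export
consensus_geomean <- function(rankings) {
  if (is.data.frame(rankings)) {
    if (!"gene" %in% names(rankings))
      stop("a data-frame input needs a 'gene' column")
    pos_cols <- setdiff(names(rankings), "gene")
    if (length(pos_cols) != 3L)
      stop("exactly three position columns are required")
    genes <- rankings$gene
    pos <- as.matrix(rankings[, pos_cols])
    rownames(pos) <- genes
  } else {
    if (length(rankings) != 3L)
      stop("exactly three rankings are required")
    genes <- names(rankings[[1L]])
    for (i in 2:3) {
      diff1 <- setdiff(genes, names(rankings[[i]]))
      diff2 <- setdiff(names(rankings[[i]]), genes)
      if (length(diff1) || length(diff2))
        stop("rankings cover different gene sets: ",
             paste(c(diff1, diff2), collapse = ", "))
    }
    pos_cols <- if (!is.null(names(rankings))) names(rankings) else
      paste0("algorithm", 1:3)
    pos <- cbind(rankings[[1L]][genes], rankings[[2L]][genes],
                 rankings[[3L]][genes])
    colnames(pos) <- pos_cols
  }
  if (any(!is.finite(pos)) || any(pos < 1))
    stop("positions must be finite and >= 1")

  gm <- apply(pos, 1L, function(p) prod(p)^(1 / 3))
  out <- data.frame(gene = genes, pos, geom_mean = unname(gm),
                    rank = competition_ranks(unname(gm)),
                    stringsAsFactors = FALSE, row.names = NULL)
  out <- out[order(out$rank), ]
  rownames(out) <- NULL
  class(out) <- c("consensus_ranking", "data.frame")
  out
}

#' Top-k genes of a consensus ranking
#'
#' The first k genes of the final order. If genes are tied exactly at the
#' boundary, all tied genes are included with a warning.
#'
#' @param consensus a [consensus_geomean()] result.
#' @param k number of genes (default 3, the usual normalization panel size).
#' @return character vector of gene names.
#' @export
top_k <- function(consensus, k = 3) {
  if (k > nrow(consensus)) stop("k exceeds the number of genes")
  gm <- consensus$geom_mean
  cut <- sort(gm)[k]
  keep <- which(gm <= cut)
  if (length(keep) > k)
    warning("ties at the top-", k, " boundary: returning ",
            length(keep), " genes")
  consensus$gene[keep]
}

#' Run the full reference-gene stability workflow
#'
#' Converts the candidate genes' Cq values to efficiency-corrected relative
#' quantities, runs geNorm and NormFinder on them and BestKeeper on the raw
#' Cq values, and aggregates the three position vectors by geometric mean.
#'
#' @param cq a [cq_table()]; only its candidate-reference genes enter the
#'   analysis.
#' @param eff named per-gene amplification factors (see [efficiency_map()]).
#' @param groups optional NormFinder grouping (e.g.
#'   `sample_info(cq)$time_hours`); default ungrouped.
#' @param genorm_report passed to [genorm_rank()] (`report` argument).
#' @param cutoff geNorm pairwise-variation cutoff.
#' @return list with elements `genorm`, `normfinder`, `bestkeeper`,
#'   `consensus` and `rq` (the candidate relative-quantity matrix).
#' @export
rank_stability <- function(cq, eff, groups = NULL,
                           genorm_report = "stepwise", cutoff = 0.15) {
  cand <- if (inherits(cq, "cq_table")) candidate_genes(cq) else colnames(cq)
  if (length(cand) < 3L)
    stop("stability ranking needs at least 3 candidate genes")
  rq <- relative_quantities(cq, eff, genes = cand)
  gn <- genorm_rank(rq, report = genorm_report, cutoff = cutoff)
  nf <- normfinder_stability(rq, groups = groups)
  bk <- bestkeeper(cq, genes = cand)
  cons <- consensus_geomean(list(
    genorm = setNames(gn$ranking$rank, gn$ranking$gene),
    normfinder = setNames(nf$ranking$rank, nf$ranking$gene),
    bestkeeper = setNames(bk$ranking$rank, bk$ranking$gene)))
  list(genorm = gn, normfinder = nf, bestkeeper = bk,
       consensus = cons, rq = rq)
}
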