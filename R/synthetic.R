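#' Specification of a synthetic Cq data set
#'
#' Describes a time-course qPCR experiment with known ground truth. Each
#' gene g has a baseline Cq `b_g`, an amplification factor `E_g`, a
#' stability noise SD `sigma_g` (cycles), and a response profile `f_g(t)` --
#' the true log2 fold-change of its expression relative to t = 0, encoded as
#' piecewise-linear knots with `f(0) = 0`. A per-sample loading effect with
#' SD `loading_sd` (cycles) is shared by every gene of a sample; it is
#' exactly the technical variation that reference-gene normalization is
#' meant to remove.
#'
#' The generating model (inverted by the delta-Cq quantification chain) is
#'
#'   `Cq[s, g] = b_g + load_s - f_g(t_s) / log2(E_g) + eps[s, g]`
#'
#' with `load_s ~ N(0, loading_sd^2)` and `eps[s, g] ~ N(0, sigma_g^2)`.
#' Expression changes are divided by `log2(E_g)`, so genes with different
#' efficiencies encode the same fold-change by different Cq shifts.
#'
#' @param condition condition label.
#' @param time_points time points in hours.
#' @param replicates biological replicates per time point.
#' @param genes data frame with columns `gene_id`, `role`
#'   (`"candidate_reference"`/`"target"`), `baseline_cq`, `efficiency`,
#'   `sigma`.
#' @param profiles named list (by gene) of data frames with columns `time`,
#'   `log2fc`; genes without an entry have a flat profile. Profiles are
#'   interpolated linearly and held constant beyond the last knot.
#' @param loading_sd SD of the shared per-sample loading effect (cycles).
#' @return an object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(condition, time_points, replicates, genes,
                           profiles = list(), loading_sd = 0.15) {
  genes <- as.data.frame(genes)
  need <- c("gene_id", "role", "baseline_cq", "efficiency", "sigma")
  miss <- setdiff(need, names(genes))
  if (length(miss)) stop("genes is missing column(s): ",
                         paste(miss, collapse = ", "))
  if (any(genes$sigma < 0)) stop("sigma must be nonnegative")
  if (loading_sd < 0) stop("loading_sd must be nonnegative")
  if (any(genes$efficiency <= 1 | genes$efficiency > 2.2))
    stop("efficiencies must lie in (1, 2.2]")
  if (length(time_points) < 1L || replicates < 1L)
    stop("at least one time point and one replicate are required")
  stray <- setdiff(names(profiles), genes$gene_id)
  if (length(stray)) stop("profiles for unknown gene(s): ",
                          paste(stray, collapse = ", "))
  for (g in names(profiles)) {
    p <- profiles[[g]]
    if (!all(c("time", "log2fc") %in% names(p)))
      stop("profile for ", g, " needs 'time' and 'log2fc' columns")
    f0 <- approx(p$time, p$log2fc, xout = 0, rule = 2)$y
    if (abs(f0) > 1e-12)
      stop("profile for ", g, " must satisfy f(0) = 0")
  }
  structure(list(condition = condition,
                 time_points = as.numeric(time_points),
                 replicates = as.integer(replicates),
                 genes = genes, profiles = profiles,
                 loading_sd = loading_sd),
            class = "synthetic_spec")
}

profile_at <- function(spec, gene, t) {
  p <- spec$profiles[[gene]]
  if (is.null(p)) return(rep(0, length(t)))
  approx(p$time, p$log2fc, xout = t, rule = 2)$y
}

#' Default temperature-stress simulation designs
#'
#' Two ready-made [synthetic_spec()]s emulating a cold assay (7 time points
#' 0, 4, 8, 12, 24, 48, 72 h x 3 replicates = 21 samples) and a heat assay
#' (5 time points 0, 12, 24, 72 h and 7 d = 168 h, x 3 replicates = 15
#' samples), each with 11 candidate reference genes and 4 responsive target
#' genes. Baseline Cq values span roughly 8 (abundant ribosomal RNAs) to 28
#' cycles (the scarce SDR transcript); amplification factors are the
#' *H. perforatum* assay efficiencies ([hypericum_efficiencies()]). Nine
#' candidates are stable (`sigma` = 0.1 cycles); PKS1 and PKS2 are unstable
#' (`sigma` = 0.6). Targets follow the qualitative cold/heat response
#' profiles of the validation genes (CHS, CAT1, AOX1, AOX2).
#'
#' @param condition `"cold"` or `"heat"`.
#' @return a [synthetic_spec()].
#' @export
stress_design <- function(condition = c("cold", "heat")) {
  condition <- match.arg(condition)
  eff <- hypericum_efficiencies(condition)
  cand <- c("18SrRNA", "26SrRNA", "RBCL", "HYP1", "GAPDH", "GSA",
            "H2A", "TUB", "PKS1", "PKS2", "SDR")
  targ <- c("AOX1", "AOX2", "CAT1", "CHS")
  base_cold <- c(8.0, 9.5, 14.0, 20.0, 21.0, 22.0, 22.5, 23.0,
                 25.0, 26.0, 27.3,
                 22.0, 23.0, 21.5, 24.0)
  base_heat <- c(8.2, 9.8, 14.2, 21.3, 21.5, 22.3, 22.8, 23.2,
                 25.2, 26.2, 28.0,
                 22.2, 23.2, 21.8, 24.2)
  base <- if (condition == "cold") base_cold else base_heat
  sigma <- c(rep(0.1, 8), 0.6, 0.6, 0.1, rep(0.1, 4))
  genes <- data.frame(
    gene_id = c(cand, targ),
    role = c(rep("candidate_reference", length(cand)),
             rep("target", length(targ))),
    baseline_cq = base,
    efficiency = unname(eff[c(cand, targ)]),
    sigma = sigma, stringsAsFactors = FALSE)

  if (condition == "cold") {
    tp <- c(0, 4, 8, 12, 24, 48, 72)
    profiles <- list(
      CHS  = data.frame(time = c(0, 4, 8, 12, 24, 48, 72),
                        log2fc = c(0, 0.3, 0.6, 0.9, 1.4, 1.85, 1.2)),
      CAT1 = data.frame(time = c(0, 12, 24, 48, 72),
                        log2fc = c(0, 0.2, -1.0, -1.0, -0.9)),
      AOX1 = data.frame(time = c(0, 4, 8, 12, 24, 48, 72),
                        log2fc = c(0, 0.4, 0.7, 1.0, 1.49, 0.8, 0.3)),
      AOX2 = data.frame(time = c(0, 12, 24, 48, 72),
                        log2fc = c(0, -0.4, -0.93, -0.7, -0.5)))
  } else {
    tp <- c(0, 12, 24, 72, 168)
    profiles <- list(
      CHS  = data.frame(time = c(0, 12, 24, 72, 168),
                        log2fc = c(0, -1.93, -1.2, -0.3, -0.2)),
      CAT1 = data.frame(time = c(0, 12, 24, 72, 168),
                        log2fc = c(0, -0.3, -1.0, -1.0, -0.9)),
      AOX1 = data.frame(time = c(0, 12, 24, 72, 168),
                        log2fc = c(0, 0.3, 0.85, 0.85, 0.6)),
      AOX2 = data.frame(time = c(0, 12, 24, 72, 168),
                        log2fc = c(0, -0.35, -0.2, -0.1, 0)))
  }
  synthetic_spec(condition, tp, 3L, genes, profiles, loading_sd = 0.15)
}

#' Generate a synthetic Cq table with ground truth
#'
#' Draws a Cq table from a [synthetic_spec()] according to the model
#' documented there. The ground truth summarizes each candidate gene's total
#' log2-scale expression variability over the design,
#' `v_g = var(f_g(t) over samples) + (sigma_g * log2(E_g))^2`, and the
#' implied stability ordering (ascending v).
#'
#' @param spec a [synthetic_spec()].
#' @param seed integer seed; a fixed seed gives bit-identical output.
#' @return list with `cq` (a [cq_table()]) and `truth` (list with per-gene
#'   `v`, the candidate `ordering`, and the `stable_set` / `unstable_set`
#'   split at the largest gap in v).
#' @export
generate_cq <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (!is.null(seed)) set.seed(seed)
  t_s <- rep(spec$time_points, each = spec$replicates)
  rep_s <- rep(seq_len(spec$replicates), times = length(spec$time_points))
  ids <- sprintf("%s_t%03d_r%d", spec$condition, round(t_s), rep_s)
  n <- length(ids)

  load_s <- rnorm(n, 0, spec$loading_sd)
  m <- matrix(NA_real_, n, nrow(spec$genes),
              dimnames = list(ids, spec$genes$gene_id))
  for (i in seq_len(nrow(spec$genes))) {
    g <- spec$genes[i, ]
    f <- profile_at(spec, g$gene_id, t_s)
    m[, i] <- g$baseline_cq + load_s - f / log2(g$efficiency) +
      rnorm(n, 0, g$sigma)
  }

  sample_meta <- data.frame(sample_id = ids, condition = spec$condition,
                            time_hours = t_s, replicate = rep_s,
                            stringsAsFactors = FALSE)
  gene_meta <- spec$genes[, c("gene_id", "role")]
  cq <- cq_table(m, sample_meta, gene_meta)

  cand <- spec$genes$gene_id[spec$genes$role == "candidate_reference"]
  v <- vapply(cand, function(g) {
    i <- match(g, spec$genes$gene_id)
    f <- profile_at(spec, g, t_s)
    var(f) + (spec$genes$sigma[i] * log2(spec$genes$efficiency[i]))^2
  }, numeric(1))
  ord <- names(sort(v))
  sv <- sort(v)
  # split at the largest gap in v; a flat profile has no unstable genes
  if (length(v) < 2L || max(diff(sv)) <= 1e-12) {
    stable <- ord
    unstable <- character(0)
  } else {
    gap <- which.max(diff(sv))
    stable <- ord[seq_len(gap)]
    unstable <- ord[-seq_len(gap)]
  }
  truth <- list(v = v, ordering = ord,
                stable_set = stable, unstable_set = unstable)
  list(cq = cq, truth = truth)
}

#' Generate a noisy dilution series
#'
#' Simulates a standard curve for an assay with known amplification factor:
#' points at log10 relative amounts `0, -log10(step), ...` with
#' `Cq = intercept + slope * log10_amount + N(0, noise_sd^2)` and
#' `slope = -1/log10(E)`.
#'
#' @param E true amplification factor (> 1).
#' @param intercept Cq of the undiluted pool.
#' @param noise_sd measurement noise SD (cycles).
#' @param n_points number of dilution points (>= 3; default 4, an undiluted
#'   pool plus three dilutions).
#' @param step dilution factor between points (default 5, five-fold).
#' @param seed optional integer seed.
#' @param gene_id optional assay label.
#' @return a [dilution_series()].
#' @export
generate_dilution_series <- function(E, intercept, noise_sd = 0,
                                     n_points = 4, step = 5, seed = NULL,
                                     gene_id = NA_character_) {
  if (E <= 1) stop("amplification factor E must exceed 1")
  if (n_points < 3) stop("a dilution series needs at least 3 points")
  if (!is.null(seed)) set.seed(seed)
  x <- -log10(step) * (seq_len(n_points) - 1L)
  cq <- intercept + slope_from_efficiency(E) * x + rnorm(n_points, 0, noise_sd)
  dilution_series(x, cq, gene_id = gene_id)
}
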