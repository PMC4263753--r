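#' Dilution series for a standard curve
#'
#' A calibration series of Cq measurements over a serial template dilution,
#' encoded as log10 of the relative template amount (the undiluted pool at 0;
#' five-fold steps are -0.69897 apart).
#'
#' @param log10_amount numeric, log10 relative template amounts; at least 3
#'   points, strictly monotone.
#' @param cq numeric, measured Cq per point (cycles).
#' @param gene_id optional assay identifier.
#' @return an object of class `dilution_series`.
#' @export
dilution_series <- function(log10_amount, cq, gene_id = NA_character_) {
  log10_amount <- as.numeric(log10_amount)
  cq <- as.numeric(cq)
  if (length(log10_amount) != length(cq))
    stop("log10_amount and cq must have the same length")
  if (length(cq) < 3L)
    stop("a dilution series needs at least 3 points")
  if (any(!is.finite(log10_amount)) || any(!is.finite(cq)))
    stop("dilution series values must be finite")
  d <- diff(log10_amount)
  if (!(all(d > 0) || all(d < 0)))
    stop("log10 amounts must be strictly increasing or decreasing")
  structure(list(log10_amount = log10_amount, cq = cq, gene_id = gene_id),
            class = "dilution_series")
}

#' Fit a qPCR standard curve
#'
#' Ordinary least squares of Cq on log10 relative template amount. The slope
#' (cycles per log10 dilution, negative for a real assay) is converted to the
#' per-cycle amplification factor `E = 10^(-1/slope)`; `r_squared` is the
#' squared Pearson correlation of fitted vs observed Cq (the regression R2,
#' unadjusted, as instrument software reports it).
#'
#' @param series a [dilution_series()].
#' @return an object of class `standard_curve_fit` with elements `slope`,
#'   `intercept`, `r_squared`, `E`, `efficiency_percent`, `gene_id`.
#' @export
#' @examples
#' s <- dilution_series(c(0, -0.699, -1.398, -2.097),
#'                      c(20, 22.26, 24.52, 26.78))
#' fit_standard_curve(s)
fit_standard_curve <- function(series) {
  if (!inherits(series, "dilution_series"))
    stop("'series' must be a dilution_series")
  x <- series$log10_amount
  y <- series$cq
  if (var(x) == 0) stop("zero variance in log10 amounts")
  fit <- lm(y ~ x)
  slope <- unname(coef(fit)[2L])
  intercept <- unname(coef(fit)[1L])
  r2 <- 1 - sum(residuals(fit)^2) / sum((y - mean(y))^2)
  E <- efficiency_from_slope(slope)
  structure(list(slope = slope, intercept = intercept, r_squared = r2,
                 E = E, efficiency_percent = efficiency_percent(E),
                 gene_id = series$gene_id),
            class = "standard_curve_fit")
}

#' @export
print.standard_curve_fit <- function(x, ...) {
  cat(sprintf(
    "standard curve%s: slope %.4f, intercept %.2f, r2 %.4f, E %.3f (%.2f%%)\n",
    if (is.na(x$gene_id)) "" else paste0(" [", x$gene_id, "]"),
    x$slope, x$intercept, x$r_squared, x$E, x$efficiency_percent))
  invisible(x)
}

#' Convert between standard-curve slope and amplification factor
#'
#' `efficiency_from_slope()` applies `E = 10^(-1/slope)`;
#' `slope_from_efficiency()` inverts it as `slope = -1/log10(E)`;
#' `efficiency_percent()` expresses an amplification factor as percent
#' efficiency, `(E - 1) * 100` (E = 2, perfect doubling, is 100%).
#'
#' @param slope standard-curve slope in cycles per log10 dilution (nonzero).
#' @param E amplification factor per cycle (> 1 for `slope_from_efficiency`,
#'   > 0 for `efficiency_percent`).
#' @return numeric of the same length as the input.
#' @export
#' @examples
#' efficiency_from_slope(-3.3219)   # ~2: perfect doubling
#' slope_from_efficiency(2.038)     # -3.234
efficiency_from_slope <- function(slope) {
  if (any(slope == 0)) stop("slope must be nonzero")
  10^(-1 / slope)
}

#' @rdname efficiency_from_slope
#' @export
slope_from_efficiency <- function(E) {
  if (any(E <= 1)) stop("amplification factor E must exceed 1")
  -1 / log10(E)
}

#' @rdname efficiency_from_slope
#' @export
efficiency_percent <- function(E) {
  if (any(E <= 0)) stop("amplification factor E must be positive")
  (E - 1) * 100
}

#' Validate a map of per-gene amplification factors
#'
#' @param eff named numeric vector `gene_id -> E`; every value must lie in
#'   (1, 2.2].
#' @return the validated vector, invisibly usable downstream.
#' @export
efficiency_map <- function(eff) {
  eff <- unlist(eff)
  if (is.null(names(eff)) || any(!nzchar(names(eff))))
    stop("efficiencies must be named by gene")
  if (any(!is.finite(eff)) || any(eff <= 1) || any(eff > 2.2))
    stop("amplification factors must lie in (1, 2.2]")
  eff
}
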