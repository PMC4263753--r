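#' Published stability positions for Hypericum perforatum temperature stress
#'
#' Per-algorithm stability positions of the 11 candidate reference genes
#' assayed in *Hypericum perforatum* seedlings under cold (4 degC; 0--72 h)
#' and heat (35 degC; 0 h--7 d) stress, as assigned by GeNorm, NormFinder
#' and BestKeeper. Tied genes share the minimal position (competition
#' ranking): under cold stress GeNorm could not separate GAPDH and GSA
#' (both position 1, next gene at 3), and under heat stress 26SrRNA and H2A
#' share GeNorm position 1.
#'
#' These positions are the inputs of the geometric-mean consensus: feeding
#' them to [consensus_geomean()] yields the published consensus ranking for
#' each assay (cold: TUB, GSA, GAPDH on top; heat: 26SrRNA, H2A, TUB).
#'
#' @param condition `"cold"` or `"heat"`.
#' @return data frame with columns `gene`, `genorm`, `normfinder`,
#'   `bestkeeper` (integer positions 1..11).
#' @seealso [hypericum_efficiencies()] for the matching assay efficiencies.
#' @export
#' @examples
#' consensus_geomean(hypericum_ranks("cold"))
hypericum_ranks <- function(condition = c("cold", "heat")) {
  condition <- match.arg(condition)
  if (condition == "cold") {
    df <- data.frame(
      gene = c("GAPDH", "GSA", "18SrRNA", "26SrRNA", "TUB", "SDR",
               "H2A", "RBCL", "HYP1", "PKS2", "PKS1"),
      genorm     = c(1L, 1L, 3L, 4L, 5L, 6L, 7L, 8L, 9L, 10L, 11L),
      normfinder = c(4L, 5L, 2L, 3L, 1L, 6L, 8L, 7L, 9L, 10L, 11L),
      bestkeeper = c(6L, 4L, 7L, 3L, 2L, 8L, 9L, 1L, 5L, 10L, 11L),
      stringsAsFactors = FALSE)
  } else {
    df <- data.frame(
      gene = c("26SrRNA", "H2A", "GSA", "SDR", "HYP1", "TUB",
               "RBCL", "18SrRNA", "GAPDH", "PKS1", "PKS2"),
      genorm     = c(1L, 1L, 3L, 4L, 5L, 6L, 7L, 8L, 9L, 10L, 11L),
      normfinder = c(3L, 2L, 6L, 10L, 9L, 1L, 4L, 5L, 8L, 7L, 11L),
      bestkeeper = c(1L, 2L, 7L, 10L, 9L, 4L, 5L, 3L, 8L, 6L, 11L),
      stringsAsFactors = FALSE)
  }
  df
}

#' Assay amplification efficiencies for the H. perforatum panel
#'
#' Per-cycle amplification factors E of the 11 candidate reference genes and
#' 4 oxidative-stress target genes (AOX1, AOX2, CAT1, CHS) in the
#' *Hypericum perforatum* temperature-stress assays, determined from
#' four-point five-fold dilution-series standard curves, separately for the
#' cold- and heat-stress assay plates.
#'
#' @param condition `"cold"` or `"heat"`.
#' @return named numeric vector `gene -> E`.
#' @export
#' @examples
#' slope_from_efficiency(hypericum_efficiencies("cold")[["CHS"]])
hypericum_efficiencies <- function(condition = c("cold", "heat")) {
  condition <- match.arg(condition)
  cold <- c("18SrRNA" = 1.932, "26SrRNA" = 1.966, "GAPDH" = 1.905,
            "GSA" = 2.011, "HYP1" = 1.967, "H2A" = 1.988,
            "PKS1" = 2.018, "PKS2" = 1.871, "RBCL" = 1.935,
            "SDR" = 1.943, "TUB" = 1.991,
            "AOX1" = 1.934, "AOX2" = 2.022, "CAT1" = 2.018, "CHS" = 2.038)
  heat <- c("18SrRNA" = 1.905, "26SrRNA" = 1.924, "GAPDH" = 1.928,
            "GSA" = 1.982, "HYP1" = 1.968, "H2A" = 1.967,
            "PKS1" = 1.958, "PKS2" = 1.965, "RBCL" = 1.953,
            "SDR" = 1.982, "TUB" = 1.919,
            "AOX1" = 1.933, "AOX2" = 1.941, "CAT1" = 1.983, "CHS" = 2.027)
  if (condition == "cold") cold else heat
}
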