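#!/usr/bin/env Rscript
# Reference-gene stability: run geNorm, NormFinder and BestKeeper on the
# simulated Cq tables, aggregate the three position vectors by geometric
# mean, and check the consensus against the ground truth of the simulation.
# Also recompute the consensus of the published per-algorithm positions for
# the H. perforatum panel, which fixes the normalization strategy used in
# 04_quantify_targets.R (cold: TUB/GSA/GAPDH; heat: 26SrRNA/H2A/TUB).

library(refstab)

dir.create("results", showWarnings = FALSE)

for (cond in c("cold", "heat")) {
  cq <- read_cq_table(file.path("results", paste0("cq_", cond, ".tsv")))
  # roles are not carried by the TSV; restore them from the design
  spec <- stress_design(cond)
  gene_info <- setNames(spec$genes$role, spec$genes$gene_id)
  cq$genes$role <- unname(gene_info[cq$genes$gene_id])

  res <- rank_stability(cq, hypericum_efficiencies(cond),
                        groups = sample_info(cq)$time_hours)
  write_report(res$consensus,
               file.path("results", paste0("stability_", cond, ".tsv")))
  write_report(data.frame(step = names(res$genorm$v_series),
                          V = unname(res$genorm$v_series)),
               file.path("results", paste0("v_series_", cond, ".tsv")))

  truth <- read_report(file.path("results", paste0("truth_", cond, ".tsv")))
  top3 <- suppressWarnings(top_k(res$consensus, 3))
  stable <- truth$gene[truth$truly_stable]
  cat(sprintf("%s: top-3 consensus = %s (%s); V2/3 = %.3f -> %d genes suffice\n",
              cond, paste(top3, collapse = "/"),
              if (all(top3 %in% stable)) "all truly stable" else
                "contains an unstable gene!",
              res$genorm$v_series[["V2/3"]],
              res$genorm$recommended_count))
}

for (cond in c("cold", "heat")) {
  cons <- consensus_geomean(hypericum_ranks(cond))
  write_report(cons,
               file.path("results", paste0("published_consensus_", cond, ".tsv")))
  cat(sprintf("published %s panel: %s\n", cond,
              paste(top_k(cons, 3), collapse = "/")))
}
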