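#!/usr/bin/env Rscript
# Target-gene quantification: efficiency-corrected delta-Cq relative
# quantities, a geometric-mean normalization factor from the 3-gene panel
# selected in 03_stability.R, and fold changes of the four stress-responsive
# targets (CHS, CAT1, AOX1, AOX2) against the unstressed 0 h controls with
# Student t-tests per time point.

library(refstab)

dir.create("results", showWarnings = FALSE)
panels <- list(cold = c("TUB", "GSA", "GAPDH"),
               heat = c("26SrRNA", "H2A", "TUB"))

for (cond in c("cold", "heat")) {
  cq <- read_cq_table(file.path("results", paste0("cq_", cond, ".tsv")))
  spec <- stress_design(cond)
  cq$genes$role <- unname(setNames(spec$genes$role,
                                   spec$genes$gene_id)[cq$genes$gene_id])
  eff <- hypericum_efficiencies(cond)

  rq <- relative_quantities(cq, eff)
  nf <- normalization_factor(rq, panels[[cond]])
  normed <- normalize_targets(rq[, target_genes(cq)], nf)
  report <- fold_change_report(normed, sample_info(cq))
  write_report(report, file.path("results", paste0("expression_", cond, ".tsv")))

  peaks <- do.call(rbind, lapply(split(report, report$gene), function(d) {
    d[which.max(abs(log2(d$fold_change))), ]
  }))
  cat(sprintf("%s assay, largest responses (vs 0 h):\n", cond))
  for (i in seq_len(nrow(peaks)))
    cat(sprintf("  %-5s %4.0f h: %.2f-fold (%s)\n", peaks$gene[i],
                peaks$time_hours[i], peaks$fold_change[i], peaks$signif[i]))
}
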