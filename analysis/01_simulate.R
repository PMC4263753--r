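#!/usr/bin/env Rscript
# Simulate the two temperature-stress Cq data sets.
#
# The study designs: a cold assay (4 degC; 0, 4, 8, 12, 24, 48, 72 h post
# incubation x 3 replicates = 21 samples) and a heat assay (35 degC; 0, 12,
# 24, 72 h and 7 d = 168 h, x 3 replicates = 15 samples), each measuring 11
# candidate reference genes and 4 stress-responsive target genes. Raw Cq
# data for the original experiments are not public, so everything downstream
# runs on draws from the generative model in ?synthetic_spec, whose defaults
# mirror those designs.

library(refstab)

seed <- 20260930L
dir.create("results", showWarnings = FALSE)

for (cond in c("cold", "heat")) {
  sim <- generate_cq(stress_design(cond), seed = seed)
  write_cq_table(sim$cq, file.path("results", paste0("cq_", cond, ".tsv")))
  truth <- data.frame(gene = names(sim$truth$v),
                      true_log2_variability = unname(sim$truth$v),
                      truly_stable = names(sim$truth$v) %in%
                        sim$truth$stable_set)
  write_report(truth, file.path("results", paste0("truth_", cond, ".tsv")),
               digits = 5)
  cat(sprintf("%s: %d samples x %d genes; truly unstable: %s\n",
              cond, nrow(cq_values(sim$cq)), ncol(cq_values(sim$cq)),
              paste(sim$truth$unstable_set, collapse = ", ")))
}
cat("seed:", seed, "\n")
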