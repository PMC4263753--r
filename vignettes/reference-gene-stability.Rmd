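---
title: "Selecting stable reference genes and quantifying RT-qPCR expression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selecting stable reference genes and quantifying RT-qPCR expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(refstab)
```

## The problem

RT-qPCR expression measurements are relative: a target gene's
quantification cycle (Cq) reflects its transcript abundance *and* every
technical nuisance between tissue and plate — input amount, RNA integrity,
reverse-transcription yield. The standard remedy is to divide by one or
more *reference genes* assumed constant across conditions. That assumption
must be tested per experiment: a reference gene that drifts with the
treatment silently distorts every fold change computed with it.

`refstab` implements the complete selection-and-validation workflow for a
candidate reference-gene panel measured over a stress time course:

1. three stability algorithms — geNorm, NormFinder and BestKeeper;
2. a geometric-mean consensus of their rankings;
3. the geNorm pairwise-variation criterion for *how many* reference genes
   to use;
4. dilution-series standard curves and efficiency-corrected
   $\Delta C_q$ quantification of target genes against the selected panel;
5. a synthetic Cq generator with known ground truth, so the whole chain can
   be validated end to end without access to instrument data.

The bundled position tables (`hypericum_ranks()`) and assay efficiencies
(`hypericum_efficiencies()`) describe an 11-gene candidate panel assayed in
*Hypericum perforatum* seedlings under cold (4&nbsp;°C, 0–72 h) and heat
(35&nbsp;°C, 0 h–7 d) stress, with four oxidative-stress-responsive
validation targets (*CHS*, *CAT1*, *AOX1*, *AOX2*).

## The three stability measures

All three consume a samples × genes table; geNorm and NormFinder work on
efficiency-corrected relative quantities, BestKeeper on raw Cq.

**geNorm.** For genes $j,k$ the pairwise variation
$V_{jk} = \mathrm{SD}_s\!\left[\log_2 (q_{sj}/q_{sk})\right]$ is the
standard deviation (sample SD, $n-1$) of the log expression ratio. A gene's
stability measure is its average pairwise variation
$M_j = \sum_{k \ne j} V_{jk}/(N-1)$: if two genes are both stable their
ratio is constant, so genes that track the panel get small $M$. The ranking
excludes the highest-$M$ gene stepwise until two genes remain; those two
are mutually unrankable and share position 1. Both reporting conventions
are available (`report = "stepwise"` records each gene's $M$ when it was
excluded, `"first_round"` the full-panel $M$), since published tables do
not always say which they show. Log base 2 throughout; a natural-log option
exists but changes nothing in the ordering.

**NormFinder.** A model-based decomposition on $y = \log_2 q$. Centering
each sample by its across-gene mean absorbs loading effects but couples the
genes, so the naive per-gene variance is biased; with $n$ genes the
unbiased solution is
$\hat\sigma^2_{ig} = \max\{0,\; \tfrac{n}{n-2}\,(v_{ig} - V_g / (n(n-1)))\}$,
where $v_{ig}$ is the centered sample variance of gene $i$ in group $g$ and
$V_g = \sum_i v_{ig}$ (negative estimates are a small-sample artifact,
truncated at zero; at least 3 genes are required or the correction is
undefined). With $G \ge 2$ sample groups the inter-group difference
$d_{ig}$ is shrunk toward zero by the empirical-Bayes factor
$\hat\gamma^2 / (\hat\gamma^2 + \hat\sigma^2_{ig}/n_g)$, and the stability
value combines both error sources:
$\rho_i = \tfrac1G \sum_g \left(|\tilde d_{ig}| + \sqrt{\hat\sigma^2_{ig}/n_g}\right)$.
Ungrouped mode reports $\rho_i = \hat\sigma_i$. The decomposition is
derived from the stated variance model and validated against simulation
oracles (unbiasedness, rescue of a near-constant gene from
centering-induced inflation, recovery of perturbed genes); no attempt is
made to reproduce the original software's internal constants, which the
consensus only consumes through ranks anyway. Because the original
analysis does not state whether time points were supplied as subgroups,
ungrouped mode is the default and `groups =` opts in.

**BestKeeper.** Descriptive statistics on raw Cq: the published
"SD&nbsp;(±Cq)" dispersion is the *mean absolute deviation* from the
arithmetic mean — not the classic $n-1$ SD, although tables often label it
"standard deviation" — so MAD is the ranking default and both are always
reported. The BestKeeper index is the per-sample geometric mean of the
candidate panel's Cq, and each gene is correlated with it (Pearson $r$,
two-sided $p$ from the $t$ transform). Genes are ordered by ascending
dispersion with exact ties broken by larger $|r|$, then input order — the
$|r|$ tie-break matters only at printed precision, since full-precision
dispersion ties are essentially degenerate data. The index uses all
candidates (no pre-filtering), and the dispersion ≤ 1 cycle acceptability
flag is reported but never enforced.

## Consensus and panel size

Each algorithm contributes competition ranks (ties share the minimal
position; the next distinct score skips past them). The consensus is the
geometric mean of a gene's three positions, ordered ascending —
`consensus_geomean()` reproduces all 22 published geometric means of the
*H. perforatum* panel to 3 decimals from the published positions, which
also fixes the tie convention: a shared first place counts as 1 for both
genes and the next gene takes 3. Printed-score ties between distinct
full-precision scores are rounding artifacts and do *not* share ranks.
`top_k()` returns the usual 3-gene normalization panel.

How many genes are enough is decided by the geNorm pairwise variation:
$V_{n/n+1} = \mathrm{SD}_s[\log_2(NF_n/NF_{n+1})]$ between normalization
factors built from the top $n$ and $n+1$ genes. The first $n$ with
$V < 0.15$ suffices; if none qualifies all genes are recommended with a
warning. The 0.15 cutoff is the field's convention, not a hard statistical
bound.

## Quantification

`relative_quantities()` applies $RQ = E^{\Delta C_q}$ with
$\Delta C_q = C_{q,\min} - C_q$ per gene, so each gene's most-expressing
sample is the anchor at $RQ = 1$ and the per-gene minimum is taken over the
full sample set of the assay (assays are analyzed separately). Efficiencies
come from dilution-series standard curves:
$E = 10^{-1/\text{slope}}$ of the OLS fit of Cq on $\log_{10}$ template
amount, with the undiluted pool at 0 and five-fold steps $-0.699$ apart.
The normalization factor is the geometric mean of the selected references'
$RQ$; dividing a target's $RQ$ by it cancels any sample-wide loading factor
shared by the references. `fold_change_report()` compares each time point's
replicates to the $t=0$ controls: fold change of means (control pinned to
exactly 1), two-sided two-sample $t$-test (Student by default — the
software cited for the original analysis defaults to the equal-variance
test — Welch by flag), flags `*`/`**` at 0.05/0.01, and no multiplicity
correction by default (matching common practice in this literature; a
Benjamini–Hochberg option exists). Degenerate cases are explicit: identical
zero-variance groups give $p = 1$, separated zero-variance groups $p = 0$
with a warning, under-replicated groups a missing $p$ with the fold change
still reported. Whether the original analysis tested replicate values or
fold changes is not stated; replicate values are assumed.

## The synthetic generator

`generate_cq()` inverts the quantification model:
$C_q[s,g] = b_g + \ell_s - f_g(t_s)/\log_2 E_g + \varepsilon_{sg}$, with a
shared per-sample loading effect $\ell_s \sim N(0, \tau^2)$ and independent
per-gene noise $\varepsilon \sim N(0, \sigma_g^2)$. Division by
$\log_2 E_g$ makes genes with different efficiencies encode the same
fold-change differently, so efficiency correction is actually exercised;
the shared $\ell_s$ is exactly what normalization must remove, making the
invariance tests meaningful. The defaults in `stress_design()` mirror the
two assay designs (21 and 15 samples, 11 candidates + 4 targets), baseline
Cq interpolating the published extremes (≈8 for ribosomal RNAs to ≈28 for
SDR), real assay efficiencies, and target profiles tracing the reported
response shapes (e.g. CHS rising to +1.85 log2 ≈ 3.6-fold at 48 h in cold).
Chosen once and documented here:

* stable candidate noise $\sigma = 0.1$ cycles — typical replicate scatter
  for a well-behaved assay;
* two unstable candidates (PKS1, PKS2, the panel's published worst) at
  $\sigma = 0.6$ — large enough to separate rankings decisively at 21
  samples while leaving recovery genuinely stochastic;
* loading SD $\tau = 0.15$ cycles — realistic pipetting/input variation.

The ground truth orders candidates by total log2 variability
$v_g = \mathrm{var}_s f_g(t_s) + (\sigma_g \log_2 E_g)^2$ and splits
stable from unstable at the largest gap in $v$. What the generator does
*not* emulate: technical-replicate structure, plate/run effects, inhibitor
kinetics, non-Gaussian outliers, and co-regulation among candidates (the
known geNorm blind spot). Passing recovery tests therefore show the chain
is self-consistent and statistically sound at these noise scales — not
that any real panel is stable.

## Numerical choices and test scale

Sample SDs use the $n-1$ denominator everywhere. geNorm argmax ties are
broken by input column order (first-listed retained longer) and logged in
the result. Shrinkage with both prior and noise variance zero shrinks fully
to zero rather than dividing 0/0. Problem sizes in the test suite were
chosen for statistical resolution: the variance-recovery check uses 9 genes
(3 per $\sigma^2$ level) × 2000 samples averaged over 20 replicate
simulations, because an analysis of the estimator's sampling variance shows
a single 3-gene draw has ≈26% relative error at $\sigma^2 = 0.01$ — far too
noisy to certify a 10% recovery band; recovery of the stable set runs the
full workflow over 100 seeds; the $t$-vs-permutation cross-check uses 200
cases because the exhaustive $n=3+3$ permutation distribution has only 10
levels and rank correlations stabilize slowly over so coarse a support.

## A worked example

```{r example}
sim <- generate_cq(stress_design("cold"), seed = 1)
res <- rank_stability(sim$cq, hypericum_efficiencies("cold"))
head(res$consensus, 4)
res$genorm$recommended_count

refs <- top_k(res$consensus, 3)
rq <- relative_quantities(sim$cq, hypericum_efficiencies("cold"))
normed <- normalize_targets(rq[, target_genes(sim$cq)],
                            normalization_factor(rq, refs))
report <- fold_change_report(normed, sample_info(sim$cq))
subset(report, gene == "CHS" & time_hours %in% c(0, 24, 48))
```

## Limitations

* The consensus depends only on ranks, so it inherits each algorithm's
  pathologies: geNorm rewards co-regulated pairs, BestKeeper's raw-Cq
  dispersion conflates expression level with stability when efficiencies
  differ strongly.
* Published per-algorithm *scores* (M, stability values, SD/r) for the
  *H. perforatum* panel cannot be recomputed without the raw Cq data; only
  the positions, their consensus, and the downstream panel choices are
  reproduced exactly. The simulation-based property tests stand in for the
  score-level checks.
* No inter-plate calibration, absolute quantification, LOD/LOQ estimation,
  or instrument-native file parsing.
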