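test_that("relative quantities implement the delta-Cq definition", {
  m <- matrix(c(20, 21, 23, 25, 25, 28), nrow = 3,
              dimnames = list(paste0("s", 1:3), c("gA", "gB")))
  eff <- c(gA = 2, gB = 2.038)
  rq <- relative_quantities(m, eff)
  expect_equal(rq["s1", "gA"], 1)              # minimum-Cq sample
  expect_equal(rq["s2", "gA"], 0.5)            # one doubling above minimum
  expect_equal(rq["s3", "gB"], 2.038^(-3), tolerance = 1e-12)
  expect_equal(round(rq["s3", "gB"], 4), 0.1181)
  expect_true(all(rq > 0 & rq <= 1))
  expect_equal(unname(apply(rq, 2, max)), c(1, 1))
  expect_error(relative_quantities(m, c(gA = 2)), "gB")
})

test_that("relative quantities decrease strictly in Cq for fixed E > 1", {
  cqs <- seq(18, 30, by = 0.5)
  m <- cbind(gA = cqs, gB = rev(cqs))
  rownames(m) <- paste0("s", seq_along(cqs))
  rq <- relative_quantities(m, c(gA = 1.9, gB = 1.9))
  expect_true(all(diff(rq[, "gA"]) < 0))
})

test_that("normalization factor is the geometric mean of reference RQs", {
  rq <- cbind(gA = c(0.25, 0.2), gB = c(1.0, 0.5), gC = c(0.3, 0.9))
  rownames(rq) <- c("s1", "s2")
  expect_equal(unname(normalization_factor(rq, "gA")), rq[, "gA"],
               ignore_attr = TRUE)
  expect_equal(unname(normalization_factor(rq, c("gA", "gB"))[1]), 0.5)
  expect_equal(unname(normalization_factor(rq, c("gA", "gB", "gC"))[2]),
               (0.2 * 0.5 * 0.9)^(1 / 3), tolerance = 1e-12)
  expect_equal(round(unname(normalization_factor(rq, c("gA", "gB", "gC"))[2]), 4),
               0.4481)
  expect_error(normalization_factor(rq, character(0)), "at least one")
  rq[1, 1] <- 0
  expect_error(normalization_factor(rq, c("gA", "gB")), "positive")
})

test_that("normalized expression cancels shared loading artifacts", {
  set.seed(101)
  sim <- generate_cq(stress_design("cold"), seed = 101)
  eff <- hypericum_efficiencies("cold")
  refs <- c("TUB", "GSA", "GAPDH")
  rq_all <- relative_quantities(sim$cq, eff)
  norm1 <- normalize_targets(rq_all[, target_genes(sim$cq)],
                             normalization_factor(rq_all, refs))

  # double every gene's quantity in one sample (pipetting artifact)
  rq2 <- rq_all
  rq2[5, ] <- rq2[5, ] * 2
  norm2 <- normalize_targets(rq2[, target_genes(sim$cq)],
                             normalization_factor(rq2, refs))
  expect_equal(norm1, norm2, tolerance = 1e-12)

  # target RQ equal to NF everywhere -> all ones
  nf <- normalization_factor(rq_all, refs)
  expect_equal(unname(normalize_targets(cbind(t1 = nf), nf)[, 1]),
               rep(1, length(nf)), tolerance = 1e-12)
  expect_equal(unname(normalize_targets(cbind(t1 = setNames(rep(0.4, 3), paste0("s", 1:3))),
                                        setNames(rep(0.5, 3), paste0("s", 1:3)))[, 1]),
               rep(0.8, 3))
})

test_that("fold-change report pins the control to 1 and flags significance", {
  norm <- rbind(matrix(c(0.9, 1.0, 1.1), 3, 2), matrix(c(1.8, 2.0, 2.2), 3, 2))
  colnames(norm) <- c("tA", "tB")
  rownames(norm) <- paste0("s", 1:6)
  design <- data.frame(sample_id = paste0("s", 1:6),
                       time_hours = rep(c(0, 24), each = 3))
  rep <- fold_change_report(norm, design)
  ctrl <- rep[rep$time_hours == 0 & rep$gene == "tA", ]
  expect_identical(ctrl$fold_change, 1)
  expect_identical(ctrl$signif, "ns")
  t24 <- rep[rep$time_hours == 24 & rep$gene == "tA", ]
  expect_equal(t24$fold_change, 2, tolerance = 1e-12)
  expect_identical(t24$signif, "**")

  # treated identical to control -> fold 1, ns
  norm_id <- rbind(norm[1:3, , drop = FALSE], norm[1:3, , drop = FALSE])
  rownames(norm_id) <- paste0("s", 1:6)
  rep_id <- fold_change_report(norm_id, design)
  expect_equal(rep_id$fold_change[rep_id$time_hours == 24], c(1, 1))
  expect_true(all(rep_id$signif == "ns"))

  # zero variance in both groups with separated means: p = 0 with warning
  norm_deg <- cbind(tA = c(1, 1, 1, 2, 2, 2))
  rownames(norm_deg) <- paste0("s", 1:6)
  expect_warning(rep_deg <- fold_change_report(norm_deg, design),
                 "degenerate")
  expect_equal(rep_deg$p_value[rep_deg$time_hours == 24], 0)
  expect_equal(rep_deg$fold_change[rep_deg$time_hours == 24], 2)
})

test_that("t-test p-values are consistent with the exhaustive permutation oracle", {
  ctrl <- c(0.9, 1.0, 1.1)
  trt <- c(1.8, 2.0, 2.2)
  norm <- cbind(tA = c(ctrl, trt))
  rownames(norm) <- paste0("s", 1:6)
  design <- data.frame(sample_id = paste0("s", 1:6),
                       time_hours = rep(c(0, 24), each = 3))
  p_t <- fold_change_report(norm, design)$p_value[2]
  p_perm <- perm_p(trt, ctrl)
  expect_equal(p_perm, 2 / 20)    # complete separation: minimal attainable
  expect_lt(p_t, p_perm)          # parametric p consistent with the floor

  # seeded grid: the permutation support at n = 3+3 has only 10 levels with
  # heavy ties, so the agreement is checked on a grid large enough for the
  # rank correlation to stabilize, plus two classification agreements
  set.seed(202)
  cases <- replicate(200, list(x = rnorm(3, 0, 0.2),
                               y = rnorm(3, sample(c(0, 0.6), 1), 0.2)),
                     simplify = FALSE)
  p_param <- vapply(cases, function(cs) {
    n <- cbind(tA = c(cs$x, cs$y))
    rownames(n) <- paste0("s", 1:6)
    fold_change_report(n, design)$p_value[2]
  }, numeric(1))
  p_exact <- vapply(cases, function(cs) perm_p(cs$y, cs$x), numeric(1))
  expect_gt(cor(p_param, p_exact, method = "spearman"), 0.8)
  # parametric significance must coincide with the permutation floor 2/20
  expect_gte(mean(p_exact[p_param < 0.05] <= 0.1 + 1e-9), 0.95)
  # clearly non-significant permutation p must not be parametric discoveries
  expect_gte(mean(p_param[p_exact >= 0.4] > 0.1), 0.95)
})

test_that("missing replication yields missing p-values, not failures", {
  norm <- cbind(tA = c(1, 1.1, 1.05, 2))
  rownames(norm) <- paste0("s", 1:4)
  design <- data.frame(sample_id = paste0("s", 1:4),
                       time_hours = c(0, 0, 0, 24))
  rep <- fold_change_report(norm, design)
  t24 <- rep[rep$time_hours == 24, ]
  expect_true(is.na(t24$p_value))
  expect_false(is.na(t24$fold_change))
})
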