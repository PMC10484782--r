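# Generators: effect draws, cohorts, proband-relative pairs, toy variants.

test_that("gene effect draws follow the mixture prior", {
  expect_true(all(draw_gene_effects(1000, alpha = 0, eta = 2, seed = 1) == 0))
  b <- draw_gene_effects(1e5, alpha = 1, eta = 2, seed = 1)
  expect_true(all(b > 0))
  expect_rel_equal(mean(b), 0.5, 0.02)          # Exp mean 1/eta
  # with eta = ln2/ln(1.38) the median OR among associated genes is 1.38
  eta <- log(2) / log(1.38)
  b2 <- draw_gene_effects(1e5, alpha = 1, eta = eta, seed = 1)
  expect_rel_equal(median(exp(b2)), 1.38, 0.01)
  expect_error(draw_gene_effects(10, alpha = 2, eta = 1, seed = 1), "alpha")
  expect_error(draw_gene_effects(10, alpha = 0.5, eta = -1, seed = 1), "eta")
})

test_that("cohorts are reproducible by seed and vary across seeds", {
  genes <- list(gene_spec("A", 0.01), gene_spec("B", 0.02, log(2)))
  cfg <- sim_config(300, 300, genes, seed = 5)
  c1 <- simulate_cohort(cfg)
  c2 <- simulate_cohort(cfg)
  expect_identical(c1$phenotypes, c2$phenotypes)
  expect_identical(unclass(c1$carriers), unclass(c2$carriers))
  c3 <- simulate_cohort(sim_config(300, 300, genes, seed = 6))
  expect_false(identical(unclass(c1$carriers), unclass(c3$carriers)))
  # truth covers every gene; row counts consistent
  expect_setequal(c1$truth$gene_id, colnames(c1$carriers))
  expect_equal(nrow(c1$phenotypes), nrow(c1$carriers))
  expect_equal(sum(c1$phenotypes$d), 300)
  expect_equal(sum(1 - c1$phenotypes$d), 300)
})

test_that("null genes show equal carrier frequency in cases and controls", {
  genes <- lapply(1:40, function(i) gene_spec(paste0("N", i), 0.02))
  coh <- simulate_cohort(sim_config(2500, 2500, genes, seed = 31))
  d <- coh$phenotypes$d
  fr_case <- colMeans(coh$carriers[d == 1, ])
  fr_ctrl <- colMeans(coh$carriers[d == 0, ])
  # pooled binomial check per gene at ~4 sigma
  p <- (fr_case + fr_ctrl) / 2
  se <- sqrt(p * (1 - p) * 2 / 2500)
  expect_true(all(abs(fr_case - fr_ctrl) < 4.5 * se))
})

test_that("risk-gene carriers are enriched in cases and in family history", {
  coh <- small_cohort(seed = 41, n = 5000, or = 3, q = 0.005)
  ph <- coh$phenotypes
  carr <- coh$carriers[, "RISK"]
  expect_gt(mean(carr[ph$d == 1]), mean(carr[ph$d == 0]))
  # tabulated over cases: carriers report more family history
  cases <- ph$d == 1
  expect_gt(mean(ph$f[cases & carr == 1]), mean(ph$f[cases & carr == 0]))
  # downstream burden z is positive
  res <- burden_regression(carr, ph)
  expect_gt(res$z, 0)
})

test_that("oversampling enriches accepted cases for family history and youth", {
  genes <- list(gene_spec("A", 0.01))
  plain <- simulate_cohort(sim_config(2000, 500, genes, seed = 8,
    study_specs = list(study_spec("S"))))
  enr <- simulate_cohort(sim_config(2000, 500, genes, seed = 8,
    study_specs = list(study_spec("S", fh_oversample = 4, young_oversample = 3))))
  pf <- function(coh) mean(coh$phenotypes$f[coh$phenotypes$d == 1])
  py <- function(coh) mean(coh$phenotypes$age_band[coh$phenotypes$d == 1] == "<50")
  expect_gt(pf(enr), pf(plain))
  expect_gt(py(enr), py(plain))
  # controls are not oversampled
  expect_lt(abs(mean(enr$phenotypes$f[enr$phenotypes$d == 0]) -
                  mean(plain$phenotypes$f[plain$phenotypes$d == 0])), 0.08)
})

test_that("infeasible sampling raises a simulation error", {
  genes <- list(gene_spec("A", 0.01))
  # cases practically ungenerable at this baseline risk
  cfg <- sim_config(500, 10, genes, baseline_risk = 1e-5, seed = 1)
  expect_error(simulate_cohort(cfg), "simulation error")
})

test_that("proband-relative pairs: null and degenerate cases give FRR 1", {
  # beta = 0: no familial aggregation
  p0 <- simulate_proband_relative_pairs(0.001, 0, 0.1, 1e6, 7)
  expect_lt(abs(empirical_frr(p0) - 1), 0.02)
  # no carriers at all
  p1 <- simulate_proband_relative_pairs(0, log(3), 0.1, 1e6, 7)
  expect_lt(abs(empirical_frr(p1) - 1), 0.02)
  expect_error(simulate_proband_relative_pairs(0.01, log(3), 0.5, 10, 1),
               "penetrance")
})

test_that("allele transmission: relative carrier frequency given carrier proband", {
  q <- 0.01
  pr <- simulate_proband_relative_pairs(q, 0, 0.1, 2e6, 3)
  rel_freq <- mean(pr$relative_carrier[pr$proband_carrier == 1])
  # P(rel carrier | proband carrier) = 1/2 + q/2 (+ O(q) background overlap)
  expect_lt(abs(rel_freq - (0.5 + q / 2)), 4 * sqrt(0.25 / (2e6 * q)))
})

test_that("empirical FRR errors: no affected relatives / probands", {
  pairs <- data.frame(proband_carrier = 0, proband_affected = c(1, 0),
                      relative_carrier = 0, relative_affected = c(0, 0))
  expect_error(empirical_frr(pairs), "undefined")
  pairs2 <- pairs; pairs2$proband_affected <- 0; pairs2$relative_affected <- 1
  expect_error(empirical_frr(pairs2), "proband")
})

test_that("toy variant panel covers every classification boundary", {
  for (seed in c(3, 77)) {
    vars <- simulate_annotated_variants(n_genes = 6, seed = seed)
    ann <- vars$annotations
    for (g in unique(ann$gene_id)) {
      tx <- vars$transcripts[[g]]
      pen_end <- tx$exons[tx$n_exons - 1, "end"]
      va <- ann[ann$gene_id == g, ]
      # a variant exactly 50 bp from the penultimate exon 3' end, and both
      # neighbours of the threshold
      expect_true(any(va$exon_index == tx$n_exons - 1 &
                        pen_end - va$position == 50))
      expect_true(any(pen_end - va$position == 49))
      expect_true(any(pen_end - va$position == 51))
      expect_true(any(va$exon_index == tx$n_exons))     # last-exon PTV
      # a missense with AF exactly 0.001 and AFs straddling it
      miss <- va[va$consequence == "missense", ]
      expect_true(any(miss$panel_af == 1e-3 & miss$cohort_af == 1e-3))
      expect_true(any(miss$panel_af < 1e-3) && any(miss$cohort_af > 1e-3))
      # CADD / Helix straddle 20 / 0.5
      expect_true(any(miss$cadd < 20) && any(miss$cadd >= 20))
      expect_true(any(miss$helix <= 0.5) && any(miss$helix > 0.5))
    }
  }
})

test_that("toy variant generation is deterministic", {
  v1 <- simulate_annotated_variants(n_genes = 10, seed = 3)
  v2 <- simulate_annotated_variants(n_genes = 10, seed = 3)
  expect_identical(v1$annotations, v2$annotations)
  expect_identical(v1$genotypes, v2$genotypes)
  expect_identical(v1$transcript_table, v2$transcript_table)
})
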