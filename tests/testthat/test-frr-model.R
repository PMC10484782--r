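# FRR formula, mixture likelihood, empirical-Bayes fit and FRR shares.

test_that("single-gene FRR formula: null cases and positivity", {
  expect_equal(gene_frr(0.3, 0), 1)
  expect_equal(gene_frr(0, 2), 1)
  # lambda >= 1 over an admissible grid, equality only at p=0 or beta=0
  for (p in c(0, 1e-4, 1e-3, 0.01, 0.1))
    for (b in c(-0.5, 0, 0.3, 1, 2)) {
      l <- gene_frr(p, b)
      expect_gte(l, 1)
      if (p > 0 && b != 0) expect_gt(l, 1)
    }
  # allele frequencies above 0.5 are outside the rare-dominant model
  expect_error(gene_frr(0.6, 1), "0.5")
})

test_that("FRR formula agrees with the family-simulation oracle", {
  # Monte-Carlo pairs vs closed form at the contract's parameter point
  pairs <- simulate_proband_relative_pairs(0.002, log(3), 0.05, 2e6, 7)
  expect_rel_equal(empirical_frr(pairs), gene_frr(0.001, log(3)), 0.05)
  # a second point with a visible excess (larger p and OR)
  pairs2 <- simulate_proband_relative_pairs(0.01, log(5), 0.05, 2e6, 8)
  expect_rel_equal(empirical_frr(pairs2), gene_frr(0.005, log(5)), 0.05)
})

test_that("total FRR is additive on the excess scale and permutation-invariant", {
  expect_equal(total_frr(c(1, 1, 1)), 1)
  expect_equal(total_frr(c(1.02, 1.03)), 1.05)
  l <- c(1.1, 1.004, 1.02)
  expect_equal(total_frr(l), total_frr(rev(l)))
  expect_error(total_frr(c(1.1, 0.9)), ">= 1")
})

test_that("adjusted frequency: carrier-count estimate plus SV allele frequency", {
  gc <- gene_counts("g", a = 5, b = 15, n1 = 1e4, n0 = 9e4, sv_freq = 0)
  expect_equal(adjusted_frequency(gc), 1e-4)
  gc$sv_freq <- 2e-5
  expect_equal(adjusted_frequency(gc), 1.2e-4)
  gc0 <- gene_counts("g", a = 0, b = 0, n1 = 1e4, n0 = 9e4)
  expect_equal(adjusted_frequency(gc0), 0)
  gcc <- gene_counts("g", a = 5, b = 15, n1 = 1e4, n0 = 9e4, sv_freq = 1e-5)
  expect_equal(adjusted_frequency(gcc, controls_only = TRUE),
               15 / (2 * 9e4) + 1e-5)
  expect_error(gene_counts("g", a = 11, b = 0, n1 = 10, n0 = 10), "exceed")
})

test_that("marginal likelihood: alpha = 0 collapses to the null normal", {
  gc <- gene_counts(c("g1", "g2"), a = c(12, 3), b = c(40, 30),
                    n1 = 1e4, n0 = 9e4)
  eo_beta <- log((12 * (9e4 - 40)) / (40 * (1e4 - 12)))
  eo_se <- sqrt(1 / 12 + 1 / 40 + 1 / (1e4 - 12) + 1 / (9e4 - 40))
  ll <- marginal_loglik(gc, eb_prior(0, 2))
  expect_equal(ll[1], dnorm(eo_beta, 0, eo_se, log = TRUE))
})

test_that("closed-form mixture integral matches adaptive quadrature to 1e-8", {
  # stress grid over effect size, information and prior rate
  grid <- expand.grid(a = c(1, 5, 40, 200), eta = c(0.5, 2, 8),
                      n1 = c(2e3, 5e4))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    gc <- gene_counts("g", a = g$a, b = 20, n1 = g$n1, n0 = g$n1 * 2)
    for (alpha in c(0.01, 0.5, 1)) {
      pr <- eb_prior(alpha, g$eta)
      cf <- marginal_loglik(gc, pr)
      qd <- marginal_loglik(gc, pr, likelihood = "quadrature")
      expect_rel_equal(cf, qd, 1e-8)
    }
  }
})

test_that("strong positive evidence favours a nonzero mixture weight", {
  gc <- gene_counts("g", a = 120, b = 60, n1 = 1e4, n0 = 1e4)  # beta_hat ~ 0.7
  expect_gt(marginal_loglik(gc, eb_prior(0.05, 2)),
            marginal_loglik(gc, eb_prior(0, 2)))
})

test_that("median OR inverts the exponential rate", {
  expect_equal(median_or(eb_prior(0.1, log(2))), exp(1))
  expect_equal(median_or(eb_prior(0.1, log(2) / log(1.38))), 1.38)
  expect_lt(median_or(eb_prior(0.1, 50)), 1.02)  # eta large -> OR -> 1
})

test_that("empirical-Bayes fit recovers the generating mixture", {
  counts <- simulate_gene_counts(5000, alpha = 0.05, eta = 2,
                                 n1 = 5e4, n0 = 5e4,
                                 carrier_freq = 0.001, seed = 5)
  fit <- fit_eb(counts)
  expect_true(fit$converged)
  expect_lt(abs(fit$prior$alpha - 0.05), 0.02)
  expect_lt(abs(fit$prior$eta - 2) / 2, 0.3)
  # posterior probability rises with beta_hat at comparable information
  # (the posterior depends on (beta_hat, se); within a narrow se band the
  # ordering must follow beta_hat)
  med <- median(fit$genes$se)
  g <- fit$genes[abs(fit$genes$se - med) / med < 0.02, ]
  expect_gt(nrow(g), 50)
  expect_gt(cor(g$beta_hat, g$posterior_assoc, method = "spearman"), 0.95)
})

test_that("null-only data drive alpha to the boundary", {
  counts <- simulate_gene_counts(3000, alpha = 0, eta = 2, n1 = 5e4, n0 = 5e4,
                                 carrier_freq = 0.001, seed = 6)
  fit <- fit_eb(counts)
  expect_lt(fit$prior$alpha, 0.01)
  expect_true(all(fit$genes$posterior_assoc < 0.5))
})

test_that("overwhelming single-gene evidence yields posterior ~ 1", {
  # one decisive gene among nulls: beta_hat ~ 1 with tiny standard error
  counts <- simulate_gene_counts(500, alpha = 0, eta = 2, n1 = 2e5, n0 = 2e5,
                                 carrier_freq = 0.005, seed = 9)
  counts$a[1] <- round(counts$b[1] * exp(1))  # ~ e-fold enrichment in cases
  fit <- fit_eb(counts)
  expect_gt(fit$genes$posterior_assoc[1], 0.99)
})

test_that("FRR percent: additive over a partition, zero for empty subset", {
  counts <- simulate_gene_counts(300, alpha = 0.2, eta = 1.5, n1 = 2e4,
                                 n0 = 2e4, carrier_freq = 0.003, seed = 11)
  fit <- fit_eb(counts)
  all_pct <- frr_percent(fit)
  half <- fit$genes$gene_id[1:150]
  rest <- setdiff(fit$genes$gene_id, half)
  expect_equal(frr_percent(fit, half) + frr_percent(fit, rest), all_pct)
  expect_equal(frr_percent(fit, character(0)), 0)
  expect_equal(frr_percent(fit, sample(half)), frr_percent(fit, half))
  expect_error(frr_percent(fit, "NOT_A_GENE"), "unknown gene")
  expect_error(frr_percent(fit, half, lambda_obs = 1), "exceed")
})

test_that("a strong known gene's FRR share matches the truth-based value", {
  # one strong gene (OR 4, carrier freq 2e-3) among nulls at biobank scale
  counts <- simulate_gene_counts(1000, alpha = 0, eta = 2, n1 = 5e4, n0 = 2e5,
                                 carrier_freq = 2e-3, seed = 13)
  q <- 2e-3; or <- 4
  odds <- q / (1 - q) * exp(log(or))
  set.seed(14)
  counts$a[1] <- rbinom(1, 5e4, odds / (1 + odds))
  counts$b[1] <- rbinom(1, 2e5, q)
  fit <- fit_eb(counts, controls_only = TRUE)
  truth_pct <- 100 * (gene_frr(q / 2, log(or)) - 1) / (2 - 1)
  got <- frr_percent(fit, counts$gene_id[1], lambda_obs = 2)
  expect_gt(fit$genes$posterior_assoc[1], 0.99)
  # 25% band: posterior shrinkage plus count noise gave ~9-13% deviations
  # across pilot seeds
  expect_rel_equal(got, truth_pct, 0.25)
})
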