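# Empirical-Bayes decomposition of the familial relative risk (FRR)
# explained by protein-truncating variants.

#' Familial relative risk contributed by one gene
#'
#' Under a rare dominant model in which all PTVs in a gene have aggregate
#' allele frequency `p` and confer the same relative risk `exp(beta)`, the
#' multiplicative contribution of the gene to the first-degree familial
#' relative risk is
#' \deqn{\lambda_j = 1 + \frac{p\,(e^{\beta}-1)^2}{(2p(e^{\beta}-1)+1)^2}.}
#' `lambda_j >= 1` always, with equality iff `p = 0` or `beta = 0`.
#'
#' @param p Aggregate PTV allele frequency in `[0, 0.5]` (note: allele
#'   frequency, about half the carrier frequency for rare variants).
#' @param beta Per-carrier log odds ratio.
#' @return `lambda_j`, the gene's FRR contribution.
#' @examples
#' gene_frr(0.001, log(3))
#' @export
gene_frr <- function(p, beta) {
  check_prob(p, "p", upper = 0.5)
  r <- exp(beta) - 1
  den <- 2 * p * r + 1
  if (any(den <= 0)) stop_validation("degenerate denominator: 2p(e^beta - 1) + 1 <= 0")
  1 + p * r^2 / den^2
}

#' Total FRR over genes
#'
#' Assuming risks conferred by different genes combine additively on the
#' excess-risk scale, the total familial relative risk over `J` genes is
#' `1 + sum(lambda_j - 1)`.
#'
#' @param lambdas Vector of per-gene FRR contributions, all `>= 1`.
#' @return Total FRR.
#' @export
total_frr <- function(lambdas) {
  if (any(lambdas < 1)) stop_validation("per-gene lambda must be >= 1")
  1 + sum(lambdas - 1)
}

#' Gene-level carrier counts
#'
#' Container for the per-gene summary statistics the empirical-Bayes model
#' consumes: carrier counts in cases (`a`) and controls (`b`), cohort
#' sizes, and the structural-variant allele frequency used to adjust the
#' PTV frequency.
#'
#' @param gene_id Gene labels.
#' @param a,b Carrier counts in cases / controls.
#' @param n1,n0 Case / control totals.
#' @param sv_freq Structural-variant allele frequency (0 if none).
#' @return Data frame of class `gene_counts`.
#' @export
gene_counts <- function(gene_id, a, b, n1, n0, sv_freq = 0) {
  df <- data.frame(gene_id = as.character(gene_id), a = a, b = b,
                   n1 = n1, n0 = n0, sv_freq = sv_freq,
                   stringsAsFactors = FALSE)
  if (any(df$a > df$n1) || any(df$b > df$n0))
    stop_validation("carrier counts exceed cohort sizes")
  if (any(df$a < 0) || any(df$b < 0) || any(df$sv_freq < 0))
    stop_validation("counts and frequencies must be non-negative")
  class(df) <- c("gene_counts", class(df))
  df
}

#' Structural-variant-adjusted PTV allele frequency
#'
#' Estimates the PTV allele frequency from the carrier counts over the full
#' sample, `p_hat = (a + b) / (2 (n1 + n0))`, then adds the
#' structural-variant allele frequency: large deletions that remove exons
#' are functionally equivalent to PTVs but invisible to exome calling, and
#' since SV and PTV carriers are disjoint rare events to first order the
#' adjustment is additive on the allele-frequency scale.
#'
#' @param counts A [gene_counts()] data frame (or any data frame with
#'   columns `a`, `b`, `n1`, `n0`, `sv_freq`).
#' @param controls_only If `TRUE`, estimate from controls only
#'   (`b / (2 n0)`).
#' @return Numeric vector of adjusted allele frequencies.
#' @export
adjusted_frequency <- function(counts, controls_only = FALSE) {
  p_hat <- if (controls_only) counts$b / (2 * counts$n0)
           else (counts$a + counts$b) / (2 * (counts$n1 + counts$n0))
  p_adj <- p_hat + counts$sv_freq
  if (any(p_adj > 0.5)) stop_validation("adjusted allele frequency exceeds 0.5")
  p_adj
}

# Empirical log-OR and Woolf standard error from the 2x2 carrier table,
# with a 0.5 continuity correction applied only when some cell is zero.
empirical_logor <- function(a, b, n1, n0) {
  cells <- cbind(a, n1 - a, b, n0 - b)
  cc <- as.numeric(apply(cells, 1, function(r) any(r == 0))) * 0.5
  a2 <- a + cc; c2 <- n1 - a + cc; b2 <- b + cc; d2 <- n0 - b + cc
  list(beta_hat = log(a2 * d2 / (b2 * c2)),
       se = sqrt(1 / a2 + 1 / b2 + 1 / c2 + 1 / d2))
}

#' Effect-size mixture prior
#'
#' Prior over gene log odds ratios: a proportion `alpha` of genes are risk
#' associated with `beta ~ Exponential(rate = eta)`; the remaining genes
#' are null (`beta = 0`).  The exponential captures a skewed landscape —
#' a few genes of large effect, most associated genes of small effect.
#'
#' @param alpha Proportion of risk-associated genes in `[0, 1]`.
#' @param eta Exponential rate (`> 0`); the median OR among associated
#'   genes is `exp(log(2) / eta)`.
#' @return Object of class `eb_prior`.
#' @export
eb_prior <- function(alpha, eta) {
  check_prob(alpha, "alpha")
  if (!is.numeric(eta) || length(eta) != 1 || is.na(eta) || eta <= 0)
    stop_validation("eta must be a positive scalar")
  structure(list(alpha = alpha, eta = eta), class = "eb_prior")
}

#' Median odds ratio among associated genes
#'
#' The median of `Exponential(eta)` is `log(2)/eta`, so the median OR of
#' risk-associated genes under the mixture prior is `exp(log(2)/eta)`.
#'
#' @param prior An [eb_prior()] (or anything with an `eta` element).
#' @return Median OR (`> 1`).
#' @export
median_or <- function(prior) {
  if (prior$eta <= 0) stop_validation("eta must be positive")
  exp(log(2) / prior$eta)
}

# log of the integral  int_0^inf  phi(beta_hat; beta, s^2) eta e^(-eta beta) dbeta
# = eta * exp(eta^2 s^2 / 2 - eta beta_hat) * Phi((beta_hat - eta s^2)/s)
# (exponentially modified Gaussian tail), computed on the log scale.
log_assoc_component <- function(beta_hat, s, eta) {
  log(eta) + eta^2 * s^2 / 2 - eta * beta_hat +
    stats::pnorm((beta_hat - eta * s^2) / s, log.p = TRUE)
}

#' Approximate marginal log-likelihood of one gene's carrier counts
#'
#' The observed carrier counts are summarised by the empirical log-OR
#' `beta_hat` of the 2x2 carrier table (0.5 continuity correction when any
#' cell is zero) with Woolf standard error `s`, and `beta_hat` is treated
#' as normal about the true `beta`.  Under the mixture prior the marginal
#' likelihood is
#' \deqn{(1-\alpha)\,\phi(\hat\beta; 0, s^2) +
#'   \alpha \int_0^\infty \phi(\hat\beta; \beta, s^2)\,\eta e^{-\eta\beta}\,d\beta,}
#' the integral having the closed form of an exponentially modified
#' Gaussian tail.  With `likelihood = "quadrature"` the integral is instead
#' evaluated by adaptive quadrature — an independent cross-check of the
#' closed form.
#'
#' @param counts A [gene_counts()] data frame (any number of rows).
#' @param prior An [eb_prior()].
#' @param likelihood `"closed_form"` (default) or `"quadrature"`.
#' @return Numeric vector of per-gene log marginal likelihoods.
#' @export
marginal_loglik <- function(counts, prior, likelihood = c("closed_form", "quadrature")) {
  likelihood <- match.arg(likelihood)
  if (!inherits(prior, "eb_prior")) prior <- eb_prior(prior$alpha, prior$eta)
  if (any(counts$a + counts$b < 1))
    stop_validation("each gene needs at least one carrier")
  eo <- empirical_logor(counts$a, counts$b, counts$n1, counts$n0)
  log_null <- stats::dnorm(eo$beta_hat, 0, eo$se, log = TRUE)
  if (prior$alpha == 0) return(log_null)
  if (likelihood == "closed_form") {
    log_assoc <- log_assoc_component(eo$beta_hat, eo$se, prior$eta)
  } else {
    log_assoc <- mapply(function(bh, s) {
      val <- stats::integrate(function(b) stats::dnorm(bh, b, s) *
                                stats::dexp(b, rate = prior$eta),
                              0, Inf, rel.tol = 1e-12)$value
      log(val)
    }, eo$beta_hat, eo$se)
  }
  if (prior$alpha == 1) return(log_assoc)
  logsumexp2(log(1 - prior$alpha) + log_null, log(prior$alpha) + log_assoc)
}

# Gauss-Legendre nodes on [0, upper] for posterior integrals over beta.
beta_quadrature <- function(n_nodes = 256, upper = 5) {
  gl <- pracma::gaussLegendre(n_nodes, 0, upper)
  list(x = gl$x, w = gl$w)
}

#' Fit the empirical-Bayes effect-size mixture
#'
#' Maximises the summed [marginal_loglik()] over `(alpha, eta)` by bounded
#' quasi-Newton optimisation (`L-BFGS-B` on `logit(alpha)`, `log(eta)`)
#' from five deterministic starting points, then fills per-gene posterior
#' quantities:
#' \itemize{
#'   \item `posterior_assoc`: posterior probability the gene is risk
#'     associated, `alpha L1 / ((1-alpha) L0 + alpha L1)`;
#'   \item `expected_lambda_minus1`: posterior mean of
#'     `gene_frr(p_adj, beta) - 1`, integrating `beta` over the posterior
#'     of the associated component by 256-node Gauss-Legendre quadrature on
#'     `[0, 5]` (the null component contributes 0);
#'   \item `p_adj`: structural-variant-adjusted allele frequency.
#' }
#'
#' @param counts A [gene_counts()] data frame, one row per gene; at least
#'   100 genes are recommended for a stable fit (warns below).
#' @param controls_only Passed to [adjusted_frequency()].
#' @param n_nodes,beta_max Quadrature resolution and upper limit for
#'   posterior integrals.
#' @return An `eb_fit` list: `prior` ([eb_prior()]), `loglik`, `converged`,
#'   and `genes`, a data frame with the per-gene posteriors.
#' @export
fit_eb <- function(counts, controls_only = FALSE, n_nodes = 256, beta_max = 5) {
  if (nrow(counts) < 100)
    warning("fit_eb: fewer than 100 genes; mixture estimates may be unstable")
  keep <- counts$a + counts$b >= 1
  counts <- counts[keep, , drop = FALSE]
  eo <- empirical_logor(counts$a, counts$b, counts$n1, counts$n0)

  negll <- function(par) {
    alpha <- stats::plogis(par[1]); eta <- exp(par[2])
    log_null <- stats::dnorm(eo$beta_hat, 0, eo$se, log = TRUE)
    log_assoc <- log_assoc_component(eo$beta_hat, eo$se, eta)
    ll <- sum(logsumexp2(log(1 - alpha) + log_null, log(alpha) + log_assoc))
    if (!is.finite(ll)) 1e10 else -ll
  }
  starts <- cbind(alpha = c(1e-4, 1e-3, 0.01, 0.05, 0.2),
                  eta = c(0.5, 1, 2, 4, 8))
  best <- NULL
  for (k in seq_len(nrow(starts))) {
    par0 <- c(stats::qlogis(starts[k, 1]), log(starts[k, 2]))
    opt <- tryCatch(
      stats::optim(par0, negll, method = "L-BFGS-B",
                   lower = c(stats::qlogis(1e-8), log(1e-3)),
                   upper = c(stats::qlogis(0.999), log(50))),
      error = function(e) NULL)
    if (!is.null(opt) && (is.null(best) || opt$value < best$value)) best <- opt
  }
  if (is.null(best)) stop("fit_eb: optimiser failed from every start")
  alpha <- stats::plogis(best$par[1]); eta <- exp(best$par[2])
  prior <- eb_prior(alpha, eta)

  # per-gene posteriors
  log_null <- stats::dnorm(eo$beta_hat, 0, eo$se, log = TRUE)
  log_assoc <- log_assoc_component(eo$beta_hat, eo$se, eta)
  la <- log(alpha) + log_assoc
  ln <- log(1 - alpha) + log_null
  posterior_assoc <- 1 / (1 + exp(ln - la))

  p_adj <- adjusted_frequency(counts, controls_only = controls_only)
  gl <- beta_quadrature(n_nodes, beta_max)
  exp_lm1 <- vapply(seq_len(nrow(counts)), function(i) {
    # posterior density over beta within the associated component
    dens <- stats::dnorm(eo$beta_hat[i], gl$x, eo$se[i]) *
      stats::dexp(gl$x, rate = eta)
    norm <- sum(gl$w * dens)
    if (norm <= 0) return(0)
    lam1 <- gene_frr(rep(p_adj[i], length(gl$x)), gl$x) - 1
    posterior_assoc[i] * sum(gl$w * dens * lam1) / norm
  }, numeric(1))

  genes <- data.frame(gene_id = counts$gene_id,
                      beta_hat = eo$beta_hat, se = eo$se,
                      p_adj = p_adj,
                      posterior_assoc = posterior_assoc,
                      expected_lambda_minus1 = exp_lm1,
                      stringsAsFactors = FALSE)
  structure(list(prior = prior, loglik = -best$value,
                 converged = best$convergence == 0, genes = genes),
            class = "eb_fit")
}

#' @export
print.eb_fit <- function(x, ...) {
  cat("Empirical-Bayes effect-size mixture fit\n")
  cat(sprintf("  alpha (proportion of risk genes): %.4g\n", x$prior$alpha))
  cat(sprintf("  eta (exponential rate):           %.4g  (median OR %.3f)\n",
              x$prior$eta, median_or(x$prior)))
  cat(sprintf("  log-likelihood: %.2f  converged: %s  genes: %d\n",
              x$loglik, x$converged, nrow(x$genes)))
  invisible(x)
}

#' Percent of the familial relative risk explained by a gene set
#'
#' The share of the observed first-degree FRR attributable to PTVs in a
#' gene subset:
#' `100 * sum(expected_lambda_minus1) / (lambda_obs - 1)`.  Additive over
#' disjoint subsets.  `lambda_obs` defaults to 2.0, the conventional
#' first-degree familial relative risk for breast cancer.
#'
#' @param fit An `eb_fit` from [fit_eb()].
#' @param subset Optional character vector of gene ids (default: all fitted
#'   genes); must be a subset of the fitted genes.
#' @param lambda_obs Observed total first-degree FRR (`> 1`).
#' @return Percentage of `lambda_obs - 1` explained.
#' @export
frr_percent <- function(fit, subset = NULL, lambda_obs = 2.0) {
  if (lambda_obs <= 1) stop_validation("lambda_obs must exceed 1")
  genes <- fit$genes
  if (is.null(subset)) {
    sel <- rep(TRUE, nrow(genes))
  } else {
    unknown <- setdiff(subset, genes$gene_id)
    if (length(unknown))
      stop_validation("unknown gene(s) in subset: ",
                      paste(utils::head(unknown, 5), collapse = ", "))
    sel <- genes$gene_id %in% subset
  }
  100 * sum(genes$expected_lambda_minus1[sel]) / (lambda_obs - 1)
}

#' Simulate per-gene carrier counts under the mixture model
#'
#' Draws the summary data the empirical-Bayes model is fitted to: per gene,
#' a log-OR from the mixture prior, then carrier counts in controls at the
#' population carrier frequency and in cases at the odds-scaled frequency.
#' Used for parameter-recovery checks of [fit_eb()] at full cohort scale
#' without simulating individual samples.
#'
#' @param n_genes Number of genes.
#' @param alpha,eta True mixture parameters ([eb_prior()] scale).
#' @param n1,n0 Case / control totals.
#' @param carrier_freq Scalar or per-gene vector of population carrier
#'   frequencies (carriers, not alleles).
#' @param seed Integer seed.
#' @return A [gene_counts()] data frame with attribute `"truth"` (data
#'   frame of per-gene `carrier_freq`, `beta`).
#' @export
simulate_gene_counts <- function(n_genes, alpha, eta, n1, n0,
                                 carrier_freq = 0.001, seed = 1) {
  check_count(n_genes, "n_genes", min = 1L)
  beta <- draw_gene_effects(n_genes, alpha, eta, seed = seed)
  q <- rep_len(carrier_freq, n_genes)
  with_seed(seed + 1L, {
    odds <- q / (1 - q) * exp(beta)
    q_case <- odds / (1 + odds)
    a <- stats::rbinom(n_genes, n1, q_case)
    b <- stats::rbinom(n_genes, n0, q)
  })
  out <- gene_counts(sprintf("G%05d", seq_len(n_genes)), a = a, b = b,
                     n1 = n1, n0 = n0, sv_freq = 0)
  attr(out, "truth") <- data.frame(gene_id = out$gene_id,
                                   carrier_freq = q, beta = beta,
                                   stringsAsFactors = FALSE)
  out
}
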