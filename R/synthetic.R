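# Synthetic cohorts, proband-relative pairs and annotated toy variants
# with the statistical structure the analysis stages assume.

#' Per-gene simulation parameters
#'
#' @param gene_id Gene label.
#' @param carrier_freq Aggregate PTV carrier probability in the population
#'   (`[0, 0.5]`); the allele frequency is `carrier_freq / 2` under the
#'   rare-variant approximation.
#' @param log_or Per-carrier log odds ratio for disease.
#' @param log_or_young Optional log-OR for cases diagnosed under 50
#'   (defaults to `log_or`); lets age-restricted scans be exercised.
#' @param sv_carrier_freq Structural-variant carrier frequency.
#' @param chrom Chromosome label (`"X"` engages the females-only rule).
#' @param missense_count,missense_af,cadd_range,helix_range Parameters for
#'   toy missense annotation simulation.
#' @return Object of class `gene_spec`.
#' @export
gene_spec <- function(gene_id, carrier_freq, log_or = 0, log_or_young = NULL,
                      sv_carrier_freq = 0, chrom = "1", missense_count = 0,
                      missense_af = 5e-4, cadd_range = c(10, 40),
                      helix_range = c(0, 1)) {
  check_prob(carrier_freq, "carrier_freq", upper = 0.5)
  check_prob(sv_carrier_freq, "sv_carrier_freq")
  if (carrier_freq + sv_carrier_freq >= 1)
    stop_validation("carrier_freq + sv_carrier_freq must be < 1")
  if (missense_af < 0) stop_validation("missense_af must be >= 0")
  structure(list(gene_id = gene_id, carrier_freq = carrier_freq,
                 log_or = log_or,
                 log_or_young = if (is.null(log_or_young)) log_or else log_or_young,
                 sv_carrier_freq = sv_carrier_freq, chrom = chrom,
                 missense_count = missense_count, missense_af = missense_af,
                 cadd_range = cadd_range, helix_range = helix_range),
            class = "gene_spec")
}

#' Study sampling specification
#'
#' Oversampling multipliers implement family-history / early-onset
#' enrichment by rejection sampling of cases: a case with a positive family
#' history (or young at diagnosis) is accepted with probability
#' proportional to the multiplier, relative to unenriched cases.
#'
#' @param label Study label.
#' @param fh_oversample Acceptance multiplier for family-history-positive
#'   cases (`>= 1`).
#' @param young_oversample Acceptance multiplier for cases under 50.
#' @param country_pool Countries sampled uniformly for this study.
#' @param libprep Library-preparation label.
#' @return Object of class `study_spec`.
#' @export
study_spec <- function(label, fh_oversample = 1, young_oversample = 1,
                       country_pool = c("UK", "DE", "ES", "FR"),
                       libprep = paste0(label, "_lib")) {
  if (fh_oversample < 1 || young_oversample < 1)
    stop_validation("oversampling multipliers must be >= 1")
  structure(list(label = label, fh_oversample = fh_oversample,
                 young_oversample = young_oversample,
                 country_pool = country_pool, libprep = libprep),
            class = "study_spec")
}

#' Cohort simulation configuration
#'
#' @param n_cases,n_controls Totals over all studies (split evenly across
#'   `study_specs`).
#' @param genes List of [gene_spec()] objects.
#' @param baseline_risk Lifetime disease probability `K` of a non-carrier
#'   (also the affection probability of a non-carrier's relative).
#' @param fh_rate_noncarrier Background probability of a positive family
#'   history from sources other than the simulated first-degree relative.
#' @param seed Integer seed, recorded in all outputs.
#' @param study_specs List of [study_spec()] objects.
#' @param p_female Probability a sample is female (sex is a noise label
#'   with no effect on disease).
#' @param young_frac Probability a sample is in the `"<50"` age band.
#' @param pc_confound Optional length-10 vector of log-odds effects of the
#'   principal components on disease (default zero: PCs are pure noise).
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(n_cases, n_controls, genes, baseline_risk = 0.1,
                       fh_rate_noncarrier = 0.05, seed = 1,
                       study_specs = list(study_spec("study1")),
                       p_female = 0.5, young_frac = 0.3,
                       pc_confound = rep(0, 10)) {
  check_count(n_cases, "n_cases", min = 1L)
  check_count(n_controls, "n_controls", min = 1L)
  if (baseline_risk <= 0 || baseline_risk >= 1)
    stop_validation("baseline_risk must lie strictly in (0, 1)")
  check_prob(fh_rate_noncarrier, "fh_rate_noncarrier")
  if (!length(genes) || !all(vapply(genes, inherits, logical(1), "gene_spec")))
    stop_validation("genes must be a non-empty list of gene_spec objects")
  structure(list(n_cases = n_cases, n_controls = n_controls, genes = genes,
                 baseline_risk = baseline_risk,
                 fh_rate_noncarrier = fh_rate_noncarrier,
                 seed = check_count(seed, "seed"), study_specs = study_specs,
                 p_female = p_female, young_frac = young_frac,
                 pc_confound = pc_confound),
            class = "sim_config")
}

#' Draw per-gene log odds ratios from the mixture prior
#'
#' A proportion `alpha` of genes are risk associated with
#' `beta ~ Exponential(rate = eta)`; the rest are null (`beta = 0`).
#'
#' @param n_genes Number of genes.
#' @param alpha Proportion of associated genes in `[0, 1]`.
#' @param eta Exponential rate (`> 0`); median OR among associated genes is
#'   `exp(log(2)/eta)`.
#' @param seed Integer seed.
#' @return Numeric vector of per-gene `beta`.
#' @examples
#' draw_gene_effects(10, alpha = 0.5, eta = 2, seed = 1)
#' @export
draw_gene_effects <- function(n_genes, alpha, eta, seed) {
  check_count(n_genes, "n_genes", min = 1L)
  check_prob(alpha, "alpha")
  if (!is.numeric(eta) || length(eta) != 1 || is.na(eta) || eta <= 0)
    stop_validation("eta must be a positive scalar")
  with_seed(seed, {
    assoc <- stats::runif(n_genes) < alpha
    beta <- numeric(n_genes)
    beta[assoc] <- stats::rexp(sum(assoc), rate = eta)
    beta
  })
}

# Draw sparse carrier index sets for one block of nb individuals:
# list (per gene) of carrier row indices.
draw_carrier_sets <- function(nb, freqs) {
  lapply(freqs, function(q) {
    k <- stats::rbinom(1, nb, q)
    if (k == 0) integer() else sort(sample.int(nb, k))
  })
}

#' Simulate a case-control cohort
#'
#' Generates a multi-study case-control dataset under the generative model
#' the burden pipeline assumes:
#' \itemize{
#'   \item per gene, carrier status is Bernoulli at the gene's population
#'     carrier frequency (no diploid genotypes — the analysis collapses to
#'     0/1 anyway);
#'   \item disease follows a logistic model,
#'     `logit P(d=1) = logit(K) + sum_j beta_j c_j` (plus any configured
#'     PC confounding), with `K` the non-carrier baseline risk;
#'   \item family history: one first-degree relative is simulated per
#'     sample, inheriting each carried allele with probability 1/2 and
#'     affected with probability `min(1, K exp(sum_j beta_j c'_j))`; `f = 1`
#'     if that relative is affected or by an independent background draw at
#'     `fh_rate_noncarrier`.  Thus risk-gene carriers have elevated family
#'     history, with a log-OR for `f` about half that for `d`;
#'   \item per study, cases are accepted by rejection sampling weighted by
#'     the study's family-history / early-onset oversampling multipliers;
#'   \item covariates (sex, age band, country, library prep, 10 PCs,
#'     ER/PR/HER2/TN markers for cases) are populated; by default they
#'     carry no true effect.
#' }
#'
#' @param config A [sim_config()].
#' @return A `simulated_cohort`: list with `phenotypes` (data frame),
#'   `carriers` (a `carrier_table`), `truth` (per-gene `carrier_freq`,
#'   `log_or`, `chrom`), `gene_chrom` (named vector), and `seed`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  genes <- config$genes
  gids <- vapply(genes, `[[`, character(1), "gene_id")
  freqs <- vapply(genes, `[[`, numeric(1), "carrier_freq")
  beta <- vapply(genes, `[[`, numeric(1), "log_or")
  beta_y <- vapply(genes, `[[`, numeric(1), "log_or_young")
  K <- config$baseline_risk
  n_st <- length(config$study_specs)
  case_quota <- diff(round(seq(0, config$n_cases, length.out = n_st + 1)))
  ctrl_quota <- diff(round(seq(0, config$n_controls, length.out = n_st + 1)))

  with_seed(config$seed, {
    pheno <- list(); carr_idx <- rep(list(list()), length(genes)); n_out <- 0L
    for (s in seq_len(n_st)) {
      sp <- config$study_specs[[s]]
      need_case <- case_quota[s]; need_ctrl <- ctrl_quota[s]
      wmax <- sp$fh_oversample * sp$young_oversample
      tries <- 0L
      while ((need_case > 0 || need_ctrl > 0) && tries < 30L) {
        tries <- tries + 1L
        nb <- min(1e6, max(2000L, ceiling(2 * max(need_case, 1) * wmax / K),
                           ceiling(1.2 * max(need_ctrl, 1) / (1 - K))))
        young <- stats::runif(nb) < config$young_frac
        sex <- ifelse(stats::runif(nb) < config$p_female, "F", "M")
        pcs <- matrix(stats::rnorm(nb * 10), nb, 10)
        sets <- draw_carrier_sets(nb, freqs)
        eta <- rep(stats::qlogis(K), nb) + drop(pcs %*% config$pc_confound)
        rel_lrr <- numeric(nb)
        for (g in seq_along(genes)) {
          idx <- sets[[g]]
          if (!length(idx)) next
          eta[idx] <- eta[idx] + ifelse(young[idx], beta_y[g], beta[g])
          transmitted <- idx[stats::runif(length(idx)) < 0.5]
          rel_lrr[transmitted] <- rel_lrr[transmitted] + beta[g]
        }
        d <- as.integer(stats::runif(nb) < stats::plogis(eta))
        rel_aff <- stats::runif(nb) < pmin(1, K * exp(rel_lrr))
        f <- as.integer(rel_aff | stats::runif(nb) < config$fh_rate_noncarrier)

        w <- ifelse(f == 1, sp$fh_oversample, 1) *
             ifelse(young, sp$young_oversample, 1)
        case_ok <- d == 1 & stats::runif(nb) < w / wmax
        take_case <- utils::head(which(case_ok), need_case)
        take_ctrl <- utils::head(which(d == 0), need_ctrl)
        take <- c(take_case, take_ctrl)
        if (!length(take)) next
        need_case <- need_case - length(take_case)
        need_ctrl <- need_ctrl - length(take_ctrl)

        is_case <- d[take] == 1
        er <- pr <- her2 <- tn <- rep(NA_character_, length(take))
        nc <- sum(is_case)
        if (nc > 0) {
          er[is_case] <- ifelse(stats::runif(nc) < 0.8, "+", "-")
          pr[is_case] <- ifelse(stats::runif(nc) < 0.7, "+", "-")
          her2[is_case] <- ifelse(stats::runif(nc) < 0.15, "+", "-")
          tn[is_case] <- ifelse(er[is_case] == "-" & pr[is_case] == "-" &
                                  her2[is_case] == "-", "+", "-")
        }
        blk <- data.frame(
          sample_id = NA_character_, d = d[take], f = f[take],
          sex = sex[take], age_band = ifelse(young[take], "<50", "50+"),
          ER = er, PR = pr, HER2 = her2, TN = tn,
          study = sp$label,
          country = sample(sp$country_pool, length(take), replace = TRUE),
          libprep = sp$libprep, stringsAsFactors = FALSE)
        pcs_take <- pcs[take, , drop = FALSE]
        colnames(pcs_take) <- paste0("PC", 1:10)
        blk <- cbind(blk, as.data.frame(pcs_take))
        pheno[[length(pheno) + 1]] <- blk
        for (g in seq_along(genes)) {
          hit <- match(intersect(sets[[g]], take), take)
          if (length(hit)) carr_idx[[g]][[length(carr_idx[[g]]) + 1]] <- n_out + hit
        }
        n_out <- n_out + length(take)
      }
      if (need_case > 0 || need_ctrl > 0)
        stop("simulation error: could not generate requested cases/controls ",
             "for study '", sp$label, "' (baseline_risk too small or ",
             "oversampling too aggressive); still needed ", need_case,
             " cases and ", need_ctrl, " controls")
    }
    phenotypes <- do.call(rbind, pheno)
    phenotypes$sample_id <- sprintf("S%06d", seq_len(nrow(phenotypes)))
    rownames(phenotypes) <- NULL
    mat <- matrix(0L, nrow(phenotypes), length(genes),
                  dimnames = list(phenotypes$sample_id, gids))
    for (g in seq_along(genes)) {
      rows <- unlist(carr_idx[[g]], use.names = FALSE)
      if (length(rows)) mat[rows, g] <- 1L
    }
    truth <- data.frame(gene_id = gids, carrier_freq = freqs, log_or = beta,
                        chrom = vapply(genes, `[[`, character(1), "chrom"),
                        stringsAsFactors = FALSE)
    structure(list(phenotypes = phenotypes,
                   carriers = carrier_table(mat, class = "PTV"),
                   truth = truth,
                   gene_chrom = stats::setNames(truth$chrom, truth$gene_id),
                   seed = config$seed),
              class = "simulated_cohort")
  })
}

#' @export
print.simulated_cohort <- function(x, ...) {
  cat("Simulated cohort:", sum(x$phenotypes$d == 1), "cases /",
      sum(x$phenotypes$d == 0), "controls;", ncol(x$carriers), "genes; seed",
      x$seed, "\n")
  invisible(x)
}

#' Simulate proband-relative pairs for one gene
#'
#' Monte-Carlo oracle for the single-gene familial relative risk: draws a
#' proband carrying the gene's PTVs at `carrier_freq`, a first-degree
#' relative who shares a transmitted allele with probability 1/2 and
#' otherwise carries at the population frequency, and affection for both
#' with probability `min(1, K exp(beta * carrier))`.
#'
#' @param carrier_freq Population carrier probability.
#' @param log_or Per-carrier log relative risk `beta`.
#' @param K Baseline affection probability; `K * exp(log_or)` must be
#'   `<= 1`.
#' @param n Number of pairs.
#' @param seed Integer seed.
#' @return Data frame with binary columns `proband_carrier`,
#'   `proband_affected`, `relative_carrier`, `relative_affected`.
#' @export
simulate_proband_relative_pairs <- function(carrier_freq, log_or, K, n, seed) {
  check_prob(carrier_freq, "carrier_freq", upper = 0.5)
  check_prob(K, "K")
  check_count(n, "n", min = 1L)
  if (K * exp(log_or) > 1)
    stop_validation("penetrance K * exp(log_or) exceeds 1")
  with_seed(seed, {
    pc <- stats::runif(n) < carrier_freq
    shared <- stats::runif(n) < 0.5
    rc <- (pc & shared) | (stats::runif(n) < carrier_freq)
    pa <- stats::runif(n) < K * exp(log_or * pc)
    ra <- stats::runif(n) < K * exp(log_or * rc)
    data.frame(proband_carrier = as.integer(pc),
               proband_affected = as.integer(pa),
               relative_carrier = as.integer(rc),
               relative_affected = as.integer(ra))
  })
}

#' Empirical familial relative risk from simulated pairs
#'
#' `P(relative affected | proband affected) / P(relative affected)`,
#' estimated by tabulation.
#'
#' @param pairs Output of [simulate_proband_relative_pairs()].
#' @return Positive scalar FRR estimate.
#' @export
empirical_frr <- function(pairs) {
  if (nrow(pairs) < 1) stop_validation("no pairs supplied")
  if (sum(pairs$proband_affected) < 1)
    stop_validation("no affected probands: FRR undefined")
  p_rel <- mean(pairs$relative_affected)
  if (p_rel == 0)
    stop(structure(class = c("exomeburden_undefined_estimate", "error", "condition"),
                   list(message = "no affected relatives: FRR estimate undefined",
                        call = sys.call())))
  mean(pairs$relative_affected[pairs$proband_affected == 1]) / p_rel
}

#' Simulate annotated toy variants
#'
#' Emits toy transcripts (ordered exons, 0-based half-open transcript-
#' forward coordinates) and a variant panel that deliberately covers every
#' classification boundary: PTVs in interior exons, in the last exon, at
#' the penultimate exon's 3' end at distances 49/50/51 bases (the 50-base
#' NMD-escape threshold exactly and one base either side), and missense
#' variants with allele frequencies straddling 0.001 (including exactly
#' 0.001) and CADD / Helix scores straddling 20 / 0.5.  A small genotype
#' matrix per gene (entries 0/1/2/NA) accompanies the panel.
#'
#' @param n_genes Number of genes.
#' @param exons_per_gene Integer range (min, max) of exon counts, min
#'   `>= 3`.
#' @param extra_variants_per_gene Integer range of additional randomly
#'   placed variants beyond the deterministic boundary set.
#' @param n_samples Samples in the genotype matrices.
#' @param seed Integer seed; identical seeds give byte-identical output.
#' @return List with `transcripts` (named list of [transcript_model()]),
#'   `transcript_table` (BED-like exon data frame), `annotations` (variant
#'   annotation data frame) and `genotypes` (named list of sample x variant
#'   allele-count matrices).
#' @export
simulate_annotated_variants <- function(n_genes = 5, exons_per_gene = c(3, 6),
                                        extra_variants_per_gene = c(2, 4),
                                        n_samples = 30, seed = 1) {
  check_count(n_genes, "n_genes", min = 1L)
  if (exons_per_gene[1] < 3) stop_validation("need at least 3 exons per gene")
  with_seed(seed, {
    transcripts <- list(); ann <- list(); geno <- list(); tx_rows <- list()
    for (gi in seq_len(n_genes)) {
      gid <- sprintf("GENE%03d", gi)
      n_ex <- sample(seq(exons_per_gene[1], exons_per_gene[2]), 1)
      lens <- sample(150:400, n_ex, replace = TRUE)
      starts <- cumsum(c(0, utils::head(lens, -1) + 100))   # 100-bp introns
      exons <- cbind(start = starts, end = starts + lens)
      tx <- transcript_model(gid, exons, strand = sample(c("+", "-"), 1))
      transcripts[[gid]] <- tx
      tx_rows[[gid]] <- data.frame(gene_id = gid, exon_index = seq_len(n_ex),
                                   start = exons[, 1], end = exons[, 2],
                                   strand = tx$strand, stringsAsFactors = FALSE)
      pen <- n_ex - 1
      pen_end <- exons[pen, 2]
      mid <- function(i) floor((exons[i, 1] + exons[i, 2]) / 2)
      v <- list(
        list(csq = "stop_gained", ex = 1, pos = mid(1)),                 # interior
        list(csq = "frameshift", ex = n_ex, pos = mid(n_ex)),            # last exon
        list(csq = "stop_gained", ex = pen, pos = pen_end - 50),         # dist 50
        list(csq = "stop_gained", ex = pen, pos = pen_end - 49),         # dist 49
        list(csq = "stop_gained", ex = pen, pos = pen_end - 51),         # dist 51
        list(csq = "splice_donor", ex = 1, pos = exons[1, 2] - 1),
        list(csq = "missense", ex = 1, pos = mid(1) + 1,
             paf = 5e-4, caf = 5e-4, cadd = 25, helix = 0.7),            # rare, both tiers
        list(csq = "missense", ex = 1, pos = mid(1) + 2,
             paf = 5e-4, caf = 2e-3, cadd = 25, helix = 0.7),            # fails dual filter
        list(csq = "missense", ex = 1, pos = mid(1) + 3,
             paf = 1e-3, caf = 1e-3, cadd = 25, helix = 0.7),            # AF exactly 0.001
        list(csq = "missense", ex = 2, pos = mid(2),
             paf = 5e-4, caf = 5e-4, cadd = 19, helix = 0.6),            # CADD below 20
        list(csq = "missense", ex = 2, pos = mid(2) + 1,
             paf = 5e-4, caf = 5e-4, cadd = 20, helix = 0.5)             # edges: 20 in, 0.5 out
      )
      n_extra <- sample(seq(extra_variants_per_gene[1],
                            extra_variants_per_gene[2]), 1)
      for (k in seq_len(n_extra)) {
        ex <- sample(n_ex, 1)
        v[[length(v) + 1]] <- list(
          csq = sample(c("missense", "stop_gained", "other"), 1),
          ex = ex, pos = exons[ex, 1] + sample(lens[ex], 1) - 1,
          paf = stats::runif(1, 0, 2e-3), caf = stats::runif(1, 0, 2e-3),
          cadd = stats::runif(1, 10, 40), helix = stats::runif(1))
      }
      rows <- do.call(rbind, lapply(seq_along(v), function(k) {
        vv <- v[[k]]
        data.frame(variant_id = sprintf("%s_v%02d", gid, k), gene_id = gid,
                   consequence = vv$csq, exon_index = vv$ex, position = vv$pos,
                   panel_af = if (is.null(vv$paf)) 1e-4 else vv$paf,
                   cohort_af = if (is.null(vv$caf)) 1e-4 else vv$caf,
                   cadd = if (is.null(vv$cadd)) NA_real_ else vv$cadd,
                   helix = if (is.null(vv$helix)) NA_real_ else vv$helix,
                   stringsAsFactors = FALSE)
      }))
      ann[[gid]] <- rows
      m <- matrix(sample(c(0L, 0L, 0L, 0L, 1L, 2L, NA), n_samples * nrow(rows),
                         replace = TRUE),
                  n_samples, nrow(rows),
                  dimnames = list(sprintf("s%03d", seq_len(n_samples)),
                                  rows$variant_id))
      geno[[gid]] <- m
    }
    list(transcripts = transcripts,
         transcript_table = do.call(rbind, c(tx_rows, make.row.names = FALSE)),
         annotations = do.call(rbind, c(ann, make.row.names = FALSE)),
         genotypes = geno)
  })
}
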