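# Top-level pipeline: simulate -> classify -> burden per study -> meta ->
# frr, with a run manifest for reproducibility.

#' Pipeline run configuration
#'
#' Configuration for [run_pipeline()].  The packaged demo pipeline runs on
#' simulated data (the real cohorts this analysis was designed for are
#' access-controlled), so the configuration mixes simulator settings with
#' analysis thresholds.  It round-trips losslessly through YAML via
#' [write_run_config()] / [read_run_config()].
#'
#' @param out_dir Output directory (created if absent).
#' @param seed Master seed; per-stage seeds are derived from it.
#' @param stages Stages to run, in order, a subset of
#'   `c("simulate", "classify", "burden", "meta", "frr")`.
#' @param n_cases,n_controls Per-study sample sizes.
#' @param n_genes Genes in the simulated scan.
#' @param alpha,eta Mixture prior used to draw true gene effects.
#' @param carrier_freq Population carrier frequency for simulated genes.
#' @param anchor_or Odds ratio of the anchor gene (simulated at
#'   `4 * carrier_freq` so its association is well-determined).
#' @param baseline_risk,fh_rate_noncarrier Simulator parameters; see
#'   [sim_config()].
#' @param studies Named list study label -> list with `fh_oversample`,
#'   `young_oversample`, `covariates` (character vector, `"pcs"` allowed).
#' @param anchor_genes,reference_study Meta-analysis anchoring.
#' @param af_max,cadd_min,helix_min,nmd_window Classification thresholds.
#' @param lambda_obs Observed first-degree FRR for [frr_percent()].
#' @return Object of class `run_config`.
#' @export
run_config <- function(out_dir, seed = 1, stages = c("simulate", "classify",
                                                     "burden", "meta", "frr"),
                       n_cases = 1500, n_controls = 1500, n_genes = 60,
                       alpha = 0.05, eta = 2, carrier_freq = 0.005,
                       anchor_or = 3, baseline_risk = 0.1,
                       fh_rate_noncarrier = 0.05,
                       studies = list(
                         BCAC = list(fh_oversample = 3, young_oversample = 2,
                                     covariates = c("country", "libprep")),
                         UKB = list(fh_oversample = 1, young_oversample = 1,
                                    covariates = c("pcs", "sex"))),
                       anchor_genes = "ANCHOR1", reference_study = NULL,
                       af_max = 0.001, cadd_min = 20, helix_min = 0.5,
                       nmd_window = 50, lambda_obs = 2.0) {
  if (af_max <= 0 || cadd_min <= 0 || helix_min <= 0 || nmd_window <= 0)
    stop_validation("thresholds must be positive")
  stages <- match.arg(stages, several.ok = TRUE)
  if (is.null(reference_study)) reference_study <- names(studies)[length(studies)]
  structure(list(out_dir = out_dir, seed = check_count(seed, "seed"),
                 stages = stages, n_cases = n_cases, n_controls = n_controls,
                 n_genes = n_genes, alpha = alpha, eta = eta,
                 carrier_freq = carrier_freq, anchor_or = anchor_or,
                 baseline_risk = baseline_risk,
                 fh_rate_noncarrier = fh_rate_noncarrier, studies = studies,
                 anchor_genes = anchor_genes, reference_study = reference_study,
                 af_max = af_max, cadd_min = cadd_min, helix_min = helix_min,
                 nmd_window = nmd_window, lambda_obs = lambda_obs),
            class = "run_config")
}

#' @rdname run_config
#' @param config A `run_config`.
#' @param path YAML file path.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  do.call(run_config, yaml::read_yaml(path))
}

# Demo gene panel: one strong anchor gene plus mixture-drawn effects.
pipeline_genes <- function(config) {
  beta <- draw_gene_effects(config$n_genes, config$alpha, config$eta,
                            seed = config$seed)
  genes <- lapply(seq_len(config$n_genes), function(i)
    gene_spec(sprintf("G%03d", i), carrier_freq = config$carrier_freq,
              log_or = beta[i]))
  anchors <- lapply(config$anchor_genes, function(g)
    gene_spec(g, carrier_freq = 4 * config$carrier_freq,
              log_or = log(config$anchor_or)))
  c(anchors, genes)
}

#' Run the analysis pipeline
#'
#' Executes the selected stages in order — simulate the per-study cohorts,
#' classify toy annotated variants, run the per-study burden scans, combine
#' them in the anchor-weighted meta-analysis, and decompose the FRR — and
#' writes every intermediate as TSV under `config$out_dir`.  All numbers
#' are fixed-format at 6 significant digits, so re-running with an
#' identical configuration reproduces identical bytes.  A manifest (JSON)
#' records the package version, configuration hash, seed and per-file
#' checksums; a failing stage aborts with its name and quarantines partial
#' outputs under `out_dir/partial`.
#'
#' @param config A [run_config()].
#' @return The run manifest, invisibly (list; also written as
#'   `manifest.json`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  cfg_path <- file.path(out, "config.yaml")
  write_run_config(config, cfg_path)
  stage_dir <- file.path(out, "partial")

  run_stage <- function(name, fn) {
    if (!name %in% config$stages) return(invisible(NULL))
    dir.create(stage_dir, showWarnings = FALSE)
    ok <- FALSE
    on.exit({
      if (ok) {
        for (fl in list.files(stage_dir, full.names = TRUE))
          file.rename(fl, file.path(out, basename(fl)))
      }
      unlink(stage_dir, recursive = TRUE)
    })
    tryCatch(fn(stage_dir), error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    ok <- TRUE
    invisible(NULL)
  }

  genes <- pipeline_genes(config)
  study_labels <- names(config$studies)
  cohorts <- NULL

  simulate_cohorts <- function() {
    lapply(seq_along(study_labels), function(s) {
      sp <- config$studies[[s]]
      cfg <- sim_config(config$n_cases, config$n_controls, genes,
                        baseline_risk = config$baseline_risk,
                        fh_rate_noncarrier = config$fh_rate_noncarrier,
                        seed = config$seed + 1000L * s,
                        study_specs = list(study_spec(
                          study_labels[s], fh_oversample = sp$fh_oversample,
                          young_oversample = sp$young_oversample)))
      simulate_cohort(cfg)
    })
  }

  run_stage("simulate", function(dir) {
    cohorts <<- simulate_cohorts()
    for (s in seq_along(study_labels)) {
      lab <- study_labels[s]
      write_phenotype_tsv(cohorts[[s]]$phenotypes,
                          file.path(dir, paste0("phenotypes_", lab, ".tsv")))
      write_carrier_tsv(cohorts[[s]]$carriers,
                        file.path(dir, paste0("carriers_", lab, ".tsv")))
      write_tsv_table(cohorts[[s]]$truth,
                      file.path(dir, paste0("truth_", lab, ".tsv")))
    }
  })
  if (is.null(cohorts) && any(c("burden", "meta", "frr") %in% config$stages))
    cohorts <- simulate_cohorts()

  run_stage("classify", function(dir) {
    toy <- simulate_annotated_variants(n_genes = 5, seed = config$seed)
    cls <- classify_variants(toy$annotations, toy$transcripts,
                             af_max = config$af_max, cadd_min = config$cadd_min,
                             helix_min = config$helix_min,
                             nmd_window = config$nmd_window)
    write_tsv_table(cls, file.path(dir, "classified_variants.tsv"))
    tab <- collapse_carriers(toy$genotypes, cls, class_filter = "PTV")
    write_carrier_tsv(tab, file.path(dir, "toy_ptv_carriers.tsv"))
    write_tsv_table(missingness_report(toy$genotypes),
                    file.path(dir, "toy_missingness.tsv"))
  })

  scans <- NULL
  run_scans <- function() {
    lapply(seq_along(study_labels), function(s) {
      run_genome_scan(cohorts[[s]]$carriers, cohorts[[s]]$phenotypes,
                      covariate_spec = config$studies[[s]]$covariates,
                      gene_chrom = cohorts[[s]]$gene_chrom)
    })
  }
  run_stage("burden", function(dir) {
    scans <<- run_scans()
    for (s in seq_along(study_labels))
      write_tsv_table(scans[[s]],
                      file.path(dir, paste0("burden_", study_labels[s], ".tsv")))
  })
  if (is.null(scans) && any(c("meta", "frr") %in% config$stages))
    scans <- run_scans()
  if (!is.null(scans)) names(scans) <- study_labels

  meta <- NULL
  run_stage("meta", function(dir) {
    meta <<- meta_analyse(scans, config$anchor_genes, config$reference_study)
    write_tsv_table(meta, file.path(dir, "meta.tsv"))
    write_tsv_table(export_ranked_list(meta), file.path(dir, "ranked_genes.tsv"))
    write_tsv_table(qq_plot_data(meta$p), file.path(dir, "qq_data.tsv"))
    lam <- data.frame(
      scan = c(study_labels, "meta"),
      lambda = c(vapply(scans, function(sc) inflation_lambda(sc$z), numeric(1)),
                 inflation_lambda(meta$z_m)))
    write_tsv_table(lam, file.path(dir, "inflation.tsv"))
  })

  run_stage("frr", function(dir) {
    d1 <- cohorts[[1]]$phenotypes$d
    counts <- NULL
    for (s in seq_along(cohorts)) {
      ph <- cohorts[[s]]$phenotypes
      cc <- cohorts[[s]]$carriers
      a <- colSums(cc[ph$d == 1, , drop = FALSE])
      b <- colSums(cc[ph$d == 0, , drop = FALSE])
      if (is.null(counts)) {
        counts <- gene_counts(colnames(cc), a, b, sum(ph$d == 1), sum(ph$d == 0))
      } else {
        counts$a <- counts$a + a; counts$b <- counts$b + b
        counts$n1 <- counts$n1 + sum(ph$d == 1)
        counts$n0 <- counts$n0 + sum(ph$d == 0)
      }
    }
    fit <- suppressWarnings(fit_eb(counts))
    jsonlite::write_json(list(alpha = fit$prior$alpha, eta = fit$prior$eta,
                              median_or = median_or(fit$prior),
                              loglik = fit$loglik, converged = fit$converged,
                              frr_percent_all = frr_percent(
                                fit, lambda_obs = config$lambda_obs)),
                         file.path(dir, "eb_fit.json"),
                         auto_unbox = TRUE, digits = 6)
    per_gene <- fit$genes
    per_gene$frr_percent <- 100 * per_gene$expected_lambda_minus1 /
      (config$lambda_obs - 1)
    write_tsv_table(per_gene, file.path(dir, "frr_per_gene.tsv"))
  })

  files <- setdiff(list.files(out), c("manifest.json"))
  sums <- tools::md5sum(file.path(out, files))
  names(sums) <- files
  manifest <- list(tool = "exomeburden",
                   version = as.character(utils::packageVersion("exomeburden")),
                   config_hash = unname(tools::md5sum(cfg_path)),
                   seed = config$seed, stages = config$stages,
                   checksums = as.list(sums),
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
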