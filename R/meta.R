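#' Two-sided normal P value and its inverse
#'
#' `two_sided_p()` converts a z score to the two-sided tail probability
#' `2 * (1 - pnorm(|z|))`; `z_quantile()` inverts it, returning the positive
#' z score whose two-sided P value equals `p`.  These are the conventions
#' used throughout the genome scan and meta-analysis: P = 0.001 corresponds
#' to z = 3.29 and the exome-wide threshold P = 2.5e-6 to z = 4.71.
#'
#' @param z Numeric vector of z scores.
#' @param p Numeric vector of probabilities in (0, 1).
#' @return A numeric vector of probabilities (`two_sided_p`) or positive
#'   z scores (`z_quantile`).
#' @examples
#' z_quantile(0.001)        # 3.29
#' z_quantile(2.5e-6)       # 4.71
#' two_sided_p(z_quantile(1e-8))
#' @export
two_sided_p <- function(z) {
  if (!is.numeric(z) || anyNA(z)) stop_validation("z must be numeric and non-missing")
  2 * stats::pnorm(abs(z), lower.tail = FALSE)
}

#' @rdname two_sided_p
#' @export
z_quantile <- function(p) {
  if (!is.numeric(p) || anyNA(p) || any(p <= 0) || any(p >= 1))
    stop_validation("p must lie strictly in (0, 1)")
  stats::qnorm(p / 2, lower.tail = FALSE)
}

#' Combine per-study z scores with weights
#'
#' Weighted z-score (Stouffer-type) combination:
#' \deqn{z_M = \frac{\sum_j w_j z_j}{\sqrt{\sum_j w_j^2}}}
#' With equal weights this is the classical unweighted Stouffer statistic;
#' it is invariant to rescaling all weights by a common positive factor,
#' and under independent standard-normal `zs` it is standard normal for any
#' fixed weights.
#'
#' @param zs Numeric vector of per-study z scores.
#' @param ws Numeric vector of strictly positive per-study weights, same
#'   length as `zs`.
#' @return A list with elements `z_m` and the two-sided `p`.
#' @examples
#' combine_z(c(3, 4), c(1, 1))  # z_m = 7 / sqrt(2)
#' @export
combine_z <- function(zs, ws) {
  if (length(zs) != length(ws))
    stop_validation("zs and ws must have the same length")
  if (length(zs) == 0) stop_validation("at least one study required")
  if (!is.numeric(zs) || anyNA(zs) || any(!is.finite(zs)))
    stop_validation("zs must be finite")
  if (!is.numeric(ws) || anyNA(ws) || any(ws <= 0))
    stop_validation("ws must be strictly positive")
  z_m <- sum(ws * zs) / sqrt(sum(ws^2))
  list(z_m = z_m, p = two_sided_p(z_m))
}

#' Anchor-gene meta-analysis weights
#'
#' Derives per-study weights from the z scores of an established risk gene
#' (or genes) so that studies with different ascertainment — for example one
#' oversampled for family history — can be combined on a common effect
#' scale.  The reference study receives weight 1 and every other study the
#' ratio of its anchor z score to the reference's.  With several anchor
#' genes (`mode = "multi"`) the ratio of summed anchor z scores is used,
#' which reduces to the single-gene rule when one gene is supplied.
#'
#' All anchor z scores must be positive: an anchor gene that is not
#' risk-associated in every study cannot calibrate the weights.
#'
#' @param anchor_z Numeric matrix (genes x studies) or named numeric vector
#'   (one anchor gene) of anchor-gene z scores; column/element names are the
#'   study labels.
#' @param reference_study Label of the study whose weight is fixed at 1.
#' @param mode `"single"` (one anchor gene required) or `"multi"` (z scores
#'   summed over anchor genes).
#' @return Named numeric vector of strictly positive per-study weights.
#' @examples
#' anchor_weights(c(BCAC = 12.4, UKB = 8.0), reference_study = "UKB")
#' @export
anchor_weights <- function(anchor_z, reference_study, mode = c("single", "multi")) {
  mode <- match.arg(mode)
  if (is.null(dim(anchor_z))) anchor_z <- matrix(anchor_z, nrow = 1,
                                                 dimnames = list(NULL, names(anchor_z)))
  studies <- colnames(anchor_z)
  if (is.null(studies)) stop_validation("anchor_z must carry study labels")
  if (!reference_study %in% studies)
    stop_validation("reference study '", reference_study, "' not among studies")
  if (mode == "single" && nrow(anchor_z) != 1)
    stop_validation("mode 'single' requires exactly one anchor gene")
  if (anyNA(anchor_z) || any(anchor_z <= 0))
    stop(structure(class = c("exomeburden_anchor_error", "error", "condition"),
                   list(message = paste("anchor z scores must all be positive;",
                                        "weights are undefined for a non-risk anchor"),
                        call = sys.call())))
  sums <- colSums(anchor_z)
  w <- sums / sums[reference_study]
  names(w) <- studies
  w
}

#' Weighted z-score meta-analysis across studies
#'
#' Joins per-study burden-scan results by gene, derives anchor-gene weights
#' from the scans themselves, and combines z scores with [combine_z()].
#' Genes absent from a study are combined over the studies in which they
#' were testable, with the missing study's weight dropped and the row
#' flagged in `studies_used`.
#'
#' @param study_results Named list of per-study result data frames, each
#'   with columns `gene_id` and `z` (e.g. output of [run_genome_scan()]).
#' @param anchor_genes Character vector of anchor gene ids (all must be
#'   present in every study).
#' @param reference_study Study label whose weight is fixed at 1.
#' @return Data frame with columns `gene_id`, `z_m`, `p`, one weight column
#'   `w_<study>` per study, and `studies_used` (comma-separated labels).
#'   Attribute `"weights"` carries the weight vector.
#' @export
meta_analyse <- function(study_results, anchor_genes, reference_study) {
  if (is.null(names(study_results)) || any(names(study_results) == ""))
    stop_validation("study_results must be a named list")
  studies <- names(study_results)
  anchor_z <- sapply(study_results, function(res) {
    idx <- match(anchor_genes, res$gene_id)
    if (anyNA(idx))
      stop_validation("anchor gene(s) missing from a study scan: ",
                      paste(anchor_genes[is.na(idx)], collapse = ", "))
    res$z[idx]
  })
  if (is.null(dim(anchor_z))) anchor_z <- matrix(anchor_z, nrow = 1,
                                                 dimnames = list(NULL, studies))
  w <- anchor_weights(anchor_z, reference_study,
                      mode = if (length(anchor_genes) == 1) "single" else "multi")

  genes <- sort(unique(unlist(lapply(study_results, `[[`, "gene_id"))))
  zmat <- sapply(study_results, function(res) res$z[match(genes, res$gene_id)])
  if (is.null(dim(zmat))) zmat <- matrix(zmat, nrow = length(genes))
  res <- do.call(rbind, lapply(seq_along(genes), function(i) {
    ok <- !is.na(zmat[i, ])
    cz <- combine_z(zmat[i, ok], w[ok])
    data.frame(gene_id = genes[i], z_m = cz$z_m, p = cz$p,
               studies_used = paste(studies[ok], collapse = ","),
               stringsAsFactors = FALSE)
  }))
  for (s in studies) res[[paste0("w_", s)]] <- unname(w[s])
  attr(res, "weights") <- w
  res
}

#' Genomic inflation factor from z scores
#'
#' Lambda is the median observed chi-squared statistic (`z^2`) divided by
#' the median of the 1-df chi-squared distribution (0.4549364).  Values
#' near 1 indicate a calibrated scan; values below 1 indicate conservative
#' tests, as is common for rare-carrier burden statistics.
#'
#' @param zs Numeric vector of z scores; fewer than 20 finite values
#'   triggers a warning.
#' @return Positive scalar lambda.
#' @export
inflation_lambda <- function(zs) {
  zs <- zs[is.finite(zs)]
  if (length(zs) == 0) stop_validation("no finite z scores supplied")
  if (length(zs) < 20) warning("inflation_lambda: fewer than 20 z scores; estimate unstable")
  stats::median(zs^2) / stats::qchisq(0.5, df = 1)
}

#' Ranked gene list for gene-set enrichment
#'
#' Orders genes by decreasing combined z score (ties broken
#' lexicographically by gene id), the form consumed by GSEA-style tools.
#'
#' @param meta Data frame with columns `gene_id` and `z_m`.
#' @return Data frame (`gene_id`, `z_m`) in rank order.
#' @export
export_ranked_list <- function(meta) {
  if (nrow(meta) == 0)
    return(data.frame(gene_id = character(), z_m = numeric(), stringsAsFactors = FALSE))
  ord <- order(-meta$z_m, meta$gene_id)
  out <- meta[ord, c("gene_id", "z_m"), drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Quantile-quantile plot data for a genome scan
#'
#' Expected versus observed -log10 P under the uniform null, suitable for
#' plotting with any graphics system.
#'
#' @param p Numeric vector of P values.
#' @return Data frame with columns `expected` and `observed` (-log10 scale),
#'   sorted by significance.
#' @export
qq_plot_data <- function(p) {
  check_prob(p, "p")
  n <- length(p)
  data.frame(expected = -log10(stats::ppoints(n)),
             observed = -log10(sort(p)))
}
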