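# Variant classification: PTV / rare-missense categories and per-gene
# carrier collapsing.

PTV_CONSEQUENCES <- c("stop_gained", "frameshift", "splice_donor", "splice_acceptor")

#' Transcript model
#'
#' One transcript per gene, as an ordered exon table in transcript-forward
#' coordinates: exons are listed 5' to 3' in coding direction, each as a
#' 0-based half-open `[start, end)` interval.  Because coordinates are
#' already transcript-forward, the strand is informational only.
#'
#' @param gene_id Gene label.
#' @param exons Two-column matrix or data frame of exon `start`, `end`
#'   (0-based, half-open), ordered 5' to 3'.
#' @param strand `"+"` or `"-"`.
#' @return An object of class `transcript_model`.
#' @export
transcript_model <- function(gene_id, exons, strand = "+") {
  exons <- as.matrix(exons)[, 1:2, drop = FALSE]
  storage.mode(exons) <- "double"
  colnames(exons) <- c("start", "end")
  if (nrow(exons) < 1) stop_validation("transcript needs at least one exon")
  if (any(exons[, "end"] <= exons[, "start"]))
    stop_validation("each exon must satisfy end > start")
  if (nrow(exons) > 1 && any(diff(exons[, "start"]) <= 0 |
                             exons[-1, "start"] < exons[-nrow(exons), "end"]))
    stop_validation("exons must be non-overlapping and ordered 5' to 3'")
  if (!strand %in% c("+", "-")) stop_validation("strand must be '+' or '-'")
  structure(list(gene_id = gene_id, strand = strand, exons = exons,
                 n_exons = nrow(exons)),
            class = "transcript_model")
}

#' @export
print.transcript_model <- function(x, ...) {
  cat("Transcript", x$gene_id, "(", x$strand, "strand ):",
      x$n_exons, "exons,",
      sum(x$exons[, "end"] - x$exons[, "start"]), "bp\n")
  invisible(x)
}

#' Does a protein-truncating variant escape nonsense-mediated decay?
#'
#' A premature stop in the last exon, or within the last `window` bases of
#' the penultimate exon, generally escapes nonsense-mediated mRNA decay
#' (NMD) because it lies downstream of the final exon-junction complex.
#' Such PTVs are excluded from burden categories since the truncated
#' protein may retain function.
#'
#' The distance is measured in transcript-forward coordinates as the number
#' of bases from the variant position to the 3' end of its exon, counting
#' the variant base itself: the exon's last base is at distance 1, and a
#' variant at distance `<= window` (default 50, inclusive) escapes.
#' Single-exon transcripts have no exon junction, so every position
#' escapes.
#'
#' @param variant One-row data frame or list with fields `gene_id`,
#'   `exon_index` (1-based) and `position` (0-based transcript-forward
#'   coordinate).
#' @param transcript A [transcript_model()].
#' @param window Size in bases of the escape zone at the 3' end of the
#'   penultimate exon (inclusive).
#' @return `TRUE` if the PTV is predicted to escape NMD.
#' @examples
#' tx <- transcript_model("G", cbind(c(0, 200, 400), c(100, 300, 500)))
#' v  <- list(gene_id = "G", exon_index = 3, position = 450)
#' is_nmd_escaping(v, tx)   # last exon: TRUE
#' @export
is_nmd_escaping <- function(variant, transcript, window = 50) {
  if (!identical(as.character(variant$gene_id), transcript$gene_id))
    stop_validation("variant gene '", variant$gene_id,
                    "' does not match transcript '", transcript$gene_id, "'")
  idx <- variant$exon_index
  pos <- variant$position
  if (is.null(idx) || is.null(pos) || is.na(idx) || is.na(pos))
    stop_validation("variant must carry exon_index and position")
  if (idx < 1 || idx > transcript$n_exons)
    stop_annotation("exon_index ", idx, " outside transcript (",
                    transcript$n_exons, " exons)")
  ex <- transcript$exons[idx, ]
  if (pos < ex["start"] || pos >= ex["end"])
    stop_annotation("position ", pos, " outside exon ", idx,
                    " [", ex["start"], ", ", ex["end"], ")")
  n <- transcript$n_exons
  if (n == 1) return(TRUE)
  if (idx == n) return(TRUE)
  if (idx == n - 1) {
    dist_to_3p <- ex["end"] - pos   # variant base itself counts: last base = 1
    return(unname(dist_to_3p <= window))
  }
  FALSE
}

stop_annotation <- function(...) {
  stop(structure(class = c("exomeburden_annotation_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

#' Classify a variant into burden-test categories
#'
#' Assigns the set of category labels used by the burden tests:
#' \describe{
#'   \item{PTV}{stop-gained, frameshift or canonical splice-site variant
#'     that does not escape NMD (see [is_nmd_escaping()]).}
#'   \item{RARE_MISSENSE}{missense with allele frequency below `af_max` in
#'     \emph{both} the reference panel and the analysis cohort (strict
#'     `<`).}
#'   \item{DELETERIOUS_MISSENSE_CADD}{rare missense with CADD phred
#'     `>= cadd_min`.}
#'   \item{DELETERIOUS_MISSENSE_HELIX}{rare missense with Helix score
#'     `> helix_min` (strict).}
#'   \item{OTHER}{everything else.}
#' }
#' Deleterious labels are subsets of RARE_MISSENSE; PTV excludes the
#' missense labels.
#'
#' @param variant One-row data frame or list with fields `consequence`,
#'   `panel_af`, `cohort_af`, `cadd`, `helix`, and for PTV candidates
#'   `exon_index`/`position`.
#' @param transcript The gene's [transcript_model()] (needed for the NMD
#'   rule; may be `NULL` for non-PTV consequences).
#' @param af_max,cadd_min,helix_min Category thresholds.
#' @param nmd_window Passed to [is_nmd_escaping()].
#' @return Character vector of class labels.
#' @examples
#' classify_variant(list(consequence = "missense", panel_af = 5e-4,
#'                       cohort_af = 5e-4, cadd = 25, helix = NA), NULL)
#' @export
classify_variant <- function(variant, transcript, af_max = 0.001,
                             cadd_min = 20, helix_min = 0.5, nmd_window = 50) {
  if (af_max <= 0 || cadd_min <= 0 || helix_min <= 0)
    stop_validation("thresholds must be positive")
  csq <- variant$consequence
  if (is.null(csq) || is.na(csq) || !nzchar(csq))
    stop_annotation("variant has no consequence annotation")
  labels <- character()
  if (csq %in% PTV_CONSEQUENCES) {
    if (is.null(transcript)) stop_validation("PTV classification needs a transcript")
    if (!is_nmd_escaping(variant, transcript, window = nmd_window))
      labels <- "PTV"
  } else if (csq == "missense") {
    rare <- !is.na(variant$panel_af) && !is.na(variant$cohort_af) &&
      variant$panel_af < af_max && variant$cohort_af < af_max
    if (rare) {
      labels <- "RARE_MISSENSE"
      if (!is.null(variant$cadd) && !is.na(variant$cadd) && variant$cadd >= cadd_min)
        labels <- c(labels, "DELETERIOUS_MISSENSE_CADD")
      if (!is.null(variant$helix) && !is.na(variant$helix) && variant$helix > helix_min)
        labels <- c(labels, "DELETERIOUS_MISSENSE_HELIX")
    }
  }
  if (length(labels) == 0) labels <- "OTHER"
  labels
}

#' Classify a table of annotated variants
#'
#' Vectorised front-end to [classify_variant()]: one row per variant, one
#' logical column per category.
#'
#' @param annotations Data frame with columns `variant_id`, `gene_id`,
#'   `consequence`, `exon_index`, `position`, `panel_af`, `cohort_af`,
#'   `cadd`, `helix`.
#' @param transcripts Named list of [transcript_model()] objects keyed by
#'   gene id.
#' @inheritParams classify_variant
#' @return `annotations` with added logical columns `PTV`, `RARE_MISSENSE`,
#'   `DELETERIOUS_MISSENSE_CADD`, `DELETERIOUS_MISSENSE_HELIX`, `OTHER`.
#' @export
classify_variants <- function(annotations, transcripts, af_max = 0.001,
                              cadd_min = 20, helix_min = 0.5, nmd_window = 50) {
  cats <- c("PTV", "RARE_MISSENSE", "DELETERIOUS_MISSENSE_CADD",
            "DELETERIOUS_MISSENSE_HELIX", "OTHER")
  lab <- lapply(seq_len(nrow(annotations)), function(i) {
    v <- as.list(annotations[i, ])
    classify_variant(v, transcripts[[as.character(v$gene_id)]],
                     af_max = af_max, cadd_min = cadd_min,
                     helix_min = helix_min, nmd_window = nmd_window)
  })
  for (cl in cats) annotations[[cl]] <- vapply(lab, function(l) cl %in% l, logical(1))
  annotations
}

#' Collapse allele counts to per-gene carrier indicators
#'
#' Gene-level burden collapsing: sample `i` is a carrier of gene `g`
#' (`G_i = 1`) iff it carries at least one minor allele over the gene's
#' variants in the requested class — heterozygous and homozygous carriers
#' are combined.  Missing genotypes contribute 0 (treated as non-carrier);
#' use [missingness_report()] to detect genes where this matters.
#'
#' @param genotypes Named list (one element per gene) of sample x variant
#'   allele-count matrices with entries 0/1/2/`NA`; row names are sample
#'   ids, column names variant ids.
#' @param classes Output of [classify_variants()] (or any data frame with
#'   `variant_id` plus a logical column named after `class_filter`); if
#'   `NULL`, all variants are used.
#' @param class_filter Category label selecting the variants to collapse.
#' @return A `carrier_table`: integer 0/1 matrix samples x genes with
#'   attributes `class` and `carrier_counts` (per-gene column sums).
#' @examples
#' g <- list(G1 = matrix(c(0, 2, NA, 0), 2, 2,
#'                       dimnames = list(c("s1", "s2"), c("v1", "v2"))))
#' collapse_carriers(g)
#' @export
collapse_carriers <- function(genotypes, classes = NULL, class_filter = "PTV") {
  if (length(genotypes) == 0) stop_validation("no genes supplied")
  samples <- rownames(genotypes[[1]])
  mat <- sapply(names(genotypes), function(g) {
    m <- genotypes[[g]]
    if (!identical(rownames(m), samples))
      stop_validation("sample sets differ between gene matrices")
    keep <- colnames(m)
    if (!is.null(classes)) {
      in_class <- classes$variant_id[classes$gene_id == g & classes[[class_filter]]]
      keep <- intersect(keep, in_class)
    }
    m <- m[, keep, drop = FALSE]
    bad <- m[!is.na(m)]
    if (any(!bad %in% c(0, 1, 2)))
      stop_validation("allele counts must be 0, 1, 2 or missing")
    if (ncol(m) == 0) return(integer(length(samples)))
    as.integer(rowSums(m, na.rm = TRUE) > 0)
  })
  if (is.null(dim(mat))) mat <- matrix(mat, nrow = length(samples))
  dimnames(mat) <- list(samples, names(genotypes))
  carrier_table(mat, class = class_filter)
}

#' Construct a carrier table
#'
#' @param mat Integer 0/1 matrix, samples in rows, genes in columns.
#' @param class Variant-class label the table was collapsed on.
#' @return Object of class `carrier_table`.
#' @export
carrier_table <- function(mat, class = "PTV") {
  mat <- as.matrix(mat)
  storage.mode(mat) <- "integer"
  if (any(!mat %in% c(0L, 1L))) stop_validation("carrier indicators must be 0/1")
  structure(mat, class = c("carrier_table", class(mat)),
            variant_class = class, carrier_counts = colSums(mat))
}

#' @export
print.carrier_table <- function(x, ...) {
  cat("Carrier table:", nrow(x), "samples x", ncol(x), "genes; class",
      attr(x, "variant_class"), "\n")
  cc <- attr(x, "carrier_counts")
  cat("carriers per gene: min", min(cc), "median", stats::median(cc),
      "max", max(cc), "\n")
  invisible(x)
}

#' Cohort allele frequency
#'
#' Allele frequency of each variant in the analysis cohort: minor-allele
#' count divided by `2 x` the number of non-missing genotypes.  For genes
#' on chromosome X the frequency is computed over females only (supply
#' `sex` and set `chr_x = TRUE`); male hemizygous genotypes are not
#' modelled.
#'
#' @param genotypes Sample x variant allele-count matrix (0/1/2/`NA`).
#' @param sex Optional character vector (`"F"`/`"M"`) aligned with rows.
#' @param chr_x If `TRUE`, restrict the denominator to females.
#' @return Named numeric vector of per-variant allele frequencies.
#' @export
cohort_af <- function(genotypes, sex = NULL, chr_x = FALSE) {
  m <- as.matrix(genotypes)
  if (chr_x) {
    if (is.null(sex)) stop_validation("chr_x = TRUE requires sex")
    m <- m[sex == "F", , drop = FALSE]
  }
  n_ok <- colSums(!is.na(m))
  if (any(n_ok == 0))
    stop_validation("variant(s) with all genotypes missing: AF undefined (",
                    paste(colnames(m)[n_ok == 0], collapse = ", "), ")")
  colSums(m, na.rm = TRUE) / (2 * n_ok)
}

#' Per-gene genotype missingness report
#'
#' Because missing genotypes are collapsed as non-carriers, a gene with
#' substantial missingness that differs between cases and controls can
#' produce a spurious burden signal.  This report gives the per-gene
#' missing-call fraction (overall and by case status) so such genes can be
#' flagged and excluded.
#'
#' @param genotypes Named list of sample x variant allele-count matrices.
#' @param d Optional 0/1 disease-status vector aligned with samples.
#' @return Data frame with columns `gene_id`, `n_variants`, `missing_frac`,
#'   and when `d` is given `missing_frac_cases` / `missing_frac_controls`.
#' @export
missingness_report <- function(genotypes, d = NULL) {
  out <- do.call(rbind, lapply(names(genotypes), function(g) {
    m <- genotypes[[g]]
    row <- data.frame(gene_id = g, n_variants = ncol(m),
                      missing_frac = mean(is.na(m)), stringsAsFactors = FALSE)
    if (!is.null(d)) {
      row$missing_frac_cases <- mean(is.na(m[d == 1, , drop = FALSE]))
      row$missing_frac_controls <- mean(is.na(m[d == 0, , drop = FALSE]))
    }
    row
  }))
  rownames(out) <- NULL
  out
}
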