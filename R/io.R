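# Readers and writers.  TSV (with mandatory headers) is the canonical
# interchange format; VCF is supported for genotype ingestion and for a
# minimal GT-only export used in round-trip tests.

#' Write / read a tab-separated table
#'
#' Tables are written with a header, no quoting and numbers formatted to 6
#' significant digits, so identical reruns produce byte-identical files.
#'
#' @param x Data frame.
#' @param path File path.
#' @return `read_tsv_table` returns a data frame; `write_tsv_table` its
#'   input, invisibly.
#' @export
write_tsv_table <- function(x, path) {
  y <- x
  for (j in seq_along(y)) if (is.double(y[[j]])) y[[j]] <- format_num(y[[j]])
  utils::write.table(y, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(x)
}

#' @rdname write_tsv_table
#' @export
read_tsv_table <- function(path) {
  utils::read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

#' Write a carrier table as TSV
#'
#' Matrix layout: first column `sample_id`, one 0/1 column per gene.
#'
#' @param tab A `carrier_table`.
#' @param path File path.
#' @export
write_carrier_tsv <- function(tab, path) {
  df <- data.frame(sample_id = rownames(tab), as.data.frame(unclass(tab)),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(tab)
}

#' @rdname write_carrier_tsv
#' @param class Variant-class label to attach on reading.
#' @export
read_carrier_tsv <- function(path, class = "PTV") {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- df$sample_id
  carrier_table(mat, class = class)
}

#' Read per-gene genotype matrices from a VCF
#'
#' Reads a VCF with GT fields (multi-allelic records must be pre-split) and
#' returns allele-count matrices keyed by gene.  The gene is taken from a
#' `GENE=` tag in INFO, or by joining `ID` against `annotations$variant_id`
#' when an annotation table is supplied.  Missing calls (`./.`) are
#' preserved as `NA`.
#'
#' @param path VCF path (plain text or bgzip).
#' @param annotations Optional data frame with `variant_id`, `gene_id`.
#' @param sample_filter Optional character vector of sample ids to keep.
#' @return Named list of sample x variant allele-count matrices.
#' @export
read_vcf_carriers <- function(path, annotations = NULL, sample_filter = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(gt) || nrow(gt) == 0) stop_validation("VCF contains no GT data")
  counts <- matrix(NA_integer_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  clean <- gsub("\\|", "/", gt)
  counts[clean %in% c("0/0", "0")] <- 0L
  counts[clean %in% c("0/1", "1/0")] <- 1L
  counts[clean %in% c("1/1", "1")] <- 2L
  unknown <- !is.na(clean) & !clean %in% c("0/0", "0/1", "1/0", "1/1", "0", "1", "./.", ".")
  if (any(unknown))
    stop_validation("unsupported GT value(s): ",
                    paste(unique(clean[unknown]), collapse = ", "),
                    " (multi-allelic records must be pre-split)")
  counts <- t(counts)                      # samples x variants
  if (!is.null(sample_filter)) {
    missing <- setdiff(sample_filter, rownames(counts))
    if (length(missing))
      stop_validation("unknown sample(s): ", paste(missing, collapse = ", "))
    counts <- counts[sample_filter, , drop = FALSE]
  }
  ids <- v@fix[, "ID"]
  info <- v@fix[, "INFO"]
  gene <- sub(".*GENE=([^;]+).*", "\\1", info)
  gene[!grepl("GENE=", info)] <- NA
  if (!is.null(annotations)) {
    hit <- match(ids, annotations$variant_id)
    gene[is.na(gene)] <- annotations$gene_id[hit][is.na(gene)]
  }
  if (anyNA(gene))
    stop_validation("variant(s) with no gene assignment: ",
                    paste(utils::head(ids[is.na(gene)], 5), collapse = ", "))
  colnames(counts) <- ids
  lapply(split(seq_along(ids), gene), function(j) counts[, j, drop = FALSE])
}

#' Write per-gene genotypes as a minimal GT-only VCF
#'
#' One pseudo-variant record per variant, 0/0 / 0/1 / 1/1 / ./. genotypes
#' and a `GENE=` INFO tag; intended for round-trip testing of
#' [read_vcf_carriers()], not as a general-purpose VCF emitter.
#'
#' @param genotypes Named list of sample x variant allele-count matrices.
#' @param path Output path.
#' @export
write_vcf_carriers <- function(genotypes, path) {
  samples <- rownames(genotypes[[1]])
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene id\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", samples), collapse = "\t")), con)
  pos <- 0L
  for (g in names(genotypes)) {
    m <- genotypes[[g]]
    for (j in seq_len(ncol(m))) {
      pos <- pos + 1L
      gts <- c("0/0", "0/1", "1/1")[m[, j] + 1L]
      gts[is.na(gts)] <- "./."
      writeLines(paste(c("1", pos, colnames(m)[j], "A", "T", ".", "PASS",
                         paste0("GENE=", g), "GT", gts), collapse = "\t"), con)
    }
  }
  invisible(path)
}

#' Write phenotypes / read phenotypes
#'
#' Phenotype TSV schema: `sample_id, d, f, sex, age_band, ER, PR, HER2, TN,
#' study, country, libprep, PC1..PC10`.
#'
#' @param phenotypes Phenotype data frame.
#' @param path File path.
#' @export
write_phenotype_tsv <- function(phenotypes, path) {
  write_tsv_table(phenotypes, path)
}

#' @rdname write_phenotype_tsv
#' @export
read_phenotype_tsv <- function(path) {
  df <- read_tsv_table(path)
  for (col in c("sample_id", "d", "f")) if (!col %in% names(df))
    stop_validation("phenotype table lacks required column '", col, "'")
  df
}

#' Write a BED-like exon table / read transcripts from one
#'
#' Columns: `gene_id, exon_index, start, end, strand`; 0-based half-open
#' transcript-forward coordinates.
#'
#' @param transcript_table Data frame as above.
#' @param path File path.
#' @export
write_transcript_tsv <- function(transcript_table, path) {
  write_tsv_table(transcript_table, path)
}

#' @rdname write_transcript_tsv
#' @return `read_transcripts_tsv` returns a named list of
#'   [transcript_model()] objects.
#' @export
read_transcripts_tsv <- function(path) {
  df <- read_tsv_table(path)
  lapply(split(df, df$gene_id), function(tx) {
    tx <- tx[order(tx$exon_index), ]
    transcript_model(tx$gene_id[1], cbind(tx$start, tx$end), tx$strand[1])
  })
}
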