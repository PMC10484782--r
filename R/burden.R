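# Family-history-weighted gene burden tests (reversed logistic regression:
# genotype as outcome).

#' Family-history-weighted disease phenotype
#'
#' The quantity `d + 0.5 * f`, where `d` is case status and `f` indicates a
#' positive first-degree family history.  Used as the predictor in the
#' reversed (genotype-as-outcome) burden regression: for small effects the
#' log-OR associated with an affected first-degree relative is roughly half
#' the log-OR associated with the disease itself, so weighting family
#' history by one half recovers that information — including from
#' unaffected individuals — and markedly improves power.
#'
#' @param d 0/1 disease status vector.
#' @param f 0/1 first-degree family-history vector.
#' @param f_weight Weight given to family history (default 0.5; 0 discards
#'   family history).
#' @return Numeric vector `d + f_weight * f`.
#' @examples
#' fh_weighted_phenotype(c(0, 1, 0, 1), c(0, 0, 1, 1))  # 0, 1, 0.5, 1.5
#' @export
fh_weighted_phenotype <- function(d, f, f_weight = 0.5) {
  check_binary(d, "d")
  check_binary(f, "f")
  if (length(d) != length(f)) stop_validation("d and f must have equal length")
  d + f_weight * f
}

# Build the regression design matrix: intercept, weighted phenotype, then
# covariates.  Factor covariates are expanded to dummies; covariate columns
# that are constant on the analysis subset are dropped silently (they carry
# no information); genuine collinearity is reported with the column name.
build_design <- function(dfh, phenotypes, covariate_spec) {
  cols <- list(`(Intercept)` = rep(1, length(dfh)), dfh = dfh)
  for (cv in expand_covariates(covariate_spec, phenotypes)) {
    if (!cv %in% names(phenotypes))
      stop_validation("covariate '", cv, "' not found in phenotype table")
    x <- phenotypes[[cv]]
    if (is.numeric(x)) {
      cols[[cv]] <- x
    } else {
      x <- factor(x)
      if (nlevels(x) > 1) {
        mm <- stats::model.matrix(~x)[, -1, drop = FALSE]
        colnames(mm) <- paste0(cv, levels(x)[-1])
        for (j in seq_len(ncol(mm))) cols[[colnames(mm)[j]]] <- mm[, j]
      }
    }
  }
  X <- do.call(cbind, cols)
  const <- apply(X[, -1, drop = FALSE], 2, function(v) length(unique(v)) == 1)
  X <- X[, c(TRUE, !const), drop = FALSE]
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop_validation("design matrix rank-deficient; collinear column(s): ",
                    paste(bad, collapse = ", "))
  }
  X
}

# "pcs" expands to all PC<k> columns present in the table.
expand_covariates <- function(covariate_spec, phenotypes) {
  out <- character()
  for (cv in covariate_spec) {
    if (identical(cv, "pcs")) {
      out <- c(out, grep("^PC[0-9]+$", names(phenotypes), value = TRUE))
    } else out <- c(out, cv)
  }
  out
}

# Firth penalised logistic fit (Jeffreys-prior score adjustment).  Only
# used as a fallback when plain maximum likelihood separates or fails to
# converge, which is routine when carriers are very rare.
firth_logistic <- function(X, y, maxit = 100, tol = 1e-8) {
  beta <- rep(0, ncol(X))
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    p <- stats::plogis(eta)
    w <- p * (1 - p)
    XtWX <- crossprod(X, X * w)
    inv <- tryCatch(solve(XtWX), error = function(e) NULL)
    if (is.null(inv)) break
    h <- rowSums((X %*% inv) * X) * w     # hat-matrix diagonal
    U <- crossprod(X, y - p + h * (0.5 - p))
    step <- drop(inv %*% U)
    if (max(abs(step)) > 5) step <- step * 5 / max(abs(step))
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  p <- stats::plogis(drop(X %*% beta))
  w <- p * (1 - p)
  vcov <- solve(crossprod(X, X * w))
  list(coefficients = beta, se = sqrt(diag(vcov)))
}

#' Single-gene burden regression
#'
#' Fits the reversed logistic regression for one gene: the 0/1 carrier
#' indicator is the outcome and the family-history-weighted disease status
#' `d + 0.5 f` (see [fh_weighted_phenotype()]) plus covariates are the
#' predictors.  The reported effect is the weighted-phenotype coefficient
#' (Wald `beta`, `se`, `z`, two-sided `p`).  With no family history and no
#' covariates this coefficient equals the usual 2x2-table log odds ratio —
#' the symmetry of the odds ratio is what licenses the reversed model.
#'
#' Rare carriers make complete separation routine; when maximum likelihood
#' fails to converge or diverges, a Firth penalised fit is substituted and
#' the result is flagged `converged = FALSE`.
#'
#' @param carriers 0/1 carrier vector (one entry per sample).
#' @param phenotypes Data frame with at least `d` and `f` columns plus any
#'   covariates named in `covariate_spec`.
#' @param covariate_spec Character vector of covariate column names; the
#'   token `"pcs"` expands to all `PC1..PCk` columns.
#' @param f_weight Family-history weight (0.5 default; 0 ignores family
#'   history).
#' @return One-row data frame (`gene_id` unset): `n_case_carriers`,
#'   `n_control_carriers`, `beta`, `se`, `z`, `p`, `converged`.
#' @export
burden_regression <- function(carriers, phenotypes, covariate_spec = character(),
                              f_weight = 0.5) {
  check_binary(carriers, "carriers")
  if (length(carriers) != nrow(phenotypes))
    stop_validation("carriers and phenotypes are of different sizes")
  if (sum(carriers) == 0)
    stop(structure(class = c("exomeburden_skip_gene", "error", "condition"),
                   list(message = "no carriers: gene requires at least one carrier of a variant",
                        call = sys.call())))
  if (sum(phenotypes$d) == 0) stop_validation("no cases in analysis subset")
  f <- phenotypes$f
  f[is.na(f)] <- 0       # missing family history treated as negative
  dfh <- fh_weighted_phenotype(phenotypes$d, f, f_weight = f_weight)
  X <- build_design(dfh, phenotypes, covariate_spec)
  y <- carriers

  # warm start at the intercept-only solution: halves the IRLS iterations
  # for rare outcomes without changing the optimum
  start <- c(stats::qlogis(min(max(mean(y), 1e-6), 1 - 1e-6)),
             rep(0, ncol(X) - 1))
  fit <- suppressWarnings(stats::glm.fit(X, y, family = stats::binomial(),
                                         start = start))
  ok <- fit$converged && max(abs(fit$coefficients)) < 15
  if (ok) {
    w <- fit$weights
    vcov <- tryCatch(solve(crossprod(X, X * w)), error = function(e) NULL)
    ok <- !is.null(vcov) && all(diag(vcov) > 0) && sqrt(vcov["dfh", "dfh"]) < 20
  }
  if (ok) {
    beta <- fit$coefficients["dfh"]
    se <- sqrt(vcov["dfh", "dfh"])
    converged <- TRUE
  } else {
    ff <- firth_logistic(X, y)
    i <- match("dfh", colnames(X))
    beta <- ff$coefficients[i]
    se <- ff$se[i]
    converged <- FALSE
  }
  z <- unname(beta / se)
  data.frame(n_case_carriers = sum(carriers[phenotypes$d == 1]),
             n_control_carriers = sum(carriers[phenotypes$d == 0]),
             beta = unname(beta), se = unname(se), z = unname(z),
             p = two_sided_p(z), converged = converged)
}

# Resolve a restriction spec to the sample subset it keeps.  Cases are
# restricted; controls are always retained.
restrict_samples <- function(phenotypes, restriction) {
  if (is.null(restriction)) return(rep(TRUE, nrow(phenotypes)))
  keep_case <- switch(restriction,
    age_lt50 = phenotypes$age_band == "<50",
    `ER+` = phenotypes$ER %in% "+", `ER-` = phenotypes$ER %in% "-",
    `PR+` = phenotypes$PR %in% "+", `PR-` = phenotypes$PR %in% "-",
    TN = phenotypes$TN %in% "+",
    stop_validation("unknown restriction '", restriction, "'")
  )
  keep_case[is.na(keep_case)] <- FALSE   # missing subtype: drop the case
  phenotypes$d == 0 | keep_case
}

#' Genome-wide burden scan
#'
#' Runs [burden_regression()] for every gene with at least one carrier,
#' with optional case restrictions and the chromosome-X rule:
#' \itemize{
#'   \item `restriction = "age_lt50"` keeps only cases diagnosed under 50;
#'     `"ER+"`, `"ER-"`, `"PR+"`, `"PR-"`, `"TN"` keep only cases of that
#'     tumour subtype (cases with missing subtype are dropped).  Controls
#'     are never restricted.
#'   \item Genes whose chromosome (via `gene_chrom`) is `"X"` are analysed
#'     in females only.
#' }
#' Genes with zero carriers after restriction are skipped and listed in the
#' `"skipped"` attribute with the reason.
#'
#' @param carrier_tab A `carrier_table` (samples x genes), e.g. from
#'   [collapse_carriers()] or a simulated cohort.
#' @param phenotypes Phenotype data frame aligned with the table's rows.
#' @param covariate_spec Covariate columns; see [burden_regression()].
#' @param restriction Optional restriction label (above).
#' @param gene_chrom Optional named character vector gene -> chromosome.
#' @param f_weight Family-history weight.
#' @return Data frame of per-gene results (one row per tested gene) with a
#'   `"skipped"` attribute (data frame `gene_id`, `reason`).
#' @export
run_genome_scan <- function(carrier_tab, phenotypes, covariate_spec = character(),
                            restriction = NULL, gene_chrom = NULL, f_weight = 0.5) {
  if (nrow(carrier_tab) != nrow(phenotypes))
    stop_validation("carrier table and phenotype table differ in sample count")
  keep <- restrict_samples(phenotypes, restriction)
  if (sum(phenotypes$d[keep]) == 0)
    stop_validation("restriction '", restriction, "' leaves no cases")
  vclass <- attr(carrier_tab, "variant_class")
  genes <- colnames(carrier_tab)
  females <- phenotypes$sex == "F"

  results <- vector("list", length(genes))
  skipped <- list()
  for (i in seq_along(genes)) {
    g <- genes[i]
    on_x <- !is.null(gene_chrom) && identical(unname(gene_chrom[g]), "X")
    sel <- if (on_x) keep & females else keep
    y <- carrier_tab[sel, g]
    if (sum(y) == 0) {
      skipped[[g]] <- if (on_x && sum(carrier_tab[keep, g]) > 0)
        "carriers only among excluded males (chrX)" else "zero carriers"
      next
    }
    res <- tryCatch(
      burden_regression(y, phenotypes[sel, , drop = FALSE], covariate_spec,
                        f_weight = f_weight),
      exomeburden_skip_gene = function(e) NULL)
    if (is.null(res)) { skipped[[g]] <- "zero carriers"; next }
    res <- cbind(data.frame(gene_id = g, variant_class = vclass,
                            stringsAsFactors = FALSE), res)
    results[[i]] <- res
  }
  out <- do.call(rbind, results[!vapply(results, is.null, logical(1))])
  if (is.null(out))
    out <- data.frame(gene_id = character(), variant_class = character(),
                      n_case_carriers = integer(), n_control_carriers = integer(),
                      beta = numeric(), se = numeric(), z = numeric(),
                      p = numeric(), converged = logical())
  rownames(out) <- NULL
  attr(out, "skipped") <- data.frame(gene_id = names(skipped),
                                     reason = unlist(skipped, use.names = FALSE),
                                     stringsAsFactors = FALSE)
  out
}
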