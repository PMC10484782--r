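# NMD-escape rule, burden categories and carrier collapsing.

test_that("NMD escape rule: last exon and 50-bp zone of penultimate exon", {
  tx <- toy_tx()
  # last exon: every position escapes
  expect_true(is_nmd_escaping(toy_variant(3, 600), tx))
  expect_true(is_nmd_escaping(toy_variant(3, 699), tx))
  # interior exon never escapes
  expect_false(is_nmd_escaping(toy_variant(1, 50), tx))
  # penultimate exon: 200 bp from the 3' end does not escape
  expect_false(is_nmd_escaping(toy_variant(2, 500 - 200), tx))
  # boundary: exactly 50 bases escapes, 51 does not (inclusive window)
  expect_true(is_nmd_escaping(toy_variant(2, 500 - 50), tx))
  expect_false(is_nmd_escaping(toy_variant(2, 500 - 51), tx))
  expect_true(is_nmd_escaping(toy_variant(2, 499), tx))  # exon's last base
})

test_that("NMD escape boundary agrees with a brute-force position scan", {
  tx <- toy_tx()
  # independent oracle: enumerate every position of the penultimate exon and
  # count bases from the position to the exon end, variant base included
  for (pos in 200:499) {
    n_bases_to_end <- length(pos:499)
    expect_identical(is_nmd_escaping(toy_variant(2, pos), tx),
                     n_bases_to_end <= 50)
  }
})

test_that("single-exon transcripts escape everywhere; bad positions error", {
  tx1 <- transcript_model("TOY", cbind(0, 300))
  expect_true(is_nmd_escaping(toy_variant(1, 0), tx1))
  expect_true(is_nmd_escaping(toy_variant(1, 299), tx1))
  tx <- toy_tx()
  expect_error(is_nmd_escaping(toy_variant(1, 150), tx), "outside exon")
  expect_error(is_nmd_escaping(toy_variant(5, 50), tx), "outside transcript")
  expect_error(is_nmd_escaping(toy_variant(1, 50, gene_id = "OTHER"), tx),
               "does not match")
})

test_that("classification thresholds: dual AF, CADD and Helix edges", {
  cl <- function(...) classify_variant(list(consequence = "missense", ...), NULL)
  # rare missense with both deleterious tiers
  expect_setequal(cl(panel_af = 5e-4, cohort_af = 5e-4, cadd = 25, helix = 0.7),
                  c("RARE_MISSENSE", "DELETERIOUS_MISSENSE_CADD",
                    "DELETERIOUS_MISSENSE_HELIX"))
  # fails the dual filter: rare in panel but not in cohort
  expect_identical(cl(panel_af = 5e-4, cohort_af = 2e-3, cadd = 25, helix = 0.7),
                   "OTHER")
  expect_identical(cl(panel_af = 2e-3, cohort_af = 5e-4, cadd = 25, helix = 0.7),
                   "OTHER")
  # AF comparison is strict: exactly 0.001 is not rare
  expect_identical(cl(panel_af = 1e-3, cohort_af = 1e-3, cadd = 25, helix = 0.7),
                   "OTHER")
  # CADD >= 20 inclusive; Helix > 0.5 strict
  expect_setequal(cl(panel_af = 5e-4, cohort_af = 5e-4, cadd = 20, helix = 0.5),
                  c("RARE_MISSENSE", "DELETERIOUS_MISSENSE_CADD"))
  expect_setequal(cl(panel_af = 5e-4, cohort_af = 5e-4, cadd = 19.9, helix = 0.51),
                  c("RARE_MISSENSE", "DELETERIOUS_MISSENSE_HELIX"))
  expect_error(classify_variant(list(consequence = NA), NULL), "consequence")
})

test_that("PTV classification composes with the NMD rule", {
  tx <- toy_tx()
  expect_identical(classify_variant(toy_variant(1, 50), tx), "PTV")
  # stop-gained in the last exon is OTHER
  expect_identical(classify_variant(toy_variant(3, 650), tx), "OTHER")
  # splice variants are PTVs; splice_region is not in the PTV set
  expect_identical(classify_variant(toy_variant(1, 50, "splice_acceptor"), tx),
                   "PTV")
  v <- toy_variant(1, 50); v$consequence <- "splice_region"
  expect_identical(classify_variant(v, tx), "OTHER")
})

test_that("category monotonicity in the thresholds", {
  vars <- simulate_annotated_variants(n_genes = 4, seed = 9)
  base <- classify_variants(vars$annotations, vars$transcripts)
  wider_af <- classify_variants(vars$annotations, vars$transcripts, af_max = 0.01)
  higher_cadd <- classify_variants(vars$annotations, vars$transcripts, cadd_min = 30)
  # relaxing af_max can only grow RARE_MISSENSE
  expect_true(all(wider_af$RARE_MISSENSE >= base$RARE_MISSENSE))
  # raising cadd_min can only shrink the CADD tier
  expect_true(all(higher_cadd$DELETERIOUS_MISSENSE_CADD <=
                    base$DELETERIOUS_MISSENSE_CADD))
  # deleterious tiers are subsets of RARE_MISSENSE; PTV excludes missense
  expect_true(all(!base$DELETERIOUS_MISSENSE_CADD | base$RARE_MISSENSE))
  expect_true(all(!base$DELETERIOUS_MISSENSE_HELIX | base$RARE_MISSENSE))
  expect_true(all(!(base$PTV & base$RARE_MISSENSE)))
  # classification is deterministic
  expect_identical(base, classify_variants(vars$annotations, vars$transcripts))
})

test_that("carrier collapsing: het/hom combined, missing as non-carrier", {
  # exhaustive enumeration of 2-variant genotype patterns
  vals <- c(0, 1, 2, NA)
  grid <- expand.grid(g1 = vals, g2 = vals)
  m <- as.matrix(grid)
  rownames(m) <- sprintf("s%02d", seq_len(nrow(m)))
  colnames(m) <- c("v1", "v2")
  tab <- collapse_carriers(list(G = m))
  expected <- as.integer(rowSums(m, na.rm = TRUE) > 0)
  expect_identical(unname(tab[, "G"]), expected)
  # named cases from the contract
  expect_identical(unname(tab[which(grid$g1 == 0 & grid$g2 == 2), "G"]), 1L)
  expect_identical(unname(tab[which(is.na(grid$g1) & grid$g2 == 1), "G"]), 1L)
  expect_identical(unname(tab[which(is.na(grid$g1) & is.na(grid$g2)), "G"]), 0L)
})

test_that("collapsing respects the class filter and is idempotent", {
  vars <- simulate_annotated_variants(n_genes = 3, seed = 4)
  cls <- classify_variants(vars$annotations, vars$transcripts)
  tab <- collapse_carriers(vars$genotypes, cls, class_filter = "PTV")
  # every variant that entered the PTV column fails is_nmd_escaping
  ptv <- cls[cls$PTV, ]
  for (i in seq_len(nrow(ptv)))
    expect_false(is_nmd_escaping(as.list(ptv[i, ]),
                                 vars$transcripts[[ptv$gene_id[i]]]))
  # idempotence: collapsing the collapsed 0/1 table is the identity
  again <- collapse_carriers(setNames(lapply(colnames(tab), function(g)
    matrix(tab[, g], ncol = 1, dimnames = list(rownames(tab), g))),
    colnames(tab)))
  expect_identical(unname(unclass(again)), unname(unclass(tab)))
  # empty variant set yields an all-zero column
  none <- cls; none$PTV <- FALSE
  z <- collapse_carriers(vars$genotypes, none, class_filter = "PTV")
  expect_true(all(z == 0L))
})

test_that("cohort allele frequency uses non-missing denominators", {
  g <- matrix(0L, 1000, 3, dimnames = list(sprintf("s%04d", 1:1000), c("a", "b", "c")))
  g[1, "a"] <- 1L                # 1 het among 1000 -> 0.0005
  g[1, "b"] <- 2L                # 1 hom among 1000 -> 0.001
  g[1:2, "c"] <- 1L; g[501:1000, "c"] <- NA  # 2 het among 500 -> 0.002
  af <- cohort_af(g)
  expect_equal(unname(af), c(0.0005, 0.001, 0.002))
  # chromosome X: females-only denominator
  sex <- rep(c("F", "M"), each = 500)
  af_x <- cohort_af(g[, "a", drop = FALSE], sex = sex, chr_x = TRUE)
  expect_equal(unname(af_x), 1 / 1000)
  g[, 1] <- NA
  expect_error(cohort_af(g), "missing")
})

test_that("missingness report separates cases from controls", {
  g <- list(G = matrix(c(NA, NA, 0, 0), 4, 1,
                       dimnames = list(paste0("s", 1:4), "v1")))
  rep <- missingness_report(g, d = c(1, 1, 0, 0))
  expect_equal(rep$missing_frac, 0.5)
  expect_equal(rep$missing_frac_cases, 1)
  expect_equal(rep$missing_frac_controls, 0)
})
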