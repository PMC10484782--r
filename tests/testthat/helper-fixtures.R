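# Shared fixtures, built in code at test time.

# 3-exon toy transcript; penultimate exon [200, 500) is long enough to hold
# positions well outside the 50-bp escape zone.
toy_tx <- function() {
  transcript_model("TOY", cbind(c(0, 200, 600), c(100, 500, 700)))
}

toy_variant <- function(exon_index, position, consequence = "stop_gained",
                        gene_id = "TOY") {
  list(variant_id = "v", gene_id = gene_id, consequence = consequence,
       exon_index = exon_index, position = position,
       panel_af = 1e-4, cohort_af = 1e-4, cadd = 30, helix = 0.9)
}

# Small two-gene cohort used by several burden tests.
small_cohort <- function(seed = 101, n = 3000, or = 3, q = 0.01) {
  genes <- list(gene_spec("RISK", q, log_or = log(or)),
                gene_spec("NULL1", q))
  simulate_cohort(sim_config(n, n, genes, seed = seed))
}

expect_rel_equal <- function(x, y, tol) {
  expect_lt(abs(x - y) / abs(y), tol)
}
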