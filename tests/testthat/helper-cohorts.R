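# Small in-code fixtures shared across test files.

study_fixture <- function() {
  st <- study_snp_table()
  genotypes_from_counts(attr(st, "panel"), st)
}

# A tiny two-SNP genotype matrix from explicit calls.
toy_gm <- function(calls_a, calls_b, ids = NULL) {
  calls <- cbind(snpA = calls_a, snpB = calls_b)
  rownames(calls) <- ids %||% paste0("s", seq_len(nrow(calls)))
  genotype_matrix(calls)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

toy_outcome <- function(time, event, ids = NULL) {
  survival_outcome(ids %||% paste0("s", seq_along(time)), time, event)
}

# Cohort with a planted two-SNP interaction and four null SNPs.
planted_two_way <- function(n, hr = 0.25, seed = 1) {
  cfg <- synthetic_config(
    n = n, planted_subset = c("rs2071559", "rs208294"),
    hr_favorable = hr, seed = seed)
  gen_cohort(cfg)
}
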