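# Small cohorts used across tests: full study design but fewer plants and a
# lighter background-gene panel, so individual tests stay fast.
small_cohort_config <- function(seed = 42, ...) {
  args <- utils::modifyList(
    list(n_males = 3, n_females = 3, n_background_genes = 300,
         amplicon_depth = 500, seed = seed),
    list(...)
  )
  do.call(truth_config, args)
}

# Independent one-sided Fisher oracle: explicit hypergeometric enumeration of
# all 2x2 tables with the observed margins, summing the probability of tables
# at least as extreme in the first cell.
enumerate_fisher_p <- function(a, b, c, d) {
  m <- a + b
  f <- c + d
  K <- a + c
  ks <- max(0, K - f):min(m, K)
  probs <- choose(m, ks) * choose(f, K - ks) / choose(m + f, K)
  sum(probs[ks >= a])
}

# Run the ASE stages directly on in-memory cohort tables (no VCF round trip).
run_ase_stages <- function(cohort, dna_min_depth = 20, mono_threshold = 0.9,
                           rna_min_depth = 20, alpha = 0.05) {
  dna_calls <- call_genotype_dna(
    dplyr::filter(cohort$dna, assay == "amplicon"),
    min_depth = dna_min_depth
  )
  site_ase <- classify_site_rna(
    dplyr::filter(cohort$rna, assay == "amplicon"), dna_calls,
    mono_threshold = mono_threshold, min_depth = rna_min_depth
  )
  gene_ase <- aggregate_gene_ase(site_ase)
  sex_association(gene_ase, alpha = alpha)
}
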