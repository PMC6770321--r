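# The "stated world" used by the acceptance suite: a two-set breeding cohort
# with the study's family structure, scaled in line and SNP count to desk
# size where noted. Genetic lengths 160 cM per chromosome; LD and half-sib
# structure from the generator defaults.

acceptance_design <- function(n_lines = 600L, n_chr = 10L, snps_per_chr = 300L) {
  breeding_design(
    n_parents = 96L, n_shared_parents = 6L,
    set_sizes = c(n_lines %/% 2L, n_lines - n_lines %/% 2L),
    n_full_sib_families = round(n_lines / 4),
    chromosomes = data.frame(name = paste0("chr", seq_len(n_chr)),
                             n_snps = snps_per_chr, length_cM = 160))
}

# flour-yield-like architecture: Table 2 components as simulation truth
flour_arch <- function() {
  trait_architecture(genetic_var = 2.8, residual_var = 4.6)
}
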