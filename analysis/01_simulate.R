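#!/usr/bin/env Rscript
# Simulate the two-population study: a generic population and an enriched
# target population sharing common SNP-HLA haplotypes, reference cohorts
# for both, an independent test cohort and a large unphenotyped target
# cohort. Writes genotypes (VCF), truth HLA typings, truth haplotypes and
# the enriched-haplotype register.

source("analysis/00_settings.R")

study <- simulate_study(sim_cfg, n_ref = n_reference, n_test = n_test,
                        seed = analysis_seed)
target <- sample_cohort(study$pop_target, n_target, sim_cfg,
                        seed = analysis_seed + 5L,
                        population = "target", sample_prefix = "F")

save_cohort <- function(co, stem) {
  write_genotypes(co$genotypes, path_of(stem, "_genotypes.vcf"), "vcf")
  write_hla_table(co$typing, path_of(stem, "_hla.tsv"))
  write.table(co$truth_haplotypes, path_of(stem, "_haplotypes.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
}
save_cohort(study$ref_generic, "ref_generic")
save_cohort(study$ref_target, "ref_target")
save_cohort(study$test, "test")
save_cohort(target, "target")

writeLines(enriched_haplotype_ids(study$pop_target),
           path_of("enriched_haplotypes.txt"))
snp_sets <- lapply(study$pop_target$loci, `[[`, "snp_ids")
jsonlite::write_json(snp_sets, path_of("locus_snp_sets.json"))
write.table(study$pop_target$snp_table, path_of("snp_table.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

cat("Simulated", length(sim_cfg$loci), "loci;",
    n_reference, "reference samples per population;",
    n_test, "test and", n_target, "target samples.\n")
cat("Enriched haplotypes carry", sim_cfg$enriched_mass,
    "of the target population's frequency mass and are absent from the",
    "generic population.\n")
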