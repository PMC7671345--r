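#!/usr/bin/env Rscript
# Train one attribute-bagging panel per reference population on the
# harmonized SNPs and impute the test cohort with both, saving the model
# archives and the calls.

source("analysis/00_settings.R")

snp_sets <- lapply(jsonlite::read_json(path_of("locus_snp_sets.json"),
                                       simplifyVector = TRUE), as.character)
test_g <- read_genotypes(path_of("test_genotypes.harmonized.vcf"), "vcf")

for (panel in c("target", "generic")) {
  g <- read_genotypes(path_of("ref_", panel, "_genotypes.harmonized.vcf"),
                      "vcf")
  t <- read_hla_table(path_of("ref_", panel, "_hla.tsv"))
  # harmonization may have dropped block SNPs; keep the surviving ones
  sets <- lapply(snp_sets, intersect, y = colnames(g$dosage))
  m <- train_hla_models(g, t, run_cfg, seed = analysis_seed, snp_sets = sets)
  save_hla_model(m, path_of("model_", panel, ".json"), cfg = run_cfg)
  calls <- impute_cohort(m, test_g)$calls
  write_calls(calls, path_of("calls_", panel, ".tsv"))
  cat("Panel", panel, ": trained", length(m), "locus models on",
      m[[1]]$n_train, "samples; mean test posterior",
      round(mean(calls$posterior), 3), "\n")
}
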