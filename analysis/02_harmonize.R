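#!/usr/bin/env Rscript
# Harmonize the SNP content of two synthetic platform manifests across
# genome builds: the manifests share the simulated SNPs but one carries
# planted defects — SNPs missing from one platform, allele mismatches
# between builds, strand flips and palindromic SNPs — so the exclusion
# machinery is exercised end to end.

source("analysis/00_settings.R")

snp_tab <- read.delim(path_of("snp_table.tsv"))
comp <- c(A = "T", C = "G", G = "C", T = "A")

m37 <- snp_manifest(data.frame(
  rsid = snp_tab$id, build = "b37", chrom = snp_tab$chrom,
  pos = snp_tab$pos, alleleA = snp_tab$ref, alleleB = snp_tab$alt,
  platform = "array1"))

m38 <- data.frame(
  rsid = snp_tab$id, build = "b38", chrom = snp_tab$chrom,
  pos = snp_tab$pos + 1000L, alleleA = snp_tab$ref, alleleB = snp_tab$alt,
  platform = "array2")
set.seed(analysis_seed)
# planted defects: 5 SNPs dropped, 5 allele mismatches, 10 strand flips
drop_idx <- sample(nrow(m38), 5)
mismatch_idx <- sample(setdiff(seq_len(nrow(m38)), drop_idx), 5)
flip_idx <- sample(setdiff(seq_len(nrow(m38)), c(drop_idx, mismatch_idx)), 10)
for (i in mismatch_idx) {
  others <- setdiff(names(comp), c(m38$alleleA[i], m38$alleleB[i]))
  m38$alleleB[i] <- others[1]
}
m38$alleleA[flip_idx] <- comp[m38$alleleA[flip_idx]]
m38$alleleB[flip_idx] <- comp[m38$alleleB[flip_idx]]
m38 <- snp_manifest(m38[-drop_idx, ])

h <- harmonize_snps(list(m37, m38))
write_harmonized_set(h, path_of("harmonized_snps.tsv"))

cat("Harmonized", nrow(h$snps), "of", nrow(snp_tab), "SNPs;",
    nrow(h$exclusions), "excluded:\n")
print(table(h$exclusions$reason))

# restrict all cohort genotypes to the harmonized set
for (stem in c("ref_generic", "ref_target", "test", "target")) {
  g <- read_genotypes(path_of(stem, "_genotypes.vcf"), "vcf")
  gs <- subset_genotypes(g, h)
  write_genotypes(gs, path_of(stem, "_genotypes.harmonized.vcf"), "vcf")
}
cat("Wrote harmonized genotype files for all cohorts.\n")
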