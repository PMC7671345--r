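test_that("population simulation is deterministic, normalised and covers all alleles", {
  cfg <- small_sim_cfg()
  p1 <- simulate_population(cfg, seed = 9)
  p2 <- simulate_population(cfg, seed = 9)
  expect_identical(p1, p2)
  for (lm in p1$loci) {
    expect_equal(sum(lm$freq), 1, tolerance = 1e-12)
    expect_setequal(unique(lm$hla), unique(lm$hla))
    expect_length(unique(lm$hla), cfg$n_alleles)
  }
  # with as many alleles as haplotypes, each haplotype is a distinct allele
  cfg2 <- small_sim_cfg(n_alleles = 10L, n_shared_haplotypes = 10L)
  p3 <- simulate_population(cfg2, seed = 1)
  expect_length(unique(p3$loci$A$hla), 10L)
  expect_error(simulate_population(small_sim_cfg(n_alleles = 11L)),
               "cannot cover")
})

test_that("enriched population adds mass-constrained novel haplotypes only", {
  cfg <- small_sim_cfg()
  base <- simulate_population(cfg, seed = 4)
  enr <- derive_enriched_population(base, cfg, seed = 5)
  for (locus in names(base$loci)) {
    b <- base$loci[[locus]]
    e <- enr$loci[[locus]]
    is_e <- e$origin == "enriched"
    expect_equal(sum(e$freq[is_e]), cfg$enriched_mass, tolerance = 1e-12)
    expect_equal(sum(e$freq), 1, tolerance = 1e-12)
    # shared haplotypes identical in SNP vectors and labels, rescaled freqs
    expect_identical(e$haplotypes[!is_e, ], b$haplotypes)
    expect_identical(e$hla[!is_e], b$hla)
    expect_equal(e$freq[!is_e], b$freq * (1 - cfg$enriched_mass))
    # enriched SNP vectors are novel
    bkeys <- apply(b$haplotypes, 1, paste, collapse = "")
    ekeys <- apply(e$haplotypes[is_e, , drop = FALSE], 1, paste, collapse = "")
    expect_length(intersect(bkeys, ekeys), 0)
  }
  expect_setequal(enriched_haplotype_ids(enr),
                  unlist(lapply(enr$loci, function(l)
                    l$hap_id[l$origin == "enriched"])))
  # zero enrichment mass leaves the base model untouched
  cfg0 <- small_sim_cfg(enriched_mass = 0)
  expect_identical(derive_enriched_population(base, cfg0, seed = 5), base)
})

test_that("noiseless cohorts satisfy the dosage-haplotype identity", {
  cfg <- small_sim_cfg(genotype_noise = 0)
  pop <- simulate_population(cfg, seed = 2)
  co <- sample_cohort(pop, 40, cfg, seed = 3)
  for (locus in names(pop$loci)) {
    lm <- pop$loci[[locus]]
    th <- co$truth_haplotypes[co$truth_haplotypes$locus == locus, ]
    expected <- lm$haplotypes[match(th$hap1, lm$hap_id), ] +
      lm$haplotypes[match(th$hap2, lm$hap_id), ]
    got <- co$genotypes$dosage[th$sample, lm$snp_ids]
    expect_equal(unname(got), unname(expected))
    # typing equals the haplotypes' HLA labels (unordered)
    lab <- cbind(lm$hla[match(th$hap1, lm$hap_id)],
                 lm$hla[match(th$hap2, lm$hap_id)])
    ty <- co$typing[co$typing$locus == locus, ]
    ty <- ty[match(th$sample, ty$sample), ]
    expect_equal(ty$allele1, pmin(lab[, 1], lab[, 2]))
    expect_equal(ty$allele2, pmax(lab[, 1], lab[, 2]))
  }
  # homozygous draws list the allele twice
  hom <- co$truth_haplotypes$hap1 == co$truth_haplotypes$hap2
  if (any(hom)) {
    i <- which(hom)[1]
    row <- co$truth_haplotypes[i, ]
    ty <- co$typing[co$typing$sample == row$sample &
                      co$typing$locus == row$locus, ]
    expect_equal(ty$allele1, ty$allele2)
  }
})

test_that("cohort allele frequencies match the population within binomial error", {
  cfg <- small_sim_cfg(loci = "A", n_snps = 10L)
  pop <- simulate_population(cfg, seed = 6)
  n <- 20000
  co <- sample_cohort(pop, n, cfg, seed = 7)
  lm <- pop$loci$A
  pop_freq <- tapply(lm$freq, lm$hla, sum)
  obs <- table(c(co$typing$allele1, co$typing$allele2)) / (2 * n)
  for (al in names(pop_freq)) {
    p <- pop_freq[[al]]
    se <- sqrt(p * (1 - p) / (2 * n))
    expect_lt(abs(obs[[al]] - p), 3 * se + 1e-9)
  }
})

test_that("phenotype simulation hits its prevalence and planted effects", {
  cfg <- small_sim_cfg(loci = "A")
  pop <- simulate_population(cfg, seed = 8)
  co <- sample_cohort(pop, 10000, cfg, seed = 9)
  # no effects: case fraction ~ 10%
  ph <- simulate_phenotypes(co$typing, prevalence_intercept = qlogis(0.1),
                            seed = 10)
  se <- sqrt(0.1 * 0.9 / 10000)
  expect_lt(abs(mean(ph$status) - 0.1), 3 * se)
  expect_identical(ph, simulate_phenotypes(co$typing,
                                           prevalence_intercept = qlogis(0.1),
                                           seed = 10))
  # planted logOR +1 raises the carriage odds ratio above 1
  al <- names(sort(table(c(co$typing$allele1, co$typing$allele2)),
                   decreasing = TRUE))[1]
  eff <- setNames(1, al)
  ph2 <- simulate_phenotypes(co$typing, effects = eff, seed = 11)
  carrier <- with(co$typing, tapply(allele1 == al | allele2 == al,
                                    sample, any))[ph2$sample]
  tab <- table(carrier, ph2$status)
  or <- (tab["TRUE", "1"] * tab["FALSE", "0"]) /
    (tab["TRUE", "0"] * tab["FALSE", "1"])
  expect_gt(or, 1)
  expect_error(simulate_phenotypes(co$typing,
                                   effects = c("Z*99:99" = 1), seed = 1),
               "absent")
})
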