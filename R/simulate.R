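#' Simulate a base population of SNP+HLA haplotypes
#'
#' Builds, per locus, a pool of extended haplotypes: a binary SNP allele
#' vector over the locus block plus the HLA allele the haplotype carries,
#' with Dirichlet-drawn frequencies. Every one of the `n_alleles` HLA
#' labels is carried by at least one haplotype. SNP/HLA LD arises because
#' each haplotype deterministically links its SNP vector to one HLA allele.
#'
#' @param cfg A [simulation_config()].
#' @param seed Integer seed (default `cfg$seed`).
#' @return An object of class `population_model`: per locus a list with
#'   `snp_ids`, `haplotypes` (haplotypes x SNPs 0/1 matrix), `hla`,
#'   `freq`, `origin` (`"shared"`/`"enriched"`), `hap_id`; plus a global
#'   `snp_table` usable as a [genotype_matrix()] annotation.
#' @export
simulate_population <- function(cfg, seed = cfg$seed) {
  if (cfg$n_alleles > cfg$n_shared_haplotypes)
    stop("n_alleles exceeds n_shared_haplotypes: cannot cover every allele")
  with_seed(seed, {
    loci <- list()
    snp_rows <- list()
    bases <- c("A", "C", "G", "T")
    for (l in seq_along(cfg$loci)) {
      locus <- cfg$loci[l]
      n_h <- cfg$n_shared_haplotypes
      hap <- matrix(as.integer(stats::runif(n_h * cfg$n_snps) < 0.5),
                    nrow = n_h, ncol = cfg$n_snps)
      alleles <- sprintf("%s*%02d:01", locus, seq_len(cfg$n_alleles))
      lab <- c(alleles,
               if (n_h > cfg$n_alleles)
                 sample(alleles, n_h - cfg$n_alleles, replace = TRUE))
      freq <- stats::rgamma(n_h, shape = cfg$dirichlet_alpha)
      freq <- freq / sum(freq)
      snp_ids <- sprintf("rs%d", l * 100000L + seq_len(cfg$n_snps))
      # alt excludes ref and its complement: palindromic (A/T, C/G) SNPs
      # are strand-ambiguous and real genotyping platforms avoid them
      comp <- c(A = "T", C = "G", G = "C", T = "A")
      ref <- sample(bases, cfg$n_snps, replace = TRUE)
      alt <- vapply(ref, function(b)
        sample(setdiff(bases, c(b, comp[[b]])), 1), "")
      snp_rows[[l]] <- data.frame(
        id = snp_ids, chrom = "6",
        pos = 29000000L + (l - 1L) * 300000L + seq_len(cfg$n_snps) * 250L,
        ref = ref, alt = alt, locus = locus, stringsAsFactors = FALSE)
      loci[[locus]] <- list(snp_ids = snp_ids, haplotypes = hap,
                            hla = lab, freq = freq,
                            origin = rep("shared", n_h),
                            hap_id = sprintf("%s_H%02d", locus, seq_len(n_h)))
    }
    structure(list(loci = loci,
                   snp_table = do.call(rbind, snp_rows),
                   cfg = cfg),
              class = "population_model")
  })
}

#' Derive the enriched target population from a base population
#'
#' Copies the base population and adds, per locus, `n_enriched_haplotypes`
#' novel haplotypes (a shared SNP vector mutated at 10-30% of sites, HLA
#' label drawn from the existing allele set) carrying total frequency
#' `enriched_mass`; shared-haplotype frequencies are rescaled by
#' `1 - enriched_mass`. These haplotypes have frequency zero in the base
#' population — the analogue of haplotypes common in an isolated population
#' but missing elsewhere. With `enriched_mass = 0` the base model is
#' returned unchanged.
#'
#' @param base A `population_model` from [simulate_population()].
#' @param cfg The [simulation_config()] (supplies enrichment knobs).
#' @param seed Integer seed.
#' @return A `population_model` with `origin == "enriched"` rows appended.
#' @export
derive_enriched_population <- function(base, cfg, seed = cfg$seed + 1L) {
  if (cfg$enriched_mass == 0 || cfg$n_enriched_haplotypes == 0) return(base)
  with_seed(seed, {
    out <- base
    for (locus in names(base$loci)) {
      lm <- base$loci[[locus]]
      n_snps <- ncol(lm$haplotypes)
      n_e <- cfg$n_enriched_haplotypes
      existing <- apply(lm$haplotypes, 1, paste, collapse = "")
      new_hap <- matrix(0L, n_e, n_snps)
      for (e in seq_len(n_e)) {
        repeat {
          src <- lm$haplotypes[sample(nrow(lm$haplotypes), 1), ]
          n_mut <- max(1L, round(stats::runif(1, 0.1, 0.3) * n_snps))
          sites <- sample(n_snps, n_mut)
          src[sites] <- 1L - src[sites]
          if (!(paste(src, collapse = "") %in%
                c(existing, apply(new_hap[seq_len(e - 1), , drop = FALSE],
                                  1, paste, collapse = "")))) break
        }
        new_hap[e, ] <- src
      }
      e_freq <- stats::rgamma(n_e, shape = cfg$dirichlet_alpha)
      e_freq <- e_freq / sum(e_freq) * cfg$enriched_mass
      e_hla <- sample(unique(lm$hla), n_e, replace = TRUE)
      out$loci[[locus]] <- list(
        snp_ids = lm$snp_ids,
        haplotypes = rbind(lm$haplotypes, new_hap),
        hla = c(lm$hla, e_hla),
        freq = c(lm$freq * (1 - cfg$enriched_mass), e_freq),
        origin = c(lm$origin, rep("enriched", n_e)),
        hap_id = c(lm$hap_id, sprintf("%s_E%02d", locus, seq_len(n_e))))
    }
    out
  })
}

# Per-site flip noise on a dosage matrix: 0 -> 1, 2 -> 1, 1 -> 0 or 2 with
# equal odds, each site independently with probability `rate`. Consumes
# from the active RNG stream.
flip_dosages <- function(dos, rate) {
  if (rate <= 0) return(dos)
  flip <- matrix(stats::runif(length(dos)) < rate, nrow = nrow(dos))
  up <- matrix(stats::runif(length(dos)) < 0.5, nrow = nrow(dos))
  out <- dos
  out[flip & dos == 0L] <- 1L
  out[flip & dos == 2L] <- 1L
  het <- flip & dos == 1L
  out[het] <- ifelse(up[het], 2L, 0L)
  out
}

#' Re-emit a genotype matrix with fresh measurement noise
#'
#' Applies the generator's per-site flip model (`0 -> 1`, `2 -> 1`,
#' `1 -> 0` or `2` with equal odds) to an existing genotype matrix,
#' emulating an independent noisy re-measurement of the same samples.
#' Missing entries stay missing.
#'
#' @param g A [genotype_matrix()].
#' @param rate Per-site flip probability.
#' @param seed Integer seed.
#' @return A [genotype_matrix()] with flipped entries.
#' @export
add_genotype_noise <- function(g, rate, seed = 1L) {
  stopifnot(inherits(g, "genotype_matrix"), rate >= 0, rate <= 1)
  with_seed(seed, {
    dos <- flip_dosages(g$dosage, rate)
    dos[is.na(g$dosage)] <- NA_integer_
    genotype_matrix(dos, g$snps)
  })
}

#' IDs of enriched haplotypes in a population model
#'
#' @param pop A `population_model`.
#' @return Character vector of haplotype IDs flagged `"enriched"`.
#' @export
enriched_haplotype_ids <- function(pop) {
  unlist(lapply(pop$loci, function(lm) lm$hap_id[lm$origin == "enriched"]),
         use.names = FALSE)
}

#' Sample a cohort of diploid individuals from a population
#'
#' Per sample and locus, two haplotypes are drawn i.i.d. from the locus
#' frequency table; the emitted genotype is the allele sum with per-site
#' flip noise (`0 -> 1`, `2 -> 1`, `1 -> 0` or `2` with equal odds) at rate
#' `cfg$genotype_noise`. Truth typing and truth haplotype IDs are recorded
#' before noise.
#'
#' @param pop A `population_model`.
#' @param n Number of samples.
#' @param cfg The [simulation_config()].
#' @param seed Integer seed.
#' @param population Population label stored on the cohort.
#' @param sample_prefix Prefix for generated sample IDs.
#' @return An object of class `cohort`: list with `genotypes`
#'   ([genotype_matrix()]), `typing` ([hla_typing()]), `truth_haplotypes`
#'   (sample, locus, hap1, hap2), and `population`.
#' @export
sample_cohort <- function(pop, n, cfg, seed, population = "pop",
                          sample_prefix = "S") {
  stopifnot(n >= 1)
  with_seed(seed, {
    samples <- sprintf("%s%04d", sample_prefix, seq_len(n))
    dos_blocks <- list()
    typ_rows <- list()
    hap_rows <- list()
    for (locus in names(pop$loci)) {
      lm <- pop$loci[[locus]]
      i1 <- sample.int(length(lm$freq), n, replace = TRUE, prob = lm$freq)
      i2 <- sample.int(length(lm$freq), n, replace = TRUE, prob = lm$freq)
      dos <- lm$haplotypes[i1, , drop = FALSE] +
        lm$haplotypes[i2, , drop = FALSE]
      dos <- flip_dosages(dos, cfg$genotype_noise)
      colnames(dos) <- lm$snp_ids
      dos_blocks[[locus]] <- dos
      p <- sort_pair(lm$hla[i1], lm$hla[i2])
      typ_rows[[locus]] <- data.frame(sample = samples, locus = locus,
                                      allele1 = p$a1, allele2 = p$a2,
                                      stringsAsFactors = FALSE)
      hap_rows[[locus]] <- data.frame(sample = samples, locus = locus,
                                      hap1 = lm$hap_id[i1],
                                      hap2 = lm$hap_id[i2],
                                      stringsAsFactors = FALSE)
    }
    dosage <- do.call(cbind, dos_blocks)
    rownames(dosage) <- samples
    snps <- pop$snp_table[match(colnames(dosage), pop$snp_table$id),
                          c("id", "chrom", "pos", "ref", "alt")]
    typing <- do.call(rbind, typ_rows)
    rownames(typing) <- NULL
    structure(list(genotypes = genotype_matrix(dosage, snps),
                   typing = hla_typing(typing, loci = names(pop$loci)),
                   truth_haplotypes = do.call(rbind, hap_rows),
                   population = population),
              class = "cohort")
  })
}

#' @export
print.cohort <- function(x, ...) {
  cat("cohort (", x$population, "): ", nrow(x$genotypes$dosage),
      " samples, ", ncol(x$genotypes$dosage), " SNPs, ",
      length(unique(x$typing$locus)), " HLA loci\n", sep = "")
  invisible(x)
}

#' Simulate case-control phenotypes with covariates from true HLA types
#'
#' Disease status is Bernoulli with logit equal to
#' `intercept + sum(allele dosage x log-OR) + covariate terms`. Covariates
#' are age ~ N(55, 10), sex ~ Bernoulli(0.5), BMI ~ N(27, 4) and `n_pcs`
#' principal-component coordinates ~ N(0, 1); covariate effects apply on the
#' standardised scale ((age-55)/10, sex-0.5, (BMI-27)/4, PCs as-is), so with
#' zero allele effects the case fraction stays at
#' `plogis(prevalence_intercept)` up to logistic curvature in the covariate
#' term.
#'
#' @param truth An [hla_typing()] table (the true allele pairs).
#' @param effects Named numeric vector: allele name -> log odds ratio.
#' @param covar_effects Named numeric vector over
#'   `c("age","sex","bmi","pc1",...)`; `NULL` means all zero.
#' @param prevalence_intercept Intercept on the logit scale.
#' @param n_pcs Number of PC covariates to generate.
#' @param seed Integer seed.
#' @return data.frame of class `phenotype_table`: `sample`, `status`,
#'   `age`, `sex`, `bmi`, `pc1..pcK`.
#' @export
simulate_phenotypes <- function(truth, effects = numeric(0),
                                covar_effects = NULL,
                                prevalence_intercept = stats::qlogis(0.1),
                                n_pcs = 10L, seed = 1L) {
  samples <- unique(truth$sample)
  if (length(effects) > 0) {
    present <- unique(c(truth$allele1, truth$allele2))
    absent <- setdiff(names(effects), present)
    if (length(absent) > 0)
      stop("effect references allele(s) absent from truth: ",
           paste(absent, collapse = ", "))
  }
  with_seed(seed, {
    n <- length(samples)
    age <- stats::rnorm(n, 55, 10)
    sex <- stats::rbinom(n, 1, 0.5)
    bmi <- stats::rnorm(n, 27, 4)
    pcs <- matrix(stats::rnorm(n * n_pcs), n, n_pcs,
                  dimnames = list(NULL, paste0("pc", seq_len(n_pcs))))
    lin <- rep(prevalence_intercept, n)
    for (al in names(effects)) {
      d <- tapply((truth$allele1 == al) + (truth$allele2 == al),
                  truth$sample, sum)
      lin <- lin + effects[[al]] * as.numeric(d[samples])
    }
    if (!is.null(covar_effects)) {
      std <- cbind(age = (age - 55) / 10, sex = sex - 0.5,
                   bmi = (bmi - 27) / 4, pcs)
      use <- intersect(names(covar_effects), colnames(std))
      for (v in use) lin <- lin + covar_effects[[v]] * std[, v]
    }
    status <- stats::rbinom(n, 1, stats::plogis(lin))
    out <- data.frame(sample = samples, status = status, age = age,
                      sex = sex, bmi = bmi, stringsAsFactors = FALSE)
    out <- cbind(out, as.data.frame(pcs))
    class(out) <- c("phenotype_table", "data.frame")
    out
  })
}
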