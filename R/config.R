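#' Run configuration for the imputation pipeline
#'
#' Bundles the knobs shared by training, evaluation and association stages.
#' Defaults follow the study design this package reproduces: seven classical
#' HLA loci, 100-classifier ensembles, and a genome-wide style significance
#' threshold of 5e-5 for HLA allele associations.
#'
#' @param loci Character vector of locus names, in display order.
#' @param n_classifiers Number of classifiers per locus ensemble.
#' @param pp_threshold_grid Strictly ascending posterior-probability
#'   thresholds in `[0, 1]` used by sweep analyses.
#' @param n_bootstrap Bootstrap replicates for error distributions.
#' @param n_permutations Permutation replicates for paired error tests.
#' @param alpha_assoc Significance level flagged in association scans.
#' @param n_pcs Number of genetic principal components used as covariates.
#' @param n_refine Maximum greedy refinement moves per classifier.
#' @param calibrate_posteriors Fit an out-of-bag isotonic calibration map
#'   per locus model and report calibrated best-guess confidences. Raw
#'   bagged posterior averages are systematically underconfident; the
#'   out-of-bag ensemble predictions measure and correct that bias.
#' @param em_tol,em_max_iter EM convergence tolerance and iteration cap used
#'   when fitting classifier haplotype tables. Looser than the
#'   [em_haplotype_frequencies()] defaults: inside a bagged ensemble the
#'   residual frequency error is far below the bagging noise, so the extra
#'   iterations buy nothing.
#' @param seed Base seed from which stage seeds are derived.
#' @return A list of class `run_config`.
#' @export
run_config <- function(loci = c("A", "B", "C", "DRB1", "DQA1", "DQB1", "DPB1"),
                       n_classifiers = 100L,
                       pp_threshold_grid = seq(0, 0.95, by = 0.05),
                       n_bootstrap = 100L,
                       n_permutations = 1000L,
                       alpha_assoc = 5e-5,
                       n_pcs = 10L,
                       n_refine = 5L,
                       calibrate_posteriors = TRUE,
                       em_tol = 1e-6,
                       em_max_iter = 200L,
                       seed = 1L) {
  stopifnot(length(loci) >= 1, !anyDuplicated(loci))
  counts <- c(n_classifiers = n_classifiers, n_bootstrap = n_bootstrap,
              n_permutations = n_permutations, n_pcs = n_pcs)
  if (any(counts < 1)) stop("all counts must be >= 1")
  if (any(pp_threshold_grid < 0) || any(pp_threshold_grid > 1) ||
      is.unsorted(pp_threshold_grid, strictly = TRUE))
    stop("pp_threshold_grid must be strictly ascending within [0, 1]")
  if (alpha_assoc <= 0 || alpha_assoc >= 1) stop("alpha_assoc must be in (0, 1)")
  if (n_refine < 0) stop("n_refine must be >= 0")
  if (em_tol <= 0 || em_max_iter < 1) stop("invalid EM settings")
  structure(list(loci = as.character(loci),
                 n_classifiers = as.integer(n_classifiers),
                 pp_threshold_grid = as.numeric(pp_threshold_grid),
                 n_bootstrap = as.integer(n_bootstrap),
                 n_permutations = as.integer(n_permutations),
                 alpha_assoc = alpha_assoc,
                 n_pcs = as.integer(n_pcs),
                 n_refine = as.integer(n_refine),
                 calibrate_posteriors = isTRUE(calibrate_posteriors),
                 em_tol = em_tol,
                 em_max_iter = as.integer(em_max_iter),
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Configuration of the synthetic two-population MHC generator
#'
#' Defines the ground-truth haplotype structure: per locus, a block of
#' biallelic SNPs in strong LD with the HLA allele carried by each haplotype.
#' Two populations share `n_shared_haplotypes` common haplotypes; the target
#' population additionally carries `n_enriched_haplotypes` rare haplotypes
#' (absent from the generic population) holding total frequency
#' `enriched_mass` — the analogue of haplotypes enriched in an isolated
#' population.
#'
#' @param loci Locus names (one independent SNP block each).
#' @param n_snps SNPs per locus block.
#' @param n_alleles Distinct HLA alleles per locus.
#' @param n_shared_haplotypes Haplotypes shared by both populations, per locus.
#' @param n_enriched_haplotypes Enriched haplotypes per locus (target
#'   population only).
#' @param enriched_mass Total frequency carried by enriched haplotypes in the
#'   target population, in `[0, 1)`; 0 disables enrichment entirely.
#' @param dirichlet_alpha Concentration of the Dirichlet draw for haplotype
#'   frequencies.
#' @param genotype_noise Per-site allele flip probability applied when
#'   emitting genotypes.
#' @param recombination_prob Per-meiosis recombination probability between
#'   locus blocks. Retained for completeness; with loci simulated as
#'   independent blocks it does not alter any output.
#' @param seed Base seed.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(loci = c("A", "B", "C", "DRB1", "DQA1", "DQB1", "DPB1"),
                              n_snps = 50L,
                              n_alleles = 8L,
                              n_shared_haplotypes = 30L,
                              n_enriched_haplotypes = 8L,
                              enriched_mass = 0.15,
                              dirichlet_alpha = 0.8,
                              genotype_noise = 0.002,
                              recombination_prob = 0.01,
                              seed = 1L) {
  stopifnot(length(loci) >= 1, !anyDuplicated(loci))
  counts <- c(n_snps, n_alleles, n_shared_haplotypes, n_enriched_haplotypes)
  if (any(counts < 1)) stop("all counts must be >= 1")
  if (enriched_mass < 0 || enriched_mass >= 1)
    stop("enriched_mass must be in [0, 1)")
  probs <- c(genotype_noise, recombination_prob)
  if (any(probs < 0) || any(probs > 1)) stop("probabilities must be in [0, 1]")
  if (dirichlet_alpha <= 0) stop("dirichlet_alpha must be positive")
  structure(list(loci = as.character(loci),
                 n_snps = as.integer(n_snps),
                 n_alleles = as.integer(n_alleles),
                 n_shared_haplotypes = as.integer(n_shared_haplotypes),
                 n_enriched_haplotypes = as.integer(n_enriched_haplotypes),
                 enriched_mass = enriched_mass,
                 dirichlet_alpha = dirichlet_alpha,
                 genotype_noise = genotype_noise,
                 recombination_prob = recombination_prob,
                 seed = as.integer(seed)),
            class = "simulation_config")
}
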