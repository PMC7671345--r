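#' Simulate the full two-population study design
#'
#' Generates the generic (base) population and the enriched target
#' population, then draws one reference cohort per population and a test
#' cohort from the target population — the synthetic stand-in for a
#' study comparing a population-matched reference panel with a generic one
#' on an independent test set.
#'
#' @param sim_cfg A [simulation_config()].
#' @param n_ref Reference cohort size per population.
#' @param n_test Test cohort size (drawn from the target population).
#' @param seed Integer seed; all stage seeds derive from it.
#' @return List: `pop_generic`, `pop_target`, `ref_generic`, `ref_target`,
#'   `test`.
#' @export
simulate_study <- function(sim_cfg = simulation_config(), n_ref = 800L,
                           n_test = 200L, seed = sim_cfg$seed) {
  pop_g <- simulate_population(sim_cfg, seed = derive_seed(seed, 1))
  pop_t <- derive_enriched_population(pop_g, sim_cfg,
                                      seed = derive_seed(seed, 2))
  list(pop_generic = pop_g,
       pop_target = pop_t,
       ref_generic = sample_cohort(pop_g, n_ref, sim_cfg,
                                   seed = derive_seed(seed, 3),
                                   population = "generic",
                                   sample_prefix = "G"),
       ref_target = sample_cohort(pop_t, n_ref, sim_cfg,
                                  seed = derive_seed(seed, 4),
                                  population = "target",
                                  sample_prefix = "T"),
       test = sample_cohort(pop_t, n_test, sim_cfg,
                            seed = derive_seed(seed, 5),
                            population = "target",
                            sample_prefix = "X"))
}

#' Train both reference panels and impute the test cohort
#'
#' Runs the core comparison: a panel trained on the target (enriched)
#' population versus a panel trained on the generic population, both
#' applied to the same test cohort from the target population, with
#' allele-level error tables for each.
#'
#' @param study A [simulate_study()] result.
#' @param run_cfg A [run_config()].
#' @param seed Integer seed for training.
#' @return List: `models_target`, `models_generic`, `calls_target`,
#'   `calls_generic`, `posteriors_target`, `posteriors_generic`,
#'   `errors_target`, `errors_generic`.
#' @export
run_panel_comparison <- function(study, run_cfg = run_config(),
                                 seed = run_cfg$seed) {
  snp_sets <- lapply(study$pop_target$loci, `[[`, "snp_ids")
  m_t <- train_hla_models(study$ref_target$genotypes,
                          study$ref_target$typing, run_cfg,
                          seed = derive_seed(seed, 11),
                          snp_sets = snp_sets)
  m_g <- train_hla_models(study$ref_generic$genotypes,
                          study$ref_generic$typing, run_cfg,
                          seed = derive_seed(seed, 12),
                          snp_sets = snp_sets)
  imp_t <- impute_cohort(m_t, study$test$genotypes)
  imp_g <- impute_cohort(m_g, study$test$genotypes)
  truth <- study$test$typing
  list(models_target = m_t, models_generic = m_g,
       calls_target = imp_t$calls, calls_generic = imp_g$calls,
       posteriors_target = imp_t$posteriors,
       posteriors_generic = imp_g$posteriors,
       errors_target = count_errors(truth, imp_t$calls, panel = "target"),
       errors_generic = count_errors(truth, imp_g$calls, panel = "generic"))
}

#' Overall allele error rate of an error table
#'
#' @param e An [count_errors()] table.
#' @return Total errors over `2 x` number of calls.
#' @export
overall_error_rate <- function(e) sum(e$errors) / (2 * nrow(e))
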