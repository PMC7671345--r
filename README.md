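# hlapanel

Training, evaluation and validation of **population-specific HLA imputation
reference panels**.

## The scientific problem

The classical HLA genes (HLA-A, -B, -C, -DRB1, -DQA1, -DQB1, -DPB1) are the
most polymorphic loci in the human genome and the strongest single genetic
susceptibility factor for autoimmune disease. For biobank-scale cohorts,
two-field HLA alleles are *imputed* from MHC-region SNPs in strong LD with
them, using models trained on a reference panel that has both SNP genotypes
and clinical-grade HLA types. Because LD structure differs between
populations — isolated populations carry haplotypes that are common locally
but rare or missing elsewhere — a panel matched to the study population
should beat a generic continental panel, and a generic panel's errors
should concentrate in carriers of the population-enriched haplotypes.

`hlapanel` implements the full pipeline for testing those claims and is
aimed at statistical geneticists building or evaluating imputation panels:

* **SNP harmonization** across platform manifests and genome builds
  (intersection by rsID, allele-set consistency, strand normalisation,
  palindromic exclusion).
* **Attribute-bagging imputation**: per locus, an ensemble of classifiers,
  each a bootstrap sample plus a random SNP subset of size ⌈√m⌉ refined by
  greedy out-of-bag moves, with an EM-fitted *extended-haplotype* table
  (SNP pattern + HLA allele → frequency). Prediction averages per-classifier
  diplotype posteriors with OOB-accuracy weights; reported confidences are
  OOB-calibrated. The EM/prediction core is C++ (Rcpp).
* **Evaluation**: allele-level error counting (multiset matching),
  sample-level bootstraps, paired permutation tests on total errors and on
  threshold-sweep error rates, ROC/AUC of the posterior as a correctness
  score, posterior-threshold retention sweeps, 10-fold cross-validated
  "best panel by posterior" selection, and attribution of errors to
  enriched-haplotype carriers.
* **Frequency validation**: per-batch imputed allele frequencies against an
  independent reference table across posterior cutoffs, and the rank
  correlation of batch deviation with imputed allele count.
* **Association**: logistic regression of imputed allele dosage
  (best-guess or posterior-expected) on case-control status with age, sex,
  BMI and 10 genetic PCs as covariates; fixed 5e-5 significance threshold;
  posterior-cutoff sensitivity sweeps.
* **Synthetic data**: a generator for two related populations sharing
  common SNP-HLA haplotypes, one carrying enriched rare haplotypes absent
  from the other, plus cohorts, genotype noise and phenotypes with planted
  allele effects — the stand-in for access-controlled clinical cohorts.

## Worked example

```r
library(hlapanel)

# two populations: "generic" and an isolate with enriched rare haplotypes
sim <- simulation_config()                 # 7 loci, 50 SNPs & 8 alleles each
study <- simulate_study(sim, n_ref = 800, n_test = 200, seed = 42)

# train one panel per population, impute the same test cohort with both
cfg <- run_config(n_classifiers = 25, seed = 42)
cmp <- run_panel_comparison(study, cfg, seed = 42)

sum(cmp$errors_target$errors)              # matched panel:   5 allele errors
sum(cmp$errors_generic$errors)             # generic panel: 409 allele errors
permutation_test_total_errors(cmp$errors_target, cmp$errors_generic,
                              n_perm = 1000, seed = 1)$p_value
#> 0.000999001

att <- attribute_errors_to_haplotypes(cmp$errors_generic,
                                      study$test$truth_haplotypes,
                                      enriched_haplotype_ids(study$pop_target))
att$carrier_error_share                    # 1.0  (all errors in carriers)
att$carrier_fraction                       # 0.9
```

The matched panel makes two orders of magnitude fewer allele-level errors
(5 vs 409 of 2800 imputed alleles here, i.e. 0.18% vs 14.6%), the paired
permutation test rejects equality, and the generic panel's errors fall
entirely in carriers of enriched haplotypes — the package's synthetic
analogue of population-matched panels outperforming generic ones.

The numbered drivers under `analysis/` run the same study as a narrated
six-step workflow (simulate → harmonize → train/impute → evaluate →
validate frequencies → associate), writing tables under `results/analysis/`.

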