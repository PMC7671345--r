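# brute-force error count: best over both assignments of call to truth slots
brute_errors <- function(t1, t2, c1, c2) {
  min((c1 != t1) + (c2 != t2), (c1 != t2) + (c2 != t1))
}

test_that("error counting uses multiset matching, including homozygote truths", {
  truth <- hla_typing(data.frame(
    sample = c("S1", "S2", "S3"), locus = "A",
    allele1 = c("A*01:01", "A*01:01", "A*01:01"),
    allele2 = c("A*02:01", "A*02:01", "A*01:01")))
  calls <- toy_calls(c("A*02:01", "A*01:01", "A*01:01"),
                     c("A*01:01", "A*03:01", "A*02:01"),
                     sample = c("S1", "S2", "S3"))
  e <- count_errors(truth, calls)
  expect_equal(e$errors, c(0L, 1L, 1L))
  # exhaustive check over all pair combinations of 3 alleles
  als <- c("A*01:01", "A*02:01", "A*03:01")
  combos <- expand.grid(t1 = als, t2 = als, c1 = als, c2 = als,
                        stringsAsFactors = FALSE)
  combos <- combos[combos$t1 <= combos$t2 & combos$c1 <= combos$c2, ]
  tr <- hla_typing(data.frame(sample = paste0("S", seq_len(nrow(combos))),
                              locus = "A", allele1 = combos$t1,
                              allele2 = combos$t2))
  cl <- toy_calls(combos$c1, combos$c2,
                  sample = paste0("S", seq_len(nrow(combos))))
  e2 <- count_errors(tr, cl)
  expected <- mapply(brute_errors, combos$t1, combos$t2, combos$c1, combos$c2)
  expect_equal(e2$errors, unname(expected))
  # flagged calls count 2 errors and are tallied separately
  cf <- toy_calls("A*01:01", "A*01:01", sample = "S1", flagged = TRUE)
  ef <- count_errors(truth[truth$sample == "S1", ], cf)
  expect_equal(ef$errors, 2L)
  expect_equal(attr(ef, "n_flagged"), 1L)
  expect_error(count_errors(truth, toy_calls("A*01:01", "A*01:01",
                                             sample = "S9")),
               "without truth")
})

test_that("error totals agree across sample, locus and overall summaries", {
  sc <- small_sim_cfg()
  st <- simulate_study(sc, n_ref = 60, n_test = 40, seed = 17)
  rc <- run_config(n_classifiers = 3, seed = 17)
  cmp <- run_panel_comparison(st, rc, seed = 17)
  e <- cmp$errors_generic
  by_locus <- tapply(e$errors, e$locus, sum)
  by_sample <- tapply(e$errors, e$sample, sum)
  expect_equal(sum(by_locus), sum(e$errors))
  expect_equal(sum(by_sample), sum(e$errors))
  expect_equal(overall_error_rate(e), sum(e$errors) / (2 * nrow(e)))
})

test_that("bootstrap resamples whole samples and is seed-stable", {
  e0 <- make_error_table(rep(0L, 10))
  b0 <- bootstrap_error_distribution(e0, n_boot = 20, seed = 1)
  expect_true(all(b0$replicates == 0))
  e <- make_error_table(c(rep(0L, 30), rep(1L, 6), 2L),
                        sample = paste0("S", 1:37))
  b1 <- bootstrap_error_distribution(e, n_boot = 200, seed = 2)
  b2 <- bootstrap_error_distribution(e, n_boot = 200, seed = 2)
  expect_identical(b1, b2)
  se <- sd(b1$replicates[, 1]) / sqrt(200)
  expect_lt(abs(mean(b1$replicates[, 1]) - sum(e$errors)), 3 * se + 0.5)
})

test_that("paired permutation test honours the +1 convention and extremes", {
  eA <- make_error_table(c(0L, 1L, 2L, 0L))
  pm <- permutation_test_total_errors(eA, eA, n_perm = 99, seed = 1)
  expect_equal(pm$observed, 0)
  expect_equal(pm$p_value, 1)
  eZ <- make_error_table(rep(0L, 200), sample = paste0("S", 1:200))
  eT <- make_error_table(rep(2L, 200), sample = paste0("S", 1:200))
  pm2 <- permutation_test_total_errors(eZ, eT, n_perm = 200, seed = 3)
  expect_equal(pm2$p_value, 1 / 201)
  expect_gt(pm2$p_value, 0)
  expect_error(permutation_test_total_errors(eA, make_error_table(0L)),
               "identical")
})

test_that("threshold sweep retains monotonically and matches the hand count", {
  e <- make_error_table(c(2L, 1L, 0L, 0L), posterior = c(0.4, 0.6, 0.8, 1.0))
  sw <- threshold_sweep(e, grid = c(0, 0.5, 0.99, 1))
  expect_equal(sw$retained_prop[1], 1)
  expect_equal(sw$error_rate[sw$threshold == 0.5], 1 / 6)
  expect_equal(sw$retained_prop[sw$threshold == 0.5], 3 / 4)
  expect_true(all(diff(sw$retained_prop) <= 0))
  # nothing retained above the top posterior
  sw2 <- threshold_sweep(e, grid = c(0, 1.01))
  expect_true(is.na(sw2$error_rate[2]))
})

test_that("sweep permutation test is exchangeable-null exact in the identity case", {
  eA <- make_error_table(c(0L, 1L, 2L, 0L), posterior = c(0.9, 0.6, 0.3, 0.8))
  pmI <- permutation_test_sweep(eA, eA, grid = c(0, 0.5), n_perm = 99, seed = 1)
  expect_equal(pmI$observed, 0)
  expect_equal(pmI$p_value, 1)
  # dominance: B worse at every threshold -> positive statistic
  eB <- make_error_table(c(2L, 2L, 2L, 1L), posterior = c(0.9, 0.6, 0.3, 0.8))
  pmD <- permutation_test_sweep(eA, eB, grid = c(0, 0.25, 0.5), n_perm = 99,
                                seed = 1)
  expect_gt(pmD$observed, 0)
})

test_that("rank-formula AUC matches hand computation, extremes, and trapezoids", {
  # perfect separation
  ePerf <- make_error_table(c(0L, 0L, 1L, 2L),
                            posterior = c(0.9, 0.8, 0.3, 0.2))
  expect_equal(roc_auc(ePerf)$auc, 1)
  # worked 4-call example: two correct (0.9, 0.8), two errors (0.7, 0.95)
  eMix <- make_error_table(c(0L, 0L, 1L, 1L),
                           posterior = c(0.9, 0.8, 0.7, 0.95))
  expect_equal(roc_auc(eMix)$auc, 0.5)
  # rank formula equals trapezoidal area, with ties present
  set.seed(9)
  eTie <- make_error_table(sample(c(0L, 1L, 2L), 300, TRUE),
                           posterior = round(runif(300), 2),
                           sample = paste0("S", 1:300))
  r <- roc_auc(eTie)
  expect_equal(r$auc, roc_trapezoid_area(r$curve), tolerance = 1e-12)
  # agreement with an independent implementation
  if (requireNamespace("pROC", quietly = TRUE)) {
    ref <- pROC::auc(pROC::roc(response = eTie$errors == 0,
                               predictor = eTie$posterior,
                               direction = "<", quiet = TRUE))
    expect_equal(r$auc, as.numeric(ref), tolerance = 1e-12)
  }
  # null scores: AUC near 1/2
  set.seed(10)
  eNull <- make_error_table(rbinom(2000, 1, 0.3),
                            posterior = runif(2000),
                            sample = paste0("S", 1:2000))
  expect_lt(abs(roc_auc(eNull)$auc - 0.5), 0.05)
  expect_error(roc_auc(make_error_table(c(0L, 0L))), "undefined")
})

test_that("bestPP selection reproduces a dominating panel and the identity case", {
  truth <- hla_typing(data.frame(
    sample = paste0("S", 1:20), locus = "A",
    allele1 = "A*01:01", allele2 = "A*02:01"))
  good <- toy_calls(rep("A*01:01", 20), rep("A*02:01", 20),
                    sample = paste0("S", 1:20), posterior = 0.95)
  bad <- toy_calls(rep("A*01:01", 20), rep("A*01:01", 20),
                   sample = paste0("S", 1:20), posterior = 0.5)
  same <- bestpp_reference_selection(good, good, truth, k = 5, seed = 1)
  expect_equal(same$per_locus$errors_bestpp, same$per_locus$errors_A)
  dom <- bestpp_reference_selection(good, bad, truth, k = 5, seed = 1)
  expect_equal(dom$per_locus$errors_bestpp, dom$per_locus$errors_A)
  expect_true(all(dom$selections == "A"))
})

test_that("error attribution to enriched-haplotype carriers covers the extremes", {
  e <- make_error_table(c(2L, 1L, 0L, 0L), sample = paste0("S", 1:4))
  th <- data.frame(sample = paste0("S", 1:4), locus = "A",
                   hap1 = c("H1", "H2", "H3", "H4"),
                   hap2 = c("E1", "H1", "H2", "H3"))
  none <- attribute_errors_to_haplotypes(e, th, enriched_ids = character(0))
  expect_equal(none$carrier_error_share, 0)
  all_in <- attribute_errors_to_haplotypes(e, th, enriched_ids = c("E1", "H2"))
  expect_equal(all_in$carrier_error_share, 1)
  expect_equal(all_in$carrier_fraction, 0.75)
  expect_equal(all_in$n_samples_with_error, 2)
  expect_equal(all_in$max_errors_per_sample, 2)
})
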