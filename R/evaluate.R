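#' Count allele-level imputation errors against truth typings
#'
#' Per call, the error is `2 -` the size of the maximum multiset matching
#' between the imputed unordered pair and the true unordered pair (so a
#' heterozygous call against a homozygous truth scores 1, not 2). Flagged
#' calls (no usable classifier) score 2 errors and are tallied separately
#' in the `n_flagged` attribute.
#'
#' @param truth An [hla_typing()] table.
#' @param calls Calls data.frame from [impute_cohort()].
#' @param panel Panel label stored on the table.
#' @return data.frame of class `error_table`: `sample`, `locus`, `errors`
#'   (0/1/2), `posterior`, `panel`.
#' @export
count_errors <- function(truth, calls, panel = "panel") {
  key_truth <- paste(truth$sample, truth$locus, sep = "\r")
  key_call <- paste(calls$sample, calls$locus, sep = "\r")
  miss <- !(key_call %in% key_truth)
  if (any(miss))
    stop("calls without truth typing: ",
         paste(utils::head(gsub("\r", "/", key_call[miss]), 5), collapse = ", "))
  tr <- truth[match(key_call, key_truth), ]
  flagged <- if (!is.null(calls$flagged)) calls$flagged else
    is.na(calls$allele1)
  errors <- integer(nrow(calls))
  ok <- !flagged & !is.na(calls$allele1)
  errors[ok] <- 2L - pair_overlap(tr$allele1[ok], tr$allele2[ok],
                                  calls$allele1[ok], calls$allele2[ok])
  errors[!ok] <- 2L
  out <- data.frame(sample = calls$sample, locus = calls$locus,
                    errors = errors, posterior = calls$posterior,
                    panel = panel, stringsAsFactors = FALSE)
  class(out) <- c("error_table", "data.frame")
  attr(out, "n_flagged") <- sum(!ok)
  out
}

#' Bootstrap distribution of per-locus total errors
#'
#' The resampling unit is the sample — all its loci move together, since
#' errors at different loci of one individual are dependent.
#'
#' @param e An [count_errors()] table.
#' @param n_boot Number of bootstrap replicates.
#' @param seed Integer seed.
#' @return List with `replicates` (n_boot x loci matrix of total errors)
#'   and `summary` (per locus: point estimate, bootstrap median, q25, q75).
#' @export
bootstrap_error_distribution <- function(e, n_boot = 100L, seed = 1L) {
  samples <- unique(e$sample)
  loci <- unique(e$locus)
  # samples x loci matrix of per-(sample, locus) errors
  em <- matrix(0L, length(samples), length(loci),
               dimnames = list(samples, loci))
  em[cbind(match(e$sample, samples), match(e$locus, loci))] <- e$errors
  reps <- with_seed(seed, {
    out <- matrix(0, n_boot, length(loci), dimnames = list(NULL, loci))
    for (b in seq_len(n_boot)) {
      idx <- sample.int(length(samples), replace = TRUE)
      out[b, ] <- colSums(em[idx, , drop = FALSE])
    }
    out
  })
  summ <- data.frame(locus = loci,
                     total_errors = colSums(em),
                     boot_median = apply(reps, 2, stats::median),
                     boot_q25 = apply(reps, 2, stats::quantile, 0.25),
                     boot_q75 = apply(reps, 2, stats::quantile, 0.75),
                     stringsAsFactors = FALSE)
  rownames(summ) <- NULL
  list(replicates = reps, summary = summ)
}

# Align two error tables on identical (sample, locus) keys; returns them
# sorted identically, plus the sample factor for per-sample aggregation.
align_error_tables <- function(eA, eB) {
  kA <- paste(eA$sample, eA$locus, sep = "\r")
  kB <- paste(eB$sample, eB$locus, sep = "\r")
  if (!setequal(kA, kB) || length(kA) != length(kB))
    stop("error tables must cover identical (sample, locus) sets")
  eA <- eA[order(kA), ]
  eB <- eB[order(kB), ]
  list(eA = eA, eB = eB)
}

#' Paired permutation test for the difference in total errors
#'
#' Both panels impute the same samples, so the design is paired: the null
#' is generated by independently swapping the panel labels of each sample's
#' error vector (all loci together) with probability 1/2. The statistic is
#' `sum(errors B) - sum(errors A)`; the two-sided p-value uses the +1
#' convention and can never be 0.
#'
#' @param eA,eB [count_errors()] tables over identical (sample, locus) sets.
#' @param n_perm Number of permutation replicates.
#' @param seed Integer seed.
#' @return List of class `permutation_result`: `observed`, `replicates`,
#'   `p_value`.
#' @export
permutation_test_total_errors <- function(eA, eB, n_perm = 1000L, seed = 1L) {
  al <- align_error_tables(eA, eB)
  d <- tapply(al$eB$errors - al$eA$errors, al$eA$sample, sum)
  d <- as.numeric(d)
  obs <- sum(d)
  reps <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      sgn <- ifelse(stats::runif(length(d)) < 0.5, -1, 1)
      sum(sgn * d)
    }, numeric(1))
  })
  p <- (1 + sum(abs(reps) >= abs(obs))) / (n_perm + 1)
  structure(list(observed = obs, replicates = reps, p_value = p),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat("permutation test: observed =", x$observed,
      ", p =", format(x$p_value, digits = 4),
      "(", length(x$replicates), "replicates )\n")
  invisible(x)
}

#' Error rate and retention across posterior-probability thresholds
#'
#' At each threshold `t`, calls with posterior `>= t` are retained; the
#' error rate is erroneous alleles over `2 x` retained calls and the
#' retained proportion is retained calls over all calls (non-increasing in
#' `t`).
#'
#' @param e An [count_errors()] table.
#' @param grid Ascending thresholds in `[0, 1]`.
#' @return data.frame of class `sweep_result`: `threshold`, `error_rate`
#'   (`NA` where nothing is retained), `retained_prop`.
#' @export
threshold_sweep <- function(e, grid = seq(0, 0.95, by = 0.05)) {
  n <- nrow(e)
  out <- data.frame(threshold = grid,
                    error_rate = NA_real_,
                    retained_prop = NA_real_)
  for (i in seq_along(grid)) {
    keep <- e$posterior >= grid[i]
    nk <- sum(keep)
    out$retained_prop[i] <- nk / n
    out$error_rate[i] <- if (nk > 0) sum(e$errors[keep]) / (2 * nk) else NA_real_
  }
  class(out) <- c("sweep_result", "data.frame")
  out
}

#' Paired permutation test on the threshold-sweep error-rate gap
#'
#' The statistic is the sum over the threshold grid of
#' `errorRate_B(t) - errorRate_A(t)`; the null swaps each sample's rows
#' between the two panels with probability 1/2, exactly as in
#' [permutation_test_total_errors()].
#'
#' @param eA,eB [count_errors()] tables over identical (sample, locus) sets.
#' @param grid Ascending thresholds.
#' @param n_perm Number of permutation replicates.
#' @param seed Integer seed.
#' @return A `permutation_result`.
#' @export
permutation_test_sweep <- function(eA, eB, grid = seq(0, 0.95, by = 0.05),
                                   n_perm = 1000L, seed = 1L) {
  al <- align_error_tables(eA, eB)
  samples <- unique(al$eA$sample)
  si <- match(al$eA$sample, samples)
  n_s <- length(samples)
  n_t <- length(grid)
  # per sample x threshold: retained-call and error totals for each panel
  agg <- function(e) {
    err <- matrix(0, n_s, n_t)
    cnt <- matrix(0, n_s, n_t)
    for (i in seq_len(n_t)) {
      keep <- e$posterior >= grid[i]
      err[, i] <- as.numeric(rowsum(e$errors * keep, si, reorder = TRUE))
      cnt[, i] <- as.numeric(rowsum(as.numeric(keep), si, reorder = TRUE))
    }
    list(err = err, cnt = cnt)
  }
  A <- agg(al$eA)
  B <- agg(al$eB)
  stat_for <- function(swap) {
    errA <- crossprod(A$err, 1 - swap) + crossprod(B$err, swap)
    cntA <- crossprod(A$cnt, 1 - swap) + crossprod(B$cnt, swap)
    errB <- crossprod(B$err, 1 - swap) + crossprod(A$err, swap)
    cntB <- crossprod(B$cnt, 1 - swap) + crossprod(A$cnt, swap)
    rA <- ifelse(cntA > 0, errA / (2 * cntA), NA_real_)
    rB <- ifelse(cntB > 0, errB / (2 * cntB), NA_real_)
    sum(rB - rA, na.rm = TRUE)
  }
  obs <- stat_for(rep(0, n_s))
  reps <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      stat_for(as.numeric(stats::runif(n_s) < 0.5))
    }, numeric(1))
  })
  p <- (1 + sum(abs(reps) >= abs(obs))) / (n_perm + 1)
  structure(list(observed = obs, replicates = reps, p_value = p),
            class = "permutation_result")
}

#' ROC/AUC of the posterior probability as a correctness score
#'
#' Calls with one or two errors form a single "error" category analysed
#' against zero-error calls; the posterior probability is the score (higher
#' predicts a correct call). The AUC is computed by the rank (Mann-Whitney)
#' formula with mid-rank tie correction, which equals the trapezoidal area
#' under the empirical ROC curve.
#'
#' @param e An [count_errors()] table containing both outcome classes.
#' @return List of class `roc_result`: `auc`, `curve` (data.frame
#'   `threshold`, `fpr`, `tpr`), `n_correct`, `n_error`.
#' @export
roc_auc <- function(e) {
  correct <- e$errors == 0
  n1 <- sum(correct)
  n0 <- sum(!correct)
  if (n1 == 0 || n0 == 0)
    stop("AUC undefined: all calls are in one outcome category")
  r <- rank(e$posterior)
  auc <- (sum(r[correct]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  thr <- sort(unique(e$posterior), decreasing = TRUE)
  tpr <- vapply(thr, function(t) mean(e$posterior[correct] >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(e$posterior[!correct] >= t), numeric(1))
  curve <- data.frame(threshold = c(Inf, thr), fpr = c(0, fpr),
                      tpr = c(0, tpr))
  structure(list(auc = auc, curve = curve, n_correct = n1, n_error = n0),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat("ROC: AUC =", format(x$auc, digits = 4), "(", x$n_correct,
      "correct vs", x$n_error, "erroneous calls )\n")
  invisible(x)
}

#' Trapezoidal area under a ROC curve
#'
#' @param curve data.frame with `fpr`, `tpr` (as in [roc_auc()]).
#' @return The trapezoidal area.
#' @export
roc_trapezoid_area <- function(curve) {
  o <- order(curve$fpr, curve$tpr)
  fpr <- c(curve$fpr[o], 1)
  tpr <- c(curve$tpr[o], 1)
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

#' Cross-validated selection of the best reference by posterior probability
#'
#' Samples are split into `k` folds. Per locus and fold, the panel with the
#' higher mean posterior over the other `k - 1` folds is selected and its
#' calls are scored on the held-out fold; errors accumulate over folds.
#'
#' @param callsA,callsB Calls from two panels over the same samples/loci.
#' @param truth An [hla_typing()] table.
#' @param k Number of folds.
#' @param seed Integer seed for the fold assignment.
#' @return List with `per_locus` (data.frame `locus`, `errors_bestpp`,
#'   `errors_A`, `errors_B`) and `selections` (locus x fold panel choices).
#' @export
bestpp_reference_selection <- function(callsA, callsB, truth, k = 10L,
                                       seed = 1L) {
  samples <- sort(unique(callsA$sample))
  if (!setequal(samples, unique(callsB$sample)))
    stop("panels must cover the same samples")
  if (k > length(samples)) stop("k exceeds number of samples")
  fold <- with_seed(seed, sample(rep(seq_len(k), length.out = length(samples))))
  names(fold) <- samples
  eA <- count_errors(truth, callsA, panel = "A")
  eB <- count_errors(truth, callsB, panel = "B")
  loci <- unique(callsA$locus)
  sel <- matrix(NA_character_, length(loci), k,
                dimnames = list(loci, paste0("fold", seq_len(k))))
  err_best <- stats::setNames(numeric(length(loci)), loci)
  for (locus in loci) {
    cA <- callsA[callsA$locus == locus, ]
    cB <- callsB[callsB$locus == locus, ]
    xA <- eA[eA$locus == locus, ]
    xB <- eB[eB$locus == locus, ]
    for (f in seq_len(k)) {
      train_s <- samples[fold != f]
      test_s <- samples[fold == f]
      mA <- mean(cA$posterior[cA$sample %in% train_s])
      mB <- mean(cB$posterior[cB$sample %in% train_s])
      pick <- if (mA >= mB) "A" else "B"
      sel[locus, f] <- pick
      ex <- if (pick == "A") xA else xB
      err_best[locus] <- err_best[locus] +
        sum(ex$errors[ex$sample %in% test_s])
    }
  }
  per_locus <- data.frame(
    locus = loci,
    errors_bestpp = as.numeric(err_best),
    errors_A = as.numeric(tapply(eA$errors, eA$locus, sum)[loci]),
    errors_B = as.numeric(tapply(eB$errors, eB$locus, sum)[loci]),
    stringsAsFactors = FALSE)
  list(per_locus = per_locus, selections = sel)
}

#' Attribute imputation errors to enriched-haplotype carriers
#'
#' A sample is a carrier if any of its true haplotypes (at any locus) is in
#' `enriched_ids`. Reports the share of all allele-level errors that fall
#' in carriers, the carrier fraction of the cohort, the number of samples
#' with at least one error, the maximum per-sample error count, and the
#' per-sample error histogram.
#'
#' @param e An [count_errors()] table.
#' @param truth_haplotypes data.frame `sample`, `locus`, `hap1`, `hap2`
#'   (from [sample_cohort()]).
#' @param enriched_ids Haplotype IDs counted as enriched (see
#'   [enriched_haplotype_ids()]).
#' @return List: `carrier_error_share`, `carrier_fraction`,
#'   `n_samples_with_error`, `max_errors_per_sample`, `per_sample`
#'   (data.frame `sample`, `errors`, `carrier`).
#' @export
attribute_errors_to_haplotypes <- function(e, truth_haplotypes, enriched_ids) {
  carriers <- unique(truth_haplotypes$sample[
    truth_haplotypes$hap1 %in% enriched_ids |
      truth_haplotypes$hap2 %in% enriched_ids])
  per_sample <- stats::aggregate(errors ~ sample, data = as.data.frame(e), sum)
  per_sample$carrier <- per_sample$sample %in% carriers
  total <- sum(per_sample$errors)
  share <- if (total > 0) sum(per_sample$errors[per_sample$carrier]) / total else 0
  list(carrier_error_share = share,
       carrier_fraction = mean(unique(e$sample) %in% carriers),
       n_samples_with_error = sum(per_sample$errors > 0),
       max_errors_per_sample = max(per_sample$errors),
       per_sample = per_sample)
}
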