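#' Allele dosage matrix from imputation calls
#'
#' `mode = "best_guess"`: dosage is the count of the allele in the
#' best-guess pair (0/1/2). `mode = "expected"`: dosage is the posterior
#' expectation of that count, summed over the full pair distribution (the
#' per-locus expected dosages of all alleles then sum to 2 per sample).
#' Calls below `pp_cutoff` (and flagged calls) yield missing dosage.
#'
#' @param calls Calls data.frame.
#' @param alleles Character vector of alleles to extract.
#' @param mode `"best_guess"` or `"expected"`.
#' @param pp_cutoff Posterior cutoff below which dosage is `NA`.
#' @param posteriors For `mode = "expected"`: the `posteriors` element
#'   returned by [impute_cohort()] (per-locus full pair distributions).
#' @return Numeric matrix samples x alleles.
#' @export
dosage_matrix <- function(calls, alleles, mode = c("best_guess", "expected"),
                          pp_cutoff = 0, posteriors = NULL) {
  mode <- match.arg(mode)
  samples <- unique(calls$sample)
  out <- matrix(NA_real_, length(samples), length(alleles),
                dimnames = list(samples, alleles))
  locus_of <- sub("\\*.*$", "", alleles)
  if (mode == "best_guess") {
    for (i in seq_along(alleles)) {
      cl <- calls[calls$locus == locus_of[i], ]
      d <- (cl$allele1 == alleles[i]) + (cl$allele2 == alleles[i])
      d[cl$posterior < pp_cutoff | cl$flagged] <- NA_real_
      out[match(cl$sample, samples), i] <- d
    }
    return(out)
  }
  if (is.null(posteriors))
    stop("mode = 'expected' needs the full posterior tables")
  for (i in seq_along(alleles)) {
    locus <- locus_of[i]
    po <- posteriors[[locus]]
    if (is.null(po)) next
    cnt <- (po$pairs$allele1 == alleles[i]) + (po$pairs$allele2 == alleles[i])
    d <- as.numeric(po$posterior %*% cnt)
    names(d) <- rownames(po$posterior)
    cl <- calls[calls$locus == locus, ]
    d <- d[cl$sample]
    d[cl$posterior < pp_cutoff | cl$flagged] <- NA_real_
    out[match(cl$sample, samples), i] <- d
  }
  out
}

#' Logistic-regression association of one allele dosage with disease
#'
#' Maximum-likelihood logistic regression of case-control status on allele
#' dosage plus age, sex, BMI and the first `n_pcs` principal components;
#' Wald test and 95% CI for the dosage coefficient. Samples with missing
#' dosage are dropped. Degenerate fits (no dosage variation, perfect
#' separation, non-convergence) are returned flagged with a missing
#' p-value, never as an error.
#'
#' @param dosage Named numeric vector (sample -> dosage, `NA` = missing).
#' @param phenotype A [simulate_phenotypes()]-style data.frame (`sample`,
#'   `status`, `age`, `sex`, `bmi`, `pc1..`).
#' @param n_pcs Number of PC covariates to include.
#' @return data.frame of class `association_result` with one row: `logor`,
#'   `se`, `ci_lo`, `ci_hi`, `p_value`, `n_cases`, `n_controls`, `flagged`.
#' @export
fit_allele_association <- function(dosage, phenotype, n_pcs = 10L) {
  ph <- as.data.frame(phenotype)
  d <- dosage[match(ph$sample, names(dosage))]
  keep <- !is.na(d)
  ph <- ph[keep, , drop = FALSE]
  d <- d[keep]
  flag <- function(reason) {
    structure(data.frame(logor = NA_real_, se = NA_real_, ci_lo = NA_real_,
                         ci_hi = NA_real_, p_value = NA_real_,
                         n_cases = sum(ph$status == 1),
                         n_controls = sum(ph$status == 0),
                         flagged = TRUE, reason = reason,
                         stringsAsFactors = FALSE),
              class = c("association_result", "data.frame"))
  }
  if (nrow(ph) == 0 || length(unique(ph$status)) < 2)
    return(flag("need at least one case and one control"))
  if (length(unique(d)) < 2) return(flag("no dosage variation"))
  pcs <- paste0("pc", seq_len(n_pcs))
  pcs <- pcs[pcs %in% names(ph)]
  df <- cbind(ph[, c("status", "age", "sex", "bmi", pcs)], dosage = d)
  fit <- tryCatch(
    suppressWarnings(stats::glm(status ~ ., data = df,
                                family = stats::binomial())),
    error = function(e) NULL)
  if (is.null(fit) || !fit$converged) return(flag("non-convergence"))
  co <- summary(fit)$coefficients
  if (!("dosage" %in% rownames(co))) return(flag("dosage dropped from fit"))
  est <- co["dosage", "Estimate"]
  se <- co["dosage", "Std. Error"]
  if (!is.finite(se) || se > 10) return(flag("separation"))
  structure(data.frame(logor = est, se = se,
                       ci_lo = est - 1.96 * se, ci_hi = est + 1.96 * se,
                       p_value = co["dosage", "Pr(>|z|)"],
                       n_cases = sum(df$status == 1),
                       n_controls = sum(df$status == 0),
                       flagged = FALSE, reason = NA_character_,
                       stringsAsFactors = FALSE),
            class = c("association_result", "data.frame"))
}

#' Scan all common alleles for disease association
#'
#' Tests every allele with frequency at least `freq_floor` in the calls
#' against every phenotype table, flagging associations with
#' `p < cfg$alpha_assoc`. Results are sorted by p-value within disease.
#'
#' @param calls Calls data.frame.
#' @param phenotypes Named list of phenotype tables, one per disease.
#' @param cfg A [run_config()].
#' @param mode Dosage mode, see [dosage_matrix()].
#' @param pp_cutoff Posterior cutoff applied to dosages.
#' @param freq_floor Minimum allele frequency tested.
#' @param posteriors Full posterior tables (for `mode = "expected"`).
#' @return data.frame: `disease`, `allele`, association columns,
#'   `significant`.
#' @export
association_scan <- function(calls, phenotypes, cfg = run_config(),
                             mode = "best_guess", pp_cutoff = 0,
                             freq_floor = 0.005, posteriors = NULL) {
  ft <- allele_frequencies(calls, pp_cutoff = pp_cutoff)
  test_alleles <- ft$allele[!is.na(ft$allele) & ft$freq >= freq_floor]
  dos <- dosage_matrix(calls, test_alleles, mode = mode,
                       pp_cutoff = pp_cutoff, posteriors = posteriors)
  rows <- list()
  for (disease in names(phenotypes)) {
    for (al in test_alleles) {
      r <- fit_allele_association(dos[, al], phenotypes[[disease]],
                                  n_pcs = cfg$n_pcs)
      r$disease <- disease
      r$allele <- al
      rows[[paste(disease, al)]] <- r
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$significant <- !out$flagged & !is.na(out$p_value) &
    out$p_value < cfg$alpha_assoc
  out <- out[order(match(out$disease, names(phenotypes)), out$p_value), ]
  out[, c("disease", "allele", "logor", "se", "ci_lo", "ci_hi", "p_value",
          "n_cases", "n_controls", "flagged", "reason", "significant")]
}

#' Sensitivity of one association to the posterior cutoff
#'
#' Refits [fit_allele_association()] for one allele at each cutoff in
#' `grid`, reporting sample counts so attrition is visible. Cutoff 0
#' reproduces the unfiltered fit exactly.
#'
#' @param calls Calls data.frame.
#' @param phenotype One phenotype table.
#' @param allele Allele name.
#' @param grid Ascending posterior cutoffs.
#' @param mode Dosage mode.
#' @param n_pcs Number of PC covariates.
#' @param posteriors Full posterior tables (for `mode = "expected"`).
#' @return data.frame with one row per cutoff.
#' @export
pp_cutoff_effect_sweep <- function(calls, phenotype, allele,
                                   grid = c(0, 0.5, 0.9),
                                   mode = "best_guess", n_pcs = 10L,
                                   posteriors = NULL) {
  rows <- lapply(grid, function(cutoff) {
    dos <- dosage_matrix(calls, allele, mode = mode, pp_cutoff = cutoff,
                         posteriors = posteriors)
    r <- fit_allele_association(dos[, 1], phenotype, n_pcs = n_pcs)
    r$pp_cutoff <- cutoff
    r$n_used <- r$n_cases + r$n_controls
    r
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
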