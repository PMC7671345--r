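#' EM estimation of extended-haplotype frequencies
#'
#' Estimates frequencies of extended haplotypes (SNP allele pattern over a
#' subset of sites, plus the HLA allele carried) from unphased genotypes
#' with known unordered HLA pairs. The E-step distributes each sample over
#' all ordered (haplotype, haplotype) pairs consistent with its genotype
#' and HLA pair; missing SNP sites are marginalised by summing over both
#' alleles. Iteration stops when the largest frequency change drops below
#' `tol` or after `max_iter` iterations; frequencies below `prune` are then
#' removed and the rest renormalised.
#'
#' @param geno N x k matrix of dosages (0/1/2/NA) over the SNP subset,
#'   k <= 25.
#' @param hla N x 2 matrix (or data.frame) of HLA allele names per sample,
#'   unordered (homozygotes repeat the allele).
#' @param tol Convergence tolerance on the max frequency change.
#' @param max_iter Iteration cap.
#' @param prune Frequency below which haplotypes are dropped at the end.
#' @return List with `table` (data.frame `pattern` — a string of 0/1 over
#'   the subset sites — `hla`, `freq`), `loglik` (observed-data
#'   log-likelihood at the solution), `n_iter`, and `n_dropped` (samples
#'   whose phase enumeration exceeded the internal cap and were excluded).
#' @export
em_haplotype_frequencies <- function(geno, hla, tol = 1e-8, max_iter = 500L,
                                     prune = 1e-9) {
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  if (ncol(geno) > 25) stop("SNP subset too large for pattern enumeration (> 25)")
  hla <- as.matrix(hla)
  stopifnot(nrow(hla) == nrow(geno), ncol(hla) == 2)
  alleles <- sort(unique(as.character(hla)))
  idx <- matrix(match(as.character(hla), alleles) - 1L, ncol = 2)
  fit <- .cpp_em_fit(geno, idx, tol, as.integer(max_iter), prune, 2^20)
  list(table = data.frame(pattern = pattern_to_string(fit$pattern, ncol(geno)),
                          hla = alleles[fit$hla + 1L],
                          freq = fit$freq, stringsAsFactors = FALSE),
       loglik = fit$loglik, n_iter = fit$n_iter,
       n_dropped = sum(fit$dropped))
}

pattern_to_string <- function(p, k) {
  if (length(p) == 0) return(character(0))
  bits <- vapply(seq_len(k), function(j) bitwAnd(p, bitwShiftL(1L, j - 1L)) > 0,
                 logical(length(p)))
  bits <- matrix(bits, nrow = length(p))
  apply(bits, 1, function(b) paste(as.integer(b), collapse = ""))
}

pattern_to_int <- function(s) {
  vapply(strsplit(s, ""), function(b)
    sum(as.integer(as.integer(b) * 2^(seq_along(b) - 1))), numeric(1))
}

#' Observed-data log-likelihood of a haplotype frequency table
#'
#' Computes, for each sample, the probability of its genotype and HLA pair
#' under the table (summing frequency products over all consistent ordered
#' haplotype pairs) and returns the sum of log probabilities. Useful for
#' comparing fits against independent optimisers.
#'
#' @param table data.frame `pattern`, `hla`, `freq` as returned by
#'   [em_haplotype_frequencies()].
#' @param geno N x k dosage matrix over the same SNP subset.
#' @param hla N x 2 HLA allele names.
#' @return The log-likelihood (samples with zero support contribute `-Inf`).
#' @export
haplotype_loglik <- function(table, geno, hla) {
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  hla <- as.matrix(hla)
  alleles <- sort(unique(c(as.character(hla), table$hla)))
  n_al <- length(alleles)
  post <- .cpp_predict(as.integer(pattern_to_int(table$pattern)),
                       match(table$hla, alleles) - 1L,
                       table$freq, n_al, geno, 2^20)
  cols <- pair_col(match(hla[, 1], alleles) - 1L,
                   match(hla[, 2], alleles) - 1L, n_al)
  sum(log(post[cbind(seq_len(nrow(geno)), cols)]))
}

# Unnormalised posterior over unordered allele pairs for one classifier.
# `alleles` is the locus-model allele set; table HLA labels must be in it.
classifier_posterior <- function(classifier, geno, alleles) {
  tab <- classifier$table
  .cpp_predict(as.integer(pattern_to_int(tab$pattern)),
               match(tab$hla, alleles) - 1L,
               tab$freq, length(alleles), geno, 2^20)
}

# Best-guess pair per row of a (possibly unnormalised) posterior matrix.
# Ties break to the lexicographically first pair (columns are ordered by
# sorted allele index). Rows with no support return NA.
best_pair <- function(post, alleles) {
  pt <- pair_index_table(length(alleles))
  top <- apply(post, 1, function(p) if (all(p == 0)) NA_integer_ else which.max(p))
  ok <- !is.na(top)
  a1 <- a2 <- rep(NA_character_, nrow(post))
  a1[ok] <- alleles[pt$a[top[ok]] + 1L]
  a2[ok] <- alleles[pt$b[top[ok]] + 1L]
  s <- rowSums(post)
  prob <- ifelse(ok & s > 0, post[cbind(seq_len(nrow(post)),
                                        ifelse(ok, top, 1L))] / s, 0)
  data.frame(allele1 = a1, allele2 = a2, posterior = prob,
             stringsAsFactors = FALSE)
}

# Multiset overlap of two unordered allele pairs, vectorised.
pair_overlap <- function(t1, t2, c1, c2) {
  m <- integer(length(t1))
  for (i in seq_along(t1)) {
    truth <- c(t1[i], t2[i])
    call <- c(c1[i], c2[i])
    ov <- 0L
    for (al in call) {
      j <- match(al, truth)
      if (!is.na(j)) {
        truth <- truth[-j]
        ov <- ov + 1L
      }
    }
    m[i] <- ov
  }
  m
}

#' Train a per-locus attribute-bagging imputation model
#'
#' Builds `cfg$n_classifiers` classifiers. Each classifier bootstrap-
#' resamples the training samples, draws a random SNP subset of size
#' `ceiling(sqrt(n_snps))` from the supplied SNP pool, then makes up to
#' `cfg$n_refine` greedy grow/swap moves, accepting a move only if it
#' strictly raises out-of-bag accuracy. The extended-haplotype table of
#' each classifier is fitted by [em_haplotype_frequencies()] on the in-bag
#' samples. Deterministic given `seed`.
#'
#' @param g A [genotype_matrix()] of the training cohort.
#' @param t An [hla_typing()] table covering the training samples at `locus`.
#' @param locus Locus name.
#' @param cfg A [run_config()].
#' @param seed Integer seed.
#' @param snps Optional SNP pool (column names of `g`) the classifiers draw
#'   from; defaults to all columns. Restricting the pool to the locus's
#'   flanking block is recommended, mirroring how imputation models use
#'   SNPs near the locus.
#' @param subset_size Initial SNP subset size per classifier; defaults to
#'   `ceiling(sqrt(length(pool)))`, capped at 25 by the pattern enumeration
#'   bound.
#' @return Object of class `locus_model`: `locus`, `classifiers` (each:
#'   `snps`, `table`, `oob_acc`), `alleles`, `n_train`, `snp_pool`.
#' @export
train_locus_model <- function(g, t, locus, cfg, seed = cfg$seed, snps = NULL,
                              subset_size = NULL) {
  stopifnot(inherits(g, "genotype_matrix"))
  tl <- t[t$locus == locus, , drop = FALSE]
  samples <- intersect(rownames(g$dosage), tl$sample)
  if (length(samples) < 2) stop("too few typed training samples at ", locus)
  tl <- tl[match(samples, tl$sample), ]
  alleles <- sort(unique(c(tl$allele1, tl$allele2)))
  if (length(alleles) < 2) stop("monomorphic locus: ", locus)
  pool <- snps %||% colnames(g$dosage)
  pool <- intersect(pool, colnames(g$dosage))
  if (length(pool) == 0) stop("empty SNP pool for ", locus)
  k0 <- min(subset_size %||% ceiling(sqrt(length(pool))), 25L, length(pool))
  geno <- g$dosage[samples, pool, drop = FALSE]
  hla_idx <- cbind(match(tl$allele1, alleles), match(tl$allele2, alleles)) - 1L
  n <- length(samples)

  em_tol <- cfg$em_tol %||% 1e-6
  em_max_iter <- cfg$em_max_iter %||% 200L
  fit_one <- function(subset, inbag) {
    fit <- .cpp_em_fit(geno[inbag, subset, drop = FALSE],
                       hla_idx[inbag, , drop = FALSE],
                       em_tol, as.integer(em_max_iter), 1e-9, 2^20)
    list(snps = subset,
         table = data.frame(pattern = pattern_to_string(fit$pattern,
                                                        length(subset)),
                            hla = alleles[fit$hla + 1L],
                            freq = fit$freq, stringsAsFactors = FALSE))
  }
  oob_accuracy <- function(cl, oob) {
    if (length(oob) == 0) return(0)
    post <- classifier_posterior(cl, geno[oob, cl$snps, drop = FALSE], alleles)
    bp <- best_pair(post, alleles)
    truth1 <- alleles[hla_idx[oob, 1] + 1L]
    truth2 <- alleles[hla_idx[oob, 2] + 1L]
    ov <- ifelse(is.na(bp$allele1), 0L,
                 pair_overlap(truth1, truth2, bp$allele1, bp$allele2))
    mean(ov / 2)
  }

  classifiers <- vector("list", cfg$n_classifiers)
  for (j in seq_len(cfg$n_classifiers)) {
    classifiers[[j]] <- with_seed(derive_seed(seed, j), {
      inbag <- sample.int(n, n, replace = TRUE)
      oob <- setdiff(seq_len(n), unique(inbag))
      subset <- sample(pool, k0)
      cl <- fit_one(subset, inbag)
      acc <- oob_accuracy(cl, oob)
      for (r in seq_len(cfg$n_refine)) {
        outside <- setdiff(pool, subset)
        if (length(outside) == 0) break
        grow <- stats::runif(1) < 0.5 && length(subset) < min(25L, length(pool))
        cand <- if (grow) c(subset, sample(outside, 1))
                else c(subset[-sample.int(length(subset), 1)],
                       sample(outside, 1))
        cl_cand <- fit_one(cand, inbag)
        acc_cand <- oob_accuracy(cl_cand, oob)
        if (acc_cand > acc) {
          subset <- cand
          cl <- cl_cand
          acc <- acc_cand
        }
      }
      cl$oob_acc <- acc
      cl
    })
  }
  model <- structure(list(locus = locus, classifiers = classifiers,
                          alleles = alleles, n_train = n, snp_pool = pool,
                          calibration = NULL),
                     class = "locus_model")
  if (isTRUE(cfg$calibrate_posteriors %||% TRUE))
    model$calibration <- fit_oob_calibration(model, geno, hla_idx, seed)
  model
}

# Out-of-bag ensemble calibration: for each training sample, average the
# posteriors of the classifiers that did NOT see it in-bag (the standard
# out-of-bag ensemble prediction), then fit an isotonic map from the raw
# best-guess posterior to the empirical probability of a fully correct
# call. Bagged posterior averages are systematically underconfident —
# classifiers whose bootstrap missed a rare haplotype pull mass off the
# truth while the informed majority still decides correctly — and the
# out-of-bag data measures exactly that bias.
fit_oob_calibration <- function(model, geno, hla_idx, seed) {
  n <- nrow(geno)
  n_al <- length(model$alleles)
  P <- n_al * (n_al + 1) / 2
  accum <- matrix(0, n, P)
  wsum <- numeric(n)
  weights <- vapply(model$classifiers, function(cl) cl$oob_acc, numeric(1))
  if (all(weights <= 0)) weights <- rep(1, length(weights))
  for (j in seq_along(model$classifiers)) {
    cl <- model$classifiers[[j]]
    oob <- with_seed(derive_seed(seed, j), {
      inbag <- sample.int(n, n, replace = TRUE)
      setdiff(seq_len(n), unique(inbag))
    })
    if (length(oob) == 0) next
    post <- classifier_posterior(cl, geno[oob, cl$snps, drop = FALSE],
                                 model$alleles)
    rs <- rowSums(post)
    ok <- rs > 0
    if (!any(ok)) next
    rows <- oob[ok]
    accum[rows, ] <- accum[rows, , drop = FALSE] +
      weights[j] * post[ok, , drop = FALSE] / rs[ok]
    wsum[rows] <- wsum[rows] + weights[j]
  }
  covered <- wsum > 0
  if (sum(covered) < 20) return(NULL)
  posterior <- accum[covered, , drop = FALSE] / wsum[covered]
  bp <- best_pair(posterior, model$alleles)
  truth1 <- model$alleles[hla_idx[covered, 1] + 1L]
  truth2 <- model$alleles[hla_idx[covered, 2] + 1L]
  correct <- as.numeric(pair_overlap(truth1, truth2,
                                     bp$allele1, bp$allele2) == 2L)
  o <- order(bp$posterior)
  iso <- stats::isoreg(bp$posterior[o], correct[o])
  knots <- !duplicated(iso$x, fromLast = TRUE)
  list(x = iso$x[knots], y = pmin(pmax(iso$yf[knots], 0), 1))
}

# Apply a stored isotonic calibration map to raw posterior values.
# Piecewise-linear interpolation between the isotonic knots; flat segments
# produce tied scores, which downstream rank statistics treat by mid-ranks.
apply_calibration <- function(calibration, p) {
  if (is.null(calibration) || length(calibration$x) < 2) return(p)
  stats::approx(calibration$x, calibration$y, xout = p, rule = 2,
                ties = "ordered")$y
}

#' @export
print.locus_model <- function(x, ...) {
  cat("locus_model ", x$locus, ": ", length(x$classifiers),
      " classifiers, ", length(x$alleles), " alleles, trained on ",
      x$n_train, " samples\n", sep = "")
  invisible(x)
}

#' Train models for every locus of a reference cohort
#'
#' @param g Training [genotype_matrix()].
#' @param t Training [hla_typing()].
#' @param cfg A [run_config()].
#' @param seed Integer seed.
#' @param snp_sets Optional named list locus -> SNP pool; e.g. the per-locus
#'   blocks of a `population_model` (`lapply(pop$loci, [["snp_ids"]])`).
#' @return Named list of [train_locus_model()] results, class `hla_model_set`.
#' @export
train_hla_models <- function(g, t, cfg, seed = cfg$seed, snp_sets = NULL) {
  loci <- intersect(cfg$loci, unique(t$locus))
  models <- lapply(seq_along(loci), function(i) {
    train_locus_model(g, t, loci[i], cfg, seed = derive_seed(seed, 1000 + i),
                      snps = snp_sets[[loci[i]]])
  })
  names(models) <- loci
  class(models) <- "hla_model_set"
  models
}

#' Impute HLA genotypes at one locus
#'
#' Per classifier, the posterior of each unordered HLA pair is proportional
#' to the summed frequency products of consistent extended-haplotype pairs
#' (heterozygous diplotypes counted twice via ordered pairs). Per-classifier
#' posteriors are normalised and averaged with weights proportional to
#' out-of-bag accuracy (equal weights if all accuracies are zero). A
#' classifier whose subset SNPs are all missing for a sample — or that has
#' no haplotype support for the sample's genotype — is skipped for that
#' sample. Samples with zero usable classifiers get a flagged call with a
#' missing pair and probability 0.
#'
#' If the model carries an out-of-bag calibration map (the training
#' default), the reported best-guess posterior is the calibrated
#' confidence; the full pair distribution in `posterior` stays on the raw
#' averaged scale so that expected dosages keep summing to 2.
#'
#' @param model A [train_locus_model()] result.
#' @param g Target [genotype_matrix()].
#' @return List with `calls` (data.frame `sample`, `locus`, `allele1`,
#'   `allele2`, `posterior`, `flagged`, `batch`), `posterior` (samples x
#'   pairs matrix, rows summing to 1 for unflagged samples), `pairs`
#'   (data.frame `allele1`, `allele2` describing the columns), and
#'   `alleles`.
#' @export
impute <- function(model, g) {
  stopifnot(inherits(model, "locus_model"), inherits(g, "genotype_matrix"))
  usable <- vapply(model$classifiers,
                   function(cl) any(cl$snps %in% colnames(g$dosage)),
                   logical(1))
  if (!any(usable)) stop("no classifier has any SNP present in target data")
  n <- nrow(g$dosage)
  n_al <- length(model$alleles)
  P <- n_al * (n_al + 1) / 2
  accum <- matrix(0, n, P)
  wsum <- numeric(n)
  weights <- vapply(model$classifiers, function(cl) cl$oob_acc, numeric(1))
  if (all(weights <= 0)) weights <- rep(1, length(weights))
  for (j in which(usable)) {
    cl <- model$classifiers[[j]]
    sub <- matrix(NA_integer_, n, length(cl$snps))
    have <- cl$snps %in% colnames(g$dosage)
    sub[, have] <- g$dosage[, cl$snps[have], drop = FALSE]
    post <- classifier_posterior(cl, sub, model$alleles)
    rs <- rowSums(post)
    ok <- rs > 0
    if (!any(ok)) next
    w <- weights[j]
    accum[ok, ] <- accum[ok, , drop = FALSE] +
      w * post[ok, , drop = FALSE] / rs[ok]
    wsum[ok] <- wsum[ok] + w
  }
  flagged <- wsum == 0
  posterior <- accum
  posterior[!flagged, ] <- posterior[!flagged, , drop = FALSE] / wsum[!flagged]
  bp <- best_pair(posterior, model$alleles)
  bp$posterior <- apply_calibration(model$calibration, bp$posterior)
  bp$posterior[flagged] <- 0
  calls <- data.frame(sample = rownames(g$dosage), locus = model$locus,
                      allele1 = bp$allele1, allele2 = bp$allele2,
                      posterior = bp$posterior, flagged = flagged,
                      batch = NA_integer_, stringsAsFactors = FALSE)
  pt <- pair_index_table(n_al)
  pairs <- data.frame(allele1 = model$alleles[pt$a + 1L],
                      allele2 = model$alleles[pt$b + 1L],
                      stringsAsFactors = FALSE)
  rownames(posterior) <- rownames(g$dosage)
  list(calls = calls, posterior = posterior, pairs = pairs,
       alleles = model$alleles)
}

#' Impute HLA genotypes at every modelled locus
#'
#' @param models An `hla_model_set`.
#' @param g Target [genotype_matrix()].
#' @return List with `calls` (row-bound across loci) and `posteriors`
#'   (named list of per-locus [impute()] results).
#' @export
impute_cohort <- function(models, g) {
  res <- lapply(models, impute, g = g)
  calls <- do.call(rbind, lapply(res, `[[`, "calls"))
  rownames(calls) <- NULL
  list(calls = calls, posteriors = res)
}

#' Impute a cohort in near-equal batches
#'
#' Orchestration device for large cohorts: samples are partitioned into
#' `n_batches` groups whose sizes differ by at most one (seeded random
#' assignment), each batch is imputed separately, and the concatenated
#' calls — identical to unbatched imputation — carry their batch label for
#' downstream per-batch frequency validation.
#'
#' @param models An `hla_model_set`.
#' @param g Target [genotype_matrix()].
#' @param n_batches Number of batches.
#' @param seed Integer seed for the partition.
#' @return List with `calls` (batch column filled) and `batches` (named
#'   integer vector sample -> batch).
#' @export
impute_in_batches <- function(models, g, n_batches, seed = 1L) {
  n <- nrow(g$dosage)
  if (n_batches > n) stop("n_batches exceeds number of samples")
  assignment <- with_seed(seed, {
    lab <- rep(seq_len(n_batches), length.out = n)
    sample(lab)
  })
  names(assignment) <- rownames(g$dosage)
  parts <- lapply(seq_len(n_batches), function(b) {
    idx <- which(assignment == b)
    gb <- genotype_matrix(g$dosage[idx, , drop = FALSE], g$snps)
    calls <- impute_cohort(models, gb)$calls
    calls$batch <- b
    calls
  })
  calls <- do.call(rbind, parts)
  # restore the unbatched ordering: locus blocks in model order, samples in
  # genotype-matrix order within each block
  calls <- calls[order(match(calls$locus, names(models)),
                       match(calls$sample, rownames(g$dosage))), ]
  rownames(calls) <- NULL
  list(calls = calls, batches = assignment)
}
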