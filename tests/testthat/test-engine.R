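test_that("EM reduces to direct counting when phase is unambiguous", {
  # 1 SNP: two homozygous diplotypes at equal counts
  geno <- matrix(c(2L, 2L, 0L, 0L), ncol = 1)
  hla <- cbind(c("A*01:01", "A*01:01", "A*02:01", "A*02:01"),
               c("A*01:01", "A*01:01", "A*02:01", "A*02:01"))
  fit <- em_haplotype_frequencies(geno, hla)
  tab <- fit$table[order(fit$table$pattern), ]
  expect_equal(tab$pattern, c("0", "1"))
  expect_equal(tab$hla, c("A*02:01", "A*01:01"))
  expect_equal(tab$freq, c(0.5, 0.5), tolerance = 1e-9)
  expect_equal(fit$n_dropped, 0)

  # fully homozygous samples over 3 SNPs: frequencies = sample proportions
  pats <- rbind(c(0L, 0L, 0L), c(1L, 1L, 0L), c(0L, 1L, 1L))
  reps <- c(3, 2, 1)
  geno2 <- 2L * pats[rep(1:3, reps), ]
  labs <- c("A*01:01", "A*02:01", "A*03:01")[rep(1:3, reps)]
  fit2 <- em_haplotype_frequencies(geno2, cbind(labs, labs))
  expect_equal(sort(fit2$table$freq, decreasing = TRUE), reps / sum(reps),
               tolerance = 1e-9)
  expect_error(em_haplotype_frequencies(matrix(0L, 2, 26),
                                        cbind(c("A*01:01", "A*01:01"),
                                              c("A*02:01", "A*02:01"))),
               "too large")
})

test_that("C++ EM agrees with a pure-R EM from the same uniform start", {
  set.seed(42)
  pool <- rbind(c(0L, 0L, 1L), c(1L, 1L, 0L), c(0L, 1L, 1L), c(1L, 0L, 0L))
  labs <- c("A*01:01", "A*02:01", "A*02:01", "A*03:01")
  freq <- c(0.4, 0.3, 0.2, 0.1)
  n <- 30
  i1 <- sample(4, n, TRUE, freq)
  i2 <- sample(4, n, TRUE, freq)
  geno <- pool[i1, ] + pool[i2, ]
  hla <- cbind(pmin(labs[i1], labs[i2]), pmax(labs[i1], labs[i2]))
  fit <- em_haplotype_frequencies(geno, hla, tol = 1e-10, max_iter = 2000)
  ref <- r_em(geno, hla, tol = 1e-10, max_iter = 2000)
  fv <- table_as_freq_vector(fit$table)
  common <- intersect(names(fv), names(ref$freq))
  expect_equal(fv[common], ref$freq[common], tolerance = 1e-6)
  expect_equal(fit$loglik, ref$loglik, tolerance = 1e-8)
  expect_equal(haplotype_loglik(fit$table, geno, hla), fit$loglik,
               tolerance = 1e-8)
})

test_that("a perfectly tagging SNP yields out-of-bag accuracy 1", {
  # dosage of the tag SNP equals the count of allele A*02:01
  set.seed(5)
  n <- 60
  a1 <- sample(c("A*01:01", "A*02:01"), n, TRUE)
  a2 <- sample(c("A*01:01", "A*02:01"), n, TRUE)
  dos <- matrix((a1 == "A*02:01") + (a2 == "A*02:01"), ncol = 1)
  storage.mode(dos) <- "integer"
  rownames(dos) <- paste0("S", 1:n)
  g <- genotype_matrix(dos, data.frame(id = "tag", chrom = "6", pos = 1L,
                                       ref = "A", alt = "G"))
  t <- hla_typing(data.frame(sample = paste0("S", 1:n), locus = "A",
                             allele1 = a1, allele2 = a2))
  rc <- run_config(n_classifiers = 3, n_refine = 0L, seed = 2)
  m <- train_locus_model(g, t, "A", rc, seed = 2)
  for (cl in m$classifiers) expect_equal(cl$oob_acc, 1)
})

test_that("training is deterministic and models carry the requested ensemble size", {
  sc <- small_sim_cfg()
  st <- simulate_study(sc, n_ref = 80, n_test = 20, seed = 12)
  rc <- run_config(n_classifiers = 4, seed = 12)
  sets <- lapply(st$pop_target$loci, `[[`, "snp_ids")
  m1 <- train_locus_model(st$ref_target$genotypes, st$ref_target$typing, "A",
                          rc, seed = 3, snps = sets$A)
  m2 <- train_locus_model(st$ref_target$genotypes, st$ref_target$typing, "A",
                          rc, seed = 3, snps = sets$A)
  expect_identical(m1, m2)
  expect_length(m1$classifiers, 4L)
  expect_true(all(vapply(m1$classifiers, function(cl)
    all(cl$table$hla %in% m1$alleles), logical(1))))
  for (cl in m1$classifiers)
    expect_equal(sum(cl$table$freq), 1, tolerance = 1e-9)
  # monomorphic locus errors
  tmono <- st$ref_target$typing
  tmono$allele1 <- "A*01:01"
  tmono$allele2 <- "A*01:01"
  expect_error(train_locus_model(st$ref_target$genotypes,
                                 hla_typing(as.data.frame(tmono)), "A", rc),
               "monomorphic")
})

test_that("single-classifier posterior equals the hand-computed pair ratio", {
  cl <- list(snps = c("s1", "s2"),
             table = data.frame(
               pattern = c("00", "11", "10", "01"),
               hla = c("A*01:01", "A*02:01", "A*02:01", "A*03:01"),
               freq = c(0.4, 0.3, 0.2, 0.1), stringsAsFactors = FALSE),
             oob_acc = 0.9)
  model <- structure(list(locus = "A", classifiers = list(cl),
                          alleles = c("A*01:01", "A*02:01", "A*03:01"),
                          n_train = 10L, snp_pool = c("s1", "s2")),
                     class = "locus_model")
  dos <- matrix(c(1L, 1L), 1, 2, dimnames = list("S1", NULL))
  g <- genotype_matrix(dos, data.frame(id = c("s1", "s2"), chrom = "6",
                                       pos = 1:2, ref = "A", alt = "G"))
  res <- impute(model, g)
  # consistent ordered pairs: (00,11)x2 -> 0.24 on {01:01,02:01};
  # (10,01)x2 -> 0.04 on {02:01,03:01}; total 0.28
  expect_equal(res$calls$allele1, "A*01:01")
  expect_equal(res$calls$allele2, "A*02:01")
  expect_equal(res$calls$posterior, 0.24 / 0.28, tolerance = 1e-12)
  i2 <- which(res$pairs$allele1 == "A*02:01" & res$pairs$allele2 == "A*03:01")
  expect_equal(unname(res$posterior[1, i2]), 0.04 / 0.28, tolerance = 1e-12)
  expect_equal(sum(res$posterior[1, ]), 1, tolerance = 1e-12)
})

test_that("posteriors normalise and flagged samples surface missing support", {
  sc <- small_sim_cfg()
  st <- simulate_study(sc, n_ref = 80, n_test = 25, seed = 13)
  rc <- run_config(n_classifiers = 4, seed = 13)
  m <- train_hla_models(st$ref_target$genotypes, st$ref_target$typing, rc,
                        snp_sets = lapply(st$pop_target$loci, `[[`, "snp_ids"))
  res <- impute(m$A, st$test$genotypes)
  expect_true(all(abs(rowSums(res$posterior[!res$calls$flagged, ]) - 1) < 1e-9))
  # a sample with all genotypes missing gets a flagged zero-probability call
  dos <- st$test$genotypes$dosage
  dos[1, ] <- NA_integer_
  g2 <- genotype_matrix(dos, st$test$genotypes$snps)
  res2 <- impute(m$A, g2)
  expect_true(res2$calls$flagged[1])
  expect_equal(res2$calls$posterior[1], 0)
  expect_true(is.na(res2$calls$allele1[1]))
  # no usable classifier at all is an error
  gnone <- genotype_matrix(matrix(0L, 2, 2,
                                  dimnames = list(c("a", "b"), NULL)),
                           data.frame(id = c("zz1", "zz2"), chrom = "6",
                                      pos = 1:2, ref = "A", alt = "G"))
  expect_error(impute(m$A, gnone), "no classifier")
})

test_that("with one classifier on homozygous training data, imputation is table lookup", {
  set.seed(8)
  n_pool <- 6
  k <- 5
  repeat {
    pool <- matrix(sample(0:1, n_pool * k, TRUE), n_pool, k)
    if (!anyDuplicated(apply(pool, 1, paste, collapse = ""))) break
  }
  labs <- sprintf("A*%02d:01", 1:n_pool)
  reps <- c(4, 3, 3, 2, 2, 1)
  idx <- rep(1:n_pool, reps)
  geno <- 2L * pool[idx, ]
  rownames(geno) <- paste0("S", seq_along(idx))
  storage.mode(geno) <- "integer"
  g <- genotype_matrix(geno, data.frame(id = paste0("s", 1:k), chrom = "6",
                                        pos = 1:k, ref = "A", alt = "G"))
  t <- hla_typing(data.frame(sample = rownames(geno), locus = "A",
                             allele1 = labs[idx], allele2 = labs[idx]))
  rc <- run_config(n_classifiers = 1, n_refine = 0L, seed = 4)
  m <- train_locus_model(g, t, "A", rc, seed = 4, subset_size = k)
  # every classifier haplotype is one of the pool rows (in subset SNP order)
  cl1 <- m$classifiers[[1]]
  ord <- match(cl1$snps, g$snps$id)
  expect_true(all(cl1$table$pattern %in%
                    apply(pool[, ord], 1, paste, collapse = "")))
  # targets homozygous for pool rows decode to that row's label, posterior 1
  tg <- genotype_matrix(2L * pool, g$snps)
  res <- impute(m, tg)
  expect_equal(res$calls$allele1, labs)
  expect_equal(res$calls$allele2, labs)
  expect_true(all(res$calls$posterior > 1 - 1e-9))
})

test_that("batched imputation is an orchestration device, not a statistical one", {
  sc <- small_sim_cfg()
  st <- simulate_study(sc, n_ref = 80, n_test = 30, seed = 14)
  rc <- run_config(n_classifiers = 3, seed = 14)
  m <- train_hla_models(st$ref_target$genotypes, st$ref_target$typing, rc,
                        snp_sets = lapply(st$pop_target$loci, `[[`, "snp_ids"))
  ref <- impute_cohort(m, st$test$genotypes)$calls
  one <- impute_in_batches(m, st$test$genotypes, 1, seed = 1)
  expect_equal(one$calls[names(one$calls) != "batch"],
               ref[names(ref) != "batch"])
  ten <- impute_in_batches(m, st$test$genotypes, 10, seed = 2)
  expect_equal(ten$calls[names(ten$calls) != "batch"],
               ref[names(ref) != "batch"])
  sizes <- table(ten$batches)
  expect_lte(max(sizes) - min(sizes), 1)
  expect_error(impute_in_batches(m, st$test$genotypes, 31, seed = 1),
               "exceeds")
})

test_that("enlarging classifier subsets to the full block does not hurt confidence", {
  sc <- small_sim_cfg(loci = "A", n_snps = 16L, genotype_noise = 0)
  diffs <- vapply(1:5, function(s) {
    pop <- simulate_population(sc, seed = 100 + s)
    ref <- sample_cohort(pop, 120, sc, seed = 200 + s)
    test <- sample_cohort(pop, 60, sc, seed = 300 + s)
    rc <- run_config(n_classifiers = 5, n_refine = 0L, seed = s)
    mean_pp <- function(subset_size) {
      m <- train_locus_model(ref$genotypes, ref$typing, "A", rc, seed = s,
                             subset_size = subset_size)
      res <- impute(m, test$genotypes)
      e <- count_errors(test$typing, res$calls)
      mean(res$calls$posterior[e$errors == 0])
    }
    mean_pp(16L) - mean_pp(NULL)
  }, numeric(1))
  expect_gte(mean(diffs), 0)
  expect_gte(sum(diffs >= -0.01), 4)
})
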