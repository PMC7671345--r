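# Shared fixtures: small simulation configs, toy tables, and a pure-R EM
# that serves as the independent oracle for the C++ engine.

small_sim_cfg <- function(...) {
  args <- list(loci = c("A", "B"), n_snps = 20L, n_alleles = 4L,
               n_shared_haplotypes = 10L, n_enriched_haplotypes = 3L,
               enriched_mass = 0.15)
  args[names(list(...))] <- list(...)
  do.call(simulation_config, args)
}

toy_truth <- function() {
  hla_typing(data.frame(
    sample = c("S1", "S1", "S2", "S2"),
    locus = c("A", "B", "A", "B"),
    allele1 = c("A*01:01", "B*07:02", "A*02:01", "B*08:01"),
    allele2 = c("A*02:01", "B*07:02", "A*02:01", "B*44:02")))
}

toy_calls <- function(allele1, allele2, sample = paste0("S", seq_along(allele1)),
                      locus = "A", posterior = 1, flagged = FALSE) {
  data.frame(sample = sample, locus = locus, allele1 = allele1,
             allele2 = allele2, posterior = posterior, flagged = flagged,
             batch = NA_integer_, stringsAsFactors = FALSE)
}

# Build an error_table directly from vectors (for evaluation unit tests).
make_error_table <- function(errors, posterior = rep(1, length(errors)),
                             sample = paste0("S", seq_along(errors)),
                             locus = "A", panel = "p") {
  out <- data.frame(sample = sample, locus = locus, errors = errors,
                    posterior = posterior, panel = panel,
                    stringsAsFactors = FALSE)
  class(out) <- c("error_table", "data.frame")
  out
}

# ---- pure-R EM oracle --------------------------------------------------
# Enumerate the ordered extended-haplotype pairs consistent with one
# sample's genotype (0/1/2/NA per site) and unordered HLA pair.
r_enumerate_pairs <- function(g, h1, h2) {
  grow <- function(pats, opts) {
    out <- list()
    for (p in pats) for (o in opts)
      out[[length(out) + 1]] <- list(c(p[[1]], o[1]), c(p[[2]], o[2]))
    out
  }
  pairs <- list(list(integer(0), integer(0)))
  for (gi in g) {
    opts <- if (is.na(gi)) list(c(0L, 0L), c(0L, 1L), c(1L, 0L), c(1L, 1L))
    else if (gi == 0) list(c(0L, 0L))
    else if (gi == 2) list(c(1L, 1L))
    else list(c(0L, 1L), c(1L, 0L))
    pairs <- grow(pairs, opts)
  }
  key <- function(pat, al) paste0(paste(pat, collapse = ""), "|", al)
  ord <- if (h1 == h2) list(c(h1, h2)) else list(c(h1, h2), c(h2, h1))
  out <- list()
  for (p in pairs) for (o in ord)
    out[[length(out) + 1]] <- c(key(p[[1]], o[1]), key(p[[2]], o[2]))
  do.call(rbind, out)
}

r_sample_pairs <- function(geno, hla) {
  lapply(seq_len(nrow(geno)), function(s)
    r_enumerate_pairs(geno[s, ], hla[s, 1], hla[s, 2]))
}

r_loglik_pairs <- function(freq, sp) {
  sum(vapply(sp, function(m) {
    f1 <- freq[m[, 1]]
    f2 <- freq[m[, 2]]
    f1[is.na(f1)] <- 0
    f2[is.na(f2)] <- 0
    log(sum(f1 * f2))
  }, numeric(1)))
}

# Plain EM over the enumerated pair lists, from an arbitrary start.
r_em <- function(geno, hla, start = NULL, tol = 1e-10, max_iter = 2000) {
  sp <- r_sample_pairs(geno, hla)
  keys <- sort(unique(unlist(sp)))
  f <- if (is.null(start)) stats::setNames(rep(1 / length(keys),
                                               length(keys)), keys)
  else start[keys]
  n <- length(sp)
  for (it in seq_len(max_iter)) {
    cnt <- stats::setNames(rep(0, length(keys)), keys)
    for (m in sp) {
      w <- f[m[, 1]] * f[m[, 2]]
      tot <- sum(w)
      if (tot <= 0) next
      w <- w / tot
      for (j in seq_len(nrow(m))) {
        cnt[m[j, 1]] <- cnt[m[j, 1]] + w[j]
        cnt[m[j, 2]] <- cnt[m[j, 2]] + w[j]
      }
    }
    fn <- cnt / (2 * n)
    if (max(abs(fn - f)) < tol) { f <- fn; break }
    f <- fn
  }
  list(freq = f, loglik = r_loglik_pairs(f, sp))
}

# Direct likelihood maximisation over the frequency simplex via a softmax
# parameterisation (independent of the EM fixed-point iteration).
r_simplex_search <- function(geno, hla, n_restarts = 10, seed = 1) {
  sp <- r_sample_pairs(geno, hla)
  keys <- sort(unique(unlist(sp)))
  negll <- function(theta) {
    f <- exp(theta - max(theta))
    f <- stats::setNames(f / sum(f), keys)
    -r_loglik_pairs(f, sp)
  }
  best <- Inf
  set.seed(seed)
  for (r in seq_len(n_restarts)) {
    th0 <- stats::rnorm(length(keys))
    fit <- try(stats::optim(th0, negll, method = "BFGS",
                            control = list(maxit = 500)), silent = TRUE)
    if (!inherits(fit, "try-error") && fit$value < best) best <- fit$value
  }
  -best
}

# Frequency table of a fitted em_haplotype_frequencies() result as a named
# vector over "pattern|allele" keys, for comparison with the R oracle.
table_as_freq_vector <- function(table) {
  stats::setNames(table$freq, paste0(table$pattern, "|", table$hla))
}
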