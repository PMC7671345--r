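#' Allele frequencies from calls or truth typings
#'
#' Calls with posterior below `pp_cutoff` are excluded; each retained call
#' contributes two alleles (homozygotes contribute theirs twice). The
#' denominator is `2 x` retained calls per locus, always.
#'
#' @param calls Calls data.frame (or an [hla_typing()] table, which is
#'   treated as calls with posterior 1).
#' @param pp_cutoff Posterior-probability cutoff.
#' @return data.frame of class `frequency_table`: `locus`, `allele`,
#'   `count`, `denominator`, `freq`. If the cutoff excludes everything at a
#'   locus the locus appears with zero denominator and `NA` frequency, and
#'   the result carries attribute `empty = TRUE`.
#' @export
allele_frequencies <- function(calls, pp_cutoff = 0) {
  calls <- as.data.frame(calls)
  if (is.null(calls$posterior)) calls$posterior <- 1
  if (is.null(calls$flagged)) calls$flagged <- FALSE
  loci <- unique(calls$locus)
  keep <- calls$posterior >= pp_cutoff & !calls$flagged &
    !is.na(calls$allele1)
  rows <- list()
  for (locus in loci) {
    sel <- keep & calls$locus == locus
    n_ret <- sum(sel)
    if (n_ret == 0) {
      rows[[locus]] <- data.frame(locus = locus, allele = NA_character_,
                                  count = 0L, denominator = 0L,
                                  freq = NA_real_, stringsAsFactors = FALSE)
      next
    }
    al <- c(calls$allele1[sel], calls$allele2[sel])
    tab <- table(al)
    rows[[locus]] <- data.frame(locus = locus, allele = names(tab),
                                count = as.integer(tab),
                                denominator = 2L * n_ret,
                                freq = as.numeric(tab) / (2 * n_ret),
                                stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("frequency_table", "data.frame")
  attr(out, "empty") <- any(out$denominator == 0)
  out
}

#' Compare batch allele frequencies against a reference table
#'
#' Per allele, reports the mean and SD across batches of
#' `batch frequency - reference frequency`. Alleles absent from a batch (or
#' from the reference) count as frequency 0, so the union of alleles is
#' always compared. Output is sorted by decreasing `|mean difference|` and
#' is invariant to batch order.
#'
#' @param batch_tables List of [allele_frequencies()] tables, one per batch.
#' @param reference Reference [allele_frequencies()] table.
#' @return data.frame: `locus`, `allele`, `mean_diff`, `sd_diff`,
#'   `ref_freq`, `n_batches`.
#' @export
compare_frequencies <- function(batch_tables, reference) {
  stopifnot(length(batch_tables) >= 1)
  ref <- as.data.frame(reference)
  key <- function(tab) paste(tab$locus, tab$allele, sep = "\r")
  all_keys <- sort(unique(c(key(ref),
                            unlist(lapply(batch_tables, key)))))
  all_keys <- all_keys[!grepl("\rNA$", all_keys)]
  lookup <- function(tab) {
    f <- tab$freq[match(all_keys, key(tab))]
    f[is.na(f)] <- 0
    f
  }
  ref_f <- lookup(ref)
  diffs <- vapply(batch_tables, function(b) lookup(b) - ref_f,
                  numeric(length(all_keys)))
  diffs <- matrix(diffs, nrow = length(all_keys))
  parts <- strsplit(all_keys, "\r")
  out <- data.frame(locus = vapply(parts, `[`, "", 1),
                    allele = vapply(parts, `[`, "", 2),
                    mean_diff = rowMeans(diffs),
                    sd_diff = apply(diffs, 1, stats::sd),
                    ref_freq = ref_f,
                    n_batches = length(batch_tables),
                    stringsAsFactors = FALSE)
  out <- out[order(-abs(out$mean_diff)), ]
  rownames(out) <- NULL
  out
}

#' Rank correlation between batch frequency deviation and allele count
#'
#' Operationalises the deviation of a batch as the mean over union alleles
#' of `|batch frequency - reference frequency|`, and correlates it
#' (Spearman by default) with the batch's retained allele count. Batches
#' imputing more alleles are expected to deviate less.
#'
#' @param batch_tables List of [allele_frequencies()] tables.
#' @param reference Reference [allele_frequencies()] table.
#' @param method Correlation method, default `"spearman"`.
#' @return List: `estimate` (`NA` when degenerate, e.g. constant inputs),
#'   `p_value`, `per_batch` (data.frame `batch`, `mean_abs_dev`,
#'   `n_alleles`).
#' @export
deviation_vs_count_correlation <- function(batch_tables, reference,
                                           method = "spearman") {
  cmp_dev <- vapply(batch_tables, function(b) {
    d <- compare_frequencies(list(b), reference)
    mean(abs(d$mean_diff))
  }, numeric(1))
  counts <- vapply(batch_tables, function(b) sum(b$denominator[!duplicated(b$locus)]),
                   numeric(1))
  per_batch <- data.frame(batch = seq_along(batch_tables),
                          mean_abs_dev = cmp_dev, n_alleles = counts)
  if (length(unique(cmp_dev)) < 2 || length(unique(counts)) < 2)
    return(list(estimate = NA_real_, p_value = NA_real_,
                per_batch = per_batch))
  ct <- suppressWarnings(stats::cor.test(cmp_dev, counts, method = method))
  list(estimate = unname(ct$estimate), p_value = ct$p.value,
       per_batch = per_batch)
}
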