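#' Normalise HLA allele names to two-field resolution
#'
#' Truncates extra fields (`"A*02:01:01:02"` -> `"A*02:01"`). One-field
#' names (no colon) are an error: they cannot be interpreted at the
#' protein-sequence level this package works at.
#'
#' @param alleles Character vector of `GENE*FF[:FF...]` names.
#' @param context Optional label used in error messages.
#' @return Character vector of `GENE*FF:FF` names.
#' @export
normalize_hla_allele <- function(alleles, context = NULL) {
  alleles <- as.character(alleles)
  bad <- !grepl("^[A-Za-z0-9]+\\*[0-9]+:[0-9]+", alleles)
  if (any(bad))
    stop("allele not at two-field resolution",
         if (!is.null(context)) paste0(" (", context, ")"), ": ",
         paste(unique(alleles[bad]), collapse = ", "))
  sub("^([A-Za-z0-9]+\\*[0-9]+:[0-9]+).*$", "\\1", alleles)
}

#' Construct an HLA typing table
#'
#' Stores, per sample and locus, the unordered pair of two-field HLA alleles
#' (homozygotes repeat the allele). Pairs are stored lexicographically
#' sorted so equality is order-free.
#'
#' @param df data.frame with columns `sample`, `locus`, `allele1`, `allele2`.
#' @param loci Permitted locus labels.
#' @return data.frame of class `hla_typing` with normalised, sorted pairs.
#' @export
hla_typing <- function(df, loci = c("A", "B", "C", "DRB1", "DQA1", "DQB1", "DPB1")) {
  stopifnot(all(c("sample", "locus", "allele1", "allele2") %in% names(df)))
  df <- data.frame(sample = as.character(df$sample),
                   locus = as.character(df$locus),
                   allele1 = as.character(df$allele1),
                   allele2 = as.character(df$allele2),
                   stringsAsFactors = FALSE)
  unknown <- setdiff(unique(df$locus), loci)
  if (length(unknown) > 0)
    stop("unknown locus label: ", paste(unknown, collapse = ", "))
  ctx <- paste0("sample ", df$sample, ", locus ", df$locus)
  df$allele1 <- normalize_hla_allele(df$allele1, context = ctx[1])
  df$allele2 <- normalize_hla_allele(df$allele2, context = ctx[1])
  p <- sort_pair(df$allele1, df$allele2)
  df$allele1 <- p$a1
  df$allele2 <- p$a2
  key <- paste(df$sample, df$locus, sep = "\r")
  if (anyDuplicated(key)) {
    pair_key <- paste(df$allele1, df$allele2, sep = "\r")
    agree <- tapply(pair_key, key, function(z) length(unique(z)) == 1L)
    if (!all(agree))
      stop("conflicting duplicate rows for: ",
           paste(gsub("\r", "/", names(agree)[!agree]), collapse = ", "))
    df <- df[!duplicated(key), , drop = FALSE]
  }
  rownames(df) <- NULL
  class(df) <- c("hla_typing", "data.frame")
  df
}

#' Read an HLA typing table from TSV
#'
#' Expects header columns `sample`, `locus`, `allele1`, `allele2`. Alleles
#' are normalised to two-field resolution; duplicated (sample, locus) rows
#' with conflicting pairs are an error.
#'
#' @param path TSV file.
#' @param loci Permitted locus labels.
#' @return An [hla_typing()] table.
#' @export
read_hla_table <- function(path, loci = c("A", "B", "C", "DRB1", "DQA1", "DQB1", "DPB1")) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample", "locus", "allele1", "allele2")
  if (!all(need %in% names(tab)))
    stop("HLA table must have columns ", paste(need, collapse = ", "))
  hla_typing(tab, loci = loci)
}

#' Write an HLA typing table to TSV
#'
#' @param t An [hla_typing()] table.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_hla_table <- function(t, path) {
  utils::write.table(as.data.frame(t), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
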