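#' Construct a genotype matrix
#'
#' The package's container for unphased biallelic SNP genotypes: a samples x
#' SNPs matrix of alternate-allele dosages in \{0, 1, 2, NA\} plus a SNP
#' annotation table.
#'
#' @param dosage Integer matrix, samples in rows (rownames = sample IDs),
#'   SNPs in columns (colnames = SNP IDs); values 0/1/2/NA.
#' @param snps data.frame with columns `id`, `chrom`, `pos`, `ref`, `alt`,
#'   one row per dosage column, in column order.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosage, snps) {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "integer"
  stopifnot(is.data.frame(snps),
            all(c("id", "chrom", "pos", "ref", "alt") %in% names(snps)),
            nrow(snps) == ncol(dosage))
  if (anyDuplicated(snps$id))
    stop("duplicated SNP ID: ",
         paste(unique(snps$id[duplicated(snps$id)]), collapse = ", "))
  bad <- !(dosage %in% c(0L, 1L, 2L) | is.na(dosage))
  if (any(bad)) stop("dosage values must be 0, 1, 2 or NA")
  colnames(dosage) <- snps$id
  if (is.null(rownames(dosage)))
    rownames(dosage) <- paste0("S", seq_len(nrow(dosage)))
  snps <- data.frame(id = as.character(snps$id),
                     chrom = as.character(snps$chrom),
                     pos = as.integer(snps$pos),
                     ref = as.character(snps$ref),
                     alt = as.character(snps$alt),
                     stringsAsFactors = FALSE)
  structure(list(dosage = dosage, snps = snps), class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", nrow(x$dosage), "samples x", ncol(x$dosage),
      "SNPs\n")
  invisible(x)
}

#' Read SNP genotypes from VCF or a TSV dosage table
#'
#' Only biallelic SNP records are retained; multiallelic or non-SNP (indel)
#' records are skipped and the skip count reported via `message()` and the
#' `n_skipped` attribute. Missing genotypes are preserved as `NA`.
#'
#' @param path Input file.
#' @param format_name `"vcf"` (VCF 4.x, unphased diploid GT) or
#'   `"tsv-dosage"` (header `id chrom pos ref alt <sample...>`).
#' @return A [genotype_matrix()] with attribute `n_skipped`.
#' @export
read_genotypes <- function(path, format_name = c("vcf", "tsv-dosage")) {
  format_name <- match.arg(format_name)
  if (!file.exists(path)) stop("file does not exist: ", path)
  if (format_name == "vcf") read_genotypes_vcf(path) else read_genotypes_tsv(path)
}

read_genotypes_vcf <- function(path) {
  head_lines <- readLines(path, n = 500L)
  if (length(head_lines) == 0 || !grepl("^##fileformat=VCF", head_lines[1]))
    stop("malformed VCF header at line 1: missing ##fileformat")
  if (!any(grepl("^#CHROM\t", head_lines)))
    stop("malformed VCF header: no #CHROM column line within the first ",
         length(head_lines), " lines")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  is_snp <- nchar(fix$REF) == 1 & nchar(fix$ALT) == 1 &
    fix$REF %in% c("A", "C", "G", "T") & fix$ALT %in% c("A", "C", "G", "T") &
    !grepl(",", fix$ALT)
  is_snp[is.na(is_snp)] <- FALSE
  n_skipped <- sum(!is_snp)
  if (n_skipped > 0)
    message("read_genotypes: skipped ", n_skipped,
            " multiallelic or non-SNP record(s)")
  if (anyDuplicated(fix$ID[is_snp]))
    stop("duplicated SNP ID: ",
         paste(unique(fix$ID[is_snp][duplicated(fix$ID[is_snp])]),
               collapse = ", "))
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gt[is_snp, , drop = FALSE]
  fix <- fix[is_snp, , drop = FALSE]
  dos <- gt_to_dosage(gt) # SNPs x samples
  g <- genotype_matrix(t(dos),
                       data.frame(id = fix$ID, chrom = fix$CHROM,
                                  pos = as.integer(fix$POS),
                                  ref = fix$REF, alt = fix$ALT,
                                  stringsAsFactors = FALSE))
  attr(g, "n_skipped") <- n_skipped
  g
}

gt_to_dosage <- function(gt) {
  dos <- matrix(NA_integer_, nrow(gt), ncol(gt),
                dimnames = dimnames(gt))
  clean <- gsub("\\|", "/", gt)
  dos[clean %in% c("0/0")] <- 0L
  dos[clean %in% c("0/1", "1/0")] <- 1L
  dos[clean %in% c("1/1")] <- 2L
  dos
}

read_genotypes_tsv <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("id", "chrom", "pos", "ref", "alt")
  if (!all(need %in% names(tab)))
    stop("malformed dosage TSV header: need columns ",
         paste(need, collapse = ", "))
  is_snp <- nchar(tab$ref) == 1 & nchar(tab$alt) == 1 &
    tab$ref %in% c("A", "C", "G", "T") & tab$alt %in% c("A", "C", "G", "T")
  n_skipped <- sum(!is_snp)
  if (n_skipped > 0)
    message("read_genotypes: skipped ", n_skipped,
            " multiallelic or non-SNP record(s)")
  tab <- tab[is_snp, , drop = FALSE]
  samp_cols <- setdiff(names(tab), need)
  dos <- t(as.matrix(tab[, samp_cols, drop = FALSE]))
  storage.mode(dos) <- "integer"
  rownames(dos) <- samp_cols
  g <- genotype_matrix(dos, tab[, need])
  attr(g, "n_skipped") <- n_skipped
  g
}

#' Write a genotype matrix to VCF 4.2 or the TSV dosage dialect
#'
#' The VCF writer emits unphased diploid GT calls (`0/0`, `0/1`, `1/1`,
#' `./.`), one contig line per chromosome. Output from either writer parses
#' back to an equal object with [read_genotypes()].
#'
#' @param g A [genotype_matrix()].
#' @param path Output file.
#' @param format_name `"vcf"` or `"tsv-dosage"`.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(g, path, format_name = c("vcf", "tsv-dosage")) {
  format_name <- match.arg(format_name)
  stopifnot(inherits(g, "genotype_matrix"))
  if (format_name == "tsv-dosage") {
    tab <- cbind(g$snps, as.data.frame(t(g$dosage), check.names = FALSE))
    utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(path))
  }
  gt_codes <- c("0" = "0/0", "1" = "0/1", "2" = "1/1")
  gt <- matrix("./.", ncol(g$dosage), nrow(g$dosage)) # SNPs x samples
  for (i in seq_len(nrow(g$dosage))) {
    d <- g$dosage[i, ]
    gt[!is.na(d), i] <- gt_codes[as.character(d[!is.na(d)])]
  }
  header <- c("##fileformat=VCFv4.2",
              "##source=hlapanel",
              paste0("##contig=<ID=", unique(g$snps$chrom), ">"),
              '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", rownames(g$dosage)), collapse = "\t"))
  body <- paste(g$snps$chrom, g$snps$pos, g$snps$id, g$snps$ref, g$snps$alt,
                ".", "PASS", ".", "GT",
                apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}
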