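#' Read a SNP platform/build manifest
#'
#' @param path TSV with header `rsid, build, chrom, pos, alleleA, alleleB,
#'   platform`.
#' @return data.frame of class `snp_manifest`.
#' @export
read_snp_manifest <- function(path) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("rsid", "build", "chrom", "pos", "alleleA", "alleleB", "platform")
  if (!all(need %in% names(tab)))
    stop("manifest must have columns ", paste(need, collapse = ", "))
  snp_manifest(tab)
}

#' Construct a SNP manifest
#'
#' @param df data.frame with columns `rsid`, `build`, `chrom`, `pos`,
#'   `alleleA`, `alleleB`, `platform`.
#' @return The validated data.frame, classed `snp_manifest`.
#' @export
snp_manifest <- function(df) {
  need <- c("rsid", "build", "chrom", "pos", "alleleA", "alleleB", "platform")
  stopifnot(all(need %in% names(df)))
  if (anyDuplicated(df$rsid))
    stop("rsID occurring twice in one manifest: ",
         paste(unique(df$rsid[duplicated(df$rsid)]), collapse = ", "))
  bad <- !(df$alleleA %in% c("A", "C", "G", "T")) |
    !(df$alleleB %in% c("A", "C", "G", "T")) | df$alleleA == df$alleleB
  if (any(bad))
    stop("allele pair must be two distinct single bases: ",
         paste(df$rsid[bad], collapse = ", "))
  df <- as.data.frame(df)[, need]
  class(df) <- c("snp_manifest", "data.frame")
  df
}

complement_base <- function(b) c(A = "T", C = "G", G = "C", T = "A")[b]

is_palindromic <- function(a, b) {
  (a == "A" & b == "T") | (a == "T" & b == "A") |
    (a == "C" & b == "G") | (a == "G" & b == "C")
}

#' Harmonize SNP sets across platform manifests and genome builds
#'
#' Intersects manifests by rsID, then keeps SNPs whose allele pair (as a
#' set) agrees across all manifests, normalising strand by complementing a
#' manifest's pair when that makes the sets match. Palindromic (A/T, C/G)
#' SNPs are excluded whenever a complement operation would be needed, since
#' their strand cannot be resolved from alleles alone. Every rsID in the
#' union of manifests is accounted for exactly once: either retained or
#' excluded with reason `absent-from-platform`, `allele-mismatch` or
#' `strand-ambiguous`. Identity is by rsID only; per-build positions may
#' disagree and are all retained.
#'
#' @param manifests List of >= 2 [snp_manifest()] objects.
#' @return Object of class `harmonized_snp_set`: list with `snps`
#'   (data.frame rsid, alleleA, alleleB, plus `pos.<build or platform>`
#'   columns) and `exclusions` (data.frame rsid, reason).
#' @export
harmonize_snps <- function(manifests) {
  if (length(manifests) < 2) stop("need at least two manifests")
  manifests <- lapply(manifests, snp_manifest)
  ids <- lapply(manifests, function(m) m$rsid)
  union_ids <- sort(unique(unlist(ids)))
  in_all <- Reduce(intersect, ids)
  excl <- data.frame(rsid = character(0), reason = character(0),
                     stringsAsFactors = FALSE)
  absent <- setdiff(union_ids, in_all)
  if (length(absent) > 0)
    excl <- rbind(excl, data.frame(rsid = absent,
                                   reason = "absent-from-platform",
                                   stringsAsFactors = FALSE))
  in_all <- sort(in_all)
  if (length(in_all) == 0 && length(union_ids) > 0)
    stop("empty intersection of manifests: pipeline cannot proceed")

  ref <- manifests[[1]]
  ref_rows <- ref[match(in_all, ref$rsid), ]
  keep <- rep(TRUE, length(in_all))
  reason <- rep(NA_character_, length(in_all))
  for (m in manifests[-1]) {
    rows <- m[match(in_all, m$rsid), ]
    same <- (rows$alleleA == ref_rows$alleleA & rows$alleleB == ref_rows$alleleB) |
      (rows$alleleA == ref_rows$alleleB & rows$alleleB == ref_rows$alleleA)
    ca <- unname(complement_base(rows$alleleA))
    cb <- unname(complement_base(rows$alleleB))
    comp <- (ca == ref_rows$alleleA & cb == ref_rows$alleleB) |
      (ca == ref_rows$alleleB & cb == ref_rows$alleleA)
    pal <- is_palindromic(rows$alleleA, rows$alleleB)
    # palindromic pairs satisfy `same` and `comp` simultaneously; if a
    # complement would be required anywhere they are unresolvable
    ambiguous <- pal & !(same & !comp)
    mismatch <- !same & !comp
    drop_now <- keep & (ambiguous | mismatch)
    reason[drop_now & mismatch] <- "allele-mismatch"
    reason[drop_now & ambiguous & !mismatch] <- "strand-ambiguous"
    keep <- keep & !drop_now
  }
  if (any(!keep))
    excl <- rbind(excl, data.frame(rsid = in_all[!keep],
                                   reason = reason[!keep],
                                   stringsAsFactors = FALSE))
  retained <- in_all[keep]
  if (length(retained) == 0)
    stop("no SNP retained after harmonization: pipeline cannot proceed")
  snps <- data.frame(rsid = retained,
                     alleleA = ref_rows$alleleA[keep],
                     alleleB = ref_rows$alleleB[keep],
                     stringsAsFactors = FALSE)
  for (m in manifests) {
    lbl <- paste0("pos.", m$build[1], ".", m$platform[1])
    snps[[lbl]] <- m$pos[match(retained, m$rsid)]
  }
  excl <- excl[order(excl$rsid), , drop = FALSE]
  rownames(excl) <- NULL
  structure(list(snps = snps, exclusions = excl),
            class = "harmonized_snp_set")
}

#' Restrict a genotype matrix to a harmonized SNP set
#'
#' Keeps only harmonized rsIDs present in `g`, in harmonized order, and
#' flips dosages (`d -> 2 - d`) where `g`'s ref/alt orientation is reversed
#' relative to the agreed allele pair. SNPs absent from `g` are dropped and
#' counted in the `n_absent` attribute.
#'
#' @param g A [genotype_matrix()].
#' @param h A `harmonized_snp_set`.
#' @return A [genotype_matrix()] with attribute `n_absent`.
#' @export
subset_genotypes <- function(g, h) {
  stopifnot(inherits(g, "genotype_matrix"), inherits(h, "harmonized_snp_set"))
  idx <- match(h$snps$rsid, g$snps$id)
  present <- !is.na(idx)
  n_absent <- sum(!present)
  if (n_absent > 0)
    message("subset_genotypes: ", n_absent,
            " harmonized SNP(s) absent from genotype matrix")
  idx <- idx[present]
  dos <- g$dosage[, idx, drop = FALSE]
  snps <- g$snps[idx, , drop = FALSE]
  agreed_a <- h$snps$alleleA[present]
  agreed_b <- h$snps$alleleB[present]
  flipped <- snps$ref == agreed_b & snps$alt == agreed_a
  straight <- snps$ref == agreed_a & snps$alt == agreed_b
  if (any(!flipped & !straight))
    stop("genotype alleles incompatible with agreed pair for: ",
         paste(snps$id[!flipped & !straight], collapse = ", "))
  if (any(flipped)) {
    dos[, flipped] <- 2L - dos[, flipped]
    snps$ref[flipped] <- agreed_a[flipped]
    snps$alt[flipped] <- agreed_b[flipped]
  }
  rownames(snps) <- NULL
  out <- genotype_matrix(dos, snps)
  attr(out, "n_absent") <- n_absent
  out
}

#' Write a harmonized SNP set (and its exclusion log) to TSV
#'
#' @param h A `harmonized_snp_set`.
#' @param path Output TSV for the retained SNPs; the exclusion log goes to
#'   `<path>.exclusions.tsv`.
#' @return `path`, invisibly.
#' @export
write_harmonized_set <- function(h, path) {
  utils::write.table(h$snps, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(h$exclusions, paste0(path, ".exclusions.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
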