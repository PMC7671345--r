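make_manifest <- function(rsid, alleleA, alleleB, build = "b37",
                          platform = "arr1", pos = seq_along(rsid) * 100L) {
  snp_manifest(data.frame(rsid = rsid, build = build, chrom = "6", pos = pos,
                          alleleA = alleleA, alleleB = alleleB,
                          platform = platform, stringsAsFactors = FALSE))
}

test_that("identical manifests are retained in full; mismatches are excluded", {
  rs <- sprintf("rs%02d", 1:10)
  m1 <- make_manifest(rs, rep("A", 10), rep("G", 10))
  m2 <- make_manifest(rs, rep("A", 10), rep("G", 10), build = "b38")
  h <- harmonize_snps(list(m1, m2))
  expect_equal(h$snps$rsid, sort(rs))
  expect_equal(nrow(h$exclusions), 0L)

  # rs1 A/G in one build, A/C in the other -> allele-mismatch
  m3 <- make_manifest(rs, c("A", rep("A", 9)), c("C", rep("G", 9)),
                      build = "b38")
  h2 <- harmonize_snps(list(m1, m3))
  expect_false("rs01" %in% h2$snps$rsid)
  expect_equal(h2$exclusions$reason[h2$exclusions$rsid == "rs01"],
               "allele-mismatch")
})

test_that("strand handling matches base-pair enumeration against complements", {
  # oracle: for each of the 6 unordered base pairs, comparing against the
  # complemented pair must retain exactly the non-palindromic ones
  pairs <- list(c("A", "C"), c("A", "G"), c("A", "T"),
                c("C", "G"), c("C", "T"), c("G", "T"))
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  for (p in pairs) {
    palindromic <- setequal(p, comp[p])
    m1 <- make_manifest("rs1", p[1], p[2])
    m2 <- make_manifest("rs1", unname(comp[p[1]]), unname(comp[p[2]]),
                        build = "b38")
    if (palindromic) {
      expect_error(harmonize_snps(list(m1, m2)), "no SNP retained")
    } else {
      h <- harmonize_snps(list(m1, m2))
      expect_equal(h$snps$rsid, "rs1")
      expect_equal(nrow(h$exclusions), 0L)
    }
    # identical palindromic pairs are still unresolvable
    m3 <- make_manifest("rs1", p[1], p[2], build = "b38")
    if (palindromic) {
      expect_error(harmonize_snps(list(m1, m3)), "no SNP retained")
    }
  }
})

test_that("every union rsID is accounted for exactly once and order is immaterial", {
  set.seed(21)
  bases <- c("A", "C", "G", "T")
  rs <- sprintf("rs%03d", 1:40)
  draw <- function(ids, build, platform) {
    a <- sample(bases, length(ids), TRUE)
    b <- vapply(a, function(x) sample(setdiff(bases, x), 1), "")
    make_manifest(ids, a, b, build = build, platform = platform)
  }
  m1 <- draw(rs[1:35], "b37", "arr1")
  m2 <- draw(rs[6:40], "b38", "arr2")
  m3 <- draw(rs[1:38], "b38", "arr3")
  h <- harmonize_snps(list(m1, m2, m3))
  accounted <- sort(c(h$snps$rsid, h$exclusions$rsid))
  expect_equal(accounted, sort(rs))
  expect_setequal(unique(h$exclusions$reason),
                  intersect(unique(h$exclusions$reason),
                            c("absent-from-platform", "allele-mismatch",
                              "strand-ambiguous")))
  for (perm in list(c(2, 1, 3), c(3, 2, 1))) {
    h2 <- harmonize_snps(list(m1, m2, m3)[perm])
    expect_setequal(h2$snps$rsid, h$snps$rsid)
  }
})

test_that("duplicated rsIDs within a manifest and empty intersections error", {
  m1 <- make_manifest(c("rs1", "rs2"), c("A", "A"), c("G", "G"))
  expect_error(make_manifest(c("rs1", "rs1"), c("A", "A"), c("G", "G")),
               "twice")
  m2 <- make_manifest(c("rs3", "rs4"), c("A", "A"), c("G", "G"), build = "b38")
  expect_error(harmonize_snps(list(m1, m2)), "empty intersection")
  expect_error(harmonize_snps(list(m1)), "two manifests")
})

test_that("subset_genotypes reorders, flips swapped orientations and drops absentees", {
  set.seed(31)
  n_snp <- 50
  rs <- sprintf("rs%03d", seq_len(n_snp))
  m1 <- make_manifest(rs, rep("A", n_snp), rep("G", n_snp))
  m2 <- make_manifest(rs, rep("A", n_snp), rep("G", n_snp), build = "b38")
  h <- harmonize_snps(list(m1, m2))
  dos <- matrix(sample(0:2, 5 * n_snp, TRUE), 5, n_snp,
                dimnames = list(paste0("S", 1:5), NULL))
  # one SNP stored with swapped ref/alt relative to the agreed pair
  snps <- data.frame(id = rs, chrom = "6", pos = seq_len(n_snp),
                     ref = "A", alt = "G", stringsAsFactors = FALSE)
  snps$ref[7] <- "G"; snps$alt[7] <- "A"
  perm <- sample(n_snp)
  g <- genotype_matrix(dos[, perm], snps[perm, ])
  out <- subset_genotypes(g, h)
  expect_equal(colnames(out$dosage), h$snps$rsid)
  i7 <- which(h$snps$rsid == "rs007")
  orig <- g$dosage[, "rs007"]
  expect_equal(unname(out$dosage[, i7]), unname(2L - orig))
  straight <- which(h$snps$rsid == "rs010")
  expect_equal(unname(out$dosage[, straight]), unname(g$dosage[, "rs010"]))

  # 3 of the harmonized SNPs missing from g -> dropped with a count
  keep <- setdiff(rs, c("rs001", "rs002", "rs003"))
  g2 <- genotype_matrix(g$dosage[, keep], g$snps[match(keep, g$snps$id), ])
  out2 <- suppressMessages(subset_genotypes(g2, h))
  expect_equal(ncol(out2$dosage), n_snp - 3L)
  expect_equal(attr(out2, "n_absent"), 3L)
})
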