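test_that("PLINK round trip reproduces calls exactly", {
  G <- toy_geno(10, 20, seed = 3, missing_rate = 0.05)
  # calls count the sample minor allele (the container's invariant)
  flip <- colMeans(G$calls, na.rm = TRUE) / 2 > 0.5
  G$calls[, flip] <- 2L - G$calls[, flip]
  prefix <- file.path(withr::local_tempdir(), "toy")
  write_plink(G, prefix)
  G2 <- read_plink(prefix)
  expect_identical(unname(G2$calls), unname(G$calls))
  expect_identical(G2$subject_ids, G$subject_ids)
  expect_identical(G2$snp_table$snp_id, G$snp_table$snp_id)
})

test_that("PLINK reader encodes the sample minor allele and missingness", {
  # 2 subjects, 1 SNP: AA and AB with B minor -> calls (0, 1)
  calls <- matrix(c(0L, 1L), 2, 1)
  st <- tibble::tibble(snp_id = "rs1", chr = "1", pos = 100L,
                       allele1 = "B", allele2 = "A")
  G <- genotype_matrix(calls, st, c("s1", "s2"))
  prefix <- file.path(withr::local_tempdir(), "mini")
  write_plink(G, prefix)
  G2 <- read_plink(prefix)
  expect_equal(unname(G2$calls[, 1]), c(0L, 1L))
  # missing genotype survives as the sentinel, others unchanged
  calls[2, 1] <- NA_integer_
  G <- genotype_matrix(calls, st, c("s1", "s2"))
  write_plink(G, prefix)
  G3 <- read_plink(prefix)
  expect_true(is.na(G3$calls[2, 1]))
  expect_equal(G3$calls[1, 1], 0L)
})

test_that("PLINK reader rejects malformed files", {
  dir <- withr::local_tempdir()
  G <- toy_geno(4, 3)
  write_plink(G, file.path(dir, "ok"))
  # corrupt magic bytes
  bed <- file.path(dir, "ok.bed")
  raw <- readBin(bed, "raw", file.size(bed))
  raw[1] <- as.raw(0xff)
  writeBin(raw, bed)
  expect_error(read_plink(file.path(dir, "ok")), "magic")
  # truncated payload
  write_plink(G, file.path(dir, "tr"))
  raw <- readBin(file.path(dir, "tr.bed"), "raw",
                 file.size(file.path(dir, "tr.bed")))
  writeBin(raw[-length(raw)], file.path(dir, "tr.bed"))
  expect_error(read_plink(file.path(dir, "tr")), "mismatch")
  expect_error(read_plink(file.path(dir, "absent")), "missing")
})

test_that("genotype TSV round trip preserves the matrix", {
  G <- toy_geno(8, 6, seed = 5, missing_rate = 0.1)
  dir <- withr::local_tempdir()
  write_genotype_tsv(G, file.path(dir, "g.tsv"), file.path(dir, "s.tsv"))
  G2 <- read_genotype_tsv(file.path(dir, "g.tsv"), file.path(dir, "s.tsv"))
  expect_identical(unname(G2$calls), unname(G$calls))
  expect_equal(G2$snp_table$pos, G$snp_table$pos)
})

test_that("maf_filter keeps exactly the SNPs above threshold", {
  # 4 subjects, calls (0,0,0,1) -> maf 0.125, removed at 0.25
  calls <- cbind(c(0L, 0L, 0L, 1L), c(1L, 1L, 2L, 0L))
  st <- tibble::tibble(snp_id = c("a", "b"), chr = "1", pos = c(1L, 2L),
                       allele1 = "A", allele2 = "B")
  G <- genotype_matrix(calls, st)
  Gf <- maf_filter(G, 0.25)
  expect_identical(Gf$snp_table$snp_id, "b")
  expect_equal(nrow(Gf$calls), 4)
  # threshold 0 retains all polymorphic SNPs
  expect_equal(ncol(maf_filter(G, 0)$calls), 2)
  expect_error(maf_filter(G, 0.7), "threshold")
  expect_warning(maf_filter(G, 0.5), "every SNP")
})

test_that("maf_filter matches a brute-force frequency check and is idempotent", {
  G <- toy_geno(30, 50, seed = 7, maf = 0.3, missing_rate = 0.05)
  maf <- vapply(seq_len(50), function(k) {
    x <- G$calls[, k]
    sum(x, na.rm = TRUE) / (2 * sum(!is.na(x)))
  }, 1)
  Gf <- maf_filter(G, 0.25)
  expect_identical(Gf$snp_table$snp_id, G$snp_table$snp_id[maf > 0.25])
  expect_identical(maf_filter(Gf, 0.25)$snp_table$snp_id, Gf$snp_table$snp_id)
})

test_that("allele-combination encoding is one-hot and invertible", {
  # genotype 1 -> het column only
  G1 <- genotype_matrix(matrix(1L, 1, 1),
                        tibble::tibble(snp_id = "rs1", chr = "1", pos = 1L,
                                       allele1 = "A", allele2 = "B"))
  A1 <- encode_allele_combinations(G1)
  expect_equal(unname(A1$values[1, ]),
               as.integer(A1$column_map$combo == "het"))
  # complete 10x5 matrix: each SNP's three columns sum to 10
  G <- toy_geno(10, 5, seed = 2)
  A <- encode_allele_combinations(G)
  sums <- tapply(colSums(A$values), A$column_map$snp_id, sum)
  expect_true(all(sums == 10))
  # encode -> decode is the identity (including missing cells)
  G <- toy_geno(15, 8, seed = 3, missing_rate = 0.1)
  A <- encode_allele_combinations(G)
  miss_rows <- which(is.na(G$calls), arr.ind = TRUE)
  G2 <- decode_allele_combinations(A, G$snp_table)
  expect_identical(unname(G2$calls), unname(G$calls))
  # a missing genotype blanks all three of its columns
  if (nrow(miss_rows)) {
    r <- miss_rows[1, ]
    cols <- which(A$column_map$snp_id == G$snp_table$snp_id[r[2]])
    expect_true(all(is.na(A$values[r[1], cols])))
  }
})

test_that("snp_overlap implements the overlap coefficient", {
  a <- sprintf("rs%03d", 1:100)
  b <- c(sprintf("rs%03d", 1:30), sprintf("xx%03d", 1:10))
  ov <- snp_overlap(a, b)
  expect_equal(ov$coefficient, 30 / 40)
  expect_setequal(ov$shared, sprintf("rs%03d", 1:30))
  expect_equal(snp_overlap(a, a)$coefficient, 1)
  expect_equal(snp_overlap(a, paste0("zz", 1:5))$coefficient, 0)
  # symmetric and bounded
  expect_equal(snp_overlap(b, a)$coefficient, ov$coefficient)
  expect_error(snp_overlap(character(0), a), "non-empty")
})

test_that("GMT and annotation readers parse and validate", {
  dir <- withr::local_tempdir()
  gmt <- file.path(dir, "p.gmt")
  writeLines(c("pathA\tdesc\tG1\tG2\tG3", "pathB\tdesc\tG2\tG4"), gmt)
  sets <- read_gene_sets(gmt)
  expect_named(sets, c("pathA", "pathB"))
  expect_setequal(sets$pathA, c("G1", "G2", "G3"))
  writeLines(c("pathA\td\tG1", "pathA\td\tG2"), gmt)
  expect_error(read_gene_sets(gmt), "duplicate")
  writeLines("pathA\tdesc", gmt)
  expect_error(read_gene_sets(gmt), "malformed")
  ann_file <- file.path(dir, "ann.tsv")
  writeLines(c("rs1\tGENE_A", "rs2\tGENE_A"), ann_file)
  ann <- read_annotation(ann_file)
  expect_equal(ann$gene[ann$snp_id == "rs1"], "GENE_A")
  # round trip through write_gene_sets
  write_gene_sets(list(px = c("G1", "G9")), gmt)
  expect_equal(read_gene_sets(gmt)$px, c("G1", "G9"))
})
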