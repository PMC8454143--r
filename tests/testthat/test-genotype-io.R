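test_that("PED/MAP parsing transcribes the dosage coding rules", {
  dir <- withr::local_tempdir()
  writeLines(c("1 v1 0 1000", "1 v2 0 2000", "1 v3 0 3000"),
             file.path(dir, "t.map"))
  writeLines(c("F1 I1 0 0 1 -9 A A A G G G",
               "F1 I2 0 0 1 -9 A G 0 0 A G"),
             file.path(dir, "t.ped"))
  g <- read_pedmap(file.path(dir, "t.ped"), file.path(dir, "t.map"))
  # dosage counts allele_b (lexicographically larger); "0 0" is missing
  expect_equal(unname(g$calls[1, ]), c(0L, 1L, 2L))
  expect_equal(unname(g$calls[2, ]), c(1L, NA_integer_, 1L))
  expect_equal(g$variants$allele_a, c("A", "A", "A"))
  expect_equal(g$variants$allele_b, c("G", "G", "G"))
  expect_equal(g$samples, c("I1", "I2"))
  # monomorphic variant: the single observed allele is allele_a, calls are 0
  writeLines("1 m1 0 500", file.path(dir, "m.map"))
  writeLines(c("F1 I1 0 0 1 -9 G G", "F1 I2 0 0 1 -9 G G"),
             file.path(dir, "m.ped"))
  gm <- read_pedmap(file.path(dir, "m.ped"), file.path(dir, "m.map"))
  expect_equal(unname(gm$calls[, 1]), c(0L, 0L))
  expect_equal(gm$variants$allele_a, "G")
})

test_that("PED column mismatches and duplicate variant ids are rejected", {
  dir <- withr::local_tempdir()
  writeLines(c("1 v1 0 1000", "1 v2 0 2000"), file.path(dir, "t.map"))
  writeLines("F1 I1 0 0 1 -9 A A A", file.path(dir, "t.ped"))
  expect_error(read_pedmap(file.path(dir, "t.ped"), file.path(dir, "t.map")),
               "line 1")
  writeLines(c("1 v1 0 1000", "1 v1 0 2000"), file.path(dir, "dup.map"))
  writeLines("F1 I1 0 0 1 -9 A A A G", file.path(dir, "t2.ped"))
  expect_error(read_pedmap(file.path(dir, "t2.ped"), file.path(dir, "dup.map")),
               "duplicate")
})

test_that("variants are sorted by chromosome and position on load", {
  dir <- withr::local_tempdir()
  writeLines(c("2 v1 0 500", "1 v2 0 9000", "1 v3 0 100"),
             file.path(dir, "t.map"))
  writeLines(c("F1 I1 0 0 1 -9 A A A G G G",
               "F1 I2 0 0 1 -9 A G G G A A"), file.path(dir, "t.ped"))
  g <- read_pedmap(file.path(dir, "t.ped"), file.path(dir, "t.map"))
  expect_equal(g$variants$id, c("v3", "v2", "v1"))
  expect_equal(unname(g$calls[1, ]), c(2L, 1L, 0L))
  expect_equal(unname(g$calls[2, ]), c(0L, 2L, 1L))
})

test_that("BED round trip reproduces the call matrix exactly (fuzzed)", {
  for (seed in 1:8) {
    g <- toy_geno(n = sample(1:7, 1), m = sample(5:40, 1), seed = seed)
    dir <- withr::local_tempdir()
    write_bedset(g, file.path(dir, "g.bed"), file.path(dir, "g.bim"),
                 file.path(dir, "g.fam"))
    g2 <- read_bedset(file.path(dir, "g.bed"), file.path(dir, "g.bim"),
                      file.path(dir, "g.fam"))
    expect_identical(unname(g2$calls), unname(g$calls))
    expect_equal(g2$variants$pos_bp, g$variants$pos_bp)
  }
})

test_that("PED text and BED binary readers agree on the same data", {
  g <- toy_geno(n = 5, m = 24, seed = 99)
  # keep every variant polymorphic so PED allele inference is determined
  g$calls[1, ] <- 0L
  g$calls[2, ] <- 2L
  dir <- withr::local_tempdir()
  write_pedmap(g, file.path(dir, "g.ped"), file.path(dir, "g.map"))
  write_bedset(g, file.path(dir, "g.bed"), file.path(dir, "g.bim"),
               file.path(dir, "g.fam"))
  ga <- read_pedmap(file.path(dir, "g.ped"), file.path(dir, "g.map"))
  gb <- read_bedset(file.path(dir, "g.bed"), file.path(dir, "g.bim"),
                    file.path(dir, "g.fam"))
  expect_identical(unname(ga$calls), unname(gb$calls))
})

test_that("malformed BED files fail closed", {
  dir <- withr::local_tempdir()
  g <- toy_geno(n = 3, m = 10)
  write_bedset(g, file.path(dir, "g.bed"), file.path(dir, "g.bim"),
               file.path(dir, "g.fam"))
  raw <- readBin(file.path(dir, "g.bed"), "raw", 1e4)
  writeBin(raw[1:(length(raw) - 2)], file.path(dir, "trunc.bed"))
  expect_error(read_bedset(file.path(dir, "trunc.bed"), file.path(dir, "g.bim"),
                           file.path(dir, "g.fam")), "bytes")
  raw2 <- raw; raw2[1] <- as.raw(0x00)
  writeBin(raw2, file.path(dir, "magic.bed"))
  expect_error(read_bedset(file.path(dir, "magic.bed"), file.path(dir, "g.bim"),
                           file.path(dir, "g.fam")), "magic")
})

test_that("QC removes samples and variants at the stated strict boundaries", {
  set.seed(1)
  n <- 40; m <- 200
  p <- runif(m, 0.2, 0.5)
  calls <- matrix(rbinom(n * m, 2L, rep(p, each = n)), n, m)
  # sample 1: call rate ~0.94 -> removed; sample 2: ~0.96 -> kept
  calls[1, 21:32] <- NA
  calls[2, 21:28] <- NA
  # variant 1 (after the above): force MAF 0.04 via column overwrite
  calls[, 3] <- c(rep(1L, round(2 * 0.04 * n)), rep(0L, n - round(2 * 0.04 * n)))
  calls[, 4] <- 0L  # monomorphic
  variants <- tibble::tibble(id = paste0("v", 1:m), chrom = rep(1L, m),
                             pos_bp = seq(1000, by = 4000, length.out = m),
                             allele_a = "A", allele_b = "G")
  variants$chrom[5] <- 30L  # non-autosomal
  g <- geno_matrix(calls, paste0("I", 1:n), variants)
  qc <- apply_qc(g)
  expect_false("I1" %in% qc$genotypes$samples)
  expect_true("I2" %in% qc$genotypes$samples)
  expect_false("v3" %in% qc$genotypes$variants$id)  # MAF 0.04 <= 0.05
  expect_false("v4" %in% qc$genotypes$variants$id)  # monomorphic
  expect_false("v5" %in% qc$genotypes$variants$id)  # chromosome 30
  expect_equal(qc$report$removed[qc$report$filter == "non_autosomal"], 1L)
})

test_that("QC is idempotent", {
  st <- small_study()
  qc1 <- apply_qc(st$g)
  qc2 <- apply_qc(qc1$genotypes)
  expect_identical(qc2$genotypes$calls, qc1$genotypes$calls)
  expect_equal(sum(qc2$report$removed), 0)
})

test_that("HWE exact test matches brute-force enumeration for totals <= 50", {
  set.seed(7)
  cases <- rbind(
    c(5, 0, 5), c(25, 50, 25), c(100, 0, 0), c(0, 1, 0), c(3, 1, 16),
    t(replicate(60, {
      n <- sample(1:50, 1)
      het <- sample(0:n, 1)
      aa <- sample(0:(n - het), 1)
      c(aa, het, n - het - aa)
    }))
  )
  for (i in seq_len(nrow(cases))) {
    expect_equal(hwe_exact_test(cases[i, 1], cases[i, 2], cases[i, 3]),
                 oracle_hwe_p(cases[i, 1], cases[i, 2], cases[i, 3]),
                 tolerance = 1e-9,
                 info = paste(cases[i, ], collapse = ","))
  }
  expect_equal(hwe_exact_test(100, 0, 0), 1)
  expect_gt(hwe_exact_test(25, 50, 25), 0.99)
})
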