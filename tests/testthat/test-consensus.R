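mk_geno <- function(n_samples, pos, chrom = 1L) {
  v <- tibble::tibble(id = paste0("v", seq_along(pos)), chrom = chrom,
                      pos_bp = as.integer(pos), allele_a = "A", allele_b = "G")
  geno_matrix(matrix(0L, n_samples, length(pos)),
              sprintf("I%02d", seq_len(n_samples)), v)
}

seg_row <- function(sample, start, end, chrom = 1L) {
  tibble::tibble(sample_id = sample, chrom = chrom, start_bp = start,
                 end_bp = end, length_bp = end - start + 1,
                 n_snps = 100L, n_het = 0L, n_missing = 0L,
                 size_class = factor("Small", c("Small", "Medium", "Large")))
}

test_that("incidence rates are carrier fractions and conserve SNP counts", {
  g <- mk_geno(10, seq(1e5, 3e6, by = 1e4))
  segs <- dplyr::bind_rows(seg_row("I01", 5e5, 1.5e6), seg_row("I02", 1e6, 2e6))
  tr <- snp_incidence(segs, g)
  in_both <- tr$pos_bp >= 1e6 & tr$pos_bp <= 1.5e6
  expect_true(all(tr$rate[in_both] == 0.2))
  expect_true(all(tr$rate[tr$pos_bp < 5e5] == 0))
  # double-counting identity: sum of carrier counts = sum of per-segment SNPs
  snps_per_seg <- vapply(seq_len(nrow(segs)), function(i)
    sum(g$variants$pos_bp >= segs$start_bp[i] &
          g$variants$pos_bp <= segs$end_bp[i]), numeric(1))
  expect_equal(sum(tr$n_carriers), sum(snps_per_seg))
})

test_that("islands require strictly exceeding the rate threshold", {
  g <- mk_geno(10, seq(1e5, 3e6, by = 1e4))
  # exactly 2 of 10 carriers everywhere -> rate 0.2, never above
  segs <- dplyr::bind_rows(seg_row("I01", 1e5, 3e6), seg_row("I02", 1e5, 3e6))
  tr <- snp_incidence(segs, g)
  expect_equal(nrow(find_islands(tr, 0.2)), 0)
  # one extra carrier on a single SNP's span pushes it over
  segs3 <- dplyr::bind_rows(segs, seg_row("I03", 1.5e6, 1.5e6))
  tr3 <- snp_incidence(segs3, g)
  isl <- find_islands(tr3, 0.2)
  expect_equal(nrow(isl), 1)
  expect_equal(isl$start_bp, 1.5e6)
  expect_equal(isl$n_snps, 1L)
  expect_equal(isl$max_rate, 0.3)
})

test_that("islands split across gaps beyond the merge distance", {
  pos <- seq(1e5, 5e6, by = 1e4)
  g <- mk_geno(10, pos)
  segs <- dplyr::bind_rows(
    lapply(1:3, function(i) seg_row(sprintf("I%02d", i), 5e5, 1e6)),
    lapply(1:3, function(i) seg_row(sprintf("I%02d", i), 1.15e6, 1.6e6))
  )
  tr <- snp_incidence(segs, g)
  isl <- find_islands(tr, 0.2, max_gap_bp = 1e5)
  expect_equal(nrow(isl), 2)  # 150 kb of sub-threshold SNPs between runs
  isl_merged <- find_islands(tr, 0.2, max_gap_bp = 2e5)
  expect_equal(nrow(isl_merged), 1)
})

test_that("consensus is the intersection interval of an overlap pool", {
  g <- mk_geno(10, seq(1e5, 4e6, by = 1e4))
  segs <- dplyr::bind_rows(seg_row("I01", 1e6, 2e6), seg_row("I02", 1.5e6, 3e6))
  cons <- build_consensus(segs, g, min_snps = 5)
  expect_equal(nrow(cons), 1)
  expect_equal(cons$start_bp, 1.5e6)
  expect_equal(cons$end_bp, 2e6)
  expect_equal(cons$n_carriers, 2L)
  expect_equal(cons$frequency, 0.2)
  # nested segments: consensus is the inner interval
  segs2 <- dplyr::bind_rows(seg_row("I01", 1e6, 3e6), seg_row("I02", 1.5e6, 2e6))
  cons2 <- build_consensus(segs2, g, min_snps = 5)
  expect_equal(c(cons2$start_bp, cons2$end_bp), c(1.5e6, 2e6))
  # disjoint segments: two pools
  segs3 <- dplyr::bind_rows(seg_row("I01", 1e6, 1.4e6), seg_row("I02", 2e6, 2.4e6))
  expect_equal(nrow(build_consensus(segs3, g, min_snps = 5)), 2)
})

test_that("empty-intersection pools are split greedily left to right", {
  g <- mk_geno(10, seq(1e5, 6e6, by = 1e4))
  # chain A(1-2M), B(1.8-3.5M), C(3-4M): transitive pool, empty intersection
  segs <- dplyr::bind_rows(seg_row("I01", 1e6, 2e6), seg_row("I02", 1.8e6, 3.5e6),
                           seg_row("I03", 3e6, 4e6))
  cons <- build_consensus(segs, g, min_snps = 5)
  expect_equal(nrow(cons), 2)
  expect_equal(cons$start_bp, c(1.8e6, 3e6))
  expect_equal(cons$end_bp, c(2e6, 4e6))
  expect_equal(cons$n_carriers, c(2L, 1L))
})

test_that("regions below the minimum SNP count are dropped", {
  pos <- c(seq(1e5, 9e5, by = 1e4), seq(1e6, 1.03e6, by = 1e4),
           seq(2e6, 3e6, by = 1e4))  # only 4 SNPs in [1.0, 1.03] Mb
  g <- mk_geno(10, pos)
  segs <- dplyr::bind_rows(seg_row("I01", 1e6, 1.03e6), seg_row("I02", 1e6, 1.03e6))
  expect_equal(nrow(build_consensus(segs, g, min_snps = 5)), 0)
  expect_equal(nrow(build_consensus(segs, g, min_snps = 4)), 1)
})

test_that("carrier status requires full coverage of the consensus interval", {
  segs <- dplyr::bind_rows(seg_row("I01", 1e6, 2e6), seg_row("I02", 1.5e6, 3e6),
                           seg_row("I03", 1.6e6, 1.8e6))
  # contract check on a fixed interval: only fully-covering ROH qualify
  region <- tibble::tibble(region_id = "R", chrom = 1L, start_bp = 1.5e6,
                           end_bp = 2e6)
  expect_true(carrier_status(region, segs, "I01"))
  expect_true(carrier_status(region, segs, "I02"))
  expect_false(carrier_status(region, segs, "I03"))  # covers only part
  expect_false(carrier_status(region, segs, "I04"))  # no ROH at all
  cm <- carrier_matrix(region, segs, c("I01", "I02", "I03", "I04"))
  expect_equal(unname(cm[, 1]), c(TRUE, TRUE, FALSE, FALSE))
})

test_that("consensus frequency equals the carrier-status mean on synthetic data", {
  st <- small_study()
  cons <- build_consensus(st$segments, st$g)
  cm <- carrier_matrix(cons, st$segments, st$g$samples)
  expect_equal(unname(colMeans(cm)), cons$frequency)
})

test_that("a planted high-frequency region surfaces as an island", {
  st <- small_study()
  tr <- snp_incidence(st$segments, st$g)
  isl <- find_islands(tr, 0.2)
  reg <- st$cfg$assoc_regions
  hit <- isl$chrom == reg$chrom & isl$start_bp <= reg$end_bp &
    isl$end_bp >= reg$start_bp
  expect_true(any(hit))
})
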