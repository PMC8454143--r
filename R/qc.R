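#' Exact test of Hardy-Weinberg equilibrium
#'
#' Two-sided exact test conditional on the observed allele counts: the
#' p-value is the sum, over all heterozygote counts compatible with the
#' allele counts, of the probabilities no larger than that of the observed
#' heterozygote count. Monomorphic input returns p = 1 (nothing to test).
#'
#' @param n_homA,n_het,n_homB Genotype counts (non-negative, sum >= 1).
#' @return A p-value in (0, 1].
#' @export
hwe_exact_test <- function(n_homA, n_het, n_homB) {
  stopifnot(n_homA >= 0, n_het >= 0, n_homB >= 0)
  n <- n_homA + n_het + n_homB
  if (n < 1) stop("at least one genotype required")
  nA <- 2 * n_homA + n_het
  nB <- 2 * n_homB + n_het
  if (nA == 0 || nB == 0) return(1)
  n_rare <- min(nA, nB)
  # heterozygote counts share the parity of the rare-allele count
  hets <- seq(n_rare %% 2, n_rare, by = 2)
  logp <- .hwe_log_prob(hets, n, n_rare)
  probs <- exp(logp - max(logp))
  probs <- probs / sum(probs)
  obs <- probs[match(n_het, hets)]
  min(1, sum(probs[probs <= obs * (1 + 1e-10)]))
}

# log P(n_het | n individuals, n_rare copies of the rarer allele), up to a constant
.hwe_log_prob <- function(hets, n, n_rare) {
  n_common <- 2 * n - n_rare
  hom_rare <- (n_rare - hets) / 2
  hom_common <- n - hets - hom_rare
  hets * log(2) + lfactorial(n) -
    (lfactorial(hets) + lfactorial(hom_rare) + lfactorial(hom_common))
}

#' Apply the study's quality-control filters
#'
#' Filters are applied in a fixed, logged order: (1) drop non-autosomal
#' variants, (2) drop samples with call rate at or below `sample_call_rate`,
#' (3) drop variants with missingness at or above `max_variant_missing`,
#' (4) drop variants with minor allele frequency at or below `min_maf`,
#' (5) drop variants with exact Hardy-Weinberg p at or below `hwe_p_floor`.
#' All thresholds are strict in the keep direction (a call rate of exactly
#' 0.95 is removed; a MAF of exactly 0.05 is removed), matching the stated
#' inequality directions.
#'
#' @param g A [geno_matrix()].
#' @param sample_call_rate Keep samples with call rate strictly above this.
#' @param max_variant_missing Keep variants with missingness strictly below this.
#' @param min_maf Keep variants with MAF strictly above this.
#' @param hwe_p_floor Keep variants with HWE exact p strictly above this.
#' @param autosomes Integer set of autosome codes (cattle: 1-29).
#' @return A list with `genotypes` (the filtered [geno_matrix()]) and
#'   `report` (tibble of per-filter removal counts).
#' @export
apply_qc <- function(g, sample_call_rate = 0.95, max_variant_missing = 0.05,
                     min_maf = 0.05, hwe_p_floor = 1e-6, autosomes = 1:29) {
  stopifnot(inherits(g, "geno_matrix"), length(g$samples) > 0, nrow(g$variants) > 0)
  n0 <- length(g$samples); m0 <- nrow(g$variants)

  keep_v <- g$variants$chrom %in% autosomes
  n_nonauto <- sum(!keep_v)
  g <- subset_geno(g, variants = keep_v)
  if (nrow(g$variants) == 0) stop("QC removed all variants: none autosomal")

  cr <- rowMeans(!is.na(g$calls))
  keep_s <- cr > sample_call_rate
  n_lowcr <- sum(!keep_s)
  if (!any(keep_s)) stop("QC removed all samples: call rate filter")
  g <- subset_geno(g, samples = keep_s)

  miss <- colMeans(is.na(g$calls))
  keep_m <- miss < max_variant_missing
  n_miss <- sum(!keep_m)
  g <- subset_geno(g, variants = keep_m)
  if (nrow(g$variants) == 0) stop("QC removed all variants: missingness filter")

  p <- allele_freq(g)
  maf <- pmin(p, 1 - p)
  maf[is.nan(maf)] <- 0
  keep_f <- maf > min_maf
  n_maf <- sum(!keep_f)
  g <- subset_geno(g, variants = keep_f)
  if (nrow(g$variants) == 0) stop("QC removed all variants: MAF filter")

  hwe_p <- apply(g$calls, 2L, function(col) {
    hwe_exact_test(sum(col == 0L, na.rm = TRUE), sum(col == 1L, na.rm = TRUE),
                   sum(col == 2L, na.rm = TRUE))
  })
  keep_h <- hwe_p > hwe_p_floor
  n_hwe <- sum(!keep_h)
  g <- subset_geno(g, variants = keep_h)
  if (nrow(g$variants) == 0) stop("QC removed all variants: HWE filter")

  report <- tibble(
    filter = c("non_autosomal", "sample_call_rate", "variant_missingness",
               "maf", "hwe"),
    unit = c("variant", "sample", "variant", "variant", "variant"),
    removed = c(n_nonauto, n_lowcr, n_miss, n_maf, n_hwe)
  )
  attr(report, "n_samples_in") <- n0
  attr(report, "n_samples_out") <- length(g$samples)
  attr(report, "n_variants_in") <- m0
  attr(report, "n_variants_out") <- nrow(g$variants)
  list(genotypes = g, report = report)
}
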