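#' Simulation configuration
#'
#' Describes a synthetic SNP-array study: array-density biallelic autosomal
#' SNPs with Hardy-Weinberg genotypes outside planted segments; per
#' individual, a Poisson number of autozygous segments with a short/long
#' log-normal length mixture (abundant segments around 0.7 Mb, rarer ones
#' around 6 Mb, echoing the short-dominated length spectrum of array
#' studies); optional genotyping error (heterozygous calls inside segments)
#' and missingness; and planted association regions whose carriers are
#' homozygous across the region and receive a trait effect. Phenotypes are
#' fixed effects + region effects + a GRM-correlated polygenic term +
#' residual noise.
#'
#' @param seed Integer seed; all randomness flows from it (mandatory).
#' @param n_samples Number of individuals.
#' @param n_chromosomes Number of autosomes simulated.
#' @param snps_per_chrom SNPs per chromosome.
#' @param mean_spacing_bp Mean inter-SNP spacing (array density ~4 kb).
#' @param maf_range Allele-frequency range, drawn uniformly.
#' @param segs_per_ind Poisson mean of background segments per individual.
#' @param seg_short_meanlog,seg_short_sdlog,seg_long_meanlog,seg_long_sdlog
#'   Log-normal length parameters of the short and long mixture components.
#' @param prob_long Mixture weight of the long component.
#' @param het_error_rate Probability a SNP inside a planted segment is
#'   mis-called heterozygous.
#' @param missing_rate Genome-wide missing-call probability.
#' @param assoc_regions Tibble (`chrom`, `start_bp`, `end_bp`,
#'   `carrier_freq`, `effect`) of planted association regions, or `NULL`.
#' @param farm_levels,year_levels,sex_levels Numbers of fixed-effect levels.
#' @param sigma_g2,sigma_e2 Polygenic and residual variance of the traits.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed, n_samples = 60L, n_chromosomes = 3L,
                       snps_per_chrom = 2000L, mean_spacing_bp = 4000,
                       maf_range = c(0.05, 0.5), segs_per_ind = 4,
                       seg_short_meanlog = log(7e5), seg_short_sdlog = 0.3,
                       seg_long_meanlog = log(6e6), seg_long_sdlog = 0.3,
                       prob_long = 0.15, het_error_rate = 0,
                       missing_rate = 0.002, assoc_regions = NULL,
                       farm_levels = 3L, year_levels = 4L, sex_levels = 2L,
                       sigma_g2 = 1, sigma_e2 = 1) {
  stopifnot(!missing(seed), is.numeric(seed), length(seed) == 1,
            het_error_rate >= 0, het_error_rate <= 1,
            missing_rate >= 0, missing_rate <= 1,
            sigma_g2 >= 0, sigma_e2 >= 0, prob_long >= 0, prob_long <= 1)
  structure(as.list(environment()), class = "sim_config")
}

#' Simulate genotypes with planted autozygous segments
#'
#' Positions are cumulative exponential spacings (mean `mean_spacing_bp`).
#' Outside planted segments each genotype is an independent Hardy-Weinberg
#' draw at the SNP's frequency. Inside a planted background segment the
#' individual is homozygous, the allele at each SNP drawn once by its
#' frequency (identity by descent of the individual's own two haplotypes).
#' Association-region carriers, sampled per region at the configured carrier
#' frequency, are instead homozygous for a single shared ancestral haplotype
#' drawn once per region — the footprint of selection that also creates
#' linkage disequilibrium across the region. Heterozygous errors and
#' missingness are overlaid last.
#'
#' @param config A [sim_config()].
#' @return List: `genotypes` (a [geno_matrix()]) and `truth` (list with
#'   `segments` tibble — planted background and association segments with
#'   realized SNP-boundary coordinates — and `region_carriers`).
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_samples
  samples <- sprintf("S%04d", seq_len(n))
  vars <- list(); freqs <- list()
  for (ch in seq_len(config$n_chromosomes)) {
    spacing <- pmax(1, round(rexp(config$snps_per_chrom, 1 / config$mean_spacing_bp)))
    pos <- cumsum(spacing)
    vars[[ch]] <- tibble(
      id = sprintf("snp%d_%d", ch, seq_along(pos)), chrom = ch,
      pos_bp = as.integer(pos), allele_a = "A", allele_b = "G"
    )
    freqs[[ch]] <- runif(config$snps_per_chrom, config$maf_range[1],
                         config$maf_range[2])
  }
  variants <- bind_rows(vars)
  p <- unlist(freqs)  # frequency of allele_b
  m <- nrow(variants)
  # HWE background: two independent allele draws per genotype
  calls <- matrix(rbinom(n * m, 2L, rep(p, each = n)), n, m)

  chrom_span <- vapply(vars, function(v) max(v$pos_bp), numeric(1))
  seg_rows <- list()
  plant <- function(i, ch, start_bp, len, kind) {
    vi <- which(variants$chrom == ch)
    pos <- variants$pos_bp[vi]
    inside <- which(pos >= start_bp & pos <= start_bp + len - 1)
    if (length(inside) == 0) return(NULL)
    idx <- vi[inside]
    hom <- 2L * rbinom(length(idx), 1L, p[idx])
    calls[i, idx] <<- hom
    tibble(sample_id = samples[i], chrom = ch,
           start_bp = pos[inside[1]], end_bp = pos[inside[length(inside)]],
           n_snps = length(idx), kind = kind)
  }
  for (i in seq_len(n)) {
    k <- rpois(1, config$segs_per_ind)
    if (k == 0) next
    for (s in seq_len(k)) {
      ch <- sample.int(config$n_chromosomes, 1)
      long <- runif(1) < config$prob_long
      len <- if (long) rlnorm(1, config$seg_long_meanlog, config$seg_long_sdlog)
      else rlnorm(1, config$seg_short_meanlog, config$seg_short_sdlog)
      len <- min(len, chrom_span[ch] - 1)
      start_bp <- runif(1, 1, chrom_span[ch] - len)
      seg_rows[[length(seg_rows) + 1L]] <- plant(i, ch, start_bp, len, "background")
    }
  }
  region_carriers <- list()
  if (!is.null(config$assoc_regions)) {
    ar <- as_tibble(config$assoc_regions)
    for (r in seq_len(nrow(ar))) {
      if (ar$chrom[r] > config$n_chromosomes ||
          ar$end_bp[r] > chrom_span[ar$chrom[r]]) {
        stop("association region outside the simulated SNP-covered span")
      }
      # carriers of an association region are autozygous for one shared
      # ancestral haplotype (a selection footprint), which is what generates
      # linkage disequilibrium across the region
      idx <- which(variants$chrom == ar$chrom[r] &
                     variants$pos_bp >= ar$start_bp[r] &
                     variants$pos_bp <= ar$end_bp[r])
      shared_hap <- 2L * rbinom(length(idx), 1L, p[idx])
      carriers <- which(runif(n) < ar$carrier_freq[r])
      for (i in carriers) {
        calls[i, idx] <- shared_hap
        seg_rows[[length(seg_rows) + 1L]] <- tibble(
          sample_id = samples[i], chrom = ar$chrom[r],
          start_bp = variants$pos_bp[idx[1]],
          end_bp = variants$pos_bp[idx[length(idx)]],
          n_snps = length(idx), kind = paste0("region", r)
        )
      }
      region_carriers[[r]] <- samples[carriers]
    }
  }
  # genotyping error: heterozygous mis-calls inside planted segments
  truth_segments <- bind_rows(seg_rows)
  if (config$het_error_rate > 0 && nrow(truth_segments) > 0) {
    for (r in seq_len(nrow(truth_segments))) {
      i <- match(truth_segments$sample_id[r], samples)
      idx <- which(variants$chrom == truth_segments$chrom[r] &
                     variants$pos_bp >= truth_segments$start_bp[r] &
                     variants$pos_bp <= truth_segments$end_bp[r])
      err <- idx[runif(length(idx)) < config$het_error_rate]
      if (length(err) > 0) calls[i, err] <- 1L
    }
  }
  if (config$missing_rate > 0) {
    calls[runif(n * m) < config$missing_rate] <- NA_integer_
  }
  g <- geno_matrix(calls, samples, variants)
  list(genotypes = g,
       truth = list(segments = truth_segments, region_carriers = region_carriers,
                    seed = config$seed))
}

#' Simulate phenotypes under the generative mixed model
#'
#' Traits are built as fixed effects (farm, year, sex plus the two
#' covariates) + planted region effects for carriers + a polygenic draw with
#' covariance `G * sigma_g2` (via the eigendecomposition of the realized
#' GRM, with negative eigenvalues clipped at zero) + independent
#' `N(0, sigma_e2)` noise. All four production traits (NMW, CW, ADG, LW)
#' are generated with the same design and independent polygenic/noise draws;
#' region effects apply to every trait.
#'
#' @param g The simulated [geno_matrix()].
#' @param truth Truth list from [simulate_genotypes()].
#' @param config The same [sim_config()].
#' @return List: `phenotypes` (tibble with design columns and traits) and
#'   `truth` (the input truth extended with `coefficients` and `polygenic`).
#' @export
simulate_phenotypes <- function(g, truth, config) {
  stopifnot(inherits(g, "geno_matrix"), inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  n <- length(g$samples)
  farm <- sample(paste0("farm", seq_len(config$farm_levels)), n, replace = TRUE)
  year <- sample(2008 + seq_len(config$year_levels), n, replace = TRUE)
  sex <- sample(c("M", "F")[seq_len(config$sex_levels)], n, replace = TRUE)
  wbf <- rnorm(n, 250, 25)
  fdays <- round(rnorm(n, 300, 20))
  farm_eff <- setNames(seq_len(config$farm_levels) * 10,
                       paste0("farm", seq_len(config$farm_levels)))
  year_eff <- setNames(seq_len(config$year_levels) * 5,
                       2008 + seq_len(config$year_levels))
  sex_eff <- setNames(c(0, -15)[seq_len(config$sex_levels)], c("M", "F"))
  b_wbf <- 0.8; b_fdays <- 0.5
  fixed_part <- farm_eff[farm] + year_eff[as.character(year)] + sex_eff[sex] +
    b_wbf * wbf + b_fdays * fdays
  region_part <- numeric(n)
  if (!is.null(config$assoc_regions) && length(truth$region_carriers) > 0) {
    ar <- as_tibble(config$assoc_regions)
    for (r in seq_len(nrow(ar))) {
      region_part <- region_part +
        ar$effect[r] * (g$samples %in% truth$region_carriers[[r]])
    }
  }
  # chance-monomorphic SNPs are silently dropped here; QC removes them anyway
  G <- suppressWarnings(build_grm(g))
  eg <- eigen(G, symmetric = TRUE)
  L <- eg$vectors %*% diag(sqrt(pmax(eg$values, 0)))
  traits <- c("NMW", "CW", "ADG", "LW")
  ph <- tibble(sample_id = g$samples, farm = farm, year = year, sex = sex,
               weight_before_fattening = wbf, fattening_days = fdays)
  poly <- list()
  for (tr in traits) {
    u <- sqrt(config$sigma_g2) * drop(L %*% rnorm(n))
    e <- rnorm(n, 0, sqrt(config$sigma_e2))
    ph[[tr]] <- unname(fixed_part + region_part + u + e)
    poly[[tr]] <- u
  }
  truth$coefficients <- list(farm = farm_eff, year = year_eff, sex = sex_eff,
                             weight_before_fattening = b_wbf,
                             fattening_days = b_fdays)
  truth$polygenic <- poly
  list(phenotypes = ph, truth = truth)
}

#' Write a complete synthetic fixture to disk
#'
#' Generates a seeded study of one of two sizes — "small" (60 individuals,
#' 3 chromosomes of 2,000 SNPs; seconds) or "medium" (600 individuals, 5
#' chromosomes of 10,000 SNPs; minutes) — and writes the PED/MAP genotypes,
#' the phenotype TSV and the truth tables.
#'
#' @param dir Output directory (created if needed).
#' @param size "small" or "medium".
#' @param seed Integer seed.
#' @param assoc_regions Optional planted association regions (see
#'   [sim_config()]); by default one region of ~2 Mb at carrier frequency
#'   0.3 with effect 0.5 trait units on chromosome 1.
#' @return Invisibly, a named list of the file paths written.
#' @export
sim_fixture <- function(dir, size = c("small", "medium"), seed = 1L,
                        assoc_regions = NULL) {
  size <- match.arg(size)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- if (size == "small") {
    sim_config(seed = seed, n_samples = 60L, n_chromosomes = 3L,
               snps_per_chrom = 2000L, assoc_regions = assoc_regions)
  } else {
    sim_config(seed = seed, n_samples = 600L, n_chromosomes = 5L,
               snps_per_chrom = 10000L, assoc_regions = assoc_regions)
  }
  if (is.null(assoc_regions)) {
    cfg$assoc_regions <- tibble(chrom = 1L, start_bp = 1e6, end_bp = 3e6,
                                carrier_freq = 0.3, effect = 0.5)
  }
  sim <- simulate_genotypes(cfg)
  phe <- simulate_phenotypes(sim$genotypes, sim$truth, cfg)
  paths <- list(
    ped = file.path(dir, "genotypes.ped"), map = file.path(dir, "genotypes.map"),
    phenotypes = file.path(dir, "phenotypes.tsv"),
    truth_segments = file.path(dir, "truth_segments.tsv"),
    truth_carriers = file.path(dir, "truth_region_carriers.tsv")
  )
  write_pedmap(sim$genotypes, paths$ped, paths$map)
  utils::write.table(phe$phenotypes, paths$phenotypes, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(cbind(seed = seed, sim$truth$segments), paths$truth_segments,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  carriers <- bind_rows(purrr::imap(sim$truth$region_carriers, function(ids, r) {
    if (length(ids) == 0) return(NULL)
    tibble(region = r, sample_id = ids)
  }))
  utils::write.table(carriers, paths$truth_carriers, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(paths)
}
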