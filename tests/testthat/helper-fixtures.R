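# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, builder(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# the standard small synthetic study: 60 x 3 x 2000, one planted association
# region, defaults elsewhere
small_study <- function() {
  cached("small_study", function() {
    cfg <- sim_config(seed = 20260919L,
                      assoc_regions = tibble::tibble(
                        chrom = 1L, start_bp = 1e6, end_bp = 3e6,
                        carrier_freq = 0.3, effect = 0.5))
    sim <- simulate_genotypes(cfg)
    phe <- simulate_phenotypes(sim$genotypes, sim$truth, cfg)
    segs <- detect_roh(sim$genotypes)
    list(cfg = cfg, g = sim$genotypes, truth = phe$truth,
         pheno = phe$phenotypes, segments = segs)
  })
}

# a tiny deterministic genotype matrix for parser tests
toy_geno <- function(n = 4, m = 30, seed = 42) {
  set.seed(seed)
  calls <- matrix(sample(c(0L, 1L, 2L, NA), n * m, replace = TRUE,
                         prob = c(0.4, 0.2, 0.35, 0.05)), n, m)
  variants <- tibble::tibble(
    id = paste0("v", seq_len(m)),
    chrom = rep(1:2, length.out = m)[order(rep(1:2, length.out = m))],
    pos_bp = as.integer(rep(seq(1000, by = 5000, length.out = ceiling(m / 2)),
                            2)[seq_len(m)]),
    allele_a = "A", allele_b = "C"
  )
  # ensure unique positions per chromosome
  variants$pos_bp <- variants$pos_bp + as.integer(variants$chrom)
  geno_matrix(calls, paste0("I", seq_len(n)), variants)
}

# genotype vector helpers for scanner tests: hom runs with inserted events
hom_calls <- function(n) rep(0L, n)

# random scanner-stress matrix: mixture of planted runs and noisy background
fuzz_geno_chrom <- function(n_snps, seed, spacing = 4000) {
  set.seed(seed)
  pos <- cumsum(pmax(1, round(rexp(n_snps, 1 / spacing))))
  p <- runif(n_snps, 0.05, 0.5)
  calls <- rbinom(n_snps, 2L, p)
  # plant 0-3 homozygous runs
  for (k in seq_len(sample(0:3, 1))) {
    len <- min(sample(80:500, 1), n_snps)
    st <- sample(n_snps - len + 1L, 1)
    calls[st:(st + len - 1)] <- 2L * rbinom(len, 1L, p[st:(st + len - 1)])
  }
  # sprinkle hets and missing
  calls[runif(n_snps) < 0.01] <- 1L
  calls <- as.integer(calls)
  calls[runif(n_snps) < 0.005] <- NA_integer_
  list(calls = calls, pos = pos)
}
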