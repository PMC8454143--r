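#' Scanner parameters for ROH detection
#'
#' Defaults reproduce the sliding-window screen and the six segment criteria
#' used throughout the package: a 50-SNP window allowing at most 1
#' heterozygote (and, by convention, up to 5 missing calls, the screening
#' tool's default); segments must be at least 500 kb long, contain at least
#' 100 SNPs at an average density of at most 50 kb per SNP, contain no
#' inter-SNP gap above 100 kb, and carry at most 1 heterozygous and 2 missing
#' calls. A SNP is a candidate when at least 5% of the windows covering it
#' are homozygous.
#'
#' @param window_snps Sliding window size in SNPs.
#' @param window_max_het Maximum heterozygotes per passing window.
#' @param window_max_missing Maximum missing calls per passing window.
#' @param window_hit_threshold Minimum fraction of passing windows covering a
#'   SNP for it to seed/extend a run.
#' @param min_length_bp Minimum segment length (bp).
#' @param min_snps Minimum SNPs per segment.
#' @param min_density_bp_per_snp Maximum average bp per SNP within a segment.
#' @param max_gap_bp Maximum gap between consecutive SNPs within a segment.
#' @param roh_max_het Maximum heterozygous calls within a segment.
#' @param roh_max_missing Maximum missing calls within a segment.
#' @return A list of class `roh_params`.
#' @export
roh_params <- function(window_snps = 50L, window_max_het = 1L,
                       window_max_missing = 5L, window_hit_threshold = 0.05,
                       min_length_bp = 5e5, min_snps = 100L,
                       min_density_bp_per_snp = 5e4, max_gap_bp = 1e5,
                       roh_max_het = 1L, roh_max_missing = 2L) {
  p <- list(window_snps = as.integer(window_snps),
            window_max_het = as.integer(window_max_het),
            window_max_missing = as.integer(window_max_missing),
            window_hit_threshold = window_hit_threshold,
            min_length_bp = min_length_bp, min_snps = as.integer(min_snps),
            min_density_bp_per_snp = min_density_bp_per_snp,
            max_gap_bp = max_gap_bp, roh_max_het = as.integer(roh_max_het),
            roh_max_missing = as.integer(roh_max_missing))
  stopifnot(p$window_snps > 0, p$window_max_het >= 0, p$window_max_missing >= 0,
            p$window_hit_threshold > 0, p$window_hit_threshold <= 1,
            p$min_length_bp > 0, p$min_snps > 0, p$min_density_bp_per_snp > 0,
            p$max_gap_bp > 0, p$roh_max_het >= 0, p$roh_max_missing >= 0)
  structure(p, class = "roh_params")
}

# sliding-window sum of a 0/1 vector, window w: returns n-w+1 values
.window_sums <- function(x, w) {
  cs <- c(0, cumsum(x))
  cs[(w + 1):length(cs)] - cs[1:(length(cs) - w)]
}

#' Per-SNP homozygous-window hit rates
#'
#' Slides a `window_snps`-wide window along one individual's calls on one
#' chromosome; a window is homozygous when it contains at most
#' `window_max_het` heterozygous and `window_max_missing` missing calls.
#' Each SNP's hit rate is the fraction of windows covering it that are
#' homozygous. Chromosomes shorter than one window have no windows and every
#' rate is 0.
#'
#' @param calls Integer vector of dosage calls (0/1/2/NA) in map order.
#' @param params A [roh_params()] list.
#' @return Numeric vector of hit rates in `[0, 1]`, one per SNP.
#' @export
window_hit_rates <- function(calls, params = roh_params()) {
  n <- length(calls)
  w <- params$window_snps
  if (n < w) return(numeric(n))
  het <- as.numeric(!is.na(calls) & calls == 1L)
  mis <- as.numeric(is.na(calls))
  pass <- as.numeric(.window_sums(het, w) <= params$window_max_het &
                       .window_sums(mis, w) <= params$window_max_missing)
  nw <- n - w + 1L
  # SNP i is covered by windows max(1, i-w+1) .. min(i, nw)
  cp <- c(0, cumsum(pass))
  i <- seq_len(n)
  lo <- pmax(1L, i - w + 1L)
  hi <- pmin(i, nw)
  hits <- cp[hi + 1L] - cp[lo]
  hits / (hi - lo + 1L)
}

#' Call ROH segments for one individual
#'
#' Candidate SNPs are those whose window hit rate reaches
#' `window_hit_threshold`. Maximal stretches of candidate SNPs are split at
#' inter-SNP gaps above `max_gap_bp`, then runs are grown greedily
#' left-to-right within each stretch: a run starts at the first homozygous
#' non-missing SNP, extends as far as the segment heterozygote/missing
#' allowances permit, and is trimmed to end on a homozygous non-missing SNP.
#' Runs failing the minimum length, SNP count or density criteria are
#' discarded; scanning resumes after each run. Segment coordinates span the
#' first to last SNP (1-based inclusive).
#'
#' @param calls Integer vector of one sample's calls across all variants of
#'   `variants` (same order).
#' @param variants Variant map tibble (`id`, `chrom`, `pos_bp`, ...), sorted
#'   by (chrom, pos_bp).
#' @param params A [roh_params()] list.
#' @param sample_id Sample id recorded in the output.
#' @return Tibble of segments: `sample_id`, `chrom`, `start_bp`, `end_bp`,
#'   `length_bp`, `n_snps`, `n_het`, `n_missing`, `size_class`.
#' @export
call_roh <- function(calls, variants, params = roh_params(), sample_id = "S1") {
  if (length(calls) != nrow(variants)) {
    stop("calls and variants are misaligned: ", length(calls), " calls vs ",
         nrow(variants), " variants")
  }
  out <- lapply(split(seq_len(nrow(variants)), variants$chrom), function(idx) {
    .call_roh_chrom(calls[idx], variants$pos_bp[idx], params)
  })
  chroms <- as.integer(names(out))
  segs <- bind_rows(lapply(seq_along(out), function(k) {
    if (nrow(out[[k]]) == 0) return(NULL)
    mutate(out[[k]], chrom = chroms[k])
  }))
  if (is.null(segs) || nrow(segs) == 0) return(empty_roh_tbl())
  segs |>
    mutate(sample_id = sample_id,
           length_bp = .data$end_bp - .data$start_bp + 1,
           size_class = classify_size(.data$length_bp)) |>
    select("sample_id", "chrom", "start_bp", "end_bp", "length_bp",
           "n_snps", "n_het", "n_missing", "size_class") |>
    arrange(.data$chrom, .data$start_bp)
}

empty_roh_tbl <- function() {
  tibble(sample_id = character(), chrom = integer(), start_bp = numeric(),
         end_bp = numeric(), length_bp = numeric(), n_snps = integer(),
         n_het = integer(), n_missing = integer(),
         size_class = factor(character(), levels = c("Small", "Medium", "Large")))
}

# scan one sample x one chromosome; returns start_bp/end_bp/n_snps/n_het/n_missing
.call_roh_chrom <- function(calls, pos, params) {
  empty <- tibble(start_bp = numeric(), end_bp = numeric(), n_snps = integer(),
                  n_het = integer(), n_missing = integer())
  n <- length(calls)
  if (n == 0) return(empty)
  rates <- window_hit_rates(calls, params)
  cand <- rates >= params$window_hit_threshold
  if (!any(cand)) return(empty)
  r <- rle(cand)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  rows <- list()
  het <- !is.na(calls) & calls == 1L
  mis <- is.na(calls)
  hom <- !het & !mis
  cum_het <- c(0L, cumsum(het))
  cum_mis <- c(0L, cumsum(mis))
  for (k in which(r$values)) {
    # split the candidate stretch at large inter-SNP gaps
    idx <- starts[k]:ends[k]
    gaps <- diff(pos[idx])
    cut_after <- which(gaps > params$max_gap_bp)
    sub_start <- c(idx[1L], idx[cut_after + 1L])
    sub_end <- c(idx[cut_after], idx[length(idx)])
    for (s in seq_along(sub_start)) {
      rows[[length(rows) + 1L]] <-
        .greedy_runs(sub_start[s], sub_end[s], pos, hom, cum_het, cum_mis, params)
    }
  }
  rows <- bind_rows(rows)
  if (nrow(rows) == 0) empty else rows
}

# greedy left-to-right maximal runs within [lo, hi] under the segment caps
.greedy_runs <- function(lo, hi, pos, hom, cum_het, cum_mis, params) {
  out <- list()
  i <- lo
  repeat {
    while (i <= hi && !hom[i]) i <- i + 1L
    if (i > hi) break
    # farthest j with het count <= cap and missing count <= cap on [i, j]
    j_het <- .cap_limit(cum_het, i, hi, params$roh_max_het)
    j_mis <- .cap_limit(cum_mis, i, hi, params$roh_max_missing)
    j <- min(j_het, j_mis)
    while (j > i && !hom[j]) j <- j - 1L
    n_snps <- j - i + 1L
    len <- pos[j] - pos[i] + 1
    if (len >= params$min_length_bp && n_snps >= params$min_snps &&
        len / n_snps <= params$min_density_bp_per_snp) {
      out[[length(out) + 1L]] <- tibble(
        start_bp = pos[i], end_bp = pos[j], n_snps = n_snps,
        n_het = cum_het[j + 1L] - cum_het[i],
        n_missing = cum_mis[j + 1L] - cum_mis[i]
      )
    }
    i <- j + 1L
  }
  bind_rows(out)
}

# largest j in [i, hi] with cum[j+1]-cum[i] <= cap (cum is 0-prefixed cumsum)
.cap_limit <- function(cum, i, hi, cap) {
  target <- cum[i] + cap
  # find last index j with cum[j+1] <= target via binary search
  lo <- i; hi2 <- hi
  if (cum[hi + 1L] <= target) return(hi)
  while (lo < hi2) {
    mid <- (lo + hi2 + 1L) %/% 2L
    if (cum[mid + 1L] <= target) lo <- mid else hi2 <- mid - 1L
  }
  lo
}

#' Classify ROH segments by length
#'
#' Size classes: Small covers 0.5 Mb up to (but excluding) 1 Mb, Medium 1 Mb
#' to 5 Mb inclusive, Large above 5 Mb. The shared endpoints of the published
#' class ranges are resolved by assigning 1 Mb to Medium and 5 Mb to Medium.
#'
#' @param length_bp Numeric vector of segment lengths (>= 500 kb).
#' @return Factor with levels Small, Medium, Large.
#' @export
classify_size <- function(length_bp) {
  if (any(length_bp < 5e5)) stop("ROH segments are at least 500 kb by definition")
  cls <- ifelse(length_bp < 1e6, "Small", ifelse(length_bp <= 5e6, "Medium", "Large"))
  factor(cls, levels = c("Small", "Medium", "Large"))
}

#' Detect ROH across all individuals of a genotype matrix
#'
#' Runs [call_roh()] for every sample and chromosome and returns the combined
#' segment table, ordered by (sample, chromosome, start).
#'
#' @param g A quality-controlled [geno_matrix()].
#' @param params A [roh_params()] list.
#' @return Tibble of segments (see [call_roh()]).
#' @export
detect_roh <- function(g, params = roh_params()) {
  stopifnot(inherits(g, "geno_matrix"))
  segs <- purrr::map(seq_along(g$samples), function(i) {
    call_roh(g$calls[i, ], g$variants, params, sample_id = g$samples[i])
  })
  out <- bind_rows(segs)
  if (nrow(out) == 0) return(empty_roh_tbl())
  out |> mutate(sample_ord = match(.data$sample_id, g$samples)) |>
    arrange(.data$sample_ord, .data$chrom, .data$start_bp) |>
    select(-"sample_ord")
}
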