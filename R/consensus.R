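#' Per-SNP ROH incidence track
#'
#' For every SNP of the map, the number and fraction of individuals whose
#' ROH span its position. Within one individual segments never overlap, so
#' the carrier count is a plain segment cover count.
#'
#' @param segments ROH tibble from [detect_roh()].
#' @param g The [geno_matrix()] the segments were called on.
#' @return Tibble: `chrom`, `pos_bp`, `n_carriers`, `rate`.
#' @export
snp_incidence <- function(segments, g) {
  stopifnot(inherits(g, "geno_matrix"))
  v <- g$variants
  n_samples <- length(g$samples)
  counts <- integer(nrow(v))
  for (ch in unique(segments$chrom)) {
    vi <- which(v$chrom == ch)
    pos <- v$pos_bp[vi]
    s <- segments[segments$chrom == ch, ]
    # difference-array cover count over SNP indices
    first <- findInterval(s$start_bp - 1, pos) + 1L  # first SNP >= start
    last <- findInterval(s$end_bp, pos)              # last SNP <= end
    ok <- first <= last
    d <- integer(length(pos) + 1L)
    d_add <- tabulate(first[ok], nbins = length(pos))
    d_sub <- tabulate(last[ok] + 1L, nbins = length(pos) + 1L)
    counts[vi] <- cumsum(d_add - d_sub[seq_along(pos)])
  }
  tibble(chrom = v$chrom, pos_bp = v$pos_bp, n_carriers = counts,
         rate = counts / n_samples)
}

#' ROH islands: runs of SNPs above an incidence threshold
#'
#' Maximal runs of consecutive SNPs whose ROH rate strictly exceeds
#' `rate_threshold`; runs on the same chromosome separated by at most
#' `max_gap_bp` are merged into one island.
#'
#' @param track Incidence tibble from [snp_incidence()].
#' @param rate_threshold Strict lower bound on the rate (default 0.2).
#' @param max_gap_bp Merge distance between neighbouring runs.
#' @return Tibble: `chrom`, `start_bp`, `end_bp`, `n_snps`, `max_rate`.
#' @export
find_islands <- function(track, rate_threshold = 0.2, max_gap_bp = 1e5) {
  stopifnot(nrow(track) > 0)
  out <- lapply(split(track, track$chrom), function(tr) {
    tr <- tr[order(tr$pos_bp), ]
    above <- tr$rate > rate_threshold
    if (!any(above)) return(NULL)
    r <- rle(above)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    runs <- data.frame(s = starts[r$values], e = ends[r$values])
    # merge runs whose bp gap is small
    merged <- runs[1, , drop = FALSE]
    if (nrow(runs) > 1) for (i in 2:nrow(runs)) {
      gap <- tr$pos_bp[runs$s[i]] - tr$pos_bp[merged$e[nrow(merged)]]
      if (gap <= max_gap_bp) {
        merged$e[nrow(merged)] <- runs$e[i]
      } else {
        merged <- rbind(merged, runs[i, ])
      }
    }
    tibble(
      chrom = tr$chrom[1],
      start_bp = tr$pos_bp[merged$s], end_bp = tr$pos_bp[merged$e],
      n_snps = merged$e - merged$s + 1L,
      max_rate = vapply(seq_len(nrow(merged)),
                        function(i) max(tr$rate[merged$s[i]:merged$e[i]]),
                        numeric(1))
    )
  })
  out <- bind_rows(out)
  if (nrow(out) == 0) {
    return(tibble(chrom = integer(), start_bp = numeric(), end_bp = numeric(),
                  n_snps = integer(), max_rate = numeric()))
  }
  arrange(out, .data$chrom, .data$start_bp)
}

#' Build consensus ROH regions
#'
#' Segments on a chromosome are pooled by transitive (single-linkage)
#' positional overlap; each pool's consensus is the intersection interval of
#' its members. Pools whose members share no common interval are split
#' greedily left-to-right into sub-pools with non-empty intersections.
#' Consensus regions containing fewer than `min_snps` SNPs of the map are
#' dropped. The carrier set of a region is every sample with an ROH fully
#' covering its interval (pool members always qualify, since the interval is
#' their intersection; after a pool split, members of a neighbouring sub-pool
#' may qualify too), so `frequency` always equals the population mean of
#' [carrier_status()].
#'
#' @param segments ROH tibble from [detect_roh()].
#' @param g The [geno_matrix()] (supplies the SNP map and sample count).
#' @param min_snps Minimum SNPs inside a consensus region (default 5).
#' @return Tibble: `region_id`, `chrom`, `start_bp`, `end_bp`, `n_snps`,
#'   `n_carriers`, `frequency`, `carrier_ids` (list-column).
#' @export
build_consensus <- function(segments, g, min_snps = 5L) {
  stopifnot(inherits(g, "geno_matrix"))
  n_samples <- length(g$samples)
  v <- g$variants
  res <- lapply(split(segments, segments$chrom), function(s) {
    s <- s[order(s$start_bp, s$end_bp), ]
    pools <- list()
    # transitive overlap pooling on sorted intervals
    cur <- 1L; cur_max_end <- s$end_bp[1]
    start_i <- 1L
    if (nrow(s) > 1) for (i in 2:nrow(s)) {
      if (s$start_bp[i] <= cur_max_end) {
        cur_max_end <- max(cur_max_end, s$end_bp[i])
      } else {
        pools[[length(pools) + 1L]] <- start_i:(i - 1L)
        start_i <- i; cur_max_end <- s$end_bp[i]
      }
    }
    pools[[length(pools) + 1L]] <- start_i:nrow(s)
    rows <- list()
    for (p in pools) {
      sp <- s[p, ]
      # greedy left-to-right split into sub-pools with non-empty intersection
      lo <- sp$start_bp[1]; hi <- sp$end_bp[1]; members <- 1L
      flush <- function(lo, hi, members) {
        tibble(chrom = sp$chrom[1], start_bp = lo, end_bp = hi,
               carrier_ids = list(sort(unique(sp$sample_id[members]))))
      }
      if (nrow(sp) > 1) for (i in 2:nrow(sp)) {
        if (sp$start_bp[i] <= hi) {
          lo <- max(lo, sp$start_bp[i]); hi <- min(hi, sp$end_bp[i])
          members <- c(members, i)
        } else {
          rows[[length(rows) + 1L]] <- flush(lo, hi, members)
          lo <- sp$start_bp[i]; hi <- sp$end_bp[i]; members <- i
        }
      }
      rows[[length(rows) + 1L]] <- flush(lo, hi, members)
    }
    bind_rows(rows)
  })
  res <- bind_rows(res)
  if (nrow(res) == 0) {
    return(tibble(region_id = character(), chrom = integer(),
                  start_bp = numeric(), end_bp = numeric(), n_snps = integer(),
                  n_carriers = integer(), frequency = numeric(),
                  carrier_ids = list()))
  }
  res <- res |>
    mutate(n_snps = purrr::map_int(seq_len(nrow(res)), function(i) {
      sum(v$chrom == res$chrom[i] & v$pos_bp >= res$start_bp[i] &
            v$pos_bp <= res$end_bp[i])
    })) |>
    filter(.data$n_snps >= min_snps) |>
    arrange(.data$chrom, .data$start_bp)
  # carriers: full coverage of the interval, consistent with carrier_status()
  res |>
    mutate(carrier_ids = purrr::map(seq_len(nrow(res)), function(i) {
      hit <- segments$chrom == res$chrom[i] &
        segments$start_bp <= res$start_bp[i] &
        segments$end_bp >= res$end_bp[i]
      sort(unique(segments$sample_id[hit]))
    }),
    region_id = sprintf("R%d_%d_%d", .data$chrom, .data$start_bp, .data$end_bp),
    n_carriers = purrr::map_int(.data$carrier_ids, length),
    frequency = .data$n_carriers / n_samples) |>
    select("region_id", "chrom", "start_bp", "end_bp", "n_snps", "n_carriers",
           "frequency", "carrier_ids")
}

#' Carrier status of samples for consensus regions
#'
#' A sample carries a consensus region when one of its ROH fully covers the
#' region's interval. Returns a logical matrix, samples by regions.
#'
#' @param consensus Tibble from [build_consensus()].
#' @param segments ROH tibble.
#' @param samples Character vector of sample ids (rows of the result).
#' @return Logical matrix `length(samples) x nrow(consensus)` with dimnames.
#' @export
carrier_matrix <- function(consensus, segments, samples) {
  out <- matrix(FALSE, length(samples), nrow(consensus),
                dimnames = list(samples, consensus$region_id))
  if (nrow(consensus) == 0 || nrow(segments) == 0) return(out)
  for (j in seq_len(nrow(consensus))) {
    hit <- segments$chrom == consensus$chrom[j] &
      segments$start_bp <= consensus$start_bp[j] &
      segments$end_bp >= consensus$end_bp[j]
    ids <- intersect(unique(segments$sample_id[hit]), samples)
    out[ids, j] <- TRUE
  }
  out
}

#' Carrier status of one sample for one consensus region
#'
#' @param consensus One-row tibble (a row of [build_consensus()] output).
#' @param segments ROH tibble.
#' @param sample_id One sample id.
#' @return `TRUE` iff the sample has an ROH fully covering the region.
#' @export
carrier_status <- function(consensus, segments, sample_id) {
  stopifnot(nrow(consensus) == 1)
  any(segments$sample_id == sample_id &
        segments$chrom == consensus$chrom &
        segments$start_bp <= consensus$start_bp &
        segments$end_bp >= consensus$end_bp)
}
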