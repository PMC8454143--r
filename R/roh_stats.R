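#' Per-individual ROH summaries and FROH
#'
#' One row per sample of the genotype matrix (samples without any ROH are
#' retained with zeros). `froh` is the fraction of the SNP-covered autosomal
#' genome inside the individual's ROH; the denominator is the sum over
#' chromosomes of (last SNP position - first SNP position + 1), which makes
#' the coefficient self-contained on the genotyped span rather than the
#' assembly length.
#'
#' @param segments ROH tibble from [detect_roh()].
#' @param g The [geno_matrix()] the segments were called on.
#' @return Tibble: `sample_id`, `n_roh`, `total_length_bp`, per-class length
#'   columns (`length_small_bp`, `length_medium_bp`, `length_large_bp`),
#'   `froh`.
#' @export
summarize_individuals <- function(segments, g) {
  stopifnot(inherits(g, "geno_matrix"))
  unknown <- setdiff(unique(segments$sample_id), g$samples)
  if (length(unknown) > 0) {
    stop("segment(s) reference unknown sample(s): ",
         paste(head(unknown, 3), collapse = ", "))
  }
  covered <- covered_length(g)
  base <- tibble(sample_id = g$samples)
  if (nrow(segments) == 0) {
    return(mutate(base, n_roh = 0L, total_length_bp = 0, length_small_bp = 0,
                  length_medium_bp = 0, length_large_bp = 0, froh = 0))
  }
  per_class <- segments |>
    mutate(size_class = factor(.data$size_class, levels = c("Small", "Medium", "Large"))) |>
    group_by(.data$sample_id, .data$size_class, .drop = FALSE) |>
    summarise(len = sum(.data$length_bp), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "size_class", values_from = "len",
                       values_fill = 0) |>
    rename(length_small_bp = "Small", length_medium_bp = "Medium",
           length_large_bp = "Large")
  totals <- segments |>
    group_by(.data$sample_id) |>
    summarise(n_roh = dplyr::n(), total_length_bp = sum(.data$length_bp),
              .groups = "drop")
  base |>
    left_join(totals, by = "sample_id") |>
    left_join(per_class, by = "sample_id") |>
    mutate(dplyr::across(dplyr::where(is.numeric), ~ tidyr::replace_na(.x, 0)),
           n_roh = as.integer(.data$n_roh),
           froh = .data$total_length_bp / covered)
}

#' SNP-covered autosome length of a genotype matrix
#'
#' @param g A [geno_matrix()].
#' @return Total covered length in bp (sum of per-chromosome first-to-last
#'   SNP spans, inclusive).
#' @export
covered_length <- function(g) {
  v <- g$variants
  sum(tapply(v$pos_bp, v$chrom, function(p) max(p) - min(p) + 1))
}

#' Per-chromosome ROH counts and total lengths
#'
#' @param segments ROH tibble from [detect_roh()].
#' @param g Optional [geno_matrix()]; when given, chromosomes without
#'   segments are included with zero counts.
#' @return Tibble: `chrom`, `n_roh`, `total_length_bp`, ordered by chromosome.
#' @export
summarize_chromosomes <- function(segments, g = NULL) {
  out <- segments |>
    group_by(.data$chrom) |>
    summarise(n_roh = dplyr::n(), total_length_bp = sum(.data$length_bp),
              .groups = "drop")
  if (!is.null(g)) {
    out <- tibble(chrom = sort(unique(g$variants$chrom))) |>
      left_join(out, by = "chrom") |>
      mutate(n_roh = as.integer(tidyr::replace_na(.data$n_roh, 0L)),
             total_length_bp = tidyr::replace_na(.data$total_length_bp, 0))
  }
  arrange(out, .data$chrom)
}

#' Correlation between per-individual ROH count and total length
#'
#' Pearson correlation (with the usual t-based two-sided p) between the
#' number of ROH per individual and their summed length, optionally within
#' one size class.
#'
#' @param summaries Tibble from [summarize_individuals()].
#' @param segments Optional segment tibble; required when `by_class` is given.
#' @param by_class `NULL` (all segments) or one of "Small", "Medium", "Large".
#' @return Tibble with `class`, `r`, `p_value`, `n`.
#' @export
count_length_correlation <- function(summaries, segments = NULL, by_class = NULL) {
  if (is.null(by_class)) {
    x <- summaries$n_roh
    y <- summaries$total_length_bp
    label <- "all"
  } else {
    stopifnot(!is.null(segments), by_class %in% c("Small", "Medium", "Large"))
    cls <- segments |>
      filter(.data$size_class == by_class) |>
      group_by(.data$sample_id) |>
      summarise(n_roh = dplyr::n(), total_length_bp = sum(.data$length_bp),
                .groups = "drop")
    full <- tibble(sample_id = summaries$sample_id) |>
      left_join(cls, by = "sample_id") |>
      mutate(dplyr::across(dplyr::where(is.numeric), ~ tidyr::replace_na(.x, 0)))
    x <- full$n_roh
    y <- full$total_length_bp
    label <- by_class
  }
  if (length(x) < 3) stop("need at least 3 individuals")
  if (var(x) == 0 || var(y) == 0) stop("correlation undefined: zero variance")
  ct <- cor.test(x, y, method = "pearson")
  tibble(class = label, r = unname(ct$estimate), p_value = ct$p.value,
         n = length(x))
}

#' Genome-wide union length of ROH
#'
#' Length of the union, over all individuals, of ROH intervals — the total
#' span of the genome touched by at least one ROH.
#'
#' @param segments ROH tibble.
#' @return Total union length in bp.
#' @export
roh_union_length <- function(segments) {
  if (nrow(segments) == 0) return(0)
  sum(vapply(split(segments, segments$chrom), function(s) {
    s <- s[order(s$start_bp), ]
    tot <- 0; cur_s <- s$start_bp[1]; cur_e <- s$end_bp[1]
    if (nrow(s) > 1) for (i in 2:nrow(s)) {
      if (s$start_bp[i] <= cur_e + 1) {
        cur_e <- max(cur_e, s$end_bp[i])
      } else {
        tot <- tot + (cur_e - cur_s + 1)
        cur_s <- s$start_bp[i]; cur_e <- s$end_bp[i]
      }
    }
    tot + (cur_e - cur_s + 1)
  }, numeric(1)))
}
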