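#' Pearson correlation between per-individual ROH burden and a trait
#'
#' Correlates the summed ROH length per individual (optionally restricted to
#' one size class) with an adjusted trait.
#'
#' @param summaries Tibble from [summarize_individuals()].
#' @param adjusted Tibble from [adjust_phenotypes()].
#' @param trait Trait column name in `adjusted`.
#' @param segments Segment tibble; required for class-restricted burdens.
#' @param by_class `NULL` or one of "Small", "Medium", "Large".
#' @return Tibble with `trait`, `class`, `r`, `p_value`, `n`.
#' @export
pearson_roh_trait <- function(summaries, adjusted, trait, segments = NULL,
                              by_class = NULL) {
  stopifnot(trait %in% names(adjusted))
  if (is.null(by_class)) {
    burden <- summaries |> select("sample_id", burden = "total_length_bp")
    label <- "all"
  } else {
    stopifnot(!is.null(segments))
    burden <- segments |>
      filter(.data$size_class == by_class) |>
      group_by(.data$sample_id) |>
      summarise(burden = sum(.data$length_bp), .groups = "drop")
    burden <- tibble(sample_id = summaries$sample_id) |>
      left_join(burden, by = "sample_id") |>
      mutate(burden = tidyr::replace_na(.data$burden, 0))
    label <- by_class
  }
  d <- burden |>
    left_join(select(adjusted, "sample_id", value = dplyr::all_of(trait)),
              by = "sample_id") |>
    filter(!is.na(.data$value))
  if (nrow(d) < 3) stop("need at least 3 matched individuals")
  if (var(d$burden) == 0 || var(d$value) == 0) {
    stop("correlation undefined: zero variance")
  }
  ct <- cor.test(d$burden, d$value, method = "pearson")
  tibble(trait = trait, class = label, r = unname(ct$estimate),
         p_value = ct$p.value, n = nrow(d))
}

#' Split the population into extreme phenotype groups
#'
#' The `n` individuals with the highest adjusted trait values form the high
#' group and the `n` lowest the low group; ties are broken by sample id so
#' the split is deterministic.
#'
#' @param adjusted Tibble from [adjust_phenotypes()].
#' @param trait Trait column name.
#' @param n Group size (default 300, the study design).
#' @return Tibble: `sample_id`, `group` ("high"/"low"), `value`.
#' @export
split_extremes <- function(adjusted, trait, n = 300L) {
  stopifnot(trait %in% names(adjusted))
  d <- adjusted |>
    select("sample_id", value = dplyr::all_of(trait)) |>
    filter(!is.na(.data$value))
  if (2L * n > nrow(d)) {
    stop(sprintf("2n = %d exceeds the %d phenotyped individuals", 2L * n, nrow(d)))
  }
  if (length(unique(d$value)) == 1L) {
    warning("all trait values tied; groups determined by sample id only")
  }
  d <- arrange(d, desc(.data$value), .data$sample_id)
  bind_rows(
    mutate(head(d, n), group = "high"),
    mutate(tail(d, n), group = "low") |> arrange(.data$value, .data$sample_id)
  )
}

#' Wilcoxon rank-sum test between two groups
#'
#' Exact two-sided p when the smaller group has at most 10 observations and
#' no ties are present; otherwise a normal approximation with tie and
#' continuity corrections.
#'
#' @param x,y Numeric vectors (e.g. total ROH length in the high and low
#'   groups).
#' @return Two-sided p-value.
#' @export
wilcoxon_ranksum <- function(x, y) {
  stopifnot(length(x) > 0, length(y) > 0)
  use_exact <- min(length(x), length(y)) <= 10 && !anyDuplicated(c(x, y))
  suppressWarnings(
    wilcox.test(x, y, exact = use_exact, correct = TRUE)$p.value
  )
}

#' Two-sided Fisher exact p for a 2x2 table
#'
#' Conditional on both margins, sums the hypergeometric probabilities of all
#' tables no more probable than the observed one.
#'
#' @param a,b,c,d Cell counts: high-group carriers, high-group non-carriers,
#'   low-group carriers, low-group non-carriers.
#' @return p-value in (0, 1].
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  stopifnot(a >= 0, b >= 0, c >= 0, d >= 0, a + b + c + d >= 1)
  m <- a + b   # row 1 total
  n <- c + d   # row 2 total
  k <- a + c   # column 1 total
  if (m == 0 || n == 0 || k == 0 || b + d == 0) return(1)
  support <- max(0, k - n):min(k, m)
  probs <- dhyper(support, m, n, k)
  obs <- probs[match(a, support)]
  min(1, sum(probs[probs <= obs * (1 + 1e-7)]))
}

#' Extreme-group Fisher enrichment of consensus ROH regions
#'
#' For each consensus region, builds the 2x2 table of carrier status (an ROH
#' fully covering the region) against extreme-group membership and tests it
#' with the two-sided Fisher exact test. The odds ratio is the sample odds
#' ratio, with a Haldane-Anscombe 0.5 correction when a cell is zero.
#' Regions with no carriers in either group are untestable and get p = 1.
#'
#' @param consensus Tibble from [build_consensus()] (already filtered to the
#'   minimum SNP count).
#' @param segments ROH tibble.
#' @param groups Tibble from [split_extremes()].
#' @param alpha Significance level for the `significant` flag (default 0.05).
#' @param p_adjust Multiplicity correction passed to [stats::p.adjust()]
#'   (default "none", matching the study's reported counts; "BH" available).
#' @return Tibble: region columns plus `a`, `b`, `c`, `d`, `odds_ratio`,
#'   `p_value`, `testable`, `significant`.
#' @export
fisher_enrichment <- function(consensus, segments, groups, alpha = 0.05,
                              p_adjust = "none") {
  high <- groups$sample_id[groups$group == "high"]
  low <- groups$sample_id[groups$group == "low"]
  stopifnot(length(high) > 0, length(low) > 0,
            length(intersect(high, low)) == 0)
  cm <- carrier_matrix(consensus, segments, c(high, low))
  hi_idx <- seq_along(high)
  lo_idx <- length(high) + seq_along(low)
  res <- purrr::map(seq_len(nrow(consensus)), function(j) {
    a <- sum(cm[hi_idx, j]); b <- length(high) - a
    cc <- sum(cm[lo_idx, j]); dd <- length(low) - cc
    testable <- (a + cc) > 0 && (b + dd) > 0
    p <- if (testable) fisher_exact_2x2(a, b, cc, dd) else 1
    cells <- c(a, b, cc, dd)
    if (any(cells == 0)) cells <- cells + 0.5
    tibble(a = a, b = b, c = cc, d = dd,
           odds_ratio = (cells[1] * cells[4]) / (cells[2] * cells[3]),
           p_value = p, testable = testable)
  })
  out <- bind_rows(res)
  out <- bind_cols(select(consensus, -"carrier_ids"), out)
  out$p_value_adj <- stats::p.adjust(out$p_value, method = p_adjust)
  out$significant <- out$testable & out$p_value_adj < alpha
  out
}
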