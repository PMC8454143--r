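#' Construct a genotype matrix object
#'
#' A `geno_matrix` couples a dosage-coded call matrix (individuals in rows,
#' variants in columns) with its variant map. Calls are coded as the count of
#' `allele_b`: 0 = homozygous `allele_a`, 1 = heterozygous, 2 = homozygous
#' `allele_b`, `NA` = missing. Variants are kept sorted by
#' (chromosome, position); positions are 1-based and intervals inclusive,
#' matching PLINK text formats.
#'
#' @param calls Integer matrix, `n_samples x n_variants`, values in
#'   `{0, 1, 2, NA}`.
#' @param samples Character vector of unique sample ids (row order of `calls`).
#' @param variants Data frame with columns `id`, `chrom` (integer), `pos_bp`
#'   (integer, 1-based), `allele_a`, `allele_b` (single characters).
#' @return An object of class `geno_matrix`.
#' @export
geno_matrix <- function(calls, samples, variants) {
  variants <- as_tibble(variants)
  stopifnot(
    is.matrix(calls),
    length(samples) == nrow(calls),
    nrow(variants) == ncol(calls),
    !anyDuplicated(samples),
    all(c("id", "chrom", "pos_bp", "allele_a", "allele_b") %in% names(variants))
  )
  if (anyDuplicated(variants$id)) {
    stop("duplicate variant id(s): ",
         paste(head(unique(variants$id[duplicated(variants$id)]), 5), collapse = ", "))
  }
  bad <- !(calls %in% c(0L, 1L, 2L)) & !is.na(calls)
  if (any(bad)) stop("calls must be coded 0/1/2/NA")
  storage.mode(calls) <- "integer"
  ord <- order(variants$chrom, variants$pos_bp)
  variants <- variants[ord, , drop = FALSE]
  calls <- calls[, ord, drop = FALSE]
  dimnames(calls) <- list(samples, variants$id)
  structure(list(calls = calls, samples = as.character(samples), variants = variants),
            class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat("<geno_matrix> ", length(x$samples), " samples x ", nrow(x$variants),
      " variants on ", length(unique(x$variants$chrom)), " chromosome(s)\n", sep = "")
  miss <- mean(is.na(x$calls))
  cat(sprintf("  missing call rate: %.4f\n", miss))
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$calls)

#' Subset a genotype matrix by samples and/or variants
#'
#' @param g A [geno_matrix()].
#' @param samples Character vector of sample ids, or logical/integer index.
#' @param variants Logical or integer index over variants.
#' @return A `geno_matrix`.
#' @export
subset_geno <- function(g, samples = NULL, variants = NULL) {
  stopifnot(inherits(g, "geno_matrix"))
  si <- if (is.null(samples)) seq_along(g$samples) else
    if (is.character(samples)) match(samples, g$samples) else which_index(samples, length(g$samples))
  if (anyNA(si)) stop("unknown sample id(s)")
  vi <- if (is.null(variants)) seq_len(nrow(g$variants)) else which_index(variants, nrow(g$variants))
  geno_matrix(g$calls[si, vi, drop = FALSE], g$samples[si], g$variants[vi, , drop = FALSE])
}

which_index <- function(i, n) {
  if (is.logical(i)) {
    stopifnot(length(i) == n)
    which(i)
  } else as.integer(i)
}

# per-variant B-allele frequency from observed calls (missing excluded)
allele_freq <- function(g) {
  colMeans(g$calls, na.rm = TRUE) / 2
}
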