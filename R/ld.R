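#' EM haplotype frequencies for two unphased biallelic loci
#'
#' Maximum-likelihood frequencies of the four haplotypes (AB, Ab, aB, ab;
#' capital = allele coded 0 at each locus) from unphased diploid dosages.
#' Only the double-heterozygote class has ambiguous phase; the EM splits it
#' by the current coupling/repulsion odds each iteration. Individuals
#' missing either genotype are dropped.
#'
#' @param g1,g2 Integer dosage vectors (0/1/2/NA) at the two loci.
#' @param tol Convergence tolerance on the largest frequency change.
#' @param max_iter Iteration cap.
#' @return Named numeric vector `c(AB, Ab, aB, ab)` summing to 1, with
#'   attributes `n_iter` and `loglik_trace`.
#' @export
em_haplotype_freqs <- function(g1, g2, tol = 1e-10, max_iter = 1000L) {
  keep <- !is.na(g1) & !is.na(g2)
  g1 <- g1[keep]; g2 <- g2[keep]
  if (length(g1) == 0) stop("no complete genotype pairs")
  if (var(g1) == 0 || var(g2) == 0) stop("monomorphic locus")
  n <- length(g1)
  # 3x3 genotype table, rows = g1 dosage, cols = g2 dosage
  tab <- matrix(0, 3, 3)
  for (i in seq_len(n)) tab[g1[i] + 1L, g2[i] + 1L] <- tab[g1[i] + 1L, g2[i] + 1L] + 1
  pA <- 1 - mean(g1) / 2   # frequency of allele coded 0 at locus 1
  pB <- 1 - mean(g2) / 2
  f <- c(AB = pA * pB, Ab = pA * (1 - pB), aB = (1 - pA) * pB,
         ab = (1 - pA) * (1 - pB))
  # unambiguous haplotype counts contributed by each genotype cell
  # cell (i,j): dosage i of allele 'a', j of allele 'b' (counting coded-1 allele)
  base <- c(AB = 2 * tab[1, 1] + tab[1, 2] + tab[2, 1],
            Ab = 2 * tab[1, 3] + tab[1, 2] + tab[2, 3],
            aB = 2 * tab[3, 1] + tab[2, 1] + tab[3, 2],
            ab = 2 * tab[3, 3] + tab[3, 2] + tab[2, 3])
  ndh <- tab[2, 2]  # double heterozygotes: AB/ab or Ab/aB
  trace <- numeric(0)
  loglik <- function(f) {
    probs <- matrix(0, 3, 3)
    probs[1, 1] <- f["AB"]^2
    probs[1, 2] <- 2 * f["AB"] * f["Ab"]
    probs[1, 3] <- f["Ab"]^2
    probs[2, 1] <- 2 * f["AB"] * f["aB"]
    probs[2, 2] <- 2 * (f["AB"] * f["ab"] + f["Ab"] * f["aB"])
    probs[2, 3] <- 2 * f["Ab"] * f["ab"]
    probs[3, 1] <- f["aB"]^2
    probs[3, 2] <- 2 * f["aB"] * f["ab"]
    probs[3, 3] <- f["ab"]^2
    sum(tab[tab > 0] * log(probs[tab > 0]))
  }
  iter <- 0L
  repeat {
    iter <- iter + 1L
    coupling <- f["AB"] * f["ab"]
    repulsion <- f["Ab"] * f["aB"]
    w <- if (coupling + repulsion > 0) coupling / (coupling + repulsion) else 0.5
    cnt <- base + ndh * c(w, 1 - w, 1 - w, w)
    f_new <- cnt / (2 * n)
    trace <- c(trace, loglik(f_new))
    if (max(abs(f_new - f)) < tol || iter >= max_iter) {
      f <- f_new
      break
    }
    f <- f_new
  }
  attr(f, "n_iter") <- iter
  attr(f, "loglik_trace") <- trace
  f
}

#' Pairwise LD (r-squared and D-prime) from haplotype frequencies
#'
#' @param freqs Haplotype frequency vector from [em_haplotype_freqs()].
#' @return List with `D`, `r2`, `dprime` (absolute), `dprime_signed`.
#' @export
ld_from_freqs <- function(freqs) {
  pA <- freqs["AB"] + freqs["Ab"]
  pB <- freqs["AB"] + freqs["aB"]
  D <- unname(freqs["AB"] - pA * pB)
  denom <- pA * (1 - pA) * pB * (1 - pB)
  r2 <- if (denom > 0) unname(D^2 / denom) else NA_real_
  dmax <- if (D >= 0) min(pA * (1 - pB), (1 - pA) * pB) else
    min(pA * pB, (1 - pA) * (1 - pB))
  dprime <- if (dmax > 0) abs(D) / unname(dmax) else 0
  list(D = D, r2 = min(r2, 1), dprime = min(dprime, 1),
       dprime_signed = sign(D) * min(dprime, 1))
}

#' Pairwise LD matrix around a region
#'
#' Computes EM-based r-squared and |D'| for every SNP pair in a genomic
#' region, using pairwise-complete observations.
#'
#' @param g A [geno_matrix()].
#' @param chrom Chromosome of the region.
#' @param start_bp,end_bp Region bounds (1-based inclusive); defaults span
#'   the chromosome.
#' @return Object of class `ld_matrix`: list with `ids`, `pos_bp`, `r2` and
#'   `dprime` symmetric matrices.
#' @export
ld_matrix <- function(g, chrom, start_bp = -Inf, end_bp = Inf) {
  stopifnot(inherits(g, "geno_matrix"))
  vi <- which(g$variants$chrom == chrom & g$variants$pos_bp >= start_bp &
                g$variants$pos_bp <= end_bp)
  # restrict to polymorphic SNPs
  vi <- vi[apply(g$calls[, vi, drop = FALSE], 2, function(x) var(x, na.rm = TRUE) > 0)]
  if (length(vi) < 2) stop("fewer than 2 polymorphic SNPs in the region")
  k <- length(vi)
  r2 <- matrix(NA_real_, k, k)
  dp <- matrix(NA_real_, k, k)
  diag(r2) <- 1; diag(dp) <- 1
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      ld <- ld_from_freqs(em_haplotype_freqs(g$calls[, vi[i]], g$calls[, vi[j]]))
      r2[i, j] <- r2[j, i] <- ld$r2
      dp[i, j] <- dp[j, i] <- ld$dprime
    }
  }
  ids <- g$variants$id[vi]
  dimnames(r2) <- dimnames(dp) <- list(ids, ids)
  structure(list(ids = ids, pos_bp = g$variants$pos_bp[vi], r2 = r2, dprime = dp),
            class = "ld_matrix")
}

#' @export
print.ld_matrix <- function(x, ...) {
  cat("<ld_matrix> ", length(x$ids), " SNPs, mean r2 = ",
      sprintf("%.3f", mean(x$r2[upper.tri(x$r2)])), "\n", sep = "")
  invisible(x)
}
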