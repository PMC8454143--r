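# Independent brute-force reference implementations used to validate the
# package's optimised code paths. These deliberately use naive enumeration
# (explicit window loops, which()-based counting, choose()-product
# probabilities) rather than the prefix-sum / dhyper machinery of the
# implementation.

# --- sliding-window hit rates by direct enumeration ------------------------
oracle_window_rates <- function(calls, params) {
  n <- length(calls)
  w <- params$window_snps
  if (n < w) return(numeric(n))
  nw <- n - w + 1L
  pass <- logical(nw)
  for (j in seq_len(nw)) {
    win <- calls[j:(j + w - 1L)]
    pass[j] <- sum(win == 1L, na.rm = TRUE) <= params$window_max_het &&
      sum(is.na(win)) <= params$window_max_missing
  }
  rates <- numeric(n)
  for (i in seq_len(n)) {
    js <- max(1L, i - w + 1L):min(i, nw)
    rates[i] <- mean(pass[js])
  }
  rates
}

# --- ROH calling by direct enumeration of the shared greedy definition -----
oracle_call_roh_chrom <- function(calls, pos, params) {
  n <- length(calls)
  out <- list()
  if (n == 0) return(out)
  rates <- oracle_window_rates(calls, params)
  cand <- which(rates >= params$window_hit_threshold)
  if (length(cand) == 0) return(out)
  # consecutive candidate stretches
  breaks <- which(diff(cand) > 1L)
  stretch_start <- cand[c(1L, breaks + 1L)]
  stretch_end <- cand[c(breaks, length(cand))]
  pieces <- list()
  for (s in seq_along(stretch_start)) {
    idx <- stretch_start[s]:stretch_end[s]
    # split at large gaps
    big <- which(diff(pos[idx]) > params$max_gap_bp)
    ss <- c(idx[1L], idx[big + 1L])
    ee <- c(idx[big], idx[length(idx)])
    for (k in seq_along(ss)) pieces[[length(pieces) + 1L]] <- c(ss[k], ee[k])
  }
  hom <- !is.na(calls) & calls != 1L
  for (pc in pieces) {
    i <- pc[1]; hi <- pc[2]
    repeat {
      while (i <= hi && !hom[i]) i <- i + 1L
      if (i > hi) break
      span <- i:hi
      hets <- span[which(!is.na(calls[span]) & calls[span] == 1L)]
      miss <- span[which(is.na(calls[span]))]
      j_het <- if (length(hets) > params$roh_max_het)
        hets[params$roh_max_het + 1L] - 1L else hi
      j_mis <- if (length(miss) > params$roh_max_missing)
        miss[params$roh_max_missing + 1L] - 1L else hi
      j <- min(j_het, j_mis)
      while (j > i && !hom[j]) j <- j - 1L
      len <- pos[j] - pos[i] + 1
      nsnp <- j - i + 1L
      if (len >= params$min_length_bp && nsnp >= params$min_snps &&
          len / nsnp <= params$min_density_bp_per_snp) {
        out[[length(out) + 1L]] <- data.frame(
          start_bp = pos[i], end_bp = pos[j], n_snps = nsnp,
          n_het = sum(calls[i:j] == 1L, na.rm = TRUE),
          n_missing = sum(is.na(calls[i:j]))
        )
      }
      i <- j + 1L
    }
  }
  out
}

oracle_call_roh <- function(calls, variants, params) {
  rows <- list()
  for (ch in sort(unique(variants$chrom))) {
    sel <- variants$chrom == ch
    segs <- oracle_call_roh_chrom(calls[sel], variants$pos_bp[sel], params)
    for (s in segs) rows[[length(rows) + 1L]] <- cbind(chrom = ch, s)
  }
  if (length(rows) == 0) {
    return(data.frame(chrom = integer(), start_bp = numeric(),
                      end_bp = numeric(), n_snps = integer(),
                      n_het = integer(), n_missing = integer()))
  }
  do.call(rbind, rows)
}

# --- exact HWE p by explicit enumeration over genotype configurations ------
oracle_hwe_p <- function(n_homA, n_het, n_homB) {
  n <- n_homA + n_het + n_homB
  nA <- 2 * n_homA + n_het
  nB <- 2 * n_homB + n_het
  if (nA == 0 || nB == 0) return(1)
  hets <- seq(min(nA, nB) %% 2, min(nA, nB), by = 2)
  weight <- vapply(hets, function(h) {
    aa <- (nA - h) / 2
    bb <- (nB - h) / 2
    # multinomial count of genotype assignments x 2^h phase choices
    exp(lchoose(n, aa) + lchoose(n - aa, h) + h * log(2))
  }, numeric(1))
  probs <- weight / sum(weight)
  obs <- probs[hets == n_het]
  sum(probs[probs <= obs * (1 + 1e-9)])
}

# --- two-sided Fisher p by choose()-product enumeration --------------------
oracle_fisher_p <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  if (m == 0 || n == 0 || k == 0 || b + d == 0) return(1)
  support <- max(0, k - n):min(k, m)
  probs <- exp(lchoose(m, support) + lchoose(n, k - support) - lchoose(m + n, k))
  obs <- probs[support == a]
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# --- exact two-sided Wilcoxon by full enumeration of group assignments -----
oracle_wilcoxon_p <- function(x, y) {
  pooled <- c(x, y)
  n <- length(x)
  ranks <- rank(pooled)
  u_obs <- sum(ranks[seq_len(n)]) - n * (n + 1) / 2
  sets <- utils::combn(length(pooled), n)
  us <- apply(sets, 2, function(ix) sum(rank(pooled)[ix]) - n * (n + 1) / 2)
  p_le <- mean(us <= u_obs)
  p_ge <- mean(us >= u_obs)
  min(1, 2 * min(p_le, p_ge))
}

# --- unambiguous-phase haplotype counting (valid when no double hets) ------
oracle_ld_counting <- function(g1, g2) {
  keep <- !is.na(g1) & !is.na(g2)
  g1 <- g1[keep]; g2 <- g2[keep]
  stopifnot(!any(g1 == 1 & g2 == 1))
  n <- length(g1)
  cnt <- c(AB = 0, Ab = 0, aB = 0, ab = 0)
  for (i in seq_len(n)) {
    # alleles at locus1: A (coded 0) count = 2 - g1
    h <- switch(paste(g1[i], g2[i]),
      "0 0" = c(2, 0, 0, 0), "0 1" = c(1, 1, 0, 0), "0 2" = c(0, 2, 0, 0),
      "1 0" = c(1, 0, 1, 0), "1 2" = c(0, 1, 0, 1),
      "2 0" = c(0, 0, 2, 0), "2 1" = c(0, 0, 1, 1), "2 2" = c(0, 0, 0, 2)
    )
    cnt <- cnt + h
  }
  f <- cnt / (2 * n)
  pA <- f["AB"] + f["Ab"]; pB <- f["AB"] + f["aB"]
  D <- unname(f["AB"] - pA * pB)
  r2 <- unname(D^2 / (pA * (1 - pA) * pB * (1 - pB)))
  list(freqs = f, D = D, r2 = r2)
}

# --- restricted log-likelihood from the full-matrix definition -------------
oracle_reml_loglik <- function(y, X, G, sigma_g2, sigma_e2) {
  n <- length(y); p <- ncol(X)
  V <- sigma_g2 * G + sigma_e2 * diag(n)
  Vi <- solve(V)
  XtViX <- t(X) %*% Vi %*% X
  beta <- solve(XtViX, t(X) %*% Vi %*% y)
  r <- y - X %*% beta
  as.numeric(-0.5 * (determinant(V)$modulus + determinant(XtViX)$modulus +
                       t(r) %*% Vi %*% r + (n - p) * log(2 * pi)))
}
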