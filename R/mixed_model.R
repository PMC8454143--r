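#' Genomic relationship matrix (VanRaden method 1)
#'
#' Centers dosages by twice the observed allele frequency and scales by
#' `2 * sum(p * (1 - p))`: `G = W W' / (2 sum p(1-p))`. Missing genotypes
#' are mean-imputed per SNP for this computation only; monomorphic SNPs are
#' excluded with a warning.
#'
#' @param g A quality-controlled [geno_matrix()].
#' @return An `n x n` symmetric matrix with sample ids as dimnames and
#'   attribute `n_snps`.
#' @export
build_grm <- function(g) {
  stopifnot(inherits(g, "geno_matrix"))
  M <- g$calls
  storage.mode(M) <- "double"
  p <- colMeans(M, na.rm = TRUE) / 2
  mono <- is.na(p) | p <= 0 | p >= 1
  if (any(mono)) {
    warning(sum(mono), " monomorphic SNP(s) excluded from the GRM")
    M <- M[, !mono, drop = FALSE]
    p <- p[!mono]
  }
  if (ncol(M) == 0) stop("no polymorphic SNPs available for the GRM")
  for (j in seq_len(ncol(M))) {
    mj <- is.na(M[, j])
    if (any(mj)) M[mj, j] <- 2 * p[j]
  }
  W <- sweep(M, 2L, 2 * p)
  G <- tcrossprod(W) / (2 * sum(p * (1 - p)))
  dimnames(G) <- list(g$samples, g$samples)
  attr(G, "n_snps") <- ncol(M)
  G
}

#' REML variance components for a single-random-effect mixed model
#'
#' Fits `y = X b + u + e` with `u ~ N(0, G sigma_g2)` and
#' `e ~ N(0, I sigma_e2)` by restricted maximum likelihood. The restricted
#' likelihood is profiled down to the ratio `lambda = sigma_g2 / sigma_e2`
#' using the eigendecomposition of `G`, and maximised by bounded 1-D search
#' on `log10(lambda)`; the fit is deterministic with no starting-value
#' sensitivity. Estimates on the search boundary are flagged.
#'
#' @param y Numeric response vector.
#' @param X Full-rank fixed-effects design matrix.
#' @param G Genomic relationship matrix from [build_grm()] (or an
#'   `eigen()` decomposition of one, to amortise repeated fits).
#' @param lambda_log10_bounds Search interval for `log10(lambda)`.
#' @return List: `sigma_g2`, `sigma_e2`, `lambda`, `loglik` (restricted),
#'   `boundary`, `degenerate` (flat profile, e.g. `G = I`), plus the pieces
#'   needed for generalized least squares (`beta`, `beta_cov`).
#' @export
reml_fit <- function(y, X, G, lambda_log10_bounds = c(-6, 6)) {
  X <- as.matrix(X)
  n <- length(y)
  p <- ncol(X)
  stopifnot(nrow(X) == n, n > p + 1)
  if (qr(X)$rank < p) stop("fixed-effects design is rank deficient")
  eg <- if (is.list(G) && !is.null(G$vectors)) G else eigen(G, symmetric = TRUE)
  d <- pmax(eg$values, 0)
  ys <- crossprod(eg$vectors, y)
  Xs <- crossprod(eg$vectors, X)

  neg2_reml <- function(lambda) {
    v <- lambda * d + 1
    w <- 1 / v
    XtWX <- crossprod(Xs, Xs * w)
    XtWy <- crossprod(Xs, ys * w)
    ch <- tryCatch(chol(XtWX), error = function(e) NULL)
    if (is.null(ch)) return(Inf)
    beta <- backsolve(ch, forwardsolve(t(ch), XtWy))
    r <- ys - Xs %*% beta
    rss <- sum(r^2 * w)
    (n - p) * log(rss) + sum(log(v)) + 2 * sum(log(diag(ch)))
  }

  obj <- function(t) neg2_reml(10^t)
  opt <- optimize(obj, interval = lambda_log10_bounds, tol = 1e-9)
  # compare with the lambda -> 0 limit (pure OLS residual variance)
  at_zero <- neg2_reml(0)
  if (at_zero <= opt$objective + 1e-10) {
    lambda <- 0
    objective <- at_zero
    boundary <- TRUE
  } else {
    lambda <- 10^opt$minimum
    objective <- opt$objective
    boundary <- opt$minimum <= lambda_log10_bounds[1] + 0.01 ||
      opt$minimum >= lambda_log10_bounds[2] - 0.01
  }
  # flat-profile detection (non-identifiable, e.g. G = I)
  probe <- vapply(c(-2, 0, 2), function(t) neg2_reml(10^t), numeric(1))
  degenerate <- diff(range(probe[is.finite(probe)])) < 1e-8 * max(1, abs(objective))

  v <- lambda * d + 1
  w <- 1 / v
  XtWX <- crossprod(Xs, Xs * w)
  beta <- solve(XtWX, crossprod(Xs, ys * w))
  r <- ys - Xs %*% beta
  sigma_e2 <- sum(r^2 * w) / (n - p)
  sigma_g2 <- lambda * sigma_e2
  loglik <- -0.5 * (objective + (n - p) * (1 + log(2 * pi) - log(n - p)))
  list(sigma_g2 = sigma_g2, sigma_e2 = sigma_e2, lambda = lambda,
       loglik = loglik, boundary = boundary, degenerate = degenerate,
       beta = drop(beta), beta_cov = solve(XtWX) * sigma_e2,
       n = n, p = p)
}

#' Mixed-model association test for an ROH region
#'
#' Fits the validating model `y = X b + Z u + e` with the region's carrier
#' indicator among the fixed effects, the polygenic effect distributed
#' `N(0, G sigma_g2)` and one record per animal (`Z = I`). Variance
#' components come from [reml_fit()]; fixed effects are then generalized
#' least squares at those estimates and the carrier coefficient is tested
#' with a two-sided Wald test against a normal reference.
#'
#' @param pheno Phenotype tibble (raw trait plus design columns), one row per
#'   genotyped individual, in the sample order of `G`.
#' @param trait Trait column name (raw, unadjusted).
#' @param roh_indicator Logical/0-1 vector of region carrier status, aligned
#'   with `pheno` rows.
#' @param G GRM (or its eigendecomposition) over the same individuals.
#' @param fixed,covariates Design column names, as in [adjust_phenotypes()].
#' @return Object of class `roh_mm`: use [generics::tidy()] for the
#'   coefficient table and [generics::glance()] for variance components.
#' @export
roh_association_test <- function(pheno, trait, roh_indicator, G,
                                 fixed = c("farm", "year", "sex"),
                                 covariates = c("weight_before_fattening",
                                                "fattening_days")) {
  stopifnot(trait %in% names(pheno))
  ind <- as.numeric(roh_indicator)
  stopifnot(length(ind) == nrow(pheno))
  if (var(ind) == 0) stop("no carrier contrast: ROH indicator is constant")
  keep_fixed <- fixed[vapply(fixed, function(f)
    length(unique(pheno[[f]])) > 1, TRUE)]
  rhs <- paste(c("roh", sprintf("factor(%s)", keep_fixed), covariates),
               collapse = " + ")
  dat <- as.data.frame(pheno[, c(trait, keep_fixed, covariates)])
  dat$roh <- ind
  X <- model.matrix(stats::as.formula(paste0("~", rhs)), data = dat)
  if (qr(X)$rank < ncol(X)) {
    stop("design rank deficient after adding the ROH indicator")
  }
  fit <- reml_fit(pheno[[trait]], X, G)
  se <- sqrt(diag(fit$beta_cov))
  z <- fit$beta / se
  pvals <- 2 * pnorm(-abs(z))
  coefs <- tibble(term = colnames(X), estimate = unname(fit$beta),
                  std.error = unname(se), statistic = unname(z),
                  p.value = unname(pvals))
  structure(list(coefficients = coefs, sigma_g2 = fit$sigma_g2,
                 sigma_e2 = fit$sigma_e2, lambda = fit$lambda,
                 loglik = fit$loglik, boundary = fit$boundary,
                 degenerate = fit$degenerate, trait = trait, nobs = fit$n),
            class = "roh_mm")
}

#' @export
print.roh_mm <- function(x, ...) {
  cat("ROH mixed-model association (", x$trait, "), n = ", x$nobs, "\n", sep = "")
  cat(sprintf("  sigma_g2 = %.4g, sigma_e2 = %.4g%s\n", x$sigma_g2, x$sigma_e2,
              if (x$boundary) " (boundary)" else ""))
  r <- x$coefficients[x$coefficients$term == "roh", ]
  cat(sprintf("  ROH effect = %.4g (SE %.4g), Wald p = %.3g\n",
              r$estimate, r$std.error, r$p.value))
  invisible(x)
}

#' Tidy the coefficient table of an ROH mixed-model fit
#' @param x A `roh_mm` object.
#' @param ... Unused.
#' @return Tibble with `term`, `estimate`, `std.error`, `statistic`, `p.value`.
#' @export
tidy.roh_mm <- function(x, ...) x$coefficients

#' One-row model summary of an ROH mixed-model fit
#' @param x A `roh_mm` object.
#' @param ... Unused.
#' @return One-row tibble with variance components, ratio, log-likelihood and
#'   convergence flags.
#' @export
glance.roh_mm <- function(x, ...) {
  tibble(sigma_g2 = x$sigma_g2, sigma_e2 = x$sigma_e2, lambda = x$lambda,
         logLik = x$loglik, boundary = x$boundary, degenerate = x$degenerate,
         nobs = x$nobs)
}

#' Compare adjusted trait values between region carriers and non-carriers
#'
#' Per-class counts, means and quartiles with a two-sided Wilcoxon rank-sum
#' p-value — the boxplot-style contrast of carriers against non-carriers on
#' the adjusted scale.
#'
#' @param adjusted_values Numeric vector of adjusted trait values.
#' @param carrier Logical vector of the same length.
#' @return List with `summary` (tibble, one row per class) and `p_value`.
#' @export
compare_carriers <- function(adjusted_values, carrier) {
  stopifnot(length(adjusted_values) == length(carrier))
  keep <- !is.na(adjusted_values)
  adjusted_values <- adjusted_values[keep]
  carrier <- as.logical(carrier)[keep]
  if (sum(carrier) < 2 || sum(!carrier) < 2) {
    stop("both carrier classes need at least 2 individuals")
  }
  one <- function(v) {
    tibble(n = length(v), mean = mean(v),
           q25 = unname(quantile(v, 0.25)), median = median(v),
           q75 = unname(quantile(v, 0.75)))
  }
  smry <- bind_rows(one(adjusted_values[carrier]), one(adjusted_values[!carrier]))
  smry <- bind_cols(tibble(carrier = c(TRUE, FALSE)), smry)
  list(summary = smry,
       p_value = wilcoxon_ranksum(adjusted_values[carrier],
                                  adjusted_values[!carrier]))
}
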