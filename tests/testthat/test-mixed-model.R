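# small helper: simulate y = Xb + u + e from a given GRM
sim_y <- function(X, b, G, sigma_g2, sigma_e2) {
  eg <- eigen(G, symmetric = TRUE)
  u <- sqrt(sigma_g2) * drop(eg$vectors %*% (sqrt(pmax(eg$values, 0)) * rnorm(nrow(G))))
  drop(X %*% b) + u + rnorm(nrow(G), 0, sqrt(sigma_e2))
}

test_that("the GRM is symmetric with VanRaden scaling near 1 on the diagonal", {
  set.seed(21)
  n <- 500; m <- 5000
  p <- runif(m, 0.1, 0.5)
  calls <- matrix(rbinom(n * m, 2L, rep(p, each = n)), n, m)
  v <- tibble::tibble(id = paste0("v", 1:m), chrom = 1L,
                      pos_bp = as.integer(seq_len(m) * 100),
                      allele_a = "A", allele_b = "G")
  g <- geno_matrix(calls, sprintf("S%03d", 1:n), v)
  G <- build_grm(g)
  expect_identical(G, t(G))
  expect_lt(abs(mean(diag(G)) - 1), 0.02)
  ev <- eigen(G, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), -1e-8)
  # identical genotypes give identical rows and G_ij = G_ii
  g2 <- geno_matrix(calls[c(1, 1, 2:10), ], sprintf("T%02d", 1:11),
                    v)
  G2 <- suppressWarnings(build_grm(g2))  # tiny subset can go monomorphic
  expect_equal(G2[1, 2], G2[1, 1])
})

test_that("monomorphic SNPs are excluded from the GRM with a warning", {
  set.seed(2)
  calls <- cbind(matrix(rbinom(200, 2, 0.4), 20, 10), 0L)
  v <- tibble::tibble(id = paste0("v", 1:11), chrom = 1L,
                      pos_bp = as.integer(1:11 * 1000), allele_a = "A",
                      allele_b = "G")
  g <- geno_matrix(calls, paste0("S", 1:20), v)
  expect_warning(G <- build_grm(g), "monomorphic")
  expect_equal(attr(G, "n_snps"), 10L)
})

test_that("profile REML agrees with a direct full-likelihood grid at n = 40", {
  set.seed(31)
  n <- 40
  Z <- matrix(rbinom(n * 200, 2, 0.3), n)
  Zc <- scale(Z, scale = FALSE)
  G <- tcrossprod(Zc) / 60
  G <- G / mean(diag(G))
  X <- cbind(1, rnorm(n))
  y <- sim_y(X, c(1, 0.5), G, 1, 1)
  fit <- reml_fit(y, X, G)
  # grid over (sigma_g2, sigma_e2) with the naive full-matrix restricted LL
  grid <- expand.grid(sg = seq(0.05, 4, length.out = 40),
                      se = seq(0.05, 4, length.out = 40))
  ll <- mapply(function(sg, se) oracle_reml_loglik(y, X, G, sg, se),
               grid$sg, grid$se)
  expect_gte(fit$loglik, max(ll) - 1e-6)
  best <- grid[which.max(ll), ]
  expect_lt(abs(fit$sigma_g2 - best$sg), 0.15)
  expect_lt(abs(fit$sigma_e2 - best$se), 0.15)
  # and the reported loglik equals the naive formula at the estimates
  expect_equal(fit$loglik,
               oracle_reml_loglik(y, X, G, fit$sigma_g2, fit$sigma_e2),
               tolerance = 1e-6)
})

test_that("REML with sigma_g2 fixed at zero reduces to OLS", {
  set.seed(32)
  n <- 80
  X <- cbind(1, rnorm(n), rbinom(n, 1, 0.4))
  y <- drop(X %*% c(2, 1, 0.5)) + rnorm(n)
  G <- diag(n) * 0  # no genetic covariance possible
  fit <- reml_fit(y, X, G)
  ols <- stats::lm.fit(X, y)
  expect_equal(unname(fit$beta), unname(ols$coefficients), tolerance = 1e-8)
  expect_equal(fit$sigma_e2, sum(ols$residuals^2) / (n - 3), tolerance = 1e-6)
})

test_that("pure-noise responses drive sigma_g2 to the zero boundary", {
  set.seed(33)
  n <- 60
  Z <- matrix(rbinom(n * 300, 2, 0.3), n)
  Zc <- scale(Z, scale = FALSE)
  G <- tcrossprod(Zc) / 90; G <- G / mean(diag(G))
  X <- cbind(rep(1, n))
  at_zero <- vapply(1:20, function(i) {
    y <- rnorm(n)
    reml_fit(y, X, G)$sigma_g2 < 0.05
  }, logical(1))
  expect_gt(mean(at_zero), 0.5)
})

test_that("G = I makes the variance split non-identifiable and is flagged", {
  set.seed(34)
  n <- 50
  X <- cbind(rep(1, n))
  y <- rnorm(n)
  fit <- reml_fit(y, X, diag(n))
  expect_true(fit$degenerate)
})

test_that("REML estimates are invariant to fixed-effect reparameterisation", {
  set.seed(35)
  n <- 60
  Z <- matrix(rbinom(n * 300, 2, 0.3), n)
  Zc <- scale(Z, scale = FALSE)
  G <- tcrossprod(Zc) / 90; G <- G / mean(diag(G))
  f <- factor(sample(c("a", "b", "c"), n, replace = TRUE))
  X1 <- stats::model.matrix(~f)
  X2 <- stats::model.matrix(~ 0 + f)  # cell-means coding, same column space
  y <- sim_y(X1, c(1, 0.5, -0.5), G, 1, 1)
  f1 <- reml_fit(y, X1, G)
  f2 <- reml_fit(y, X2, G)
  expect_equal(f1$sigma_g2, f2$sigma_g2, tolerance = 1e-5)
  expect_equal(f1$sigma_e2, f2$sigma_e2, tolerance = 1e-5)
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-6)
})

test_that("the ROH association test recovers a planted region effect", {
  st <- small_study()
  set.seed(36)
  G <- suppressWarnings(build_grm(st$g))
  carriers <- st$g$samples %in% st$truth$region_carriers[[1]]
  mm <- roh_association_test(st$pheno, "LW", carriers, G)
  r <- tidy(mm)
  roh_row <- r[r$term == "roh", ]
  # planted effect is 0.5 on every trait
  expect_lt(abs(roh_row$estimate - 0.5) / roh_row$std.error, 3)
  gl <- glance(mm)
  expect_true(all(c("sigma_g2", "sigma_e2", "logLik") %in% names(gl)))
  expect_gte(gl$sigma_g2, 0)
  expect_error(roh_association_test(st$pheno, "LW", rep(TRUE, nrow(st$pheno)), G),
               "constant")
})

test_that("carrier comparison summarises both classes and flags tiny ones", {
  set.seed(37)
  adjv <- c(rnorm(30, 1), rnorm(30, 0))
  carrier <- rep(c(TRUE, FALSE), each = 30)
  cc <- compare_carriers(adjv, carrier)
  expect_equal(cc$summary$n, c(30L, 30L))
  expect_lt(cc$p_value, 0.05)
  expect_gt(cc$summary$mean[1], cc$summary$mean[2])
  same <- compare_carriers(c(rnorm(50)), rep(c(TRUE, FALSE), 25))
  expect_gt(same$p_value, 0.05)
  expect_error(compare_carriers(adjv, c(TRUE, rep(FALSE, 59))), "at least 2")
})
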