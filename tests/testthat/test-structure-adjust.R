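test_that("allele-sharing kinship has its bounds and centering", {
  pan <- toy_panel()
  calls <- unclass(pan$g)
  # duplicate a sample: identical pair gets kinship 1
  calls2 <- rbind(calls, calls[1, , drop = FALSE])
  rownames(calls2) <- c(rownames(calls), "dup")
  K <- suppressMessages(estimate_kinship(genotype_matrix(calls2)))
  expect_equal(unname(K["s01", "dup"]), 1, tolerance = 1e-6)
  expect_true(all(abs(diag(K) - 1) < 1e-12))
  expect_true(isSymmetric(unclass(K)))
  ev <- eigen(unclass(K), symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), -1e-8)
  # off-diagonal entries at worst mildly negative after PSD conditioning
  expect_gte(min(K), -0.1)
})

test_that("kinship separates diverged subpopulations", {
  spec <- simulation_spec(n_samples = 60, n_fragments = 40,
                          snps_per_fragment = c(10, 15),
                          n_subpops = 2, divergence = 1.2, seed = 31)
  sim <- simulate_genotypes(spec)
  K <- suppressMessages(estimate_kinship(sim$genotypes))
  same <- outer(sim$subpop, sim$subpop, "==")
  off <- upper.tri(K)
  expect_gt(mean(K[off & same]), mean(K[off & !same]))
})

test_that("mixed model without kinship reduces to OLS", {
  set.seed(33)
  n <- 50
  X <- covariate_set(matrix(rnorm(n), n, 1, dimnames = list(NULL, "q1")),
                     label = "Q")
  y <- drop(X %*% c(2, 1)) + rnorm(n)
  fit <- fit_mixed_model(y, X, use_kinship = FALSE)
  ols <- lm(y ~ X[, 2])
  expect_equal(unname(coef(fit)), unname(coef(ols)), tolerance = 1e-10)
  expect_equal(residuals(fit), unname(residuals(ols)), tolerance = 1e-10)
  expect_equal(fit$sigma_g2, 0)
})

test_that("profile REML matches a generic 2-D optimizer on random instances", {
  set.seed(34)
  for (r in 1:5) {
    n <- 40
    K <- stats::cov2cor(tcrossprod(matrix(rnorm(n * (n + 5)), n)))
    X <- cbind(`(Intercept)` = 1, x = rnorm(n))
    A <- 2 * K
    eg <- eigen(A, symmetric = TRUE)
    L <- eg$vectors %*% (sqrt(pmax(eg$values, 0)) * t(eg$vectors))
    y <- drop(X %*% c(1, 0.5) + sqrt(1.5) * L %*% rnorm(n) + rnorm(n))
    fit <- fit_mixed_model(y, X, K)
    negll <- function(par) {
      V <- A * exp(par[1]) + diag(exp(par[2]), n)
      cV <- chol(V); Vi <- chol2inv(cV)
      XtVX <- t(X) %*% Vi %*% X
      b <- solve(XtVX, t(X) %*% Vi %*% y)
      rr <- y - X %*% b
      drop(0.5 * (2 * sum(log(diag(cV))) +
                    determinant(XtVX)$modulus[1] -
                    determinant(crossprod(X))$modulus[1] +
                    t(rr) %*% Vi %*% rr + (n - 2) * log(2 * pi)))
    }
    o <- optim(c(0, 0), negll, method = "Nelder-Mead",
               control = list(reltol = 1e-12, maxit = 5000))
    expect_equal(fit$loglik_reml, -o$value, tolerance = 1e-4)
  }
})

test_that("null polygenic variance is recovered near zero", {
  set.seed(35)
  n <- 200
  # structured kinship: the polygenic component is identifiable, so a
  # null variance is pinned near zero
  K <- block_kinship(n, n_blocks = 5, rho = 0.5)
  X <- covariate_set(NULL, n = n)
  hits <- 0
  for (r in 1:60) {
    y <- rnorm(n)
    fit <- fit_mixed_model(y, X, K)
    if (fit$sigma_g2 <= 0.05 * var(y)) hits <- hits + 1
  }
  expect_gte(hits / 60, 0.9)
})

test_that("BIC model selection favors structure covariates when they matter", {
  set.seed(36)
  n <- 80
  subpop <- rep(1:2, each = n / 2)
  Xs <- covariate_set(matrix(as.numeric(subpop == 2), n, 1,
                             dimnames = list(NULL, "pop2")), label = "Q")
  X0 <- covariate_set(NULL, n = n)
  wins <- 0
  for (r in 1:30) {
    y <- 1.5 * (subpop == 2) + rnorm(n)
    best <- select_structure_model(y, list(X0, Xs))
    if (grepl("^Q", best$label)) wins <- wins + 1
  }
  expect_gte(wins / 30, 0.8)
  # pure noise: the null model wins on average
  null_wins <- 0
  for (r in 1:30) {
    y <- rnorm(n)
    best <- select_structure_model(y, list(X0, Xs))
    if (grepl("^null", best$label)) null_wins <- null_wins + 1
  }
  expect_gt(null_wins / 30, 0.5)
  # identical candidates: tie broken toward the (equal) parameter count,
  # deterministically the first
  b2 <- select_structure_model(rnorm(n), list(X0, X0))
  expect_equal(attr(b2, "bic_table")$bic[1], attr(b2, "bic_table")$bic[2])
  expect_true(attr(b2, "bic_table")$selected[1])
})

test_that("GRAMMAR residuals reduce to centered phenotype and OLS residuals", {
  set.seed(37)
  n <- 50
  y <- rnorm(n)
  X0 <- covariate_set(NULL, n = n)
  fit <- fit_mixed_model(y, X0, use_kinship = FALSE)
  expect_equal(grammar_residuals(fit), y - mean(y), tolerance = 1e-10)
  Xq <- covariate_set(matrix(rnorm(n), n, 1, dimnames = list(NULL, "q")),
                      label = "Q")
  fitq <- fit_mixed_model(y, Xq, use_kinship = FALSE)
  expect_equal(grammar_residuals(fitq),
               unname(residuals(lm(y ~ Xq[, 2]))), tolerance = 1e-10)
  expect_lt(abs(mean(grammar_residuals(fitq))), 1e-8)
})

test_that("GRAMMAR adjustment removes confounding with subpopulation", {
  spec0 <- simulation_spec(n_samples = 80, n_fragments = 40,
                           snps_per_fragment = c(8, 15), n_subpops = 2,
                           divergence = 1.0, subpop_shift = 1.2,
                           h2_polygenic = 0.4, seed = 38)
  deconf <- 0
  for (r in 1:10) {
    spec <- spec0; spec$seed <- spec0$seed + r
    sim <- simulate_genotypes(spec)
    ph <- simulate_phenotypes(sim, spec)
    y <- unclass(ph$phenotypes)[, 1]
    K <- ph$K
    Xp <- pca_covariates(sim$genotypes, 1)
    fit <- fit_mixed_model(y, Xp, K)
    if (abs(cor(grammar_residuals(fit), sim$subpop)) < abs(cor(y, sim$subpop)))
      deconf <- deconf + 1
  }
  expect_gte(deconf / 10, 0.9)
})

test_that("genomic-control lambda uses the chi-square median and deflates only", {
  ref <- qchisq(0.5, 1)
  ia <- suppressWarnings(inflation_factor(rep(ref, 25)))
  expect_equal(ia$lambda, 1, tolerance = 1e-12)
  set.seed(39)
  stats_infl <- 2 * rchisq(1e5, 1)
  ia2 <- inflation_factor(stats_infl)
  expect_gt(ia2$lambda, 1.95); expect_lt(ia2$lambda, 2.05)
  expect_equal(ia2$adjusted, stats_infl / ia2$lambda)
  # deflation-only: lambda < 1 leaves statistics unchanged
  set.seed(40)
  stats_defl <- 0.8 * rchisq(1e4, 1)
  ia3 <- inflation_factor(stats_defl)
  expect_lt(ia3$lambda, 1)
  expect_equal(ia3$adjusted, stats_defl)
  expect_equal(inflation_factor(stats_defl, mode = "symmetric")$adjusted,
               stats_defl / ia3$lambda)
  expect_warning(inflation_factor(rep(0.5, 10)), "fewer than 20")
})
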