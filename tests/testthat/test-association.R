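test_that("single-regressor LR test matches hand computation and errors", {
  # orthogonal toy: slope 0, LR 0
  res <- lr_test(c(1, -1, 1, -1), c(1, 1, -1, -1))
  expect_equal(res$beta1, 0, tolerance = 1e-12)
  expect_equal(res$lr, 0, tolerance = 1e-12)
  expect_equal(res$df, 1)
  expect_error(lr_test(rnorm(10), rep(2, 10)), "inestimable")
  # closed form equals -2 * (logLik null - logLik full) from a generic fit
  set.seed(50)
  y <- rnorm(25); z <- rnorm(25)
  res2 <- lr_test(y, z)
  oracle <- 2 * (as.numeric(logLik(glm(y ~ z))) -
                   as.numeric(logLik(glm(y ~ 1))))
  expect_equal(res2$lr, oracle, tolerance = 1e-6)
})

test_that("burden scores implement the three collapsing schemes", {
  n <- 100
  calls <- matrix(0, n, 3, dimnames = list(sprintf("s%03d", 1:n),
                                           c("a", "b", "c")))
  calls[1, ] <- c(0, 1, 1)
  calls[2:5, "a"] <- 1; calls[2:5, "b"] <- 0
  calls[2:6, "c"] <- 1
  g <- genotype_matrix(calls)
  maf <- compute_maf(g)
  # sum test: row mean over the m = 3 variants
  bs <- burden_score(c("a", "b", "c"), g, maf, method = "sum")
  expect_equal(bs$z[1], 2 / 3, tolerance = 1e-12)
  expect_equal(bs$m, 3L)
  # weighted sum: single carrier at p = 0.05, n = 100 -> 1/sqrt(4.75)
  calls2 <- matrix(0, n, 3, dimnames = list(rownames(calls),
                                            c("w1", "w2", "w3")))
  calls2[1:5, "w1"] <- 1       # p = 0.05... but rare needs < 0.05; keep p = 0.05 column for arithmetic
  calls2[1, "w2"] <- 1
  calls2[2, "w3"] <- 1
  g2 <- genotype_matrix(calls2)
  maf2 <- compute_maf(g2)
  bs2 <- burden_score(c("w1", "w2", "w3"), g2, maf2, method = "weighted_sum")
  w1_weight <- 1 / sqrt(n * 0.05 * 0.95)
  expect_equal(round(w1_weight, 4), 0.4588)
  expect_equal(bs2$z[3], w1_weight, tolerance = 1e-12)  # s003 carries only w1
  # function-aided: S = 2.4277, p = 1 percent -> pF = 0.3562
  calls3 <- matrix(0, n, 3, dimnames = list(rownames(calls),
                                            c("f1", "f2", "f3")))
  calls3[1, "f1"] <- 1; calls3[2, "f2"] <- 1; calls3[3, "f3"] <- 1
  g3 <- genotype_matrix(calls3)
  maf3 <- compute_maf(g3)
  expect_equal(unname(maf3["f1"]), 0.01)
  sw <- c(f1 = 2.4277, f2 = 0.6772, f3 = 0.6772)
  bs3 <- burden_score(c("f1", "f2", "f3"), g3, maf3,
                      method = "function_aided_sum",
                      s_weights = sw, fit = power_fit())
  expect_equal(bs3$z[1], 2.4277 * 0.3562, tolerance = 1e-10)
  # m < 3 excluded
  expect_error(burden_score(c("a", "b"), g, maf, method = "sum"),
               "insufficient rare variants")
})

test_that("burden statistics are invariant to sample reordering and allele flips", {
  pan <- toy_panel()
  set.seed(51)
  y <- rnorm(nrow(pan$g))
  bs <- burden_score(pan$fragments$frag_r, pan$g, pan$maf, "weighted_sum")
  lr0 <- lr_test(y, bs$z)$lr
  perm <- sample(nrow(pan$g))
  g2 <- genotype_matrix(unclass(pan$g)[perm, ],
                        samples = rownames(pan$g)[perm])
  bs2 <- burden_score(pan$fragments$frag_r, g2, compute_maf(g2),
                      "weighted_sum")
  expect_equal(lr_test(y[perm], bs2$z)$lr, lr0, tolerance = 1e-10)
  # flipping a rare SNP's coding (then re-orienting at load) leaves LR alone
  flipped <- unclass(pan$g)
  flipped[, "r2"] <- 1 - flipped[, "r2"]
  path <- tempfile(fileext = ".tsv")
  utils::write.table(data.frame(sample = rownames(flipped), flipped),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  g3 <- read_genotypes(path, "tsv")
  bs3 <- burden_score(pan$fragments$frag_r, g3, compute_maf(g3),
                      "weighted_sum")
  expect_equal(lr_test(y, bs3$z)$lr, lr0, tolerance = 1e-10)
})

test_that("multivariate test reduces, prunes collinearity, and saturates", {
  set.seed(52)
  n <- 60
  y <- rnorm(n)
  z <- rbinom(n, 1, 0.3)
  # one column: identical to lr_test
  mv <- multivariate_test(y, matrix(z, n, 1))
  expect_equal(mv$lr, lr_test(y, z)$lr, tolerance = 1e-10)
  expect_equal(mv$df, 1)
  # duplicate columns: one dropped
  mv2 <- multivariate_test(y, cbind(z, z))
  expect_equal(mv2$df, 1)
  expect_equal(attr(mv2, "retained"), 1L)
  expect_error(multivariate_test(rnorm(8),
                                 matrix(rbinom(8 * 7, 1, 0.5), 8, 7)),
               "saturated")
})

test_that("combined multivariate pooled test reduces correctly", {
  pan <- toy_panel()
  set.seed(53)
  y <- rnorm(nrow(pan$g))
  commons <- unclass(pan$g)[, c("m4", "m5")]
  pooled <- burden_score(c("m1", "m2", "m3"), pan$g, pan$maf, "weighted_sum")
  # no rare: equals multivariate on commons alone
  cm <- combined_multivariate_pooled(y, commons, NULL)
  expect_equal(cm$lr, multivariate_test(y, commons)$lr, tolerance = 1e-10)
  # no commons: equals lr_test on the pooled score
  cm2 <- combined_multivariate_pooled(y, NULL, pooled)
  expect_equal(cm2$lr, lr_test(y, pooled$z)$lr, tolerance = 1e-10)
  # pooled score must come from the weighted-sum scheme
  sum_pooled <- burden_score(c("m1", "m2", "m3"), pan$g, pan$maf, "sum")
  expect_error(combined_multivariate_pooled(y, commons, sum_pooled),
               "weighted_sum")
  expect_error(combined_multivariate_pooled(y, NULL, NULL), "no common")
})

test_that("combined test accumulates signal from commons and rares", {
  pan <- toy_panel()
  wins <- 0
  set.seed(54)
  for (r in 1:30) {
    pooled <- burden_score(c("m1", "m2", "m3"), pan$g, pan$maf,
                           "weighted_sum")
    commons <- unclass(pan$g)[, c("m4", "m5")]
    y <- 0.8 * commons[, 1] + 0.8 * pooled$z + rnorm(nrow(pan$g))
    lr_comb <- combined_multivariate_pooled(y, commons, pooled)$lr
    lr_mv <- multivariate_test(y, commons)$lr
    lr_pool <- lr_test(y, pooled$z)$lr
    if (lr_comb >= lr_mv && lr_comb >= lr_pool) wins <- wins + 1
  }
  expect_gte(wins / 30, 0.9)
})

test_that("test dispatch follows the fragment composition rule", {
  expect_equal(dispatch_fragment_tests(classify_rarity(c(0.2, 0.3, 0.1))),
               "multivariate")
  expect_setequal(
    dispatch_fragment_tests(classify_rarity(c(0.01, 0.02, 0.03, 0.04))),
    c("sum", "weighted_sum", "function_aided_sum"))
  # 2 rare + 3 common: rare tests blocked by the m >= 3 cutoff
  expect_equal(
    dispatch_fragment_tests(classify_rarity(c(0.01, 0.02, 0.2, 0.3, 0.4))),
    "multivariate")
  # mixed with enough rares: all five tests
  expect_setequal(
    dispatch_fragment_tests(classify_rarity(c(0.01, 0.02, 0.03, 0.2))),
    c("sum", "weighted_sum", "function_aided_sum", "multivariate",
      "combined"))
  expect_equal(dispatch_fragment_tests(classify_rarity(c(0, 0))),
               character(0))
})

test_that("fragment battery matches per-fragment direct computation", {
  pan <- toy_panel()
  set.seed(55)
  y <- rnorm(nrow(pan$g))
  bat <- fragment_battery(y, pan$g, pan$maf, pan$fragments, "sum")
  expect_setequal(bat$unit, c("frag_r", "frag_mix"))
  direct <- lr_test(y, burden_score(pan$fragments$frag_r, pan$g, pan$maf,
                                    "sum")$z)
  expect_equal(bat$lr[bat$unit == "frag_r"], direct$lr, tolerance = 1e-10)
  expect_equal(bat$beta1[bat$unit == "frag_r"], direct$beta1,
               tolerance = 1e-10)
  bat_mv <- fragment_battery(y, pan$g, pan$maf, pan$fragments,
                             "multivariate")
  expect_setequal(bat_mv$unit, c("frag_c", "frag_mix"))
  direct_mv <- multivariate_test(y, unclass(pan$g)[, pan$fragments$frag_c])
  expect_equal(bat_mv$lr[bat_mv$unit == "frag_c"], direct_mv$lr,
               tolerance = 1e-10)
})

test_that("permutation thresholds are deterministic and degenerate correctly", {
  pan <- toy_panel()
  set.seed(56)
  y <- rnorm(nrow(pan$g))
  p1 <- permutation_threshold(y, pan$g, pan$maf, pan$fragments, "sum",
                              n_perm = 150, seed = 9)
  p2 <- permutation_threshold(y, pan$g, pan$maf, pan$fragments, "sum",
                              n_perm = 150, seed = 9)
  expect_identical(p1$maxima, p2$maxima)
  expect_identical(p1$lr99, p2$lr99)
  expect_equal(p1$lr99,
               unname(quantile(p1$maxima, 0.99, type = 7)))
  # monotone in the quantile
  p95 <- permutation_threshold(y, pan$g, pan$maf, pan$fragments, "sum",
                               n_perm = 150, quantile = 0.95, seed = 9)
  expect_lte(p95$lr99, p1$lr99)
  expect_true(all(p1$observed$p_perm >= 0 & p1$observed$p_perm <= 1))
  expect_error(permutation_threshold(y, pan$g, pan$maf, pan$fragments,
                                     "sum", n_perm = 50), ">= 100")
})

test_that("LR/LR99 scaling flags significance at the boundary and is scale-free", {
  res <- data.frame(unit = c("a", "b", "c"), lr = c(5, 0, 10))
  sc <- scale_by_threshold(res, 5)
  expect_equal(sc$lr_ratio, c(1, 0, 2))
  expect_equal(sc$significant, c(TRUE, FALSE, TRUE))
  # multiplying a method's LRs and threshold by c > 0 preserves ordering
  sc2 <- scale_by_threshold(transform(res, lr = lr * 3.7), 5 * 3.7)
  expect_equal(order(-sc2$lr_ratio), order(-sc$lr_ratio))
  expect_equal(sc2$lr_ratio, sc$lr_ratio, tolerance = 1e-12)
  expect_error(scale_by_threshold(res, 0), "LR99")
})

test_that("single-SNP scan applies Bonferroni and finds a planted signal", {
  pan <- toy_panel()
  set.seed(57)
  y <- 1.5 * unclass(pan$g)[, "c2"] + rnorm(nrow(pan$g))
  scan <- single_snp_scan(y, pan$g, pan$maf, alpha = 0.05)
  expect_equal(attr(scan, "alpha_per_test"), 0.05 / attr(scan, "n_tested"))
  expect_equal(scan$unit[which.max(scan$lr)], "c2")
})
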