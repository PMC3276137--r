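#' Likelihood-ratio test of a single regressor
#'
#' Gaussian regression y_adj = b0 + b1 z + e compared against the
#' intercept-only model: LR = n * ln(RSS0 / RSS1), asymptotically
#' chi-square with 1 df under the null.
#'
#' @param y_adj GRAMMAR-adjusted phenotype vector.
#' @param z regressor (per-sample score or genotype column).
#' @param unit,trait,method identifiers carried into the result.
#' @return a one-row `data.frame` of class `crg_test` with columns
#'   `trait`, `unit`, `method`, `lr`, `df`, `beta0`, `beta1`, `p_asym`.
#' @export
lr_test <- function(y_adj, z, unit = "z", trait = "y", method = "single_snp") {
  y_adj <- as.numeric(y_adj); z <- as.numeric(z)
  n <- length(y_adj)
  if (length(z) != n) stop("y_adj and z differ in length")
  if (n < 4L) stop("need n >= 4")
  if (stats::var(z) == 0) stop("inestimable regressor: z is constant")
  yc <- y_adj - mean(y_adj)
  zc <- z - mean(z)
  rss0 <- sum(yc^2)
  beta1 <- sum(yc * zc) / sum(zc^2)
  beta0 <- mean(y_adj) - beta1 * mean(z)
  rss1 <- sum((yc - beta1 * zc)^2)
  if (rss1 <= .Machine$double.eps * rss0) {
    warning("perfect fit; LR capped")
    lr <- n * log(1 / .Machine$double.eps)
  } else {
    lr <- n * log(rss0 / rss1)
  }
  lr <- max(lr, 0)
  out <- data.frame(trait = trait, unit = unit, method = method,
                    lr = lr, df = 1,
                    beta0 = beta0, beta1 = beta1,
                    p_asym = stats::pchisq(lr, df = 1, lower.tail = FALSE),
                    stringsAsFactors = FALSE)
  class(out) <- c("crg_test", "data.frame")
  out
}

#' Single-SNP scan with Bonferroni control
#'
#' One [lr_test()] per polymorphic SNP; the significance flag uses the
#' Bonferroni per-test level alpha / M_tested. Monomorphic SNPs are
#' skipped and counted in attribute `n_monomorphic`.
#'
#' @param y_adj adjusted phenotype vector.
#' @param g a [genotype_matrix()].
#' @param maf per-SNP MAF from [compute_maf()] (recomputed when missing).
#' @param alpha family-wise level (default 0.05).
#' @param trait trait label.
#' @return `data.frame` of test rows with an added `significant` column;
#'   attributes `n_tested`, `n_monomorphic`, `alpha_per_test`.
#' @export
single_snp_scan <- function(y_adj, g, maf = NULL, alpha = 0.05, trait = "y") {
  if (is.null(maf)) maf <- compute_maf(g)
  poly <- maf > 0
  snps <- colnames(g)[poly]
  m_tested <- length(snps)
  rows <- vector("list", m_tested)
  for (i in seq_along(snps)) {
    z <- unclass(g)[, snps[i]]
    if (anyNA(z)) z[is.na(z)] <- mean(z, na.rm = TRUE)
    rows[[i]] <- lr_test(y_adj, z, unit = snps[i], trait = trait,
                         method = "single_snp")
  }
  out <- do.call(rbind, rows)
  thr <- alpha / m_tested
  out$significant <- out$p_asym <= thr
  attr(out, "n_tested") <- m_tested
  attr(out, "n_monomorphic") <- sum(!poly)
  attr(out, "alpha_per_test") <- thr
  out
}

#' Collapse a fragment's rare variants into a burden score
#'
#' Three collapsing schemes over the m >= 3 rare variants (MAF < 0.05) of
#' a fragment:
#' \describe{
#'   \item{sum}{z_i = (sum_j x_ij) / m — every variant weighted equally.}
#'   \item{weighted_sum}{z_i = sum_j x_ij / sqrt(n p_j (1 - p_j)) — each
#'     variant down-weighted by its binomial standard deviation, so rarer
#'     alleles count more.}
#'   \item{function_aided_sum}{z_i = sum_j S_j p_j^F x_ij — the damage
#'     category weight S_j times the predicted proportion of functional
#'     SNPs p_j^F at the variant's MAF (power-law fit, percent units by
#'     default).}
#' }
#'
#' @param snp_ids rare-variant SNP ids of one fragment.
#' @param g a [genotype_matrix()].
#' @param maf named per-SNP MAF vector.
#' @param method one of `"sum"`, `"weighted_sum"`, `"function_aided_sum"`.
#' @param s_weights named per-SNP S weights (see [s_weights_for()]);
#'   required for `function_aided_sum`.
#' @param fit a [fit_frequency_function()] or [power_fit()]; required for
#'   `function_aided_sum`.
#' @return list of class `burden_score`: `z` (per-sample score), `method`,
#'   `snp_ids`, `m`.
#' @export
burden_score <- function(snp_ids, g, maf,
                         method = c("sum", "weighted_sum",
                                    "function_aided_sum"),
                         s_weights = NULL, fit = NULL) {
  method <- match.arg(method)
  p <- maf[snp_ids]
  keep <- p > 0
  snp_ids <- snp_ids[keep]; p <- p[keep]
  m <- length(snp_ids)
  if (m < 3L) stop("insufficient rare variants: m = ", m, " < 3")
  x <- unclass(g)[, snp_ids, drop = FALSE]
  if (anyNA(x)) {
    for (j in seq_len(ncol(x))) {
      mss <- is.na(x[, j])
      if (any(mss)) x[mss, j] <- mean(x[, j], na.rm = TRUE)
    }
  }
  n <- nrow(x)
  z <- switch(method,
    sum = rowSums(x) / m,
    weighted_sum = drop(x %*% (1 / sqrt(n * p * (1 - p)))),
    function_aided_sum = {
      if (is.null(s_weights) || is.null(fit))
        stop("function_aided_sum needs s_weights and a frequency-function fit")
      pj <- if (fit$maf_units == "percent") p * 100 else p
      pf <- as.numeric(predicted_functional_proportion(pj, fit))
      drop(x %*% (s_weights[snp_ids] * pf))
    })
  structure(list(z = unname(z), method = method, snp_ids = snp_ids, m = m),
            class = "burden_score")
}

#' Multivariate test of a set of variant columns
#'
#' Joint Gaussian regression of the adjusted phenotype on all retained
#' columns; LR = n * ln(RSS0 / RSS1) with df = number of retained columns.
#' Collinear columns are reduced to a maximal independent set by QR
#' pivoting in input order (first kept).
#'
#' @param y_adj adjusted phenotype vector.
#' @param x n x m matrix of variant columns (or burden-score columns).
#' @param unit,trait,method identifiers for the result row.
#' @return a `crg_test` row (df = retained columns); attribute
#'   `retained` gives the kept column indices.
#' @export
multivariate_test <- function(y_adj, x, unit = "fragment", trait = "y",
                              method = "multivariate") {
  y_adj <- as.numeric(y_adj)
  x <- as.matrix(x)
  n <- length(y_adj)
  if (nrow(x) != n) stop("dimension mismatch")
  poly <- apply(x, 2L, function(col) stats::var(col, na.rm = TRUE) > 0)
  x <- x[, poly, drop = FALSE]
  if (ncol(x) == 0L) stop("no polymorphic columns")
  if (anyNA(x)) {
    for (j in seq_len(ncol(x))) {
      mss <- is.na(x[, j])
      if (any(mss)) x[mss, j] <- mean(x[, j], na.rm = TRUE)
    }
  }
  xc <- scale(x, center = TRUE, scale = FALSE)
  qrx <- qr(xc)
  keep <- qrx$pivot[seq_len(qrx$rank)]
  keep <- sort(keep)                      # input order, first kept
  xc <- xc[, keep, drop = FALSE]
  df <- ncol(xc)
  if (df >= n - 2L) stop("saturated model: ", df, " columns for n = ", n)
  yc <- y_adj - mean(y_adj)
  rss0 <- sum(yc^2)
  f <- stats::lm.fit(cbind(1, xc), yc)
  rss1 <- sum(f$residuals^2)
  lr <- if (rss1 <= .Machine$double.eps * rss0)
    n * log(1 / .Machine$double.eps) else n * log(rss0 / rss1)
  lr <- max(lr, 0)
  out <- data.frame(trait = trait, unit = unit, method = method,
                    lr = lr, df = df, beta0 = NA_real_, beta1 = NA_real_,
                    p_asym = stats::pchisq(lr, df = df, lower.tail = FALSE),
                    stringsAsFactors = FALSE)
  class(out) <- c("crg_test", "data.frame")
  attr(out, "retained") <- keep
  out
}

#' Combined multivariate pooled test
#'
#' Common variants enter as individual columns and the fragment's rare
#' variants enter as one pooled weighted-sum column; the joint set is
#' tested by [multivariate_test()]. With no rare variants this reduces to
#' the multivariate test of the commons; with no commons it reduces to
#' [lr_test()] on the pooled score.
#'
#' @param y_adj adjusted phenotype vector.
#' @param common_x n x c matrix of common-variant columns (may have 0
#'   columns).
#' @param pooled a [burden_score()] built with `method = "weighted_sum"`,
#'   or `NULL`.
#' @param unit,trait identifiers.
#' @return a `crg_test` row with `method = "combined"`.
#' @export
combined_multivariate_pooled <- function(y_adj, common_x, pooled = NULL,
                                         unit = "fragment", trait = "y") {
  has_common <- !is.null(common_x) && ncol(as.matrix(common_x)) > 0L
  has_pooled <- !is.null(pooled)
  if (has_pooled && pooled$method != "weighted_sum")
    stop("pooled score must be built by weighted_sum")
  if (!has_common && !has_pooled)
    stop("no common variants and no pooled rare score")
  cols <- NULL
  if (has_common) cols <- as.matrix(common_x)
  if (has_pooled) cols <- cbind(cols, pooled_rare = pooled$z)
  multivariate_test(y_adj, cols, unit = unit, trait = trait,
                    method = "combined")
}

#' Decide which tests apply to a fragment
#'
#' Fragments with only common SNPs get the multivariate common-variant
#' test. Fragments with m >= 3 rare variants get the three collapsing
#' tests; fragments with both common SNPs and a valid pooled rare score
#' additionally get the combined multivariate pooled test. Fewer than 3
#' rare variants blocks the rare-variant tests (guards against complete
#' linkage disequilibrium between two rare alleles).
#'
#' @param rarity factor from [classify_rarity()] for the fragment's SNPs.
#' @param min_rare minimum rare-variant count for collapsing tests
#'   (default 3).
#' @return character vector of applicable method names.
#' @export
dispatch_fragment_tests <- function(rarity, min_rare = 3L) {
  n_rare <- sum(rarity == "rare")
  n_common <- sum(rarity == "common")
  if (n_rare + n_common == 0L) return(character(0))
  methods <- character(0)
  if (n_common > 0L && n_rare < min_rare) methods <- "multivariate"
  if (n_rare >= min_rare) {
    methods <- c(methods, "sum", "weighted_sum", "function_aided_sum")
    if (n_common > 0L) methods <- c(methods, "multivariate", "combined")
  }
  methods
}

# Build per-fragment score columns for one method so the permutation loop
# reduces to matrix products. Returns list(fragments, type, Z, Qs) where Z
# holds single-regressor scores and Qs orthonormal bases for joint tests.
.fragment_designs <- function(g, maf, fragments, method, min_rare = 3L,
                              maf_threshold = 0.05, s_weights = NULL,
                              fit = NULL) {
  n <- nrow(g)
  designs <- list()
  for (fr in names(fragments)) {
    snps <- fragments[[fr]]
    p <- maf[snps]
    rare <- snps[p > 0 & p < maf_threshold]
    common <- snps[p >= maf_threshold]
    cols <- NULL
    z <- NULL
    if (method %in% c("sum", "weighted_sum", "function_aided_sum")) {
      if (length(rare) < min_rare) next
      z <- burden_score(rare, g, maf, method = method,
                        s_weights = s_weights, fit = fit)$z
    } else if (method == "multivariate") {
      if (length(common) == 0L) next
      cols <- unclass(g)[, common, drop = FALSE]
    } else if (method == "combined") {
      if (length(common) == 0L || length(rare) < min_rare) next
      pooled <- burden_score(rare, g, maf, method = "weighted_sum")
      cols <- cbind(unclass(g)[, common, drop = FALSE],
                    pooled_rare = pooled$z)
    } else stop("unknown method: ", method)
    if (!is.null(z)) {
      if (stats::var(z) == 0) next
      designs[[fr]] <- list(z = z)
    } else {
      for (j in seq_len(ncol(cols))) {
        mss <- is.na(cols[, j])
        if (any(mss)) cols[mss, j] <- mean(cols[, j], na.rm = TRUE)
      }
      keep <- apply(cols, 2L, stats::var) > 0
      cols <- cols[, keep, drop = FALSE]
      if (ncol(cols) == 0L) next
      xc <- scale(cols, center = TRUE, scale = FALSE)
      qrx <- qr(xc)
      piv <- sort(qrx$pivot[seq_len(qrx$rank)])
      xc <- xc[, piv, drop = FALSE]
      if (ncol(xc) >= n - 2L) next
      designs[[fr]] <- list(Q = qr.Q(qr(xc)), df = ncol(xc))
    }
  }
  designs
}

# LR of every fragment design against one (already centered) phenotype.
.design_lrs <- function(designs, yc, n) {
  rss0 <- sum(yc^2)
  vapply(designs, function(d) {
    if (!is.null(d$z)) {
      zc <- d$z - mean(d$z)
      r2 <- sum(yc * zc)^2 / (sum(zc^2) * rss0)
      -n * log(max(1 - r2, .Machine$double.eps))
    } else {
      ssfit <- sum(crossprod(d$Q, yc)^2)
      -n * log(max(1 - ssfit / rss0, .Machine$double.eps))
    }
  }, numeric(1))
}

#' Run one method's fragment battery for one trait
#'
#' @param y_adj adjusted phenotype vector.
#' @param g a [genotype_matrix()].
#' @param maf named per-SNP MAF vector.
#' @param fragments named list mapping fragment id to its SNP ids.
#' @param method one of the fragment test methods.
#' @param min_rare,maf_threshold rare-variant rules.
#' @param s_weights,fit inputs for `function_aided_sum`.
#' @param trait trait label.
#' @return `data.frame` of `crg_test` rows (one per testable fragment).
#' @export
fragment_battery <- function(y_adj, g, maf, fragments, method,
                             min_rare = 3L, maf_threshold = 0.05,
                             s_weights = NULL, fit = NULL, trait = "y") {
  designs <- .fragment_designs(g, maf, fragments, method, min_rare,
                               maf_threshold, s_weights, fit)
  if (!length(designs)) {
    out <- data.frame(trait = character(0), unit = character(0),
                      method = character(0), lr = numeric(0),
                      df = numeric(0), beta0 = numeric(0),
                      beta1 = numeric(0), p_asym = numeric(0))
    class(out) <- c("crg_test", "data.frame")
    return(out)
  }
  n <- length(y_adj)
  yc <- y_adj - mean(y_adj)
  lrs <- .design_lrs(designs, yc, n)
  dfs <- vapply(designs, function(d) if (is.null(d$df)) 1 else d$df,
                numeric(1))
  beta1 <- vapply(designs, function(d) {
    if (is.null(d$z)) return(NA_real_)
    zc <- d$z - mean(d$z)
    sum(yc * zc) / sum(zc^2)
  }, numeric(1))
  zbar <- vapply(designs, function(d) if (is.null(d$z)) NA_real_
                 else mean(d$z), numeric(1))
  out <- data.frame(trait = trait, unit = names(designs), method = method,
                    lr = unname(lrs), df = unname(dfs),
                    beta0 = ifelse(is.na(beta1), NA_real_,
                                   mean(y_adj) - beta1 * zbar),
                    beta1 = unname(beta1),
                    p_asym = stats::pchisq(unname(lrs), df = unname(dfs),
                                           lower.tail = FALSE),
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("crg_test", "data.frame")
  out
}

#' Experiment-wise permutation threshold (LR99)
#'
#' For one (trait, method) battery: the adjusted phenotype is permuted
#' `n_perm` times (seeded), the maximum LR over all testable fragments is
#' recorded per permutation, and LR99 is the empirical `quantile`-th
#' percentile (type-7 interpolation) of those maxima. Per-fragment
#' permutation p-values are the fraction of permutation maxima at or above
#' the observed LR.
#'
#' @param y_adj adjusted phenotype vector.
#' @param g,maf,fragments,method,min_rare,maf_threshold,s_weights,fit as in
#'   [fragment_battery()].
#' @param n_perm number of permutations (default 1000).
#' @param quantile threshold quantile (default 0.99).
#' @param seed integer seed; same seed gives identical thresholds.
#' @return list of class `perm_threshold`: `lr99`, `maxima`, `observed`
#'   (battery with added `p_perm`), `n_perm`, `quantile`, `seed`.
#' @export
permutation_threshold <- function(y_adj, g, maf, fragments, method,
                                  n_perm = 1000L, quantile = 0.99,
                                  seed = 1L, min_rare = 3L,
                                  maf_threshold = 0.05,
                                  s_weights = NULL, fit = NULL,
                                  trait = "y") {
  if (n_perm < 100L) stop("n_perm must be >= 100")
  designs <- .fragment_designs(g, maf, fragments, method, min_rare,
                               maf_threshold, s_weights, fit)
  obs <- fragment_battery(y_adj, g, maf, fragments, method, min_rare,
                          maf_threshold, s_weights, fit, trait = trait)
  n <- length(y_adj)
  maxima <- rep(NA_real_, n_perm)
  if (length(designs)) {
    old_seed <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old_seed))
      assign(".Random.seed", old_seed, envir = globalenv()))
    set.seed(seed)
    for (b in seq_len(n_perm)) {
      yp <- y_adj[sample.int(n)]
      maxima[b] <- max(.design_lrs(designs, yp - mean(yp), n))
    }
  } else {
    maxima <- rep(0, n_perm)
  }
  lr99 <- unname(stats::quantile(maxima, probs = quantile, type = 7))
  if (nrow(obs))
    obs$p_perm <- vapply(obs$lr, function(l) mean(maxima >= l), numeric(1))
  structure(list(lr99 = lr99, maxima = maxima, observed = obs,
                 n_perm = n_perm, quantile = quantile, seed = seed,
                 method = method, trait = trait),
            class = "perm_threshold")
}

#' Scale test statistics by their permutation threshold
#'
#' lr_ratio = LR / LR99 puts the different tests on one common scale; a
#' fragment is experiment-wise significant when lr_ratio >= 1.
#'
#' @param results a `crg_test` data.frame with an `lr` column.
#' @param lr99 positive threshold from [permutation_threshold()].
#' @return `results` with added `lr99`, `lr_ratio`, `significant` columns.
#' @export
scale_by_threshold <- function(results, lr99) {
  if (!is.numeric(lr99) || lr99 <= 0) stop("LR99 must be > 0")
  results$lr99 <- lr99
  results$lr_ratio <- results$lr / lr99
  results$significant <- results$lr_ratio >= 1
  results
}
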