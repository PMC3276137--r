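#' Build a covariate set (fixed-effect design matrix)
#'
#' @param x n x q numeric matrix of structure coordinates (no intercept
#'   column), or `NULL` for the null model.
#' @param label model label, e.g. `"null"`, `"pca(3)"`, `"Q"`.
#' @param n number of samples (required when `x` is `NULL`).
#' @return object of class `covariate_set`: design matrix with a leading
#'   intercept column, full column rank enforced.
#' @export
covariate_set <- function(x = NULL, label = "null", n = NULL) {
  if (is.null(x)) {
    if (is.null(n)) stop("n required for the null covariate set")
    X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  } else {
    x <- as.matrix(x)
    X <- cbind(`(Intercept)` = 1, x)
  }
  if (ncol(X) >= nrow(X)) stop("covariate set must have q < n columns")
  if (qr(X)$rank < ncol(X)) stop("covariate set is rank deficient")
  structure(X, label = label, class = c("covariate_set", "matrix", "array"))
}

#' Principal-component covariates from genotypes
#'
#' Centered (mean-imputed) genotype PCA as a built-in alternative to
#' file-supplied STRUCTURE/nMDS coordinates.
#'
#' @param g a [genotype_matrix()].
#' @param k number of leading components.
#' @return a [covariate_set()] labelled `"pca(k)"`.
#' @export
pca_covariates <- function(g, k = 2L) {
  x <- unclass(g)
  for (j in seq_len(ncol(x))) {
    m <- is.na(x[, j])
    if (any(m)) x[m, j] <- mean(x[, j], na.rm = TRUE)
  }
  x <- scale(x, center = TRUE, scale = FALSE)
  pc <- svd(x, nu = k, nv = 0)$u[, seq_len(k), drop = FALSE]
  colnames(pc) <- paste0("PC", seq_len(k))
  covariate_set(pc, label = sprintf("pca(%d)", k))
}

#' Read file-supplied structure covariates
#'
#' TSV with first column sample id, remaining columns coordinates
#' (e.g. STRUCTURE Q or nMDS axes).
#'
#' @param path file path.
#' @param samples sample order to align rows to.
#' @param label model label for the resulting covariate set.
#' @return a [covariate_set()].
#' @export
read_covariates <- function(path, samples, label = "Q") {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  rownames(tab) <- tab[[1L]]
  miss <- setdiff(samples, rownames(tab))
  if (length(miss)) stop("covariate file lacks samples: ",
                         paste(miss, collapse = ", "))
  covariate_set(as.matrix(tab[samples, -1L, drop = FALSE]), label = label)
}

# REML/ML engine. The single random effect with covariance 2K*sigma_g^2
# admits a 1-D profile: with A = 2K = U D U', V = sigma_e^2 (I + delta A)
# where delta = sigma_g^2 / sigma_e^2, so after rotating by U' the model is
# a weighted regression with weights 1/(1 + delta d_i) and the likelihood
# is profiled down to delta alone.
.profile_fit <- function(ytil, Xtil, d, delta, criterion) {
  n <- length(ytil); q <- ncol(Xtil)
  w <- 1 / (1 + delta * d)
  XtWX <- crossprod(Xtil, Xtil * w)
  XtWy <- crossprod(Xtil, ytil * w)
  beta <- solve(XtWX, XtWy)
  r <- ytil - Xtil %*% beta
  rss <- sum(w * r^2)
  ldV <- sum(log(1 + delta * d))
  if (criterion == "reml") {
    s2 <- rss / (n - q)
    ll <- -0.5 * ((n - q) * log(2 * pi * s2) + ldV +
                    determinant(XtWX, logarithm = TRUE)$modulus[1] -
                    determinant(crossprod(Xtil), logarithm = TRUE)$modulus[1] +
                    (n - q))
  } else {
    s2 <- rss / n
    ll <- -0.5 * (n * log(2 * pi * s2) + ldV + n)
  }
  list(ll = ll, beta = drop(beta), s2 = s2, w = w, resid = drop(r))
}

.optimize_delta <- function(ytil, Xtil, d, criterion, tol = 1e-8) {
  obj <- function(ld) -.profile_fit(ytil, Xtil, d, exp(ld), criterion)$ll
  # include delta = 0 (no polygenic variance) explicitly as a boundary case
  opt <- stats::optimize(obj, interval = c(log(1e-8), log(1e8)), tol = tol)
  ll0 <- -obj(-Inf)  # exp(-Inf) = 0
  if (ll0 >= -opt$objective) list(delta = 0, ll = ll0)
  else list(delta = exp(opt$minimum), ll = -opt$objective)
}

#' Fit the unified mixed model y = Xb + u + e
#'
#' Polygenic background u has covariance 2K sigma_g^2 and residual e has
#' I sigma_e^2, so the phenotypic covariance is V = 2K sigma_g^2 +
#' I sigma_e^2. Variance components are estimated by REML via spectral
#' decomposition of 2K (one-dimensional profile over the variance ratio),
#' fixed effects by generalized least squares at the optimum, and the
#' polygenic BLUP is u_hat = 2K sigma_g^2 V^-1 (y - X beta_hat). The ML
#' log-likelihood (maximized separately over the same profile) feeds BIC =
#' -2 lnL_ML + q_total ln(n), where q_total counts fixed effects plus
#' estimated variance parameters. Without kinship the model reduces to
#' ordinary least squares.
#'
#' @param y complete numeric phenotype vector (normalize first).
#' @param X a [covariate_set()] (or plain design matrix with intercept).
#' @param K a [estimate_kinship()] matrix; ignored when
#'   `use_kinship = FALSE`.
#' @param use_kinship include the polygenic random effect?
#' @return object of class `crg_mm` with elements `sigma_g2`, `sigma_e2`,
#'   `beta`, `u`, `loglik_reml`, `loglik_ml`, `bic`, `y_adj`, `fitted`,
#'   `label`, `n`, `q`.
#' @export
fit_mixed_model <- function(y, X, K = NULL, use_kinship = !is.null(K)) {
  y <- as.numeric(y)
  n <- length(y)
  if (anyNA(y)) stop("y must be complete")
  X <- as.matrix(X)
  q <- ncol(X)
  label <- attr(X, "label")
  if (is.null(label)) label <- "custom"

  if (!use_kinship) {
    fit <- stats::lm.fit(X, y)
    rss <- sum(fit$residuals^2)
    s2_ml <- rss / n
    ll_ml <- -0.5 * (n * log(2 * pi * s2_ml) + n)
    s2_reml <- rss / (n - q)
    ll_reml <- -0.5 * (n - q) * (log(2 * pi * s2_reml) + 1)
    out <- list(sigma_g2 = 0, sigma_e2 = s2_reml,
                beta = stats::coef(fit), u = rep(0, n),
                loglik_reml = ll_reml, loglik_ml = ll_ml,
                bic = -2 * ll_ml + (q + 1) * log(n),
                y_adj = unname(fit$residuals),
                fitted = unname(fit$fitted.values),
                use_kinship = FALSE, label = paste0(label, " -K"),
                n = n, q = q, delta = 0)
    class(out) <- "crg_mm"
    return(out)
  }

  A <- 2 * as.matrix(K)
  eg <- eigen(A, symmetric = TRUE)
  if (min(eg$values) < -1e-8)
    stop("2K is not positive semi-definite; condition the kinship matrix")
  d <- pmax(eg$values, 0)
  U <- eg$vectors
  ytil <- drop(crossprod(U, y))
  Xtil <- crossprod(U, X)

  reml <- .optimize_delta(ytil, Xtil, d, "reml")
  ml <- .optimize_delta(ytil, Xtil, d, "ml")
  at <- .profile_fit(ytil, Xtil, d, reml$delta, "reml")
  sigma_e2 <- at$s2
  sigma_g2 <- reml$delta * sigma_e2
  # BLUP in the rotated basis: delta*d/(1+delta*d) shrinkage of residuals
  shrink <- reml$delta * d / (1 + reml$delta * d)
  u <- drop(U %*% (shrink * at$resid))
  fitted_fixed <- drop(X %*% at$beta)
  y_adj <- y - fitted_fixed - u

  out <- list(sigma_g2 = sigma_g2, sigma_e2 = sigma_e2,
              beta = stats::setNames(at$beta, colnames(X)),
              u = u,
              loglik_reml = reml$ll, loglik_ml = ml$ll,
              bic = -2 * ml$ll + (q + 2) * log(n),
              y_adj = y_adj, fitted = fitted_fixed + u,
              use_kinship = TRUE, label = paste0(label, " +K"),
              n = n, q = q, delta = reml$delta)
  class(out) <- "crg_mm"
  out
}

#' @export
print.crg_mm <- function(x, ...) {
  cat(sprintf("mixed model [%s]: n = %d, q = %d\n", x$label, x$n, x$q))
  cat(sprintf("  sigma_g^2 = %.4g, sigma_e^2 = %.4g\n", x$sigma_g2, x$sigma_e2))
  cat(sprintf("  logLik(REML) = %.3f, logLik(ML) = %.3f, BIC = %.3f\n",
              x$loglik_reml, x$loglik_ml, x$bic))
  invisible(x)
}

#' @export
coef.crg_mm <- function(object, ...) object$beta

#' @export
logLik.crg_mm <- function(object, REML = TRUE, ...) {
  val <- if (REML) object$loglik_reml else object$loglik_ml
  structure(val, df = object$q + 1 + object$use_kinship, class = "logLik")
}

#' @export
residuals.crg_mm <- function(object, ...) object$y_adj

#' @export
fitted.crg_mm <- function(object, ...) object$fitted

#' Select the structure model by BIC
#'
#' Fits every candidate covariate set with and without the kinship random
#' effect and returns the fit minimizing BIC (ties broken toward fewer
#' parameters). The full BIC table is attached as attribute `bic_table`.
#'
#' @param y complete phenotype vector.
#' @param covariate_sets list of [covariate_set()] candidates.
#' @param K kinship matrix, or `NULL` to consider fixed-effect models only.
#' @return the best `crg_mm` fit.
#' @export
select_structure_model <- function(y, covariate_sets, K = NULL) {
  fits <- list()
  for (X in covariate_sets) {
    variants <- if (is.null(K)) list(FALSE) else list(FALSE, TRUE)
    for (uk in variants) {
      f <- tryCatch(fit_mixed_model(y, X, K, use_kinship = uk),
                    error = function(e) {
                      warning("candidate failed: ", conditionMessage(e))
                      NULL
                    })
      if (!is.null(f)) fits[[length(fits) + 1L]] <- f
    }
  }
  if (!length(fits)) stop("no candidate model could be fitted")
  bics <- vapply(fits, `[[`, numeric(1), "bic")
  npar <- vapply(fits, function(f) f$q + 1L + f$use_kinship, numeric(1))
  best <- order(bics, npar)[1L]
  out <- fits[[best]]
  attr(out, "bic_table") <- data.frame(
    label = vapply(fits, `[[`, character(1), "label"),
    n_par = npar, bic = bics, selected = seq_along(fits) == best)
  out
}

#' GRAMMAR-adjusted phenotype
#'
#' The residual y - X beta_hat - u_hat of the fitted structure model: the
#' phenotype with fixed structure effects and the polygenic BLUP removed,
#' used in place of y for all marker tests (two-stage GRAMMAR strategy).
#'
#' @param fit a `crg_mm`.
#' @return numeric vector of adjusted phenotypes.
#' @export
grammar_residuals <- function(fit) {
  stopifnot(inherits(fit, "crg_mm"))
  fit$y_adj
}

#' Genomic-control inflation factor
#'
#' lambda = median(LR) / 0.4549 (the chi-square 1 df median). By default
#' statistics are divided by max(lambda, 1): deflation corrects residual
#' confounding, while lambda < 1 never inflates. `mode = "symmetric"`
#' divides by lambda unconditionally; `mode = "off"` leaves them unchanged.
#'
#' @param lr_stats nonnegative statistics, nominally chi-square 1 df under
#'   the null.
#' @param mode `"deflate-only"` (default), `"symmetric"`, or `"off"`.
#' @return list of class `inflation_adjustment` with `lambda`, `divisor`,
#'   `adjusted`.
#' @export
inflation_factor <- function(lr_stats,
                             mode = c("deflate-only", "symmetric", "off")) {
  mode <- match.arg(mode)
  if (any(lr_stats < 0)) stop("statistics must be nonnegative")
  if (length(lr_stats) < 20L)
    warning("fewer than 20 statistics; lambda estimate is unstable")
  lambda <- stats::median(lr_stats) / stats::qchisq(0.5, df = 1)
  divisor <- switch(mode,
                    `deflate-only` = max(lambda, 1),
                    symmetric = lambda,
                    off = 1)
  structure(list(lambda = lambda, divisor = divisor, mode = mode,
                 adjusted = lr_stats / divisor),
            class = "inflation_adjustment")
}
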