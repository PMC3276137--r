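#' Marker-based kinship from allele sharing
#'
#' Pairwise allele-sharing similarity rescaled so that the average
#' unrelated pair has kinship zero: S_ik is the proportion of SNPs at
#' which samples i and k carry identical calls (missing calls mean-imputed
#' per SNP for this computation only, so two samples missing the same SNP
#' match), and K_ik = max(0, (S_ik - mean_off) / (1 - mean_off)) with
#' mean_off the mean off-diagonal similarity. The diagonal is set to 1 and
#' the result is projected to the nearest positive semi-definite matrix
#' (negative eigenvalues clipped) if needed.
#'
#' @param g a [genotype_matrix()].
#' @return n x n matrix of class `kinship_matrix` with attribute
#'   `estimator = "allele_sharing"`.
#' @export
estimate_kinship <- function(g) {
  stopifnot(inherits(g, "genotype_matrix"))
  n <- nrow(g); M <- ncol(g)
  if (n < 3L) stop("kinship needs at least 3 samples")
  if (M < 10L) warning("fewer than 10 SNPs; kinship estimate will be noisy")
  ploidy <- attr(g, "ploidy")
  obs <- !is.na(g)
  # exact match count via per-allele-count indicator crossproducts;
  # mean-imputed missing values match iff both samples miss the same SNP
  S <- tcrossprod(matrix(as.numeric(!obs), n))
  x <- unclass(g)
  for (v in 0:ploidy) {
    iv <- matrix(as.numeric(obs & !is.na(x) & x == v), n)
    S <- S + tcrossprod(iv)
  }
  S <- S / M
  off <- S[lower.tri(S)]
  s_bar <- mean(off)
  if (s_bar >= 1) stop("all samples identical; kinship degenerate")
  K <- (S - s_bar) / (1 - s_bar)
  K[K < 0] <- 0
  diag(K) <- 1
  K <- (K + t(K)) / 2
  ev <- eigen(K, symmetric = TRUE)
  if (min(ev$values) < -1e-10) {
    message("kinship projected to nearest PSD matrix (min eigenvalue ",
            format(min(ev$values), digits = 3), " clipped)")
    vals <- pmax(ev$values, 0)
    K <- ev$vectors %*% (vals * t(ev$vectors))
    K <- (K + t(K)) / 2
    K <- stats::cov2cor(K)   # restore the unit diagonal, PSD preserved
  }
  dimnames(K) <- list(rownames(g), rownames(g))
  structure(K, estimator = "allele_sharing",
            class = c("kinship_matrix", "matrix", "array"))
}

#' @export
print.kinship_matrix <- function(x, ...) {
  off <- x[lower.tri(x)]
  cat(sprintf("kinship_matrix (%s): %d samples, mean off-diagonal %.3f\n",
              attr(x, "estimator"), nrow(x), mean(off)))
  invisible(x)
}
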