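#' Construct a phenotype table
#'
#' @param values numeric matrix, samples in rows, traits in columns; `NA`
#'   marks missing entries.
#' @param samples,traits identifiers (default from dimnames).
#' @param state processing state: `"raw"`, `"imputed"`, or `"normalized"`.
#' @return object of class `phenotype_table` (a numeric matrix with a
#'   `state` attribute).
#' @export
phenotype_table <- function(values, samples = rownames(values),
                            traits = colnames(values), state = "raw") {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(samples) || is.null(traits))
    stop("sample and trait identifiers are required")
  if (anyDuplicated(samples)) stop("duplicated sample identifiers")
  if (anyDuplicated(traits)) stop("duplicated trait names")
  state <- match.arg(state, c("raw", "imputed", "normalized"))
  if (state != "raw" && anyNA(values))
    stop("state '", state, "' admits no missing values")
  dimnames(values) <- list(as.character(samples), as.character(traits))
  structure(values, state = state,
            class = c("phenotype_table", "matrix", "array"))
}

#' @export
print.phenotype_table <- function(x, ...) {
  cat(sprintf("phenotype_table: %d samples x %d traits (%s, %.1f%% missing)\n",
              nrow(x), ncol(x), attr(x, "state"), 100 * mean(is.na(x))))
  invisible(x)
}

#' Read a phenotype table from TSV
#'
#' First column sample id, header row trait names, `NA` for missing.
#' @param path file path.
#' @return a [phenotype_table()] in state `"raw"`.
#' @export
read_phenotypes <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) stop("parse error: TSV needs sample column + >=1 trait")
  vals <- as.matrix(tab[, -1L, drop = FALSE])
  storage.mode(vals) <- "double"
  phenotype_table(vals, samples = tab[[1L]], traits = colnames(tab)[-1L])
}

#' Impute missing phenotypes from correlated traits
#'
#' Deterministic k-nearest-trait imputation exploiting inter-trait
#' correlation: traits are standardized, each missing cell is filled with
#' the correlation-weighted mean of that sample's `k` most correlated
#' observed traits (nearest by absolute pairwise correlation over complete
#' pairs, sign carried by the correlation), then mapped back to the target
#' trait's scale.
#'
#' @param p a [phenotype_table()] in state `"raw"`.
#' @param k_neighbors number of donor traits per missing cell (default 3).
#' @return a [phenotype_table()] in state `"imputed"`.
#' @export
impute_phenotypes <- function(p, k_neighbors = 3L) {
  stopifnot(inherits(p, "phenotype_table"))
  vals <- unclass(p)
  attr(vals, "state") <- NULL
  nobs_trait <- colSums(!is.na(vals))
  if (any(nobs_trait < 2L))
    stop("trait(s) with fewer than 2 observations: ",
         paste(colnames(vals)[nobs_trait < 2L], collapse = ", "))
  if (any(rowSums(!is.na(vals)) == 0L))
    stop("sample(s) with all traits missing: ",
         paste(rownames(vals)[rowSums(!is.na(vals)) == 0L], collapse = ", "))
  if (!anyNA(vals))
    return(phenotype_table(vals, state = "imputed"))

  mu <- colMeans(vals, na.rm = TRUE)
  sd_ <- apply(vals, 2L, stats::sd, na.rm = TRUE)
  sd_[sd_ == 0] <- 1           # constant traits impute to their mean
  z <- sweep(sweep(vals, 2L, mu), 2L, sd_, "/")
  r <- suppressWarnings(stats::cor(z, use = "pairwise.complete.obs"))
  r[is.na(r)] <- 0
  diag(r) <- 0

  miss <- which(is.na(vals), arr.ind = TRUE)
  for (idx in seq_len(nrow(miss))) {
    i <- miss[idx, 1L]; t <- miss[idx, 2L]
    donors <- which(!is.na(z[i, ]))
    donors <- donors[donors != t]
    ar <- abs(r[t, donors])
    ord <- order(ar, decreasing = TRUE)
    sel <- donors[ord][seq_len(min(k_neighbors, length(donors)))]
    w <- abs(r[t, sel])
    zhat <- if (sum(w) > 0) sum(r[t, sel] * z[i, sel]) / sum(w) else 0
    vals[i, t] <- mu[t] + sd_[t] * zhat
  }
  phenotype_table(vals, state = "imputed")
}

#' Rank-based inverse-normal transform of each trait
#'
#' Applies the Blom transform qnorm((r - 3/8) / (n + 1/4)) per trait, with
#' midranks for ties, then removes any residual mean so every column is
#' centered. Rank order within a trait is preserved.
#'
#' @param p a complete [phenotype_table()] (state `"imputed"` or `"raw"`
#'   with no missing cells).
#' @return a [phenotype_table()] in state `"normalized"`.
#' @export
normalize_phenotypes <- function(p) {
  stopifnot(inherits(p, "phenotype_table"))
  vals <- unclass(p)
  attr(vals, "state") <- NULL
  if (anyNA(vals)) stop("normalize requires a complete table; impute first")
  const <- apply(vals, 2L, function(x) max(x) == min(x))
  if (any(const))
    stop("constant trait(s): ", paste(colnames(vals)[const], collapse = ", "))
  n <- nrow(vals)
  out <- apply(vals, 2L, function(x) {
    z <- stats::qnorm((rank(x, ties.method = "average") - 3 / 8) / (n + 1 / 4))
    z - mean(z)
  })
  dimnames(out) <- dimnames(vals)
  phenotype_table(out, state = "normalized")
}
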