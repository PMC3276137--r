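#' Rules mapping prediction categories to functional calls
#'
#' PolyPhen `possibly_damaging`/`probably_damaging` and SIFT `intolerant`
#' count as functional; `benign` and `tolerant` are nonfunctional; nonsense
#' changes are always functional because a premature stop is at least as
#' damaging as a probably-damaging substitution.
#'
#' @param polyphen_functional PolyPhen categories treated as functional.
#' @param sift_functional SIFT categories treated as functional.
#' @param nonsense_always_functional logical, default `TRUE`.
#' @return list of class `function_call_rules`.
#' @export
function_call_rules <- function(
    polyphen_functional = c("possibly_damaging", "probably_damaging"),
    sift_functional = "intolerant",
    nonsense_always_functional = TRUE) {
  stopifnot(!"benign" %in% polyphen_functional,
            !"tolerant" %in% sift_functional)
  structure(list(polyphen_functional = polyphen_functional,
                 sift_functional = sift_functional,
                 nonsense_always_functional = nonsense_always_functional),
            class = "function_call_rules")
}

#' Call SNPs functional or nonfunctional from predictions
#'
#' @param ann a [variant_annotation()].
#' @param rules a [function_call_rules()].
#' @param predictor `"polyphen"` or `"sift"`.
#' @return logical vector (one call per SNP). SNPs with no prediction and no
#'   nonsense flag are called `FALSE`; their count is attached as attribute
#'   `n_unscored`.
#' @export
call_functional <- function(ann, rules = function_call_rules(),
                            predictor = c("polyphen", "sift")) {
  predictor <- match.arg(predictor)
  cat_ <- ann[[predictor]]
  fun_set <- if (predictor == "polyphen") rules$polyphen_functional
             else rules$sift_functional
  out <- cat_ %in% fun_set
  if (rules$nonsense_always_functional) out <- out | ann$nonsense
  unscored <- cat_ == "none" & !ann$nonsense
  structure(out, n_unscored = sum(unscored), names = ann$snp_id)
}

#' Bin SNPs by minor allele frequency
#'
#' Twenty left-open right-closed bins of width 2.5% over (0, 0.5]; a SNP
#' with MAF m falls in bin `ceiling(m / width)` so boundary values belong
#' to the lower bin. Monomorphic SNPs (MAF 0) are rejected.
#'
#' @param mafs numeric vector in (0, 0.5].
#' @param functional_calls logical vector aligned with `mafs`.
#' @param n_bins,width binning grid (defaults 20 x 0.025).
#' @return data.frame of class `maf_binning` with columns `bin`, `lower`,
#'   `upper`, `midpoint`, `n_total`, `n_functional`, `proportion`.
#' @export
bin_by_maf <- function(mafs, functional_calls, n_bins = 20L, width = 0.025) {
  if (any(mafs <= 0)) stop("monomorphic SNP(s): MAF must be > 0 for binning")
  if (any(mafs > n_bins * width + 1e-12)) stop("MAF above binning range")
  if (length(mafs) != length(functional_calls))
    stop("mafs and functional_calls differ in length")
  bin <- pmin(pmax(ceiling(mafs / width - 1e-12), 1L), n_bins)
  n_total <- tabulate(bin, nbins = n_bins)
  n_fun <- vapply(seq_len(n_bins),
                  function(b) sum(functional_calls[bin == b]), numeric(1))
  out <- data.frame(
    bin = seq_len(n_bins),
    lower = (seq_len(n_bins) - 1L) * width,
    upper = seq_len(n_bins) * width,
    midpoint = (seq_len(n_bins) - 0.5) * width,
    n_total = n_total,
    n_functional = n_fun,
    proportion = ifelse(n_total > 0, n_fun / n_total, NA_real_)
  )
  class(out) <- c("maf_binning", "data.frame")
  out
}

#' Fit the MAF-to-proportion-functional relationship
#'
#' Fits one of three regressions of the per-bin proportion of functional
#' SNPs on the bin's representative MAF `p`: power `a * p^b` (ordinary
#' least squares of log proportion on log p), logarithmic `a * ln(p) + b`,
#' or linear `a * p + b`. R-squared is always computed on the original
#' proportion scale (squared correlation of fitted and observed) so the
#' three models are comparable.
#'
#' @param bins a [bin_by_maf()] result (or data.frame with `midpoint`,
#'   `n_total`, `proportion`).
#' @param model `"power"`, `"logarithmic"`, or `"linear"`.
#' @param maf_units `"percent"` (default; bin midpoints scaled by 100) or
#'   `"fraction"`. The published damage-prediction curves are in percent.
#' @param representative `"midpoint"` (default) or a numeric vector of
#'   per-bin representative MAFs in fraction units (e.g. per-bin mean MAF).
#' @return list of class `frequency_function_fit` with elements `model`,
#'   `a`, `b`, `r_squared`, `maf_units`, `n_bins_used`.
#' @export
fit_frequency_function <- function(bins,
                                   model = c("power", "logarithmic", "linear"),
                                   maf_units = c("percent", "fraction"),
                                   representative = "midpoint") {
  model <- match.arg(model)
  maf_units <- match.arg(maf_units)
  p <- if (identical(representative, "midpoint")) bins$midpoint
       else as.numeric(representative)
  if (maf_units == "percent") p <- p * 100
  use <- bins$n_total > 0 & !is.na(bins$proportion)
  y <- bins$proportion
  if (model == "power") use <- use & y > 0  # log scale needs y > 0
  if (sum(use) < 3L) stop("need at least 3 usable bins, got ", sum(use))
  pu <- p[use]; yu <- y[use]
  fit <- switch(model,
    power = {
      m <- stats::lm(log(yu) ~ log(pu))
      list(a = exp(unname(stats::coef(m)[1L])), b = unname(stats::coef(m)[2L]))
    },
    logarithmic = {
      m <- stats::lm(yu ~ log(pu))
      list(a = unname(stats::coef(m)[2L]), b = unname(stats::coef(m)[1L]))
    },
    linear = {
      m <- stats::lm(yu ~ pu)
      list(a = unname(stats::coef(m)[2L]), b = unname(stats::coef(m)[1L]))
    })
  fitted_orig <- switch(model,
    power = fit$a * pu ^ fit$b,
    logarithmic = fit$a * log(pu) + fit$b,
    linear = fit$a * pu + fit$b)
  r2 <- if (stats::sd(fitted_orig) == 0 || stats::sd(yu) == 0) 0
        else stats::cor(fitted_orig, yu)^2
  structure(list(model = model, a = fit$a, b = fit$b,
                 r_squared = r2, maf_units = maf_units,
                 n_bins_used = sum(use)),
            class = "frequency_function_fit")
}

#' @export
print.frequency_function_fit <- function(x, ...) {
  form <- switch(x$model,
                 power = sprintf("pF = %.4f * p^%.4f", x$a, x$b),
                 logarithmic = sprintf("pF = %.4f * ln(p) + %.4f", x$a, x$b),
                 linear = sprintf("pF = %.4f * p + %.4f", x$a, x$b))
  cat(sprintf("%s fit (%s units, %d bins): %s, R^2 = %.3f\n",
              x$model, x$maf_units, x$n_bins_used, form, x$r_squared))
  invisible(x)
}

#' Predicted proportion of functional SNPs at a given MAF
#'
#' Evaluates a fitted frequency function at MAF `p` (in the fit's units).
#' The raw, unclipped value is returned because it is used as a regression
#' weight; the value clipped to \[0, 1\] is attached as attribute
#' `clipped` for display as a proportion.
#'
#' @param p MAF value(s), strictly positive, in the fit's units.
#' @param fit a [fit_frequency_function()] result.
#' @return numeric vector of predicted proportions (unclipped).
#' @export
predicted_functional_proportion <- function(p, fit) {
  stopifnot(inherits(fit, "frequency_function_fit"))
  if (any(p <= 0)) stop("p must be > 0")
  raw <- switch(fit$model,
                power = fit$a * p ^ fit$b,
                logarithmic = fit$a * log(p) + fit$b,
                linear = fit$a * p + fit$b)
  structure(raw, clipped = pmin(1, pmax(0, raw)))
}

#' Convenience constructor for the published damage-prediction power curve
#'
#' @param a,b power-law coefficients; defaults are the PolyPhen curve fitted
#'   to the Arabidopsis fragment panel (percent MAF units).
#' @param maf_units units of `p` in `a * p^b`.
#' @return a `frequency_function_fit`.
#' @export
power_fit <- function(a = 0.3562, b = -1.4162, maf_units = "percent") {
  structure(list(model = "power", a = a, b = b, r_squared = NA_real_,
                 maf_units = maf_units, n_bins_used = NA_integer_),
            class = "frequency_function_fit")
}

#' Congruency test between PolyPhen and SIFT functional calls
#'
#' Pearson chi-square (1 df, no continuity correction) on the 2x2
#' cross-tabulation of the two predictors' functional/nonfunctional calls.
#' Also reports the proportion of SNPs called nonfunctional by both
#' (the benign-and-tolerant cell).
#'
#' @param polyphen_calls,sift_calls logical vectors over the same SNPs.
#' @return list with `chi_square`, `p_value`, `table` (2x2),
#'   `both_nonfunctional_prop`.
#' @export
congruency_test <- function(polyphen_calls, sift_calls) {
  if (length(polyphen_calls) != length(sift_calls))
    stop("call vectors must cover the same SNPs")
  tab <- table(factor(polyphen_calls, levels = c(TRUE, FALSE)),
               factor(sift_calls, levels = c(TRUE, FALSE)),
               dnn = c("polyphen", "sift"))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("a marginal total of the 2x2 table is zero")
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(chi_square = unname(ct$statistic),
       p_value = unname(ct$p.value),
       table = tab,
       both_nonfunctional_prop = tab["FALSE", "FALSE"] / sum(tab))
}

#' Per-category damage weights for the function-aided sum test
#'
#' Mean PolyPhen delta scores per damage category used as the S weight of
#' each rare variant: benign or synonymous 0.6772, possibly damaging
#' 1.7051, probably damaging 2.4277. Values are configurable but must be
#' positive and non-decreasing in damage severity.
#'
#' @param benign_or_synonymous,possibly_damaging,probably_damaging weights.
#' @return named numeric vector of class `s_weight_map`.
#' @export
s_weight_map <- function(benign_or_synonymous = 0.6772,
                         possibly_damaging = 1.7051,
                         probably_damaging = 2.4277) {
  w <- c(benign_or_synonymous = benign_or_synonymous,
         possibly_damaging = possibly_damaging,
         probably_damaging = probably_damaging)
  if (any(w <= 0)) stop("S weights must be positive")
  if (is.unsorted(w)) stop("S weights must be non-decreasing in severity")
  structure(w, class = "s_weight_map")
}

#' S weight of each SNP from its annotation
#'
#' Probably-damaging SNPs (and nonsense changes) take the probably_damaging
#' weight, possibly-damaging SNPs the middle weight, and everything else
#' (benign, synonymous, unscored) the benign_or_synonymous weight.
#'
#' @param ann a [variant_annotation()].
#' @param s_map an [s_weight_map()].
#' @return named numeric vector of per-SNP S weights.
#' @export
s_weights_for <- function(ann, s_map = s_weight_map()) {
  w <- rep(s_map[["benign_or_synonymous"]], nrow(ann))
  w[ann$polyphen == "possibly_damaging"] <- s_map[["possibly_damaging"]]
  w[ann$polyphen == "probably_damaging" | ann$nonsense] <-
    s_map[["probably_damaging"]]
  names(w) <- ann$snp_id
  w
}
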