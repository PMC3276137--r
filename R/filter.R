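#' Confirm a priori candidate genes
#'
#' A tested unit is confirmed when its gene is on the a priori candidate
#' list and it is significant at level `alpha` under *every* method
#' applicable to it (conjunction across methods). Permutation p-values are
#' used when present, else asymptotic; the source is recorded.
#'
#' @param results `data.frame` of test rows with columns `trait`, `unit`,
#'   `method`, `p_asym` and optionally `p_perm`; one row per
#'   (trait, unit, method).
#' @param gene_of named character vector mapping unit id to gene id
#'   (`NA` for units without a gene).
#' @param candidates character vector of a priori candidate gene ids.
#' @param alpha significance level for the conjunction (default 0.001).
#' @return `data.frame` with one row per (trait, unit): `trait`, `unit`,
#'   `gene`, `n_methods`, `n_significant`, `p_source`, `confirmed`.
#' @export
confirm_a_priori <- function(results, gene_of, candidates, alpha = 0.001) {
  p <- if ("p_perm" %in% names(results) && !all(is.na(results$p_perm)))
    ifelse(is.na(results$p_perm), results$p_asym, results$p_perm)
  else results$p_asym
  src <- if ("p_perm" %in% names(results) && !all(is.na(results$p_perm)))
    "permutation" else "asymptotic"
  key <- interaction(results$trait, results$unit, drop = TRUE)
  agg <- do.call(rbind, lapply(split(seq_len(nrow(results)), key), function(ix) {
    data.frame(trait = results$trait[ix[1L]],
               unit = results$unit[ix[1L]],
               n_methods = length(ix),
               n_significant = sum(p[ix] <= alpha),
               stringsAsFactors = FALSE)
  }))
  rownames(agg) <- NULL
  agg$gene <- unname(gene_of[agg$unit])
  agg$p_source <- src
  agg$confirmed <- !is.na(agg$gene) & agg$gene %in% candidates &
    agg$n_significant == agg$n_methods & agg$n_methods > 0L
  agg[, c("trait", "unit", "gene", "n_methods", "n_significant",
          "p_source", "confirmed")]
}

#' Top-k tests by LR/LR99 ratio
#'
#' Ranks all (trait, unit, method) results by `lr_ratio` descending; ties
#' broken by LR descending, then unit id ascending, so the selection is
#' deterministic. Returns all rows when fewer than `k` exist.
#'
#' @param results `data.frame` with `lr_ratio`, `lr`, `unit` columns.
#' @param k number of tests to keep (default 30).
#' @return the top-k rows with an added `rank` column.
#' @export
top_k <- function(results, k = 30L) {
  if (!"lr_ratio" %in% names(results)) stop("results lack lr_ratio")
  ord <- order(-results$lr_ratio, -results$lr, results$unit)
  out <- results[ord[seq_len(min(k, nrow(results)))], , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Functional-SNP evidence rule for a fragment
#'
#' TRUE when the fragment carries at least `min_count` predicted-functional
#' SNPs. The cutoff of three guards against two rare alleles in complete
#' linkage disequilibrium masquerading as independent evidence.
#'
#' @param snp_ids the fragment's SNP ids.
#' @param ann a [variant_annotation()] covering those SNPs.
#' @param rules a [function_call_rules()].
#' @param predictor predictor used for the functional call.
#' @param min_count evidence threshold (default 3).
#' @return logical; attribute `n_functional` carries the count and
#'   attribute `reason` is `"unannotated"` when no SNP is annotated.
#' @export
functional_snp_filter <- function(snp_ids, ann,
                                  rules = function_call_rules(),
                                  predictor = "polyphen", min_count = 3L) {
  ix <- match(snp_ids, ann$snp_id)
  ix <- ix[!is.na(ix)]
  if (!length(ix))
    return(structure(FALSE, n_functional = 0L, reason = "unannotated"))
  calls <- call_functional(ann[ix, , drop = FALSE], rules, predictor)
  nf <- sum(calls)
  structure(nf >= min_count, n_functional = nf, reason = NULL)
}

#' Cross-method consistency of significant units
#'
#' Intersects the significant unit sets of several methods and reports the
#' Venn cell counts (per-method, pairwise, higher-order, none). All
#' methods must share the unit universe.
#'
#' @param results `data.frame` with `unit`, `method` columns and either a
#'   logical `significant` column or p-values.
#' @param alpha used when `significant` is absent: p_perm (else p_asym)
#'   <= alpha.
#' @return list: `consistent` (units significant in all methods), `venn`
#'   (named counts per method combination, `"none"` for units significant
#'   nowhere), `methods`, `universe`.
#' @export
cross_method_consistency <- function(results, alpha = 0.01) {
  methods <- sort(unique(results$method))
  universes <- lapply(methods, function(m)
    sort(unique(results$unit[results$method == m])))
  uni <- universes[[1L]]
  if (!all(vapply(universes, identical, logical(1), uni)))
    stop("methods do not share the same unit universe")
  if ("significant" %in% names(results)) {
    sig <- results$significant
  } else {
    p <- if ("p_perm" %in% names(results))
      ifelse(is.na(results$p_perm), results$p_asym, results$p_perm)
    else results$p_asym
    sig <- p <= alpha
  }
  sig_sets <- lapply(methods, function(m)
    unique(results$unit[results$method == m & sig]))
  names(sig_sets) <- methods
  membership <- vapply(sig_sets, function(s) uni %in% s,
                       logical(length(uni)))
  membership <- matrix(membership, nrow = length(uni),
                       dimnames = list(uni, methods))
  cell <- apply(membership, 1L, function(r)
    if (!any(r)) "none" else paste(methods[r], collapse = "&"))
  venn <- table(cell)
  consistent <- uni[rowSums(membership) == length(methods)]
  list(consistent = sort(consistent),
       venn = stats::setNames(as.integer(venn), names(venn)),
       methods = methods, universe = uni)
}
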