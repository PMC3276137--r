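#' Run the composite resequencing association pipeline
#'
#' Orchestrates the four-step strategy on loaded data objects:
#' imputation and rank-normalization of phenotypes; kinship estimation
#' and BIC selection of the structure model per trait; GRAMMAR phenotype
#' adjustment; dispatch of the fragment test battery (multivariate
#' common-variant test, and for fragments with >= 3 rare variants the
#' sum, weighted sum and function-aided sum tests plus the combined
#' multivariate pooled test); permutation thresholds and LR/LR99 scaling
#' with genomic-control deflation; the candidate decision layer (a priori
#' confirmation at `alpha`, top-k triage, >= `min_functional` functional
#' SNPs); and, when a network is supplied, seed pruning to the target AUC
#' followed by top-n retrieval and intersection with the top tests.
#'
#' @param genotypes a [genotype_matrix()].
#' @param phenotypes a [phenotype_table()] (any state; imputed/normalized
#'   as needed).
#' @param annotations a [variant_annotation()].
#' @param fragments named list of SNP ids per fragment (defaults to the
#'   fragment membership of `annotations`).
#' @param candidates character vector of a priori candidate gene ids
#'   (optional).
#' @param network a [gene_network()] (optional).
#' @param covariate_sets list of [covariate_set()] candidates for model
#'   selection (default: null model and genotype PCA with 1..2 axes).
#' @param freq_fit a [fit_frequency_function()] result for the
#'   function-aided weights; fitted from the annotations when `NULL`.
#' @param maf_threshold rare/common boundary (default 0.05).
#' @param min_rare minimum rare variants for collapsing tests (default 3).
#' @param n_perm permutations per (trait, method) battery (default 1000).
#' @param quantile threshold quantile for LR99 (default 0.99).
#' @param alpha a priori confirmation level (default 0.001).
#' @param top_k_n top-test triage size (default 30).
#' @param min_functional functional-SNP evidence cutoff (default 3).
#' @param auc_target network seed-pruning target (default 0.95).
#' @param top_n network retrieval size (default 200).
#' @param lambda_mode genomic-control mode (see [inflation_factor()]).
#' @param seed master seed for permutations.
#' @return object of class `crgwas`: list with `results` (all scaled test
#'   rows), `single_snp`, `model_fits`, `lr99`, `lambda`, `filter`
#'   (a priori confirmation report), `top_tests`, `consistency`,
#'   `network` (pruning/retrieval/intersection, or `NULL`), `config`.
#' @export
run_crgwas <- function(genotypes, phenotypes, annotations,
                       fragments = NULL, candidates = NULL, network = NULL,
                       covariate_sets = NULL, freq_fit = NULL,
                       maf_threshold = 0.05, min_rare = 3L,
                       n_perm = 1000L, quantile = 0.99, alpha = 0.001,
                       top_k_n = 30L, min_functional = 3L,
                       auc_target = 0.95, top_n = 200L,
                       lambda_mode = "deflate-only", seed = 1L) {
  stopifnot(inherits(genotypes, "genotype_matrix"),
            inherits(phenotypes, "phenotype_table"),
            inherits(annotations, "variant_annotation"))
  if (is.null(fragments))
    fragments <- split(annotations$snp_id, annotations$fragment_id)
  gene_of <- stats::setNames(
    vapply(split(annotations$gene_id, annotations$fragment_id),
           function(gs) gs[1L], character(1)),
    names(split(annotations$gene_id, annotations$fragment_id)))

  # --- phenotype preparation ---------------------------------------------
  if (attr(phenotypes, "state") == "raw" && anyNA(phenotypes))
    phenotypes <- impute_phenotypes(phenotypes)
  if (attr(phenotypes, "state") != "normalized")
    phenotypes <- normalize_phenotypes(
      if (attr(phenotypes, "state") == "raw")
        phenotype_table(unclass(phenotypes), state = "imputed")
      else phenotypes)

  maf <- compute_maf(genotypes)
  K <- estimate_kinship(genotypes)
  if (is.null(covariate_sets))
    covariate_sets <- list(covariate_set(NULL, n = nrow(genotypes)),
                           pca_covariates(genotypes, 1L),
                           pca_covariates(genotypes, 2L))

  # --- function-prediction curve -----------------------------------------
  rules <- function_call_rules()
  if (is.null(freq_fit)) {
    calls <- call_functional(annotations, rules, "polyphen")
    ix <- match(annotations$snp_id, names(maf))
    poly <- maf[ix] > 0 & annotations$site_class == "nonsynonymous"
    freq_fit <- tryCatch({
      bins <- bin_by_maf(maf[ix][poly], calls[poly])
      fit_frequency_function(bins, "power")
    }, error = function(e) {
      message("falling back to reference power curve: ", conditionMessage(e))
      power_fit()
    })
  }
  s_w <- s_weights_for(annotations)

  # --- per-trait GRAMMAR + batteries -------------------------------------
  traits <- colnames(phenotypes)
  model_fits <- list()
  all_results <- list()
  single_rows <- list()
  lr99_tab <- list()
  methods_all <- c("multivariate", "sum", "weighted_sum",
                   "function_aided_sum", "combined")
  for (ti in seq_along(traits)) {
    tr <- traits[ti]
    y <- unclass(phenotypes)[, tr]
    fit <- select_structure_model(y, covariate_sets, K)
    model_fits[[tr]] <- fit
    y_adj <- grammar_residuals(fit)

    sscan <- single_snp_scan(y_adj, genotypes, maf, trait = tr)
    lam <- inflation_factor(sscan$lr, mode = lambda_mode)
    sscan$lr <- lam$adjusted
    sscan$p_asym <- stats::pchisq(sscan$lr, 1, lower.tail = FALSE)
    sscan$significant <- sscan$p_asym <= attr(sscan, "alpha_per_test")
    attr(sscan, "lambda") <- lam$lambda
    single_rows[[tr]] <- sscan

    for (me in methods_all) {
      pt <- permutation_threshold(
        y_adj, genotypes, maf, fragments, me,
        n_perm = n_perm, quantile = quantile,
        seed = seed + 1000L * ti + match(me, methods_all),
        min_rare = min_rare, maf_threshold = maf_threshold,
        s_weights = s_w, fit = freq_fit, trait = tr)
      if (!nrow(pt$observed)) next
      res <- scale_by_threshold(pt$observed, pt$lr99)
      all_results[[paste(tr, me)]] <- res
      lr99_tab[[paste(tr, me)]] <- data.frame(
        trait = tr, method = me, lr99 = pt$lr99,
        stringsAsFactors = FALSE)
    }
  }
  results <- do.call(rbind, all_results)
  rownames(results) <- NULL
  lr99_tab <- do.call(rbind, lr99_tab)
  rownames(lr99_tab) <- NULL

  # --- decision layer -----------------------------------------------------
  filter_report <- NULL
  if (!is.null(candidates))
    filter_report <- confirm_a_priori(results, gene_of, candidates, alpha)
  top_tests <- top_k(results, top_k_n)
  top_tests$gene <- unname(gene_of[top_tests$unit])
  top_tests$functional_pass <- vapply(top_tests$unit, function(fr)
    as.logical(functional_snp_filter(fragments[[fr]], annotations, rules,
                                     min_count = min_functional)),
    logical(1))
  rare_methods <- c("sum", "weighted_sum", "function_aided_sum")
  cons <- NULL
  rare_res <- results[results$method %in% rare_methods, , drop = FALSE]
  if (nrow(rare_res) &&
      length(unique(rare_res$method)) == length(rare_methods))
    cons <- tryCatch(cross_method_consistency(rare_res),
                     error = function(e) NULL)

  # --- network interrogation ---------------------------------------------
  net_out <- NULL
  if (!is.null(network) && !is.null(candidates)) {
    part <- connected_partition(network, candidates)
    net_out <- list(partition = part)
    if (length(part$connected) >= 3L) {
      pruned <- tryCatch(prune_seeds(network, part$connected,
                                     auc_target = auc_target),
                         error = function(e) NULL)
      if (!is.null(pruned)) {
        retrieved <- retrieve_neighbors(network, pruned$retained, top_n)
        novel <- top_tests[!is.na(top_tests$gene) &
                             !top_tests$gene %in% candidates, , drop = FALSE]
        net_out$pruned <- pruned
        net_out$retrieved <- retrieved
        net_out$posterior <- intersect_candidates(novel, retrieved)
      }
    }
  }

  out <- list(results = results, single_snp = single_rows,
              model_fits = model_fits, lr99 = lr99_tab,
              lambda = vapply(single_rows, attr, numeric(1), "lambda"),
              freq_fit = freq_fit, filter = filter_report,
              top_tests = top_tests, consistency = cons,
              network = net_out,
              config = list(maf_threshold = maf_threshold,
                            min_rare = min_rare, n_perm = n_perm,
                            quantile = quantile, alpha = alpha,
                            top_k = top_k_n,
                            min_functional = min_functional,
                            auc_target = auc_target, top_n = top_n,
                            lambda_mode = lambda_mode, seed = seed))
  class(out) <- "crgwas"
  out
}

#' @export
print.crgwas <- function(x, ...) {
  cat("composite resequencing association scan\n")
  cat(sprintf("  traits: %d, fragment tests: %d, methods: %s\n",
              length(x$model_fits), nrow(x$results),
              paste(unique(x$results$method), collapse = ", ")))
  nsig <- sum(x$results$significant)
  cat(sprintf("  experiment-wise significant (LR/LR99 >= 1): %d\n", nsig))
  if (!is.null(x$filter))
    cat(sprintf("  a priori confirmed: %d\n", sum(x$filter$confirmed)))
  if (!is.null(x$network) && !is.null(x$network$pruned))
    cat(sprintf("  network: %d seeds retained (AUC %.3f), %d retrieved, %d posterior\n",
                length(x$network$pruned$retained), x$network$pruned$auc,
                nrow(x$network$retrieved), nrow(x$network$posterior)))
  invisible(x)
}

#' @export
summary.crgwas <- function(object, ...) {
  by_m <- split(object$results, object$results$method)
  tab <- do.call(rbind, lapply(names(by_m), function(m) {
    r <- by_m[[m]]
    data.frame(method = m, n_tests = nrow(r),
               n_significant = sum(r$significant),
               max_lr_ratio = max(r$lr_ratio),
               stringsAsFactors = FALSE)
  }))
  rownames(tab) <- NULL
  structure(list(methods = tab, lambda = object$lambda,
                 top_tests = utils::head(object$top_tests, 10L),
                 config = object$config),
            class = "summary.crgwas")
}

#' @export
print.summary.crgwas <- function(x, ...) {
  cat("per-method battery:\n")
  print(x$methods, row.names = FALSE)
  cat("\ngenomic-control lambda per trait:\n")
  print(round(x$lambda, 3))
  cat("\ntop tests:\n")
  print(x$top_tests[, c("trait", "unit", "method", "lr", "lr_ratio")],
        row.names = FALSE)
  invisible(x)
}

#' QQ plot of single-SNP statistics against the chi-square null
#'
#' @param x a `crgwas` object.
#' @param trait trait to plot (default: first).
#' @param ... passed to [graphics::plot()].
#' @export
plot.crgwas <- function(x, trait = names(x$single_snp)[1L], ...) {
  lr <- sort(x$single_snp[[trait]]$lr)
  expected <- stats::qchisq(stats::ppoints(length(lr)), df = 1)
  graphics::plot(expected, lr,
                 xlab = "expected chi-square(1) quantile",
                 ylab = "observed LR",
                 main = sprintf("single-SNP QQ, %s (lambda = %.2f)",
                                trait, attr(x$single_snp[[trait]], "lambda")),
                 ...)
  graphics::abline(0, 1, col = "grey50")
  invisible(x)
}
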