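#' Specification for the synthetic study panel
#'
#' Defaults emulate the statistical structure of a resequenced inbred
#' panel: about half the SNPs rare (MAF < 5%), rare MAFs uniform on
#' (1/n, 0.05) and common MAFs uniform on [0.05, 0.5]; the probability
#' that a nonsynonymous SNP is functional decays as the power law
#' a * p^b of its MAF in percent (PolyPhen curve coefficients by
#' default); phenotypes carry subpopulation mean shifts, a polygenic term
#' with covariance 2K sigma_g^2, fragment-level causal effects and i.i.d.
#' noise.
#'
#' @param n_samples panel size (default 96, a resequencing-panel scale).
#' @param n_fragments number of gene fragments.
#' @param snps_per_fragment integer range (min, max) of SNPs per fragment.
#' @param rare_fraction target fraction of rare SNPs (default 0.5).
#' @param maf_threshold rare/common boundary (default 0.05).
#' @param functional_a,functional_b power law for P(functional | MAF),
#'   MAF in percent.
#' @param prob_probably probability a functional nonsynonymous SNP is
#'   probably (vs possibly) damaging.
#' @param nonsyn_fraction fraction of SNPs that are nonsynonymous.
#' @param n_subpops,divergence population structure: number of
#'   subpopulations and the scale of subpopulation allele-frequency
#'   shifts.
#' @param h2_polygenic polygenic heritability of each trait in [0, 1).
#' @param subpop_shift per-subpopulation phenotype mean shift (SD units).
#' @param n_traits number of traits.
#' @param causal_fragments number of fragments given causal rare variants.
#' @param effect_model `"uniform"` or `"s_weighted"` (effects proportional
#'   to S_j * p_j^F).
#' @param effect_size mean causal allele effect in residual-SD units
#'   (default 1.5: rare alleles of large effect, per the common-disease
#'   rare-variant hypothesis the collapsing tests target).
#' @param seed mandatory integer seed.
#' @return list of class `simulation_spec`.
#' @export
simulation_spec <- function(n_samples = 96L, n_fragments = 50L,
                            snps_per_fragment = c(5L, 20L),
                            rare_fraction = 0.5, maf_threshold = 0.05,
                            functional_a = 0.3562, functional_b = -1.4162,
                            prob_probably = 0.5, nonsyn_fraction = 0.45,
                            n_subpops = 2L, divergence = 0.1,
                            h2_polygenic = 0.3, subpop_shift = 0.5,
                            n_traits = 2L, causal_fragments = 0L,
                            effect_model = c("uniform", "s_weighted"),
                            effect_size = 1.5, seed) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(rare_fraction >= 0, rare_fraction <= 1,
            h2_polygenic >= 0, h2_polygenic < 1,
            prob_probably >= 0, prob_probably <= 1)
  structure(list(n_samples = n_samples, n_fragments = n_fragments,
                 snps_per_fragment = snps_per_fragment,
                 rare_fraction = rare_fraction,
                 maf_threshold = maf_threshold,
                 functional_a = functional_a, functional_b = functional_b,
                 prob_probably = prob_probably,
                 nonsyn_fraction = nonsyn_fraction,
                 n_subpops = n_subpops, divergence = divergence,
                 h2_polygenic = h2_polygenic, subpop_shift = subpop_shift,
                 n_traits = n_traits, causal_fragments = causal_fragments,
                 effect_model = match.arg(effect_model),
                 effect_size = effect_size, seed = as.integer(seed)),
            class = "simulation_spec")
}

#' Simulate a genotype panel with population structure
#'
#' SNP target MAFs are drawn from the rare/common mixture; calls are
#' Bernoulli draws per subpopulation, with subpopulation frequencies
#' shifted around the target by the divergence parameter. Realized MAFs
#' come from the sampled calls (monomorphic draws are redrawn a few times,
#' then kept as-is).
#'
#' @param spec a [simulation_spec()].
#' @return list: `genotypes` (a [genotype_matrix()]), `subpop` (integer
#'   labels), `fragments` (named list of SNP ids per fragment),
#'   `target_maf`.
#' @export
simulate_genotypes <- function(spec) {
  if (spec$n_samples < 10L) stop("n_samples must be >= 10")
  set.seed(spec$seed)
  n <- spec$n_samples
  n_snp_frag <- sample(spec$snps_per_fragment[1L]:spec$snps_per_fragment[2L],
                       spec$n_fragments, replace = TRUE)
  M <- sum(n_snp_frag)
  frag_id <- rep(sprintf("frag%03d", seq_len(spec$n_fragments)), n_snp_frag)
  snp_id <- sprintf("snp%05d", seq_len(M))
  subpop <- rep_len(seq_len(spec$n_subpops), n)

  rare <- stats::runif(M) < spec$rare_fraction
  target <- ifelse(rare,
                   stats::runif(M, 1 / n, spec$maf_threshold),
                   stats::runif(M, spec$maf_threshold, 0.5))
  # carrier counts hit the target MAF on the realized spectrum: floor for
  # rare targets and a ceiling-at-threshold for common targets keep each
  # SNP on its intended side of the rare/common boundary
  m_count <- ifelse(rare,
                    pmax(1L, floor(n * target)),
                    pmax(ceiling(n * spec$maf_threshold), round(n * target)))
  m_count <- pmin(m_count, floor(n / 2))
  calls <- matrix(0, n, M)
  for (j in seq_len(M)) {
    # divergence biases which subpopulation the carriers come from
    shift <- stats::rnorm(spec$n_subpops, 0, spec$divergence * target[j])
    pk <- pmax(target[j] + shift, 1e-6)
    carriers <- sample.int(n, m_count[j], prob = pk[subpop])
    calls[carriers, j] <- 1
  }
  g <- genotype_matrix(calls,
                       samples = sprintf("acc%03d", seq_len(n)),
                       snps = snp_id, ploidy = 1L)
  g <- orient_minor(g)
  fragments <- split(snp_id, frag_id)
  list(genotypes = g, subpop = subpop, fragments = fragments,
       target_maf = stats::setNames(target, snp_id))
}

#' Simulate per-SNP functional annotations
#'
#' Nonsynonymous status is assigned at the configured fraction; each
#' nonsynonymous SNP is functional with probability min(1, a * p^b)
#' (p = realized MAF in percent) and then probably or possibly damaging
#' per the configured odds; nonfunctional nonsynonymous SNPs are benign.
#' SIFT calls mirror the functional label with 85% concordance so the two
#' predictors are congruent but not identical. Remaining SNPs are split
#' among synonymous, intronic and intergenic classes.
#'
#' @param sim a [simulate_genotypes()] result.
#' @param spec the same [simulation_spec()].
#' @return list: `annotations` (a [variant_annotation()]), `functional`
#'   (logical truth vector).
#' @export
simulate_annotations <- function(sim, spec) {
  set.seed(spec$seed + 1L)
  g <- sim$genotypes
  maf <- compute_maf(g)
  M <- ncol(g)
  snp_id <- colnames(g)
  frag_of <- rep(names(sim$fragments), lengths(sim$fragments))
  names(frag_of) <- unlist(sim$fragments, use.names = FALSE)

  nonsyn <- stats::runif(M) < spec$nonsyn_fraction
  other_class <- sample(c("synonymous", "intronic", "intergenic"),
                        M, replace = TRUE, prob = c(0.4, 0.35, 0.25))
  site_class <- ifelse(nonsyn, "nonsynonymous", other_class)

  p_pct <- pmax(maf, 1e-6) * 100
  p_fun <- pmin(1, spec$functional_a * p_pct ^ spec$functional_b)
  functional <- nonsyn & stats::runif(M) < p_fun

  polyphen <- rep("none", M)
  polyphen[nonsyn & !functional] <- "benign"
  probably <- functional & stats::runif(M) < spec$prob_probably
  polyphen[functional & probably] <- "probably_damaging"
  polyphen[functional & !probably] <- "possibly_damaging"

  sift <- rep("none", M)
  concord <- stats::runif(M) < 0.85
  sift_fun <- ifelse(concord, functional, !functional)
  sift[nonsyn] <- ifelse(sift_fun[nonsyn], "intolerant", "tolerant")

  smap <- s_weight_map()
  delta <- rep(NA_real_, M)
  delta[polyphen == "benign"] <-
    pmax(0, stats::rnorm(sum(polyphen == "benign"),
                         smap[["benign_or_synonymous"]], 0.2))
  delta[polyphen == "possibly_damaging"] <-
    pmax(0, stats::rnorm(sum(polyphen == "possibly_damaging"),
                         smap[["possibly_damaging"]], 0.3))
  delta[polyphen == "probably_damaging"] <-
    pmax(0, stats::rnorm(sum(polyphen == "probably_damaging"),
                         smap[["probably_damaging"]], 0.4))

  ann <- variant_annotation(
    snp_id = snp_id,
    fragment_id = unname(frag_of[snp_id]),
    gene_id = paste0("gene_", unname(frag_of[snp_id])),
    site_class = site_class,
    nonsense = FALSE,
    polyphen = polyphen, sift = sift, delta_score = delta)
  list(annotations = ann,
       functional = stats::setNames(functional, snp_id))
}

#' Simulate structured phenotypes with planted causal fragments
#'
#' y = subpopulation mean shifts + polygenic term ~ N(0, 2K sigma_g^2) +
#' causal rare-allele effects + N(0, sigma_e^2), with sigma_g^2 set from
#' the polygenic heritability. Under the `s_weighted` effect model each
#' causal rare SNP's effect is proportional to S_j * p_j^F, the same
#' weight the function-aided sum test uses. The truth record lists causal
#' fragments, SNPs and effects per trait.
#'
#' @param sim a [simulate_genotypes()] result.
#' @param spec the [simulation_spec()].
#' @param K kinship matrix (estimated from the genotypes when `NULL`).
#' @param ann optional [simulate_annotations()] result (required for the
#'   `s_weighted` effect model).
#' @return list: `phenotypes` (a [phenotype_table()], state raw, no
#'   missing), `truth` (data.frame of causal SNP effects), `K`.
#' @export
simulate_phenotypes <- function(sim, spec, K = NULL, ann = NULL) {
  set.seed(spec$seed + 2L)
  g <- sim$genotypes
  n <- nrow(g)
  if (is.null(K)) K <- estimate_kinship(g)
  h2 <- spec$h2_polygenic
  sigma_e2 <- 1
  sigma_g2 <- if (h2 > 0) h2 * sigma_e2 / (1 - h2) else 0

  A <- 2 * as.matrix(K)
  eg <- eigen(A, symmetric = TRUE)
  L <- eg$vectors %*% (sqrt(pmax(eg$values, 0)) * t(eg$vectors))

  maf <- compute_maf(g)
  causal <- character(0)
  if (spec$causal_fragments > 0L) {
    # causal fragments need >= 3 rare variants for the collapsing tests
    n_rare <- vapply(sim$fragments, function(s)
      sum(maf[s] > 0 & maf[s] < spec$maf_threshold), numeric(1))
    eligible <- names(sim$fragments)[n_rare >= 3L]
    if (length(eligible) < spec$causal_fragments)
      stop("not enough fragments with >= 3 rare variants")
    causal <- sample(eligible, spec$causal_fragments)
  }

  vals <- matrix(0, n, spec$n_traits,
                 dimnames = list(rownames(g),
                                 sprintf("trait%02d", seq_len(spec$n_traits))))
  truth <- list()
  smap <- s_weight_map()
  pfit <- power_fit(spec$functional_a, spec$functional_b)
  for (t in seq_len(spec$n_traits)) {
    y <- spec$subpop_shift * (sim$subpop - mean(sim$subpop))
    if (sigma_g2 > 0)
      y <- y + sqrt(sigma_g2) * drop(L %*% stats::rnorm(n))
    for (fr in causal) {
      snps <- sim$fragments[[fr]]
      rare <- snps[maf[snps] > 0 & maf[snps] < spec$maf_threshold]
      w <- if (spec$effect_model == "s_weighted" && !is.null(ann)) {
        sw <- s_weights_for(ann$annotations, smap)[rare]
        pf <- as.numeric(predicted_functional_proportion(
          pmax(maf[rare], 1e-6) * 100, pfit))
        sw * pf
      } else rep(1, length(rare))
      eff <- spec$effect_size * w / mean(w)
      x <- unclass(g)[, rare, drop = FALSE]
      x[is.na(x)] <- 0
      y <- y + drop(x %*% eff)
      truth[[length(truth) + 1L]] <- data.frame(
        trait = colnames(vals)[t], fragment = fr, snp = rare,
        effect = eff, stringsAsFactors = FALSE)
    }
    y <- y + stats::rnorm(n, 0, sqrt(sigma_e2))
    vals[, t] <- y
  }
  truth <- if (length(truth)) do.call(rbind, truth)
           else data.frame(trait = character(0), fragment = character(0),
                           snp = character(0), effect = numeric(0))
  list(phenotypes = phenotype_table(vals, state = "raw"),
       truth = truth, K = K)
}

#' Simulate a gene network with a planted seed cluster
#'
#' Planted seeds are densely connected to each other with high LLS
#' (clique with the given within-cluster edge probability); all remaining
#' gene pairs receive sparse Erdos-Renyi noise edges with low LLS,
#' blind to cluster membership.
#'
#' @param n_genes total genes.
#' @param seed_cluster_size number of planted seed genes (>= 3).
#' @param within_lls mean LLS of within-cluster edges.
#' @param within_prob probability of each within-cluster edge (default 1,
#'   a clique).
#' @param noise_lls mean LLS of background edges.
#' @param noise_prob probability of each background edge.
#' @param seed integer seed.
#' @return list: `network` (a [gene_network()]), `seeds` (planted ids).
#' @export
simulate_network <- function(n_genes = 500L, seed_cluster_size = 20L,
                             within_lls = 2, within_prob = 1,
                             noise_lls = 0.5, noise_prob = 0.01,
                             seed = 1L) {
  if (seed_cluster_size < 3L) stop("seed_cluster_size must be >= 3")
  set.seed(seed)
  genes <- sprintf("g%04d", seq_len(n_genes))
  seeds <- genes[seq_len(seed_cluster_size)]
  pairs <- utils::combn(n_genes, 2L)
  a <- pairs[1L, ]; b <- pairs[2L, ]
  in_cluster <- a <= seed_cluster_size & b <= seed_cluster_size
  keep_in <- in_cluster & stats::runif(length(a)) < within_prob
  # background noise is blind to cluster membership
  keep_out <- !keep_in & stats::runif(length(a)) < noise_prob
  lls <- numeric(length(a))
  lls[keep_in] <- pmax(0.1, stats::rnorm(sum(keep_in), within_lls, 0.2))
  lls[keep_out] <- pmax(0.05, stats::rnorm(sum(keep_out), noise_lls, 0.1))
  keep <- keep_in | keep_out
  net <- gene_network(data.frame(gene_a = genes[a[keep]],
                                 gene_b = genes[b[keep]],
                                 lls = lls[keep],
                                 stringsAsFactors = FALSE))
  list(network = net, seeds = seeds)
}

#' Knock missing values into a phenotype table
#'
#' Utility for exercising the imputation path: sets the given fraction of
#' cells missing completely at random (never emptying a full row or
#' column).
#'
#' @param p a [phenotype_table()].
#' @param fraction fraction of cells to blank (default 0.05).
#' @param seed integer seed.
#' @return a [phenotype_table()] in state `"raw"` with missing cells.
#' @export
add_missingness <- function(p, fraction = 0.05, seed = 1L) {
  set.seed(seed)
  vals <- unclass(p)
  attr(vals, "state") <- NULL
  n_cells <- length(vals)
  idx <- sample(n_cells, ceiling(fraction * n_cells))
  vals2 <- vals
  vals2[idx] <- NA
  # keep every trait with >= 2 observations and every sample observed once
  bad_col <- colSums(!is.na(vals2)) < 2L
  bad_row <- rowSums(!is.na(vals2)) == 0L
  if (any(bad_col)) vals2[1:2, bad_col] <- vals[1:2, bad_col]
  if (any(bad_row)) vals2[bad_row, 1L] <- vals[bad_row, 1L]
  phenotype_table(vals2, state = "raw")
}
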