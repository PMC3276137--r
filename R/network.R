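#' Construct a probabilistic gene network
#'
#' Undirected weighted graph whose edge weights are log-likelihood scores
#' (LLS) of a true functional link. Self-edges are dropped, duplicate
#' pairs merged by maximum LLS, and zero/negative scores rejected.
#'
#' @param edges `data.frame` with columns `gene_a`, `gene_b`, `lls`.
#' @return object of class `gene_network`: list with `edges` (canonical
#'   pair order), `nodes`, `adj` (per-node data.frame of neighbor/lls),
#'   and counts `n_rejected`, `n_merged`, `n_self`.
#' @export
gene_network <- function(edges) {
  stopifnot(all(c("gene_a", "gene_b", "lls") %in% names(edges)))
  a <- as.character(edges$gene_a); b <- as.character(edges$gene_b)
  lls <- as.numeric(edges$lls)
  bad <- !is.finite(lls) | lls <= 0
  n_rejected <- sum(bad)
  a <- a[!bad]; b <- b[!bad]; lls <- lls[!bad]
  self <- a == b
  n_self <- sum(self)
  a <- a[!self]; b <- b[!self]; lls <- lls[!self]
  lo <- pmin(a, b); hi <- pmax(a, b)
  key <- paste(lo, hi, sep = "\r")
  n_merged <- sum(duplicated(key))
  if (n_merged) {
    lls <- vapply(split(lls, key), max, numeric(1))
    pairs <- do.call(rbind, strsplit(names(lls), "\r", fixed = TRUE))
    lo <- pairs[, 1L]; hi <- pairs[, 2L]
    lls <- unname(lls)
  }
  nodes <- sort(unique(c(lo, hi)))
  nb <- data.frame(gene = c(lo, hi), neighbor = c(hi, lo),
                   lls = c(lls, lls), stringsAsFactors = FALSE)
  adj <- split(nb[, c("neighbor", "lls")], nb$gene)
  structure(list(edges = data.frame(gene_a = lo, gene_b = hi, lls = lls,
                                    stringsAsFactors = FALSE),
                 nodes = nodes, adj = adj,
                 n_rejected = n_rejected, n_merged = n_merged,
                 n_self = n_self),
            class = "gene_network")
}

#' @export
print.gene_network <- function(x, ...) {
  cat(sprintf("gene_network: %d nodes, %d edges (LLS %.2f-%.2f)\n",
              length(x$nodes), nrow(x$edges),
              min(x$edges$lls), max(x$edges$lls)))
  if (x$n_rejected || x$n_merged || x$n_self)
    cat(sprintf("  dropped: %d nonpositive-LLS, %d self, %d duplicates merged\n",
                x$n_rejected, x$n_self, x$n_merged))
  invisible(x)
}

#' Load a gene network from a 3-column edge list
#'
#' TSV rows `gene_a<TAB>gene_b<TAB>lls`; a header line is detected and
#' skipped when the third field is not numeric.
#'
#' @param path file path.
#' @return a [gene_network()].
#' @export
load_network <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty network file")
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 3L))
    stop("parse error at line ", which(nf != 3L)[1L],
         ": expected 3 tab-separated fields")
  start <- 1L
  if (is.na(suppressWarnings(as.numeric(parts[[1L]][3L])))) start <- 2L
  if (start > length(parts)) stop("network file has no data rows")
  rows <- parts[start:length(parts)]
  lls <- suppressWarnings(as.numeric(vapply(rows, `[`, character(1), 3L)))
  if (anyNA(lls))
    stop("parse error at line ", which(is.na(lls))[1L] + start - 1L,
         ": non-numeric LLS")
  gene_network(data.frame(
    gene_a = vapply(rows, `[`, character(1), 1L),
    gene_b = vapply(rows, `[`, character(1), 2L),
    lls = lls, stringsAsFactors = FALSE))
}

#' Partition query genes by network connectivity
#'
#' @param net a [gene_network()].
#' @param queries character vector of query gene ids.
#' @return list of three disjoint sets covering the queries: `connected`
#'   (>= 1 edge to another query), `disconnected` (in the network but with
#'   no edge to any other query), `absent` (not a network node).
#' @export
connected_partition <- function(net, queries) {
  queries <- unique(as.character(queries))
  if (!length(queries)) stop("query list is empty")
  absent <- queries[!queries %in% net$nodes]
  present <- setdiff(queries, absent)
  qset <- present
  connected <- vapply(present, function(g) {
    nb <- net$adj[[g]]
    !is.null(nb) && any(nb$neighbor %in% setdiff(qset, g))
  }, logical(1))
  list(connected = sort(present[connected]),
       disconnected = sort(present[!connected]),
       absent = sort(absent))
}

#' Guilt-by-association score of a gene against a seed set
#'
#' Sum of edge LLS from `gene` to members of `seeds` (excluding the gene
#' itself); 0 when no seed neighbors exist.
#'
#' @param net a [gene_network()].
#' @param gene a network gene id.
#' @param seeds character vector of seed gene ids.
#' @return nonnegative numeric score.
#' @export
seed_score <- function(net, gene, seeds) {
  if (!gene %in% net$nodes) stop("gene not in network: ", gene)
  nb <- net$adj[[gene]]
  if (is.null(nb)) return(0)
  sum(nb$lls[nb$neighbor %in% setdiff(seeds, gene)])
}

#' Leave-one-out ROC evaluation of a seed set
#'
#' Each seed is scored with itself held out of the seed set; every
#' non-seed network gene is scored against the full seed set. The AUC is
#' the Mann-Whitney statistic (midranks for ties) of seed versus non-seed
#' scores: the probability that a random seed outranks a random non-seed.
#'
#' @param net a [gene_network()].
#' @param seeds seed gene ids (>= 3 must be network nodes).
#' @return list of class `seed_evaluation`: `auc`, `seed_scores`,
#'   `nonseed_scores`, `seeds` (those found in the network).
#' @export
loo_roc_auc <- function(net, seeds) {
  seeds <- unique(as.character(seeds))
  seeds_in <- seeds[seeds %in% net$nodes]
  if (length(seeds_in) < 3L)
    stop("need >= 3 seeds in the network, got ", length(seeds_in))
  seed_scores <- vapply(seeds_in, function(s)
    seed_score(net, s, setdiff(seeds_in, s)), numeric(1))
  nonseeds <- setdiff(net$nodes, seeds_in)
  nonseed_scores <- vapply(nonseeds, function(g)
    seed_score(net, g, seeds_in), numeric(1))
  auc <- .rank_auc(seed_scores, nonseed_scores)
  structure(list(auc = auc,
                 seed_scores = seed_scores,
                 nonseed_scores = nonseed_scores,
                 seeds = seeds_in),
            class = "seed_evaluation")
}

# Mann-Whitney AUC with midranks for ties.
.rank_auc <- function(pos, neg) {
  if (!length(neg)) return(NA_real_)
  r <- rank(c(pos, neg), ties.method = "average")
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

#' Iteratively prune weakly connected seeds to a target AUC
#'
#' Repeats: evaluate the leave-one-out AUC; stop once it meets
#' `auc_target`; otherwise remove the seed with the minimal LOO score
#' (ties broken toward the lexicographically smallest id). Errors if the
#' target is unreachable before `min_seeds` seeds remain.
#'
#' @param net a [gene_network()].
#' @param seeds initial seed gene ids.
#' @param auc_target stop once AUC >= this (default 0.95).
#' @param min_seeds smallest admissible seed set (default 3).
#' @return list: `retained` (final seed set), `auc` (final value),
#'   `trail` (`data.frame` of removed gene and the AUC measured before its
#'   removal, one row per round; empty when no pruning was needed).
#' @export
prune_seeds <- function(net, seeds, auc_target = 0.95, min_seeds = 3L) {
  seeds <- unique(as.character(seeds))
  seeds <- seeds[seeds %in% net$nodes]
  trail <- data.frame(removed = character(0), auc_before = numeric(0),
                      stringsAsFactors = FALSE)
  repeat {
    ev <- loo_roc_auc(net, seeds)
    if (ev$auc >= auc_target)
      return(list(retained = sort(seeds), auc = ev$auc, trail = trail))
    if (length(seeds) <= min_seeds)
      stop("AUC target ", auc_target, " unreachable at min_seeds = ",
           min_seeds, " (reached ", round(ev$auc, 4), "); trail: ",
           paste(trail$removed, collapse = ", "))
    sc <- ev$seed_scores
    victim <- sort(names(sc)[sc == min(sc)])[1L]
    trail <- rbind(trail, data.frame(removed = victim, auc_before = ev$auc,
                                     stringsAsFactors = FALSE))
    seeds <- setdiff(seeds, victim)
  }
}

#' Retrieve top network neighbors of the retained seeds
#'
#' Non-seed network genes ranked by [seed_score()] descending (ties by id
#' ascending); genes with zero score are excluded and at most `top_n`
#' returned.
#'
#' @param net a [gene_network()].
#' @param seeds retained seed gene ids.
#' @param top_n maximum list length (default 200).
#' @return `data.frame` with `gene`, `score`, `rank`.
#' @export
retrieve_neighbors <- function(net, seeds, top_n = 200L) {
  seeds <- unique(as.character(seeds))
  if (!length(seeds)) stop("retained seed set is empty")
  nonseeds <- setdiff(net$nodes, seeds)
  scores <- vapply(nonseeds, function(g) seed_score(net, g, seeds),
                   numeric(1))
  keep <- scores > 0
  genes <- nonseeds[keep]; scores <- scores[keep]
  ord <- order(-scores, genes)
  ord <- ord[seq_len(min(top_n, length(ord)))]
  data.frame(gene = genes[ord], score = unname(scores[ord]),
             rank = seq_along(ord), stringsAsFactors = FALSE)
}

#' Intersect top association hits with network retrieval
#'
#' Posterior candidates: genes among the top association tests (that are
#' not a priori candidates) which the network also retrieves as neighbors
#' of the pruned seed set.
#'
#' @param top_tests `data.frame` with columns `gene` and `rank` (test
#'   rank), e.g. the [top_k()] output joined to its gene ids.
#' @param retrieved [retrieve_neighbors()] output.
#' @return `data.frame` with `gene`, `test_rank`, `network_score`,
#'   `network_rank`, one row per intersecting gene.
#' @export
intersect_candidates <- function(top_tests, retrieved) {
  stopifnot("gene" %in% names(top_tests), "gene" %in% names(retrieved))
  common <- intersect(top_tests$gene, retrieved$gene)
  if (length(top_tests$gene) && length(retrieved$gene) && !length(common)) {
    pre_a <- unique(substr(top_tests$gene, 1L, 2L))
    pre_b <- unique(substr(retrieved$gene, 1L, 2L))
    if (!length(intersect(pre_a, pre_b)))
      warning("no overlap and disjoint id prefixes; check gene id namespaces")
  }
  ix_t <- match(common, top_tests$gene)
  ix_r <- match(common, retrieved$gene)
  out <- data.frame(gene = common,
                    test_rank = if ("rank" %in% names(top_tests))
                      top_tests$rank[ix_t] else NA_integer_,
                    network_score = retrieved$score[ix_r],
                    network_rank = retrieved$rank[ix_r],
                    stringsAsFactors = FALSE)
  out[order(out$test_rank, out$gene), , drop = FALSE]
}
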