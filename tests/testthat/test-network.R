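triangle_net <- function() {
  gene_network(data.frame(gene_a = c("A", "B", "C"),
                          gene_b = c("B", "C", "A"),
                          lls = c(1.5, 2.5, 2.0)))
}

test_that("edge lists load with merging, validation, and line numbers", {
  net <- triangle_net()
  expect_equal(length(net$nodes), 3L)
  expect_equal(nrow(net$edges), 3L)
  # duplicate pair merged by max LLS
  net2 <- gene_network(data.frame(gene_a = c("A", "B"), gene_b = c("B", "A"),
                                  lls = c(1.2, 2.0)))
  expect_equal(nrow(net2$edges), 1L)
  expect_equal(net2$edges$lls, 2.0)
  # nonpositive LLS rejected with a count
  net3 <- gene_network(data.frame(gene_a = c("A", "C"), gene_b = c("B", "D"),
                                  lls = c(-1, 1)))
  expect_equal(net3$n_rejected, 1L)
  expect_equal(nrow(net3$edges), 1L)
  # file round trip and malformed-row diagnostics
  path <- tempfile(fileext = ".tsv")
  writeLines(c("gene_a\tgene_b\tlls", "A\tB\t1.5", "B\tC\t2.5", "C\tA\t2.0"),
             path)
  netf <- load_network(path)
  expect_equal(netf$edges, triangle_net()$edges)
  writeLines(c("A\tB\t1.5", "B\tC"), path)
  expect_error(load_network(path), "line 2")
})

test_that("connectivity partition covers the query list", {
  net <- gene_network(data.frame(gene_a = c("A", "C"), gene_b = c("B", "X"),
                                 lls = c(1, 1)))
  part <- connected_partition(net, c("A", "B", "C", "D"))
  expect_equal(part$connected, c("A", "B"))
  expect_equal(part$disconnected, "C")   # node, but no edge to other queries
  expect_equal(part$absent, "D")
  expect_equal(length(part$connected) + length(part$disconnected) +
                 length(part$absent), 4L)
  # pairwise-unlinked queries: connected set empty
  part2 <- connected_partition(net, c("A", "X"))
  expect_equal(length(part2$connected), 0L)
})

test_that("seed scores sum LLS over seed neighbors", {
  net <- triangle_net()
  expect_equal(seed_score(net, "A", c("B", "C")), 1.5 + 2.0)
  expect_equal(seed_score(net, "A", c("A")), 0)       # self excluded
  lone <- gene_network(data.frame(gene_a = c("A", "Z"), gene_b = c("B", "Y"),
                                  lls = c(1, 1)))
  expect_equal(seed_score(lone, "Z", c("A", "B")), 0)
  expect_error(seed_score(net, "missing", "A"), "not in network")
  # monotone: adding a seed never decreases a score
  expect_gte(seed_score(net, "A", c("B", "C")), seed_score(net, "A", "B"))
})

test_that("leave-one-out ROC AUC matches rank computations", {
  # perfect separation
  nodes <- c(sprintf("s%d", 1:4), sprintf("n%d", 1:6))
  edges <- expand.grid(gene_a = sprintf("s%d", 1:4),
                       gene_b = sprintf("s%d", 1:4),
                       stringsAsFactors = FALSE)
  edges <- edges[edges$gene_a < edges$gene_b, ]
  edges$lls <- 10
  # attach the non-seeds weakly to one another so they are nodes
  noise <- data.frame(gene_a = sprintf("n%d", 1:5),
                      gene_b = sprintf("n%d", 2:6), lls = 0.1)
  net <- gene_network(rbind(edges, noise))
  ev <- loo_roc_auc(net, sprintf("s%d", 1:4))
  expect_equal(ev$auc, 1.0)
  # hand computation: path S1-S2 (1), S2-S3 (2); N1-S1 (1.5); N1-N2 (0.2)
  # LOO seed scores {1, 3, 2}; non-seed scores {1.5, 0};
  # ranks of (1,3,2 | 1.5,0) are (2,5,4 | 3,1) -> AUC = (11 - 6) / 6
  h <- gene_network(data.frame(
    gene_a = c("S1", "S2", "N1", "N1"),
    gene_b = c("S2", "S3", "S1", "N2"),
    lls = c(1, 2, 1.5, 0.2)))
  evh <- loo_roc_auc(h, c("S1", "S2", "S3"))
  expect_equal(evh$auc, 5 / 6, tolerance = 1e-12)
  expect_equal(unname(evh$seed_scores[c("S1", "S2", "S3")]), c(1, 3, 2))
  expect_error(loo_roc_auc(h, c("S1", "S2")), ">= 3 seeds")
})

test_that("null networks give AUC near 0.5 and clustered seeds near 1", {
  set.seed(70)
  # seed set large enough that the leave-one-out asymmetry (a seed has one
  # fewer potential partner than a non-seed) is negligible
  aucs <- replicate(60, {
    sim <- simulate_network(n_genes = 150, seed_cluster_size = 20,
                            within_prob = 0, noise_prob = 0.06,
                            seed = sample.int(1e6, 1))
    tryCatch(loo_roc_auc(sim$network, sim$seeds)$auc,
             error = function(e) NA_real_)
  })
  expect_lt(abs(mean(aucs, na.rm = TRUE) - 0.5), 0.02)
  clustered <- simulate_network(n_genes = 200, seed_cluster_size = 12,
                                within_prob = 1, noise_prob = 0.01,
                                seed = 71)
  expect_gte(loo_roc_auc(clustered$network, clustered$seeds)$auc, 0.95)
})

test_that("seed pruning removes isolated seeds first and reaches the target", {
  # dense background noise: nearly every non-seed has some seed edge, so
  # a zero-score seed genuinely depresses the AUC until it is pruned
  sim <- simulate_network(n_genes = 300, seed_cluster_size = 15,
                          within_lls = 2, within_prob = 1,
                          noise_lls = 0.3, noise_prob = 0.15, seed = 72)
  # five extra seeds isolated from the cluster: each touches one
  # background node only
  bg <- setdiff(sim$network$nodes, sim$seeds)
  extras <- sprintf("iso%d", 1:5)
  net <- gene_network(rbind(sim$network$edges,
                            data.frame(gene_a = extras, gene_b = bg[1:5],
                                       lls = 0.05)))
  pruned <- prune_seeds(net, c(sim$seeds, extras), auc_target = 0.95)
  expect_true(all(sim$seeds %in% pruned$retained))
  expect_false(any(extras %in% pruned$retained))
  expect_gte(pruned$auc, 0.95)
  expect_true(all(pruned$trail$removed %in% extras))
  # audit trail AUCs are reproducible
  expect_equal(pruned$trail$auc_before[1],
               loo_roc_auc(net, c(sim$seeds, extras))$auc)
  # already-passing set returned unchanged with an empty trail
  again <- prune_seeds(net, pruned$retained, auc_target = 0.95)
  expect_equal(again$retained, pruned$retained)
  expect_equal(nrow(again$trail), 0L)
  # a seed with no edges at all is removed first
  lonely <- gene_network(rbind(net$edges,
                               data.frame(gene_a = "zzz_lone",
                                          gene_b = net$nodes[100],
                                          lls = 0.01)))
  # zzz_lone only touches a background node, never another seed
  pr2 <- prune_seeds(lonely, c(sim$seeds[1:4], "zzz_lone"),
                     auc_target = 0.9)
  if (nrow(pr2$trail) > 0) expect_equal(pr2$trail$removed[1], "zzz_lone")
  # unreachable target errors with the trail in the message
  iso <- gene_network(data.frame(gene_a = c("a", "c", "e"),
                                 gene_b = c("b", "d", "f"),
                                 lls = c(1, 1, 1)))
  expect_error(prune_seeds(iso, c("a", "c", "e"), auc_target = 0.99),
               "unreachable")
})

test_that("neighbor retrieval ranks by additive score with deterministic ties", {
  net <- gene_network(data.frame(
    gene_a = c("s1", "s2", "s3", "s1", "s1", "s2", "s3"),
    gene_b = c("s2", "s3", "s1", "hub", "one", "hub", "hub"),
    lls = c(1, 1, 1, 1, 1, 1, 1)))
  got <- retrieve_neighbors(net, c("s1", "s2", "s3"), top_n = 200)
  expect_equal(got$gene, c("hub", "one"))   # 3 seed edges beat 1
  expect_equal(got$score, c(3, 1))
  # zero-score genes excluded; short lists returned as-is
  expect_equal(nrow(got), 2L)
  expect_identical(retrieve_neighbors(net, c("s1", "s2", "s3")), got)
  expect_equal(nrow(retrieve_neighbors(net, c("s1", "s2", "s3"),
                                       top_n = 1)), 1L)
})

test_that("posterior candidates are the test-network intersection", {
  top <- data.frame(gene = c("g1", "g2", "g3"), rank = 1:3)
  ret <- data.frame(gene = c("g2", "g4"), score = c(5, 1), rank = 1:2)
  inter <- intersect_candidates(top, ret)
  expect_equal(inter$gene, "g2")
  expect_equal(inter$test_rank, 2L)
  expect_equal(inter$network_score, 5)
  expect_true(all(inter$gene %in% top$gene) &&
                all(inter$gene %in% ret$gene))
  empty <- intersect_candidates(top, ret[0, ])
  expect_equal(nrow(empty), 0L)
  expect_warning(intersect_candidates(
    data.frame(gene = "AT1G01010", rank = 1),
    data.frame(gene = c("zz123", "zz124"), score = 1:2, rank = 1:2)),
    "namespace")
})
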