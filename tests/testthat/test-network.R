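# Graph data model: loaders, construction, splits, negatives, k-hop.

write_tsv <- function(df, path = tempfile(fileext = ".tsv")) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

test_that("edge lists load with undirected dedup and name normalization", {
  p <- write_tsv(data.frame(
    source_name = c("m1", "d1", " M1 "), source_kind = c("miRNA", "disease", "mirna"),
    target_name = c("d1", "m1", "d2"), target_kind = c("disease", "miRNA", "Disease")))
  edges <- load_edge_list(p, "miRNA-disease")
  expect_equal(nrow(edges), 2) # reversed duplicate collapsed, m1-d2 kept
  expect_setequal(edges$name_a, c("d1", "d2")) # canonical: disease key first
  expect_true(all(edges$weight == 1))

  many <- data.frame(source_name = paste0("m", 1:10), source_kind = "miRNA",
                     target_name = paste0("d", 1:10), target_kind = "disease")
  expect_equal(nrow(load_edge_list(write_tsv(many), "miRNA-disease")), 10)
})

test_that("loader rejects malformed input with informative errors", {
  bad_kind <- write_tsv(data.frame(source_name = "m1", source_kind = "miRNA",
                                   target_name = "m2", target_kind = "miRNA"))
  expect_error(load_edge_list(bad_kind, "miRNA-disease"), "does not match")
  missing_col <- write_tsv(data.frame(source_name = "m1", target_name = "d1"))
  expect_error(load_edge_list(missing_col, "miRNA-disease"), "missing column")
  blank <- write_tsv(data.frame(source_name = c("m1", ""), source_kind = "miRNA",
                                target_name = c("d1", "d2"),
                                target_kind = "disease"))
  expect_error(load_edge_list(blank, "miRNA-disease"), "malformed row")
  expect_error(load_edge_list(tempfile(), "miRNA-disease"), "no such file")
})

test_that("build_network dedups globally and counts kinds", {
  e1 <- edge_df(c("m1", "m2"), "miRNA", c("d1", "d1"), "disease")
  e2 <- edge_df(c("d1", "p1"), c("disease", "protein"),
                c("m1", "d1"), c("miRNA", "disease")) # first row repeats e1 edge
  net <- build_network(list(e1, e2))
  expect_equal(nrow(net$edges), 3)
  expect_equal(sum(net$kind_counts), 4)
  expect_equal(unname(net$kind_counts[c("miRNA", "disease", "protein")]),
               c(2L, 1L, 1L))
  expect_error(build_network(list()), "at least one edge")
})

test_that("per-kind totals at a reduced version of the published network shape", {
  # same five-kind shape as the reference statistics, at 1% scale
  counts <- c(miRNA = 10, lncRNA = 8, protein = 16, drug = 10, disease = 21)
  b <- gen_man_data(synth_config(
    n_nodes = counts, n_edges = setNames(rep(40L, 9), edge_kinds()),
    signal = 0, seed = 7))
  expect_equal(sum(b$network$kind_counts), nrow(b$network$nodes))
  expect_true(all(b$network$kind_counts <= counts))
})

test_that("network construction is idempotent and round-trips through TSV", {
  net <- random_net(seed = 4)
  again <- build_network(net$edges)
  expect_equal(sort(manlink:::edge_key(again$edges)),
               sort(manlink:::edge_key(net$edges)))
  p <- tempfile(fileext = ".tsv")
  write_network(net, p)
  back <- read_network(p)
  expect_equal(back$edges, net$edges)
  expect_equal(back$kind_counts, net$kind_counts)
})

test_that("k-fold splits partition edges exactly and are seed-reproducible", {
  g <- expand.grid(m = paste0("m", 1:5), d = paste0("d", 1:4),
                   stringsAsFactors = FALSE)[seq(1, 20, 2), ] # 10 edges
  net <- build_network(edge_df(g$m, "miRNA", g$d, "disease", "miRNA-disease"))
  folds <- kfold_split(net, k = 5, seed = 11)
  expect_length(folds, 5)
  test_keys <- lapply(folds, function(f) manlink:::edge_key(f$test_positives))
  expect_true(all(lengths(test_keys) == 2))
  expect_equal(sort(unlist(test_keys)), sort(manlink:::edge_key(net$edges)))
  expect_equal(sum(duplicated(unlist(test_keys))), 0)
  for (f in folds) {
    expect_equal(nrow(f$train_edges), 8)
    expect_length(intersect(manlink:::edge_key(f$train_edges),
                            manlink:::edge_key(f$test_positives)), 0)
    expect_setequal(c(manlink:::edge_key(f$train_edges),
                      manlink:::edge_key(f$test_positives)),
                    manlink:::edge_key(net$edges))
    expect_equal(nrow(f$test_negatives), nrow(f$test_positives))
  }
  again <- kfold_split(net, k = 5, seed = 11)
  expect_identical(lapply(again, `[[`, "test_positives"),
                   lapply(folds, `[[`, "test_positives"))
  other <- kfold_split(net, k = 5, seed = 12)
  expect_false(identical(lapply(other, `[[`, "test_positives"),
                         lapply(folds, `[[`, "test_positives")))
  expect_error(kfold_split(net, k = 11, seed = 1), "cannot make")
})

test_that("negative sampling returns admissible non-edges only", {
  # complete bipartite graph missing exactly one pair: the draw is forced
  full <- bipartite_net(3, 3, drop = 1)
  neg <- sample_negatives(full, 1, seed = 5)
  expect_equal(nrow(neg), 1)
  expect_setequal(c(neg$name_a, neg$name_b), c("m1", "d1"))
  expect_error(sample_negatives(full, 2, seed = 5), "only 1 admissible")

  # sparse network: all sampled pairs verified against the brute-force
  # enumeration of the admissible non-edge universe
  net <- small_bundle(seed = 2, n = 15, m = 12)$network
  neg <- sample_negatives(net, 100, seed = 9)
  expect_equal(nrow(neg), 100)
  expect_equal(anyDuplicated(manlink:::edge_key(neg)), 0)
  universe <- character()
  for (ek in edge_kinds()) {
    kp <- manlink:::EDGE_KIND_PAIRS[[ek]]
    a <- net$nodes$name[net$nodes$kind == kp[1]]
    b <- net$nodes$name[net$nodes$kind == kp[2]]
    if (!length(a) || !length(b)) next
    g <- expand.grid(a = a, b = b, stringsAsFactors = FALSE)
    g <- g[g$a != g$b | kp[1] != kp[2], ]
    cand <- manlink:::canonicalize_edges(
      edge_df(g$a, kp[1], g$b, kp[2], ek))
    universe <- c(universe, manlink:::edge_key(cand))
  }
  universe <- setdiff(unique(universe), manlink:::edge_key(net$edges))
  expect_true(all(manlink:::edge_key(neg) %in% universe))
  expect_identical(sample_negatives(net, 100, seed = 9), neg)

  strat <- sample_negatives(net, 36, seed = 9, stratified = TRUE)
  pos_tab <- table(factor(net$edges$edge_kind, edge_kinds()))
  neg_tab <- table(factor(strat$edge_kind, edge_kinds()))
  expect_true(all(abs(neg_tab - 36 * pos_tab / sum(pos_tab)) <= 1))
})

test_that("k-hop neighborhoods match an independent BFS oracle", {
  # path a - b - c
  path <- build_network(edge_df(c("a", "b"), "protein", c("b", "c"),
                                "protein", "protein-protein"))
  expect_equal(khop_neighbors(path, list(kind = "protein", name = "a"), 2)$name,
               "c")
  star <- build_network(edge_df(rep("hub", 5), "protein", paste0("l", 1:5),
                                "protein", "protein-protein"))
  expect_setequal(
    khop_neighbors(star, list(kind = "protein", name = "hub"), 1)$name,
    paste0("l", 1:5))
  expect_error(khop_neighbors(star, list(kind = "drug", name = "zz"), 1),
               "not in network")

  skip_if_not_installed("igraph")
  net <- random_net(n_nodes = 60, n_edges = 120, seed = 8)
  keys <- manlink:::node_key(net$nodes$kind, net$nodes$name)
  g <- igraph::graph_from_data_frame(
    data.frame(from = manlink:::node_key(net$edges$kind_a, net$edges$name_a),
               to = manlink:::node_key(net$edges$kind_b, net$edges$name_b)),
    directed = FALSE, vertices = keys)
  dist <- igraph::distances(g)
  for (start in sample(keys, 5)) {
    for (k in 1:3) {
      ours <- khop_neighbors(net, manlink:::split_node_key(start), k)
      oracle <- keys[is.finite(dist[start, ]) & dist[start, ] == k]
      expect_setequal(manlink:::node_key(ours$kind, ours$name), oracle)
    }
  }
})
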