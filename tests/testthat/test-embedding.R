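# Second-order LINE embedding: expansion, softmax, gradients, training
# properties, behavior vectors.

test_that("undirected edges expand to directed pairs with equal weight", {
  e <- edge_df("a", "miRNA", "b", "disease", "miRNA-disease", weight = 2.5)
  d <- directed_expand(e)
  expect_equal(nrow(d), 2)
  expect_setequal(d$src, c("miRNA:a", "disease:b"))
  expect_equal(d$weight, c(2.5, 2.5))
  expect_equal(d$src, rev(d$dst))
  e3 <- two_cliques(3) # 6 undirected edges
  expect_equal(nrow(directed_expand(e3)), 12)
})

test_that("context probabilities are a softmax over context vectors", {
  # all-zero vectors: uniform distribution
  nodes <- paste0("protein:n", 1:4)
  U <- matrix(0, 4, 2, dimnames = list(nodes, NULL))
  state <- list(vertex = U, context = U)
  p <- context_probability(state, nodes[1])
  expect_equal(unname(p), rep(0.25, 4))

  # hand-evaluated 3-node softmax
  U <- matrix(c(1, 0, 0, 1, 0.5, 0.5), 3, 2, byrow = TRUE,
              dimnames = list(paste0("protein:x", 1:3), NULL))
  C <- matrix(c(0.2, -0.1, 0.3, 0.4, 0, 0), 3, 2, byrow = TRUE,
              dimnames = list(rownames(U), NULL))
  st <- list(vertex = U, context = C)
  logits <- c(0.2, 0.3, 0) # u_1 . c_j for j = 1..3
  expect_equal(unname(context_probability(st, "protein:x1")),
               exp(logits) / sum(exp(logits)), tolerance = 1e-12)
  expect_equal(sum(context_probability(st, "protein:x3")), 1,
               tolerance = 1e-9)
  expect_error(context_probability(st, "protein:nope"), "not embedded")
})

test_that("softmax normalization holds for random states", {
  set.seed(13)
  for (i in 1:10) {
    n <- sample(3:20, 1)
    st <- list(vertex = matrix(rnorm(n * 8), n, 8,
                               dimnames = list(paste0("drug:d", 1:n), NULL)),
               context = matrix(rnorm(n * 8), n, 8,
                                dimnames = list(paste0("drug:d", 1:n), NULL)))
    p <- context_probability(st, paste0("drug:d", sample(n, 1)))
    expect_true(all(p >= 0))
    expect_equal(sum(p), 1, tolerance = 1e-9)
  }
})

test_that("analytic gradients of the exact objective match finite differences", {
  set.seed(14)
  e <- edge_df(c("a", "b", "c", "d", "a", "b", "c", "e"), "protein",
               c("b", "c", "d", "e", "c", "d", "e", "f"), "protein",
               "protein-protein", weight = runif(8, 0.5, 2))
  de <- directed_expand(e)
  nodes <- sort(unique(de$src))
  n <- length(nodes); dm <- 5
  W <- matrix(0, n, n)
  W[cbind(match(de$src, nodes), match(de$dst, nodes))] <- de$weight
  U <- matrix(rnorm(n * dm, sd = 0.4), n, dm)
  C <- matrix(rnorm(n * dm, sd = 0.4), n, dm)
  g <- line_o2_grad(U, C, W)
  h <- 1e-5
  for (trial in 1:40) {
    mat <- sample(c("U", "C"), 1)
    i <- sample(n, 1); d <- sample(dm, 1)
    bump <- function(M, delta) { M[i, d] <- M[i, d] + delta; M }
    fd <- if (mat == "U")
      (line_o2(bump(U, h), C, W) - line_o2(bump(U, -h), C, W)) / (2 * h)
    else
      (line_o2(U, bump(C, h), W) - line_o2(U, bump(C, -h), W)) / (2 * h)
    an <- if (mat == "U") g$U[i, d] else g$C[i, d]
    expect_lt(abs(fd - an) / max(abs(fd), 1e-8), 1e-4)
  }
})

test_that("exact-mode training decreases the objective", {
  st <- train_line(two_cliques(4), dim = 8, method = "exact",
                   exact_iters = 80, seed = 2)
  obj <- st$config$objective
  expect_lt(obj[length(obj)], obj[1])
  expect_true(all(is.finite(st$vertex)))
})

test_that("SGD training is bitwise deterministic under a fixed seed", {
  e <- two_cliques(5)
  a <- train_line(e, dim = 16, samples_per_edge = 200, seed = 7)
  b <- train_line(e, dim = 16, samples_per_edge = 200, seed = 7)
  expect_identical(a$vertex, b$vertex)
  expect_identical(a$context, b$context)
  c_ <- train_line(e, dim = 16, samples_per_edge = 200, seed = 8)
  expect_false(identical(a$vertex, c_$vertex))
  expect_error(train_line(e[0, ]), "empty edge set")
})

test_that("disjoint cliques separate in embedding space", {
  st <- train_line(two_cliques(5), dim = 16, total_samples = 1e5, seed = 1)
  V <- st$vertex
  in_a <- grepl(":a", rownames(V), fixed = TRUE)
  gram <- tcrossprod(V)
  diag(gram) <- NA
  within <- mean(c(gram[in_a, in_a], gram[!in_a, !in_a]), na.rm = TRUE)
  between <- mean(gram[in_a, !in_a], na.rm = TRUE)
  expect_gt(within, between)
})

test_that("nodes with identical neighborhoods embed similarly", {
  # x and y both connect to h1..h4 and never to each other
  e <- rbind(edge_df(rep("x", 4), "protein", paste0("h", 1:4), "protein",
                     "protein-protein"),
             edge_df(rep("y", 4), "protein", paste0("h", 1:4), "protein",
                     "protein-protein"),
             edge_df(paste0("h", 1:3), "protein", paste0("h", 2:4), "protein",
                     "protein-protein"))
  st <- train_line(e, dim = 8, total_samples = 5e4, seed = 3)
  V <- st$vertex / sqrt(rowSums(st$vertex^2))
  cosine <- tcrossprod(V)
  xy <- cosine["protein:x", "protein:y"]
  diag(cosine) <- NA
  expect_gt(xy, mean(cosine, na.rm = TRUE))
})

test_that("behavior vectors cover all nodes, zeroing the isolated ones", {
  b <- small_bundle(seed = 6, n = 10, m = 12)
  net <- b$network
  folds <- kfold_split(net, k = 3, seed = 2)
  f <- folds[[1]]
  st <- train_line(f$train_edges, dim = 16, samples_per_edge = 20, seed = 1)
  bv <- suppressMessages(behavior_vectors(st, net))
  expect_equal(nrow(bv$values),  nrow(net$nodes))
  train_keys <- unique(unlist(manlink:::directed_expand(f$train_edges)[1:2]))
  isolated <- setdiff(manlink:::node_key(net$nodes$kind, net$nodes$name),
                      train_keys)
  expect_equal(bv$n_isolated, length(isolated))
  if (length(isolated) > 0)
    expect_true(all(bv$values[isolated, ] == 0))
  # normalized rows have unit length (or zero)
  nrm <- sqrt(rowSums(bv$values^2))
  expect_true(all(abs(nrm[nrm > 0] - 1) < 1e-9))
  raw <- suppressMessages(behavior_vectors(st, net, normalize = FALSE))
  expect_false(all(abs(sqrt(rowSums(raw$values^2)) - 1) < 1e-9))
})

test_that("embeddings depend only on the edges passed in", {
  b <- small_bundle(seed = 8, n = 10, m = 12)
  folds <- kfold_split(b$network, k = 3, seed = 5)
  f <- folds[[1]]
  before <- train_line(f$train_edges, dim = 16, samples_per_edge = 30,
                       seed = 9)
  # mutate the held-out fold after splitting: a sentinel change that must
  # not reach the embedding
  f$test_positives$weight <- 999
  f$test_positives$name_a <- paste0(f$test_positives$name_a, "_mut")
  after <- train_line(f$train_edges, dim = 16, samples_per_edge = 30,
                      seed = 9)
  expect_identical(before$vertex, after$vertex)
  expect_identical(before$context, after$context)
})

test_that("embeddings export with a config header and full coverage", {
  st <- train_line(two_cliques(3), dim = 4, samples_per_edge = 10, seed = 1)
  p <- tempfile(fileext = ".tsv")
  write_embedding(st, p)
  first <- readLines(p, n = 1)
  expect_match(first, "^# .*seed=1")
  tab <- read.delim(p, comment.char = "#")
  expect_equal(nrow(tab), length(st$nodes))
  expect_equal(ncol(tab), 2 + 4)
})
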