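# Behavior features: second-order LINE embedding of the association graph.
# Each node i carries a vertex vector u_i and a context vector c_j; the
# model probability of context j given vertex i is the softmax of u_i . c_j
# over all nodes, and training minimizes
#   O2 = - sum over directed edges (i, j) of w_ij * log p2(j | i),
# the degree-weighted KL fit to the empirical neighbor distribution
# w_ij / d_i.  The SGD path approximates the softmax by negative sampling;
# an exact-softmax path supports small graphs and gradient verification.

#' Expand undirected edges to directed weighted edges
#'
#' Every undirected association yields two directed edges with opposite
#' directions and equal weight, the form consumed by the embedding.
#'
#' @param edges An edge data frame (see [build_network()]).
#' @return A data frame with columns `src`, `dst` (node keys `kind:name`)
#'   and `weight`, with `2 * nrow(edges)` rows.
#' @export
directed_expand <- function(edges) {
  ka <- node_key(edges$kind_a, edges$name_a)
  kb <- node_key(edges$kind_b, edges$name_b)
  data.frame(src = c(ka, kb), dst = c(kb, ka),
             weight = rep(edges$weight, 2), stringsAsFactors = FALSE)
}

line_state <- function(U, C, nodes, config) {
  rownames(U) <- rownames(C) <- nodes
  structure(list(vertex = U, context = C, nodes = nodes, config = config),
            class = "man_line")
}

#' Train a second-order LINE embedding on an edge set
#'
#' The default `method = "sgd"` draws `total_samples` directed edges with
#' probability proportional to weight (alias method) and performs one
#' negative-sampling update per draw (`negatives` noise nodes per positive,
#' noise distribution proportional to weighted out-degree^0.75, learning
#' rate decaying linearly from `rho0`).  `method = "exact"` performs
#' full-batch gradient descent on the exact-softmax objective and is
#' intended for graphs of at most a few hundred nodes.
#'
#' Only the edges passed in are ever touched: embedding a training fold
#' cannot see held-out associations.
#'
#' @param edges Undirected edge data frame (non-empty).
#' @param dim Embedding dimension (default 64).
#' @param negatives Negative samples per positive (default 5).
#' @param samples_per_edge SGD samples per directed edge (default 100);
#'   `total_samples`, if given, overrides.
#' @param total_samples Total SGD samples.
#' @param rho0 Initial learning rate (default 0.025).
#' @param seed Integer seed; training is bitwise reproducible.
#' @param method `"sgd"` (default) or `"exact"`.
#' @param exact_iters,exact_lr Iterations and step size for the exact path.
#' @return An object of class `man_line`: vertex and context matrices
#'   (rows named by node key), the node list and the configuration; the
#'   exact path also records the objective trajectory in
#'   `config$objective`.
#' @export
train_line <- function(edges, dim = 64, negatives = 5,
                       samples_per_edge = 100, total_samples = NULL,
                       rho0 = 0.025, seed = 1,
                       method = c("sgd", "exact"),
                       exact_iters = 200, exact_lr = 0.5) {
  method <- match.arg(method)
  if (is.null(edges) || nrow(edges) == 0)
    stop("cannot embed an empty edge set", call. = FALSE)
  dedges <- directed_expand(edges)
  nodes <- sort(unique(c(dedges$src, dedges$dst)))
  src <- match(dedges$src, nodes) - 1L
  dst <- match(dedges$dst, nodes) - 1L

  if (method == "sgd") {
    total <- total_samples %||% (samples_per_edge * nrow(dedges))
    fit <- line_sgd_cpp(src, dst, dedges$weight, length(nodes), dim,
                        negatives, total, rho0, as.integer(seed))
    return(line_state(fit$vertex, fit$context, nodes,
                      list(method = "sgd", dim = dim, negatives = negatives,
                           total_samples = total, rho0 = rho0, seed = seed)))
  }

  if (length(nodes) > 500)
    stop("exact-softmax training is limited to 500 nodes", call. = FALSE)
  n <- length(nodes)
  U <- with_seed(seed, matrix(runif(n * dim, -0.5 / dim, 0.5 / dim), n, dim))
  C <- matrix(0, n, dim)
  W <- matrix(0, n, n)
  W[cbind(src + 1L, dst + 1L)] <- W[cbind(src + 1L, dst + 1L)] + dedges$weight
  objective <- numeric(exact_iters + 1)
  objective[1] <- line_o2(U, C, W)
  for (it in seq_len(exact_iters)) {
    g <- line_o2_grad(U, C, W)
    step <- exact_lr / sum(W)
    U <- U - step * g$U
    C <- C - step * g$C
    objective[it + 1] <- line_o2(U, C, W)
  }
  line_state(U, C, nodes,
             list(method = "exact", dim = dim, iters = exact_iters,
                  lr = exact_lr, seed = seed, objective = objective))
}

# Row-wise log-softmax, numerically stable.
log_softmax_rows <- function(logits) {
  mx <- apply(logits, 1, max)
  sh <- logits - mx
  sh - log(rowSums(exp(sh)))
}

#' Exact second-order objective and its analytic gradient
#'
#' `line_o2` evaluates `O2 = -sum_ij W[i, j] * log softmax(U C^T)[i, j]`;
#' `line_o2_grad` returns its exact gradient with respect to the vertex and
#' context matrices.  `W` is the directed weight matrix (`W[i, j]` the
#' weight of edge i -> j).
#'
#' @param U,C Vertex and context matrices (nodes by dim).
#' @param W Square directed weight matrix.
#' @return `line_o2`: a scalar.  `line_o2_grad`: list with matrices `U`
#'   and `C`.
#' @export
line_o2 <- function(U, C, W) {
  lp <- log_softmax_rows(U %*% t(C))
  -sum(W * lp)
}

#' @rdname line_o2
#' @export
line_o2_grad <- function(U, C, W) {
  logits <- U %*% t(C)
  mx <- apply(logits, 1, max)
  ex <- exp(logits - mx)
  S <- ex / rowSums(ex)
  glogits <- S * rowSums(W) - W
  list(U = glogits %*% C, C = t(glogits) %*% U)
}

#' Model context distribution of a node
#'
#' The softmax, over all embedded nodes, of the inner products between the
#' node's vertex vector and every context vector.
#'
#' @param state A `man_line` (or any list with `vertex` and `context`
#'   matrices sharing rownames).
#' @param node Node key `"kind:name"`, or a list with `kind` and `name`.
#' @return Named probability vector over all embedded nodes, summing to 1.
#' @export
context_probability <- function(state, node) {
  key <- if (is.character(node)) node
         else node_key(normalize_kind(node$kind), normalize_name(node$name))
  i <- match(key, rownames(state$vertex))
  if (is.na(i)) stop("node not embedded: ", key, call. = FALSE)
  logits <- drop(state$context %*% state$vertex[i, ])
  p <- exp(logits - max(logits))
  setNames(p / sum(p), rownames(state$context))
}

#' Behavior vectors for a node set
#'
#' Looks up the trained vertex vector for every requested node; nodes that
#' were isolated (absent from the embedded edge set) get the all-zero
#' vector and are counted.  By default the vectors are scaled to unit
#' Euclidean norm, so pair features reflect the *direction* of a node's
#' neighborhood embedding rather than its magnitude (which mostly tracks
#' node degree); zero vectors stay zero.
#'
#' @param state A trained `man_line`.
#' @param nodes A `man_network`, a nodes data frame (`kind`, `name`), or a
#'   character vector of node keys.
#' @param normalize Scale each vector to unit norm (default TRUE).
#' @return An object of class `man_behavior`: list with `values`
#'   (nodes-by-dim matrix, rownames node keys) and `n_isolated`.
#' @export
behavior_vectors <- function(state, nodes, normalize = TRUE) {
  keys <- if (inherits(nodes, "man_network"))
    node_key(nodes$nodes$kind, nodes$nodes$name)
  else if (is.data.frame(nodes)) node_key(nodes$kind, nodes$name)
  else nodes
  dim_ <- ncol(state$vertex)
  values <- matrix(0, length(keys), dim_, dimnames = list(keys, NULL))
  hit <- match(keys, rownames(state$vertex))
  ok <- !is.na(hit)
  values[ok, ] <- state$vertex[hit[ok], , drop = FALSE]
  if (normalize) {
    nrm <- sqrt(rowSums(values^2))
    nz <- nrm > 0
    values[nz, ] <- values[nz, , drop = FALSE] / nrm[nz]
  }
  n_isolated <- sum(!ok)
  if (n_isolated > 0)
    message(n_isolated, " node(s) isolated in the embedded graph; ",
            "zero behavior vectors used")
  structure(list(values = values, n_isolated = n_isolated),
            class = "man_behavior")
}

#' @export
print.man_line <- function(x, ...) {
  cat("LINE second-order embedding:", length(x$nodes), "nodes x",
      ncol(x$vertex), "dims (", x$config$method, ")\n")
  invisible(x)
}

#' Export an embedding as TSV
#'
#' Columns `node_kind`, `node_name`, then one column per dimension; a
#' leading `#` comment line records the configuration and seed.
#'
#' @param state A `man_line`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_embedding <- function(state, path) {
  cfg <- state$config
  cfg <- cfg[setdiff(names(cfg), "objective")]
  header <- paste0("# ", paste(names(cfg), unlist(cfg), sep = "=",
                               collapse = " "))
  ref <- split_node_key(rownames(state$vertex))
  out <- cbind(data.frame(node_kind = ref$kind, node_name = ref$name,
                          stringsAsFactors = FALSE),
               as.data.frame(state$vertex))
  names(out)[-(1:2)] <- paste0("v", seq_len(ncol(state$vertex)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
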