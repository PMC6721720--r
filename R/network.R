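# Molecular association network: edge-list I/O, construction, CV splits,
# negative sampling, k-hop queries.

# Orient every undirected edge so the endpoint with the lexicographically
# smaller (kind, name) string key comes first; gives deterministic dedup.
canonicalize_edges <- function(edges) {
  if (nrow(edges) == 0) return(edges)
  key_a <- node_key(edges$kind_a, edges$name_a)
  key_b <- node_key(edges$kind_b, edges$name_b)
  swap <- key_b < key_a
  if (any(swap)) {
    tmp_n <- edges$name_a[swap]; tmp_k <- edges$kind_a[swap]
    edges$name_a[swap] <- edges$name_b[swap]
    edges$kind_a[swap] <- edges$kind_b[swap]
    edges$name_b[swap] <- tmp_n
    edges$kind_b[swap] <- tmp_k
  }
  edges
}

edge_key <- function(edges) {
  paste(node_key(edges$kind_a, edges$name_a),
        node_key(edges$kind_b, edges$name_b), sep = "|")
}

new_edge_frame <- function(name_a = character(), kind_a = character(),
                           name_b = character(), kind_b = character(),
                           edge_kind = character(), weight = numeric()) {
  data.frame(name_a = name_a, kind_a = kind_a, name_b = name_b,
             kind_b = kind_b, edge_kind = edge_kind, weight = weight,
             stringsAsFactors = FALSE)
}

validate_edge_frame <- function(edges, where = "edge list") {
  self <- edges$kind_a == edges$kind_b & edges$name_a == edges$name_b
  if (any(self))
    stop(where, ": self-loop in row(s) ",
         paste(which(self), collapse = ", "), call. = FALSE)
  implied <- edge_kind_for(edges$kind_a, edges$kind_b)
  bad <- is.na(implied) | implied != edges$edge_kind
  if (any(bad)) {
    i <- which(bad)[1]
    stop(where, ": row ", i, " (", edges$name_a[i], " [", edges$kind_a[i],
         "] -- ", edges$name_b[i], " [", edges$kind_b[i], "]) does not match ",
         "association type '", edges$edge_kind[i], "'", call. = FALSE)
  }
  if (any(!is.finite(edges$weight) | edges$weight <= 0))
    stop(where, ": weights must be positive and finite", call. = FALSE)
  invisible(edges)
}

#' Load an association edge list from a TSV file
#'
#' Reads a tab-separated file with header columns `source_name`,
#' `source_kind`, `target_name`, `target_kind` and optionally `edge_kind`
#' and `weight`.  Lines starting with `#` are ignored.  Node names are
#' trimmed and case-folded; node kinds are matched case-insensitively
#' against the five canonical kinds.  Edges are undirected: a row and its
#' reverse are the same edge, and duplicates are removed.
#'
#' @param path Path to the TSV file.
#' @param edge_kind Association type of every row (one of [edge_kinds()]).
#'   May be omitted when the file carries a per-row `edge_kind` column.
#' @return A data frame of deduplicated, canonically oriented edges with
#'   columns `name_a`, `kind_a`, `name_b`, `kind_b`, `edge_kind`, `weight`.
#' @seealso [build_network()]
#' @export
load_edge_list <- function(path, edge_kind = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- tryCatch(
    read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
               colClasses = "character"),
    error = function(e) stop("cannot parse ", path, ": ",
                             conditionMessage(e), call. = FALSE))
  need <- c("source_name", "source_kind", "target_name", "target_kind")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols) > 0)
    stop(path, ": missing column(s) ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  if (nrow(raw) == 0)
    return(new_edge_frame())
  incomplete <- !stats::complete.cases(raw[need]) |
    raw$source_name == "" | raw$target_name == ""
  if (any(incomplete))
    stop(path, ": malformed row(s) at data line ",
         paste(which(incomplete), collapse = ", "), call. = FALSE)
  ek <- if ("edge_kind" %in% names(raw)) trimws(raw$edge_kind)
        else if (!is.null(edge_kind)) rep(edge_kind, nrow(raw))
        else stop(path, ": no edge_kind column and no edge_kind argument",
                  call. = FALSE)
  if (!is.null(edge_kind) && !edge_kind %in% names(EDGE_KIND_PAIRS))
    stop("unknown association type '", edge_kind, "'", call. = FALSE)
  w <- if ("weight" %in% names(raw)) as.numeric(raw$weight) else rep(1, nrow(raw))
  edges <- new_edge_frame(
    name_a = normalize_name(raw$source_name),
    kind_a = normalize_kind(raw$source_kind),
    name_b = normalize_name(raw$target_name),
    kind_b = normalize_kind(raw$target_kind),
    edge_kind = ek, weight = w)
  validate_edge_frame(edges, where = path)
  edges <- canonicalize_edges(edges)
  edges[!duplicated(edge_key(edges)), , drop = FALSE]
}

#' Build a molecular association network from edge sets
#'
#' Takes one or more edge data frames (as returned by [load_edge_list()] or
#' built in code), unions them with global deduplication of undirected
#' edges, and assembles the node table from the edge endpoints.
#'
#' @param edge_sets A single edge data frame or a list of them.
#' @return An object of class `man_network` with components `edges` (the
#'   deduplicated canonical edge frame), `nodes` (data frame `kind`, `name`)
#'   and `kind_counts` (named integer vector over the five node kinds).
#' @examples
#' e <- data.frame(name_a = "m1", kind_a = "miRNA",
#'                 name_b = "d1", kind_b = "disease",
#'                 edge_kind = "miRNA-disease", weight = 1)
#' net <- build_network(e)
#' net
#' @export
build_network <- function(edge_sets) {
  if (is.data.frame(edge_sets)) edge_sets <- list(edge_sets)
  edges <- do.call(rbind, lapply(edge_sets, function(e) {
    e <- as.data.frame(e, stringsAsFactors = FALSE)
    if (is.null(e$weight)) e$weight <- 1
    e[c("name_a", "kind_a", "name_b", "kind_b", "edge_kind", "weight")]
  }))
  if (is.null(edges) || nrow(edges) == 0)
    stop("a molecular association network needs at least one edge",
         call. = FALSE)
  validate_edge_frame(edges)
  edges <- canonicalize_edges(edges)
  edges <- edges[!duplicated(edge_key(edges)), , drop = FALSE]
  rownames(edges) <- NULL
  nodes <- unique(rbind(
    data.frame(kind = edges$kind_a, name = edges$name_a,
               stringsAsFactors = FALSE),
    data.frame(kind = edges$kind_b, name = edges$name_b,
               stringsAsFactors = FALSE)))
  nodes <- nodes[order(kind_rank(nodes$kind), nodes$name), , drop = FALSE]
  rownames(nodes) <- NULL
  counts <- table(factor(nodes$kind, levels = KIND_LEVELS))
  structure(list(edges = edges, nodes = nodes,
                 kind_counts = setNames(as.integer(counts), KIND_LEVELS)),
            class = "man_network")
}

#' @export
print.man_network <- function(x, ...) {
  cat("Molecular association network\n")
  cat("  nodes:", nrow(x$nodes), "(",
      paste(sprintf("%s %d", names(x$kind_counts), x$kind_counts),
            collapse = ", "), ")\n")
  et <- table(x$edges$edge_kind)
  cat("  edges:", nrow(x$edges), "over", length(et), "association type(s)\n")
  for (k in names(et)) cat(sprintf("    %-16s %d\n", k, et[[k]]))
  invisible(x)
}

#' @export
summary.man_network <- function(object, ...) {
  list(n_nodes = nrow(object$nodes), n_edges = nrow(object$edges),
       kind_counts = object$kind_counts,
       edge_counts = table(object$edges$edge_kind))
}

#' Serialize / read a network as a single TSV
#'
#' The on-disk format is one TSV with columns `source_name`, `source_kind`,
#' `target_name`, `target_kind`, `edge_kind`, `weight`; it round-trips
#' exactly through [read_network()].
#'
#' @param net A `man_network`.
#' @param path Output (input) file path.
#' @return `write_network` returns `path` invisibly; `read_network` returns
#'   a `man_network`.
#' @export
write_network <- function(net, path) {
  out <- data.frame(source_name = net$edges$name_a,
                    source_kind = net$edges$kind_a,
                    target_name = net$edges$name_b,
                    target_kind = net$edges$kind_b,
                    edge_kind = net$edges$edge_kind,
                    weight = net$edges$weight,
                    stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_network
#' @export
read_network <- function(path) {
  build_network(load_edge_list(path))
}

# Fast membership test for undirected node pairs against the network edges.
network_edge_keys <- function(net) edge_key(net$edges)

#' Sample admissible negative (non-associated) node pairs
#'
#' Draws `n` distinct node pairs that are absent from the network and whose
#' kind combination is one of the nine association types.  By default the
#' sample is uniform over the pooled universe of admissible non-edges; with
#' `stratified = TRUE` the per-type counts are proportional to the per-type
#' positive counts.
#'
#' @param net A `man_network`.
#' @param n Number of pairs to draw.
#' @param seed Integer seed; the draw is reproducible.
#' @param stratified Stratify counts by association type (default pooled).
#' @param kinds Optional character vector restricting the admissible
#'   association types (default: all nine).
#' @param exclude Optional edge/pair data frame of additional pairs to
#'   avoid (e.g. negatives already drawn for another purpose).
#' @return An edge-frame-shaped data frame of `n` pairs (weight 0, label
#'   semantics "unknown association"), canonically oriented.
#' @export
sample_negatives <- function(net, n, seed, stratified = FALSE, kinds = NULL,
                             exclude = NULL) {
  kinds <- kinds %||% names(EDGE_KIND_PAIRS)
  stopifnot(all(kinds %in% names(EDGE_KIND_PAIRS)))
  nodes_by_kind <- split(net$nodes$name, factor(net$nodes$kind, KIND_LEVELS))
  pos_per_kind <- table(factor(net$edges$edge_kind, names(EDGE_KIND_PAIRS)))

  universe <- vapply(kinds, function(ek) {
    kp <- EDGE_KIND_PAIRS[[ek]]
    na_ <- length(nodes_by_kind[[kp[1]]]); nb_ <- length(nodes_by_kind[[kp[2]]])
    tot <- if (kp[1] == kp[2]) na_ * (na_ - 1) / 2 else na_ * nb_
    tot - pos_per_kind[[ek]]
  }, numeric(1))
  if (sum(universe) < n)
    stop("only ", sum(universe), " admissible non-edges available, need ", n,
         call. = FALSE)

  target <- if (stratified) {
    pos <- pos_per_kind[kinds]
    raw <- if (sum(pos) > 0) n * as.numeric(pos) / sum(pos)
           else n * universe / sum(universe)
    cnt <- floor(raw)
    rem <- n - sum(cnt)
    if (rem > 0) {
      ord <- order(raw - cnt, decreasing = TRUE)
      cnt[ord[seq_len(rem)]] <- cnt[ord[seq_len(rem)]] + 1
    }
    setNames(as.integer(cnt), kinds)
  } else NULL

  known <- network_edge_keys(net)
  if (!is.null(exclude) && nrow(exclude) > 0)
    known <- c(known, edge_key(canonicalize_edges(exclude)))
  with_seed(seed, {
    picked <- new_edge_frame()
    guard <- 0L
    repeat {
      need <- n - nrow(picked)
      if (need <= 0) break
      guard <- guard + 1L
      if (guard > 200L)
        stop("negative sampling failed to converge", call. = FALSE)
      batch <- max(2L * need, 32L)
      ek <- if (is.null(target)) {
        sample(kinds, batch, replace = TRUE, prob = universe)
      } else {
        have <- table(factor(picked$edge_kind, kinds))
        rep_len(rep(kinds, pmax(target - have, 0L) * 2L + 1L), batch)
      }
      cand <- do.call(rbind, lapply(split(seq_along(ek), ek), function(idx) {
        kp <- EDGE_KIND_PAIRS[[ek[idx[1]]]]
        a <- sample(nodes_by_kind[[kp[1]]], length(idx), replace = TRUE)
        b <- sample(nodes_by_kind[[kp[2]]], length(idx), replace = TRUE)
        new_edge_frame(a, rep(kp[1], length(idx)), b, rep(kp[2], length(idx)),
                       rep(ek[idx[1]], length(idx)), rep(0, length(idx)))
      }))
      cand <- cand[cand$name_a != cand$name_b | cand$kind_a != cand$kind_b, ,
                   drop = FALSE]
      cand <- canonicalize_edges(cand)
      keys <- edge_key(cand)
      keep <- !keys %in% known & !keys %in% edge_key(picked) &
        !duplicated(keys)
      cand <- cand[keep, , drop = FALSE]
      if (!is.null(target)) {
        for (k in kinds) {
          have <- sum(picked$edge_kind == k)
          rows <- which(cand$edge_kind == k)
          excess <- length(rows) - (target[[k]] - have)
          if (excess > 0) cand <- cand[-rows[seq_len(excess)], , drop = FALSE]
        }
      }
      if (nrow(cand) > need) cand <- cand[seq_len(need), , drop = FALSE]
      picked <- rbind(picked, cand)
    }
    rownames(picked) <- NULL
    picked
  })
}

#' Leak-safe k-fold split of the association edges
#'
#' Randomly partitions the network's edges into `k` test subsets of (almost)
#' equal size; for each fold the remaining edges are the training set and an
#' equal number of admissible non-edges is drawn as test negatives
#' (per-fold seed `seed + fold_index`).
#'
#' @param net A `man_network`.
#' @param k Number of folds (default 5).
#' @param seed Integer seed controlling the partition and negative draws.
#' @param edge_kind Optional single association type: folds are then formed
#'   over edges of that type only (the remaining edges are placed in every
#'   fold's training set) and test negatives are restricted to that type.
#' @param stratified Passed to [sample_negatives()].
#' @return A list of `k` fold objects, each a list with `fold_index`,
#'   `train_edges`, `test_positives`, `test_negatives` and `seed`.
#' @export
kfold_split <- function(net, k = 5, seed = 1, edge_kind = NULL,
                        stratified = FALSE) {
  edges <- net$edges
  pool_idx <- if (is.null(edge_kind)) seq_len(nrow(edges))
              else which(edges$edge_kind == edge_kind)
  m <- length(pool_idx)
  if (k < 2) stop("k must be at least 2", call. = FALSE)
  if (m < k) stop("cannot make ", k, " folds from ", m, " edges",
                  call. = FALSE)
  fold_of <- with_seed(seed, sample(rep(seq_len(k), length.out = m)))
  neg_kinds <- if (is.null(edge_kind)) NULL else edge_kind
  lapply(seq_len(k), function(f) {
    test_idx <- pool_idx[fold_of == f]
    test_pos <- edges[test_idx, , drop = FALSE]
    train <- edges[setdiff(seq_len(nrow(edges)), test_idx), , drop = FALSE]
    rownames(test_pos) <- rownames(train) <- NULL
    neg <- sample_negatives(net, nrow(test_pos), seed = seed + f,
                            stratified = stratified, kinds = neg_kinds)
    structure(list(fold_index = f, train_edges = train,
                   test_positives = test_pos, test_negatives = neg,
                   seed = seed + f),
              class = "man_fold")
  })
}

#' @export
print.man_fold <- function(x, ...) {
  cat("Fold", x$fold_index, "- train:", nrow(x$train_edges),
      "test +:", nrow(x$test_positives),
      "test -:", nrow(x$test_negatives), "\n")
  invisible(x)
}

# Adjacency list over node keys.
adjacency_list <- function(net) {
  ka <- node_key(net$edges$kind_a, net$edges$name_a)
  kb <- node_key(net$edges$kind_b, net$edges$name_b)
  split(c(kb, ka), c(ka, kb))
}

#' Nodes at shortest-path distance exactly k
#'
#' Breadth-first search from `node` over the undirected network; returns the
#' nodes whose shortest-path distance from `node` equals `k`.
#'
#' @param net A `man_network`.
#' @param node A list or data frame row with `kind` and `name`.
#' @param k Hop count, at least 1.
#' @return A data frame with columns `kind`, `name` (possibly empty).
#' @export
khop_neighbors <- function(net, node, k) {
  stopifnot(k >= 1)
  key <- node_key(normalize_kind(node$kind), normalize_name(node$name))
  all_keys <- node_key(net$nodes$kind, net$nodes$name)
  if (!key %in% all_keys)
    stop("node not in network: ", key, call. = FALSE)
  adj <- adjacency_list(net)
  visited <- key
  frontier <- key
  for (step in seq_len(k)) {
    nxt <- setdiff(unique(unlist(adj[frontier], use.names = FALSE)), visited)
    visited <- c(visited, nxt)
    frontier <- nxt
    if (length(frontier) == 0) break
  }
  split_node_key(sort(frontier))
}
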