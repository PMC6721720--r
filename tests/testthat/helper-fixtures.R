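# Small in-code fixtures shared across tests.

# Edge frame builder with sensible defaults.
edge_df <- function(name_a, kind_a, name_b, kind_b, edge_kind = NULL,
                    weight = 1) {
  if (is.null(edge_kind))
    edge_kind <- manlink:::edge_kind_for(kind_a, kind_b)
  data.frame(name_a = name_a, kind_a = kind_a, name_b = name_b,
             kind_b = kind_b, edge_kind = edge_kind, weight = weight,
             stringsAsFactors = FALSE)
}

# A small bipartite miRNA-disease network: m1..m_nm fully or partially
# connected to d1..d_nd.
bipartite_net <- function(nm = 3, nd = 3, drop = 0) {
  g <- expand.grid(m = paste0("m", seq_len(nm)), d = paste0("d", seq_len(nd)),
                   stringsAsFactors = FALSE)
  if (drop > 0) g <- g[-seq_len(drop), , drop = FALSE]
  build_network(edge_df(g$m, "miRNA", g$d, "disease", "miRNA-disease"))
}

# Two disjoint k-cliques of proteins, named a1.. / b1..
two_cliques <- function(k = 5) {
  mk <- function(prefix) {
    idx <- t(combn(k, 2))
    edge_df(paste0(prefix, idx[, 1]), "protein",
            paste0(prefix, idx[, 2]), "protein", "protein-protein")
  }
  rbind(mk("a"), mk("b"))
}

# Random edge list over a mixed node universe, for BFS/serialization tests.
random_net <- function(n_nodes = 40, n_edges = 80, seed = 1) {
  set.seed(seed)
  kinds <- sample(node_kinds(), n_nodes, replace = TRUE)
  names <- paste0("n", seq_len(n_nodes))
  rows <- list()
  guard <- 0
  while (length(rows) < n_edges && guard < n_edges * 50) {
    guard <- guard + 1
    i <- sample(n_nodes, 1); j <- sample(n_nodes, 1)
    if (i == j) next
    ek <- manlink:::edge_kind_for(kinds[i], kinds[j])
    if (is.na(ek)) next
    rows[[length(rows) + 1]] <-
      edge_df(names[i], kinds[i], names[j], kinds[j], ek)
  }
  build_network(do.call(rbind, rows))
}

# Tiny synthetic bundle for pipeline tests (fast).
small_bundle <- function(seed = 1, signal = 0.9, n = 40, m = 60) {
  gen_man_data(synth_config(
    n_nodes = setNames(rep(n, 5), node_kinds()),
    n_edges = setNames(rep(m, 9), edge_kinds()),
    signal = signal, seed = seed))
}

small_attributes <- function(bundle, seed = 1, epochs = 25) {
  suppressWarnings(suppressMessages(encode_attributes(
    bundle$network, sequences = bundle$sequences, smiles = bundle$smiles,
    tree_codes = bundle$tree_codes, epochs = epochs, seed = seed)))
}

# Independent brute-force 3-mer counter: substring windows counted with
# table(), a different route than the integer-coding implementation.
brute_kmer3 <- function(sequence, alphabet, map = NULL) {
  counts <- setNames(numeric(64), kmer3_names_ref(alphabet))
  s <- toupper(sequence)
  if (!is.null(map))
    s <- chartr(paste(names(map), collapse = ""),
                paste(unname(map), collapse = ""), s)
  n <- nchar(s)
  if (n < 3) return(counts)
  windows <- substring(s, 1:(n - 2), 3:n)
  windows <- windows[windows %in% names(counts)]
  if (length(windows) == 0) return(counts)
  tab <- table(windows)
  counts[names(tab)] <- as.numeric(tab)
  counts / length(windows)
}

kmer3_names_ref <- function(alphabet) {
  out <- character()
  for (a in alphabet) for (b in alphabet) for (c in alphabet)
    out <- c(out, paste0(a, b, c))
  out
}

# Brute-force semantic contributions: DD(t) = delta ^ (minimum number of
# truncation steps from any of the disease's own codes down to t).
brute_profile <- function(dag, delta = 0.5) {
  depth <- function(code) length(strsplit(code, ".", fixed = TRUE)[[1]])
  DD <- setNames(rep(NA_real_, length(dag$codes)), dag$codes)
  for (t in dag$codes) {
    best <- Inf
    for (own in dag$own_codes) {
      # t must lie on own's truncation chain: a dot-prefix (or equal)
      if (own == t || startsWith(own, paste0(t, "."))) {
        best <- min(best, depth(own) - depth(t))
      }
    }
    DD[t] <- delta^best
  }
  list(DD = DD, DV = sum(DD))
}

# Direct-definition metric reference: per-threshold confusion enumeration.
ref_metrics <- function(scores, labels, threshold = 0.5) {
  pos <- sum(labels == 1); neg <- sum(labels == 0)
  tp <- sum(scores >= threshold & labels == 1)
  fp <- sum(scores >= threshold & labels == 0)
  fn <- pos - tp; tn <- neg - fp
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- fpr <- rec <- prec <- numeric(length(thr))
  for (k in seq_along(thr)) {
    tpk <- sum(scores >= thr[k] & labels == 1)
    fpk <- sum(scores >= thr[k] & labels == 0)
    tpr[k] <- tpk / pos; fpr[k] <- fpk / neg
    rec[k] <- tpk / pos; prec[k] <- tpk / (tpk + fpk)
  }
  trap <- function(x, y) sum(diff(x) * (y[-1] + y[-length(y)]) / 2)
  mcc_den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  c(acc = (tp + tn) / (pos + neg), sen = tp / pos, spec = tn / neg,
    prec = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    mcc = if (mcc_den == 0) 0 else (tp * tn - fp * fn) / mcc_den,
    auc = trap(c(0, fpr), c(0, tpr)),
    aupr = trap(c(0, rec), c(prec[1], prec)))
}
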