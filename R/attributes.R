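# Assemble per-node 64-d attribute vectors for a whole network: raw
# features per kind (3-mer composition, semantic-similarity profile,
# fingerprint) compressed by one autoencoder per node kind.

#' Compute 64-d attribute vectors for every node of a network
#'
#' Raw features are built per node kind: miRNA and lncRNA sequences via
#' [encode_rna_3mer()], proteins via [encode_protein_3mer()], diseases as
#' their row of the pairwise semantic-similarity matrix
#' ([disease_similarity_matrix()] over the network's diseases with tree
#' codes), drugs via [fingerprint_matrix()].  Each kind's raw matrix is
#' compressed to `latent` dimensions by a kind-specific autoencoder
#' ([train_sae()]).  Nodes without raw data receive the all-zero vector;
#' the per-kind missing counts are recorded.
#'
#' Attribute vectors depend only on these molecule-intrinsic inputs, never
#' on the association edges, so they are computed once and reused across
#' cross-validation folds without leaking test associations.
#'
#' @param net A `man_network`.
#' @param sequences Named character vector of nucleotide/amino-acid
#'   sequences keyed by (case-folded) node name; used for miRNA, lncRNA
#'   and protein nodes.
#' @param smiles Named character vector of SMILES keyed by drug name.
#' @param tree_codes Named list of tree-code vectors keyed by disease name.
#' @param latent Attribute dimension (default 64).
#' @param sae_for_kmer Pass the (already 64-d) 3-mer vectors through the
#'   autoencoder as well (default TRUE); FALSE keeps them raw.
#' @param epochs,seed Autoencoder training controls; per-kind seeds are
#'   derived from `seed`.
#' @param bits,radius Fingerprint parameters, see [smiles_to_fingerprint()].
#' @return An object of class `man_attributes`: list with `values`
#'   (nodes-by-`latent` matrix, rownames `kind:name`), `missing` (named
#'   per-kind count of nodes without raw data), `saes` (per-kind
#'   autoencoders) and `latent`.
#' @export
encode_attributes <- function(net, sequences = NULL, smiles = NULL,
                              tree_codes = NULL, latent = 64,
                              sae_for_kmer = TRUE, epochs = 100, seed = 1,
                              bits = 1024, radius = 2) {
  nodes <- net$nodes
  keys <- node_key(nodes$kind, nodes$name)
  values <- matrix(0, nrow(nodes), latent, dimnames = list(keys, NULL))
  missing <- setNames(integer(length(KIND_LEVELS)), KIND_LEVELS)
  saes <- list()

  raw_for_kind <- function(kind) {
    nm <- nodes$name[nodes$kind == kind]
    if (length(nm) == 0) return(NULL)
    if (kind %in% c("miRNA", "lncRNA", "protein")) {
      have <- nm[nm %in% names(sequences)]
      if (length(have) == 0) return(list(names = nm, mat = NULL))
      enc <- if (kind == "protein") encode_protein_3mer else encode_rna_3mer
      mat <- t(vapply(sequences[have], enc, numeric(64)))
      rownames(mat) <- have
      list(names = nm, mat = mat)
    } else if (kind == "drug") {
      have <- nm[nm %in% names(smiles)]
      if (length(have) == 0) return(list(names = nm, mat = NULL))
      list(names = nm, mat = fingerprint_matrix(smiles[have], bits, radius))
    } else { # disease
      have <- nm[nm %in% names(tree_codes)]
      if (length(have) == 0) return(list(names = nm, mat = NULL))
      profiles <- lapply(have, function(d)
        semantic_profile(build_disease_dag(tree_codes[[d]], disease = d)))
      names(profiles) <- have
      list(names = nm, mat = disease_similarity_matrix(profiles))
    }
  }

  for (ki in seq_along(KIND_LEVELS)) {
    kind <- KIND_LEVELS[ki]
    raw <- raw_for_kind(kind)
    if (is.null(raw)) next
    if (is.null(raw$mat)) {
      missing[kind] <- length(raw$names)
      warning("no raw attribute data for any ", kind, " node; using zeros",
              call. = FALSE)
      next
    }
    missing[kind] <- length(raw$names) - nrow(raw$mat)
    mat <- raw$mat
    is_kmer <- kind %in% c("miRNA", "lncRNA", "protein")
    use_sae <- (sae_for_kmer || !is_kmer) && nrow(mat) >= 2
    if (use_sae) {
      # Similarity rows over few diseases can be narrower than the latent
      # space; pad with zero columns so the bottleneck width is reachable.
      if (ncol(mat) < latent)
        mat <- cbind(mat, matrix(0, nrow(mat), latent - ncol(mat)))
      sae <- train_sae(mat, latent = latent, epochs = epochs,
                       seed = derive_seed(seed, ki))
      saes[[kind]] <- sae
      enc <- predict(sae, mat, type = "latent")
    } else {
      enc <- mat
      if (ncol(enc) < latent)
        enc <- cbind(enc, matrix(0, nrow(enc), latent - ncol(enc)))
      if (ncol(enc) > latent)
        enc <- enc[, seq_len(latent), drop = FALSE]
    }
    values[node_key(kind, rownames(raw$mat)), ] <- enc
  }
  if (any(missing > 0))
    message("attribute data missing for ",
            paste(sprintf("%d %s", missing[missing > 0],
                          names(missing[missing > 0])), collapse = ", "),
            " node(s); zero vectors used")
  structure(list(values = values, missing = missing, saes = saes,
                 latent = latent),
            class = "man_attributes")
}

#' @export
print.man_attributes <- function(x, ...) {
  cat("Node attribute vectors:", nrow(x$values), "nodes x", x$latent,
      "dims;", sum(x$missing), "node(s) without raw data\n")
  invisible(x)
}

#' Export attribute vectors as TSV
#'
#' Columns: `node_kind`, `node_name`, then one column per dimension.
#'
#' @param attributes A `man_attributes` (or `man_behavior`) object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_attributes <- function(attributes, path) {
  ref <- split_node_key(rownames(attributes$values))
  out <- cbind(data.frame(node_kind = ref$kind, node_name = ref$name,
                          stringsAsFactors = FALSE),
               as.data.frame(attributes$values))
  names(out)[-(1:2)] <- paste0("v", seq_len(ncol(attributes$values)))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
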