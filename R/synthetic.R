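# Seeded generators for every raw input the pipeline consumes: sequences,
# MeSH-like tree codes, SMILES, and a heterogeneous association network
# with planted latent-factor structure so that link prediction is learnable
# end to end without any external database.

#' Configuration for the synthetic molecular association network
#'
#' Every node receives a latent factor vector of dimension `latent_dim`;
#' edges of each association type are drawn with probability mixing the
#' softplus of the latent affinity (weight `signal`) with a uniform
#' component (weight `1 - signal`).  At `signal = 0` the edges are pure
#' noise; at `signal = 1` each type consists of exactly the top pairs by
#' latent affinity.  Sequences are composition-biased by the same latent
#' factors (scaled by `signal`), so attribute features carry signal too.
#'
#' @param n_nodes Named integer vector of node counts per kind.
#' @param n_edges Named integer vector of edge counts per association type.
#' @param latent_dim Latent factor dimension (default 8).
#' @param signal Mixing weight in `[0, 1]` (default 0.9).
#' @param affinity_scale Multiplier inside the softplus (default 4).
#' @param affinity_shift Offset, in standard deviations of the latent dot
#'   product, subtracted before the softplus (default 1.5); it concentrates
#'   planted edges in the high-affinity tail.
#' @param rna_length,lncrna_length,protein_length Sequence length ranges.
#' @param depth_range,branching Tree-code hierarchy shape.
#' @param seed Integer seed; every generator output is a pure function of
#'   this configuration.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_nodes = c(miRNA = 200, lncRNA = 200,
                                     protein = 200, drug = 200,
                                     disease = 200),
                         n_edges = setNames(rep(500L, 9), edge_kinds()),
                         latent_dim = 8, signal = 0.9, affinity_scale = 4,
                         affinity_shift = 1.5,
                         rna_length = c(21, 25),
                         lncrna_length = c(200, 400),
                         protein_length = c(100, 300),
                         depth_range = c(2, 5), branching = 3, seed = 1) {
  stopifnot(all(n_nodes >= 0), all(n_edges >= 0),
            signal >= 0, signal <= 1, latent_dim >= 1)
  stopifnot(all(names(n_edges) %in% edge_kinds()))
  structure(list(n_nodes = n_nodes, n_edges = n_edges,
                 latent_dim = latent_dim, signal = signal,
                 affinity_scale = affinity_scale,
                 affinity_shift = affinity_shift,
                 rna_length = rna_length, lncrna_length = lncrna_length,
                 protein_length = protein_length,
                 depth_range = depth_range, branching = branching,
                 seed = seed),
            class = "synth_config")
}

softplus <- function(x) ifelse(x > 30, x, log1p(exp(x)))

# Sample a sequence by concatenating 3-mers drawn from `p` (64 probs over
# the alphabet cubed) and trimming to the target length.
sample_sequence <- function(len, alphabet, p = NULL) {
  kmers <- kmer3_names(alphabet)
  if (is.null(p)) p <- rep(1 / 64, 64)
  paste(sample(kmers, ceiling(len / 3), replace = TRUE, prob = p),
        collapse = "") |> substr(1, len)
}

#' Generate random sequences
#'
#' RNA sequences are uniform over \{A, C, G, U\} 3-mers, protein sequences
#' over the 20 standard residues (via uniform residues), with lengths
#' uniform in `length_range`.
#'
#' @param n Number of sequences.
#' @param kind `"rna"` or `"protein"`.
#' @param length_range Integer vector `c(min, max)`.
#' @param seed Integer seed.
#' @param names Optional sequence names (default `seq1..seqn`).
#' @param bias Optional n-by-64 matrix of 3-mer probabilities (rows) used
#'   instead of the uniform composition; for proteins the 64 entries refer
#'   to polarity-class 3-mers, realised by residues drawn uniformly within
#'   each class.
#' @return Named character vector of sequences.
#' @export
gen_sequences <- function(n, kind = c("rna", "protein"), length_range,
                          seed = 1, names = NULL, bias = NULL) {
  kind <- match.arg(kind)
  if (length(length_range) != 2 || length_range[1] > length_range[2] ||
      length_range[1] < 1)
    stop("invalid length range", call. = FALSE)
  names <- names %||% paste0("seq", seq_len(n))
  with_seed(seed, {
    lens <- sample(length_range[1]:length_range[2], n, replace = TRUE)
    out <- vapply(seq_len(n), function(i) {
      p <- if (is.null(bias)) NULL else bias[i, ]
      if (kind == "rna") {
        sample_sequence(lens[i], c("A", "C", "G", "U"), p)
      } else {
        cls <- sample_sequence(lens[i], as.character(1:4), p)
        paste(vapply(strsplit(cls, "")[[1]], function(cc)
          sample(names(AA_CLASS)[AA_CLASS == as.integer(cc)], 1), ""),
          collapse = "")
      }
    }, character(1))
    setNames(out, names)
  })
}

#' Generate a random MeSH-like tree-code table
#'
#' Grows a random forest of dot-notation codes (roots like `C01`, each
#' internal code with up to `branching` children of the form
#' `parent.nnn`), then assigns every disease one or two codes drawn from
#' the forest.  All emitted codes truncate to a top-level root, so the
#' resulting disease DAGs are acyclic and parent-closed by construction.
#'
#' @param n_diseases Number of diseases.
#' @param depth_range Depth range of the grown forest (min >= 1).
#' @param branching Maximum children per code.
#' @param seed Integer seed.
#' @param names Optional disease names.
#' @return Named list mapping disease name to a character vector of codes.
#' @export
gen_tree_codes <- function(n_diseases, depth_range = c(2, 5), branching = 3,
                           seed = 1, names = NULL) {
  stopifnot(depth_range[1] >= 1)
  names <- names %||% paste0("disease", seq_len(n_diseases))
  with_seed(seed, {
    n_roots <- max(2L, ceiling(n_diseases / 40))
    codes <- sprintf("C%02d", seq_len(n_roots))
    frontier <- codes
    max_depth <- sample(depth_range[1]:depth_range[2], 1)
    depth <- 1
    while (depth < max_depth && length(frontier) > 0) {
      children <- unlist(lapply(frontier, function(p) {
        k <- sample(0:branching, 1, prob = c(1, rep(2, branching)))
        if (k == 0) return(character())
        paste0(p, ".", sprintf("%03d", sample(100:999, k)))
      }))
      children <- unique(children)
      codes <- c(codes, children)
      frontier <- children
      depth <- depth + 1
    }
    setNames(lapply(seq_len(n_diseases), function(i)
      unique(sample(codes, sample(1:2, 1), replace = FALSE))), names)
  })
}

# Valence-safe SMILES fragments; linear concatenation of any of these
# (starting with an atom token, self-contained ring closures) is valid.
SMILES_FRAGMENTS <- c(
  "C", "CC", "CCC", "N", "O", "CO", "CN", "CS", "C(C)C", "C(C)(C)C",
  "C(=O)O", "C(=O)N", "C(=O)", "c1ccccc1", "C1CCCCC1", "c1ccncc1",
  "c1ccc(N)cc1", "c1ccc(O)cc1", "C1CCNCC1", "C1CCOC1", "C(F)(F)F",
  "CCl", "CBr", "C=C", "C#N", "CCOC", "CN(C)C", "c1ccsc1", "c1cc[nH]c1")

# Curated drug-like templates used verbatim.
SMILES_TEMPLATES <- c(
  "CC(=O)Oc1ccccc1C(=O)O",            # aspirin
  "CC(=O)Nc1ccc(O)cc1",               # paracetamol
  "CC(C)Cc1ccc(cc1)C(C)C(=O)O",       # ibuprofen
  "Cn1cnc2c1c(=O)n(C)c(=O)n2C",       # caffeine
  "NCCc1ccc(O)c(O)c1",                # dopamine
  "OC(=O)c1ccccc1O",                  # salicylic acid
  "CC(N)C(=O)O",                      # alanine
  "NC(CC(=O)O)C(=O)O",                # aspartate
  "OCC(O)CO",                         # glycerol
  "CCN(CC)CC",                        # triethylamine
  "c1ccc2ccccc2c1",                   # naphthalene
  "Oc1ccccc1",                        # phenol
  "Nc1ccccc1",                        # aniline
  "CCOC(=O)c1ccccc1",                 # ethyl benzoate
  "CC(C)NCC(O)c1ccc(O)c(O)c1",        # isoprenaline-like
  "CN1CCC(CC1)c1ccccc1",              # phenylpiperidine
  "O=C(O)CCCCC(=O)O",                 # adipic acid
  "NCCCN",                            # putrescine-like
  "OCCN1CCNCC1",                      # piperazine ethanol
  "COc1ccc(CCN)cc1")                  # methoxyphenethylamine

#' Generate random valid SMILES
#'
#' Each drug is either a curated small-molecule template or a random
#' linear assembly of valence-safe fragments (a template "decorated" by
#' chain extension); every output is validated by fingerprinting and
#' resampled on failure, so all returned SMILES are parseable.
#'
#' @param n Number of drugs.
#' @param seed Integer seed.
#' @param names Optional drug names.
#' @return Named character vector of SMILES.
#' @export
gen_smiles <- function(n, seed = 1, names = NULL) {
  names <- names %||% paste0("drug", seq_len(n))
  if (n == 0) return(setNames(character(0), character(0)))
  with_seed(seed, {
    draw_one <- function() {
      if (runif(1) < 0.4) sample(SMILES_TEMPLATES, 1)
      else paste(sample(SMILES_FRAGMENTS, sample(2:6, 1), replace = TRUE),
                 collapse = "")
    }
    out <- vapply(seq_len(n), function(i) draw_one(), character(1))
    # validate whole batches by fingerprinting; redraw any failures
    for (round in 1:10) {
      fp <- ob_fingerprints(out)
      bad <- which(apply(fp, 1, function(r) anyNA(r) || !any(r != 0)))
      if (length(bad) == 0) break
      out[bad] <- vapply(bad, function(i) draw_one(), character(1))
    }
    if (length(bad) > 0) out[bad] <- SMILES_TEMPLATES[1]
    setNames(out, names)
  })
}

#' Generate a synthetic association network with planted structure
#'
#' Draws a standard-normal latent factor vector per node, computes the
#' softplus affinity `softplus(scale * (dot - shift * sd(dot)))` for every
#' admissible pair of each requested association type, and samples exactly
#' the requested number of distinct edges per type with probability
#' proportional to `signal * affinity / mean(affinity) + (1 - signal)`
#' (at `signal = 1` the top pairs by affinity are taken outright).
#'
#' @param config A [synth_config()].
#' @return List with `network` (a `man_network`) and `latent` (node-key by
#'   `latent_dim` matrix of the planted factors).
#' @export
gen_network <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  nm <- lapply(setNames(nm = KIND_LEVELS), function(k) {
    n <- config$n_nodes[[k]] %||% 0
    if (n == 0) character(0)
    else sprintf("%s%03d", c(miRNA = "mir", lncRNA = "lnc", protein = "pro",
                             drug = "dru", disease = "dis")[[k]], seq_len(n))
  })
  with_seed(derive_seed(config$seed, 7), {
    keys <- unlist(lapply(KIND_LEVELS, function(k) node_key(k, nm[[k]])))
    Z <- matrix(rnorm(length(keys) * config$latent_dim),
                length(keys), config$latent_dim,
                dimnames = list(keys, NULL))
    s <- config$signal
    edge_sets <- lapply(names(config$n_edges), function(ek) {
      m <- config$n_edges[[ek]]
      if (m == 0) return(NULL)
      kp <- EDGE_KIND_PAIRS[[ek]]
      a_names <- nm[[kp[1]]]; b_names <- nm[[kp[2]]]
      if (kp[1] == kp[2]) {
        idx <- which(upper.tri(matrix(0, length(a_names), length(b_names))),
                     arr.ind = TRUE)
      } else {
        idx <- as.matrix(expand.grid(seq_along(a_names), seq_along(b_names)))
      }
      if (m > nrow(idx))
        stop("cannot place ", m, " edges of type ", ek, " among ",
             nrow(idx), " admissible pairs", call. = FALSE)
      za <- Z[node_key(kp[1], a_names), , drop = FALSE]
      zb <- Z[node_key(kp[2], b_names), , drop = FALSE]
      dot <- rowSums(za[idx[, 1], , drop = FALSE] *
                       zb[idx[, 2], , drop = FALSE])
      aff <- softplus(config$affinity_scale *
                        (dot - config$affinity_shift * sd(dot)))
      pick <- if (s >= 1) {
        order(aff, decreasing = TRUE)[seq_len(m)]
      } else {
        w <- s * aff / mean(aff) + (1 - s)
        sample(nrow(idx), m, prob = w)
      }
      new_edge_frame(a_names[idx[pick, 1]], rep(kp[1], m),
                     b_names[idx[pick, 2]], rep(kp[2], m),
                     rep(ek, m), rep(1, m))
    })
    net <- build_network(Filter(Negate(is.null), edge_sets))
    list(network = net, latent = Z)
  })
}

#' Generate a complete synthetic input bundle
#'
#' Produces the network plus every raw attribute input: latent-biased RNA
#' sequences for miRNA and lncRNA nodes, latent-biased protein sequences,
#' tree codes for diseases and SMILES for drugs.  The 3-mer composition
#' bias of each sequence is the softmax of a fixed random projection of
#' the node's latent vector, scaled by `signal`, which couples the
#' attribute features to the planted edge structure.
#'
#' @param config A [synth_config()].
#' @return List of class `man_synth`: `network`, `latent`, `sequences`
#'   (named by node name, all three sequence kinds), `smiles`,
#'   `tree_codes`, `config`.
#' @export
gen_man_data <- function(config = synth_config()) {
  gn <- gen_network(config)
  net <- gn$network
  Z <- gn$latent
  kinds <- split_node_key(rownames(Z))$kind
  seq_bias <- function(kind, scale = 1) {
    zk <- Z[kinds == kind, , drop = FALSE]
    if (nrow(zk) == 0) return(NULL)
    B <- with_seed(derive_seed(config$seed, match(kind, KIND_LEVELS)),
                   matrix(rnorm(64 * config$latent_dim), 64,
                          config$latent_dim))
    logits <- config$signal * scale * (zk %*% t(B)) / sqrt(config$latent_dim)
    t(apply(logits, 1, function(l) {
      e <- exp(l - max(l)); e / sum(e)
    }))
  }
  names_of <- function(kind) net$nodes$name[net$nodes$kind == kind]
  pick_rows <- function(bias, kind, names) {
    if (is.null(bias)) return(NULL)
    rownames(bias) <- split_node_key(rownames(Z))$name[kinds == kind]
    bias[names, , drop = FALSE]
  }
  sequences <- c(
    gen_sequences(length(names_of("miRNA")), "rna", config$rna_length,
                  seed = derive_seed(config$seed, 21),
                  names = names_of("miRNA"),
                  bias = pick_rows(seq_bias("miRNA"), "miRNA",
                                   names_of("miRNA"))),
    gen_sequences(length(names_of("lncRNA")), "rna", config$lncrna_length,
                  seed = derive_seed(config$seed, 22),
                  names = names_of("lncRNA"),
                  bias = pick_rows(seq_bias("lncRNA"), "lncRNA",
                                   names_of("lncRNA"))),
    gen_sequences(length(names_of("protein")), "protein",
                  config$protein_length,
                  seed = derive_seed(config$seed, 23),
                  names = names_of("protein"),
                  bias = pick_rows(seq_bias("protein"), "protein",
                                   names_of("protein"))))
  smiles <- gen_smiles(length(names_of("drug")),
                       seed = derive_seed(config$seed, 24),
                       names = names_of("drug"))
  tree_codes <- gen_tree_codes(length(names_of("disease")),
                               depth_range = config$depth_range,
                               branching = config$branching,
                               seed = derive_seed(config$seed, 25),
                               names = names_of("disease"))
  structure(list(network = net, latent = Z, sequences = sequences,
                 smiles = smiles, tree_codes = tree_codes, config = config),
            class = "man_synth")
}

#' @export
print.man_synth <- function(x, ...) {
  cat("Synthetic molecular association data (signal =", x$config$signal,
      ", seed =", x$config$seed, ")\n")
  print(x$network)
  invisible(x)
}

#' Write a synthetic bundle to a directory
#'
#' Emits one `edges_<type>.tsv` per association type, `rna.fasta`
#' (miRNA + lncRNA), `protein.fasta`, `drugs.tsv`, `diseases.tsv`,
#' `truth_latent.tsv` and a `manifest.tsv` recording the configuration.
#'
#' @param bundle A `man_synth`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_man_data <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  net <- bundle$network
  for (ek in unique(net$edges$edge_kind)) {
    sub <- net$edges[net$edges$edge_kind == ek, , drop = FALSE]
    out <- data.frame(source_name = sub$name_a, source_kind = sub$kind_a,
                      target_name = sub$name_b, target_kind = sub$kind_b,
                      edge_kind = sub$edge_kind, weight = sub$weight)
    write.table(out, file.path(dir, paste0("edges_", gsub("-", "_", ek),
                                           ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  is_rna <- names(bundle$sequences) %in%
    net$nodes$name[net$nodes$kind %in% c("miRNA", "lncRNA")]
  write_fasta_sequences(bundle$sequences[is_rna], file.path(dir, "rna.fasta"))
  write_fasta_sequences(bundle$sequences[!is_rna],
                        file.path(dir, "protein.fasta"))
  write_smiles_table(bundle$smiles, file.path(dir, "drugs.tsv"))
  write_disease_table(bundle$tree_codes, file.path(dir, "diseases.tsv"))
  lat <- data.frame(node_key = rownames(bundle$latent), bundle$latent)
  names(lat)[-1] <- paste0("z", seq_len(ncol(bundle$latent)))
  write.table(lat, file.path(dir, "truth_latent.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  cfg <- bundle$config
  flat <- unlist(cfg[setdiff(names(cfg), character(0))])
  write.table(data.frame(key = names(flat), value = unname(flat)),
              file.path(dir, "manifest.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(dir)
}
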