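# Attribute encoders: 3-mer composition, disease semantics, fingerprints,
# autoencoder compression.

test_that("RNA 3-mer encoding matches its definition on forced cases", {
  v <- encode_rna_3mer("AAAA")
  expect_equal(unname(v["AAA"]), 1)
  expect_equal(sum(v), 1)

  v <- encode_rna_3mer("ACGU")
  expect_equal(unname(v[c("ACG", "CGU")]), c(0.5, 0.5))
  expect_equal(sum(v != 0), 2)

  # T read as U; windows with other symbols skipped
  expect_equal(encode_rna_3mer("ACGT"), encode_rna_3mer("ACGU"))
  expect_equal(sum(encode_rna_3mer("ACNGU")), 0) # no window avoids the N? A-C-N, C-N-G, N-G-U all invalid
  expect_equal(sum(encode_rna_3mer("AC")), 0)
})

test_that("protein 3-mer encoding uses the four polarity classes", {
  v <- encode_protein_3mer("AAA") # Ala^3, class 1
  expect_equal(unname(v["c1c1c1"]), 1)
  v <- encode_protein_3mer("ADE") # classes 1, 4, 4
  expect_equal(unname(v["c1c4c4"]), 1)
  v <- encode_protein_3mer("ARNDCQEGHILK") # 12 residues, 10 windows
  expect_equal(sum(v), 1)
  expect_equal(max(abs(v - brute_kmer3("ARNDCQEGHILK", as.character(1:4),
                                       setNames(as.character(manlink:::AA_CLASS),
                                                names(manlink:::AA_CLASS)))),
                   na.rm = TRUE), 0, tolerance = 1e-12)
})

test_that("k-mer vectors of random sequences conserve mass and match brute force", {
  set.seed(42)
  for (i in 1:20) {
    rna <- paste(sample(c("A", "C", "G", "U", "N"), 300, replace = TRUE,
                        prob = c(rep(0.24, 4), 0.04)), collapse = "")
    v <- encode_rna_3mer(rna)
    b <- brute_kmer3(rna, c("A", "C", "G", "U"))
    expect_equal(unname(v), unname(b[names(v)]), tolerance = 1e-12)
    if (sum(v) > 0) expect_equal(sum(v), 1, tolerance = 1e-9)
    prot <- paste(sample(names(manlink:::AA_CLASS), 200, replace = TRUE),
                  collapse = "")
    vp <- encode_protein_3mer(prot)
    expect_equal(sum(vp), 1, tolerance = 1e-9)
  }
})

test_that("disease DAGs close over truncation ancestors", {
  dag <- build_disease_dag("C04.557.465.625.600")
  expect_setequal(dag$codes, c("C04.557.465.625.600", "C04.557.465.625",
                               "C04.557.465", "C04.557", "C04"))
  expect_equal(nrow(dag$edges), 4)
  top <- build_disease_dag("C04")
  expect_equal(top$codes, "C04")
  expect_equal(nrow(top$edges), 0)
  shared <- build_disease_dag(c("C04.100.200", "C04.100.300"))
  expect_equal(sum(shared$codes == "C04.100"), 1)
  expect_error(build_disease_dag(character()), "at least one tree code")
  expect_error(build_disease_dag("C04..100"), "malformed")
})

test_that("semantic profiles follow the decayed-contribution recursion", {
  chain <- semantic_profile(build_disease_dag("C04.557.465"))
  expect_equal(unname(chain$DD[c("C04.557.465", "C04.557", "C04")]),
               c(1, 0.5, 0.25))
  expect_equal(chain$DV, 1.75)
  expect_equal(unname(chain$DD["C04.557.465"]), 1) # the disease itself

  # diamond: two own codes under one grandparent
  diam <- semantic_profile(build_disease_dag(c("C04.100", "C04.200")))
  expect_equal(unname(diam$DD[c("C04.100", "C04.200", "C04")]),
               c(1, 1, 0.5))
  expect_equal(diam$DV, 2.5)
})

test_that("semantic profiles equal the brute-force truncation-chain oracle", {
  set.seed(7)
  codes_pool <- gen_tree_codes(60, depth_range = c(3, 6), branching = 4,
                               seed = 7)
  all_codes <- unique(unlist(codes_pool))
  for (i in 1:100) {
    own <- sample(all_codes, sample(1:3, 1))
    dag <- build_disease_dag(own)
    if (length(dag$codes) > 30) next
    got <- semantic_profile(dag)
    want <- brute_profile(dag)
    expect_equal(got$DD[sort(names(got$DD))], want$DD[sort(names(want$DD))],
                 tolerance = 1e-12)
    expect_equal(got$DV, want$DV, tolerance = 1e-12)
  }
})

test_that("disease similarity is symmetric, bounded and exact on hand cases", {
  a <- semantic_profile(build_disease_dag("G01.100.200"))
  b <- semantic_profile(build_disease_dag("G01.300.400"))
  expect_equal(disease_similarity(a, a), 1)
  expect_equal(disease_similarity(a, b), 0.5 / 3.5, tolerance = 1e-12)
  disjoint <- semantic_profile(build_disease_dag("H02.100"))
  expect_equal(disease_similarity(a, disjoint), 0)

  set.seed(8)
  pool <- gen_tree_codes(40, seed = 8)
  profs <- lapply(pool, function(cc) semantic_profile(build_disease_dag(cc)))
  for (i in 1:30) {
    p <- sample(profs, 2)
    s12 <- disease_similarity(p[[1]], p[[2]])
    expect_identical(s12, disease_similarity(p[[2]], p[[1]]))
    expect_gte(s12, 0); expect_lte(s12, 1)
  }
  M <- disease_similarity_matrix(profs)
  expect_equal(unname(diag(M)), rep(1, length(profs)))
  i <- sample(length(profs), 1); j <- sample(length(profs), 1)
  expect_equal(M[i, j], disease_similarity(profs[[i]], profs[[j]]),
               tolerance = 1e-12)
})

test_that("adding a shared ancestor never decreases similarity", {
  set.seed(9)
  pool <- gen_tree_codes(30, seed = 9)
  for (i in 1:20) {
    cc <- sample(pool, 2)
    base <- disease_similarity(
      semantic_profile(build_disease_dag(cc[[1]])),
      semantic_profile(build_disease_dag(cc[[2]])))
    shared <- sprintf("Z%02d", i) # fresh shared top-level ancestor
    grown <- disease_similarity(
      semantic_profile(build_disease_dag(c(cc[[1]], shared))),
      semantic_profile(build_disease_dag(c(cc[[2]], shared))))
    expect_gte(grown, base - 1e-12)
  }
})

test_that("fingerprints are deterministic bit vectors; bad SMILES error", {
  fp <- smiles_to_fingerprint("C")
  expect_length(fp, 1024)
  expect_true(all(fp %in% c(0L, 1L)))
  expect_gte(sum(fp), 1)
  expect_identical(smiles_to_fingerprint("CC(=O)Oc1ccccc1C(=O)O"),
                   smiles_to_fingerprint("CC(=O)Oc1ccccc1C(=O)O"))
  expect_error(smiles_to_fingerprint("notasmiles"), "cannot parse SMILES")
  m <- suppressWarnings(
    fingerprint_matrix(c(a = "CCO", b = "notasmiles")))
  expect_equal(attr(m, "n_failed"), 1)
  expect_equal(sum(m["b", ]), 0)
})

test_that("the autoencoder reconstructs and is seed-deterministic", {
  set.seed(10)
  x <- matrix(rbinom(100 * 128, 1, 0.2), 100, 128)
  sae <- train_sae(x, latent = 64, epochs = 40, seed = 3)
  expect_equal(dim(predict(sae, x)), c(100, 64))
  expect_lt(sae$loss[length(sae$loss)], sae$loss[1])
  # loss trajectory non-increasing up to mini-batch jitter
  expect_true(all(diff(sae$loss) <= 0.05 * sae$loss[1]))
  again <- train_sae(x, latent = 64, epochs = 40, seed = 3)
  expect_identical(sae$W1, again$W1)
  expect_identical(sae$loss, again$loss)

  # constant-row input: reconstruction approaches the row itself and the
  # latent codes of all rows coincide
  row <- runif(128)
  xc <- matrix(rep(row, each = 50), 50, 128)
  saec <- train_sae(xc, latent = 64, epochs = 150, seed = 4,
                    learning_rate = 5e-3)
  expect_lt(saec$loss[length(saec$loss)], 0.1 * saec$loss[1])
  lat <- predict(saec, xc)
  expect_lt(max(apply(lat, 2, sd)), 1e-8)

  expect_error(train_sae(matrix(c(1, NA, 2, 3), 2)), "non-finite")
  expect_error(train_sae(matrix(runif(20), 2, 10), latent = 64),
               "below latent")
})

test_that("encode_attributes yields 64-d vectors with zero fallback", {
  b <- small_bundle(seed = 5, n = 12, m = 15)
  # drop the sequence of one miRNA: that node must fall back to zeros
  drop_name <- b$network$nodes$name[b$network$nodes$kind == "miRNA"][1]
  seqs <- b$sequences[setdiff(names(b$sequences), drop_name)]
  at <- suppressWarnings(suppressMessages(encode_attributes(
    b$network, sequences = seqs, smiles = b$smiles,
    tree_codes = b$tree_codes, epochs = 10, seed = 5)))
  expect_equal(ncol(at$values), 64)
  expect_true(all(is.finite(at$values)))
  expect_equal(unname(at$missing["miRNA"]), 1L)
  expect_equal(unname(at$values[paste0("miRNA:", drop_name), ]), rep(0, 64))

  full <- small_attributes(b, seed = 5, epochs = 10)
  expect_equal(sum(full$missing), 0)
  expect_setequal(rownames(full$values),
                  manlink:::node_key(b$network$nodes$kind,
                                     b$network$nodes$name))
})
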