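# fingerprints, one-hot encodings, template selection, pipelines

test_that("fingerprints are invariant to the SMILES spelling", {
  a <- morgan_fingerprint(Ligand("OCC"), radius = 2, n_bits = 1024)
  b <- morgan_fingerprint(Ligand("CCO"), radius = 2, n_bits = 1024)
  expect_identical(a$values, b$values)
  expect_identical(a$dtype, "bit")
  expect_length(a$values, 1024L)
  expect_equal(tanimoto(a, b), 1.0)
})

test_that("fingerprint on-bits match the independent reference implementation", {
  smiles <- generate_ligand_set(12, seed = 31)
  oracle <- oracle_fingerprint_bits(smiles, radius = 2, n_bits = 1024)
  for (i in seq_along(smiles)) {
    fp <- morgan_fingerprint(smiles[i], radius = 2, n_bits = 1024)
    expect_identical(fp_on_bits(fp), oracle[[i]])
  }
  # and at other radii / widths
  oracle0 <- oracle_fingerprint_bits("c1ccccc1O", radius = 0, n_bits = 64)
  fp0 <- morgan_fingerprint("c1ccccc1O", radius = 0, n_bits = 64)
  expect_identical(fp_on_bits(fp0), oracle0[[1]])
  oracle3 <- oracle_fingerprint_bits("CC(=O)Oc1ccccc1C(=O)O",
                                     radius = 3, n_bits = 4096)
  fp3 <- morgan_fingerprint("CC(=O)Oc1ccccc1C(=O)O",
                            radius = 3, n_bits = 4096)
  expect_identical(fp_on_bits(fp3), oracle3[[1]])
})

test_that("fingerprints survive randomized-atom-order respelling", {
  for (s in generate_ligand_set(5, seed = 17)) {
    ref <- morgan_fingerprint(s, radius = 2, n_bits = 512)
    for (sp in oracle_respellings(s, 8, seed = 3)) {
      expect_identical(morgan_fingerprint(sp, radius = 2,
                                          n_bits = 512)$values,
                       ref$values)
    }
  }
})

test_that("fingerprint parameter validation rejects bad sizes", {
  expect_error(morgan_fingerprint("CCO", n_bits = 0), "n_bits")
  expect_error(morgan_fingerprint("CCO", radius = -1), "radius")
})

test_that("tanimoto similarity follows its set definition", {
  expect_equal(tanimoto(c(1, 1, 0, 0), c(1, 0, 1, 0)), 1 / 3)
  expect_equal(tanimoto(c(1, 0), c(0, 1)), 0.0)
  expect_equal(tanimoto(c(0, 0), c(0, 0)), 1.0)  # documented convention
  expect_equal(tanimoto(c(1, 1), c(1, 1)), 1.0)
  expect_error(tanimoto(c(1, 0), c(1, 0, 1)), "length")
})

test_that("one-hot SMILES encoding is exact and decodes back", {
  alpha <- default_smiles_alphabet()
  enc <- one_hot_smiles(Ligand("CCO"), max_length = 5)
  m <- enc$values
  expect_identical(dim(m), c(5L, length(alpha)))
  expect_identical(rowSums(m), c(1, 1, 1, 0, 0))
  expect_identical(decode_one_hot(enc, alpha), "CCO")

  for (s in generate_ligand_set(8, seed = 23)) {
    lig <- Ligand(s)
    enc <- one_hot_smiles(lig, max_length = 128)
    expect_identical(decode_one_hot(enc, alpha), lig$smiles)
  }
  expect_error(one_hot_smiles(Ligand("CCO"), max_length = 2), "max_length")
  expect_error(
    one_hot_smiles(Ligand("CCO"), alphabet = c("O"), max_length = 5),
    "outside the alphabet"
  )
})

test_that("one-hot sequence encoding matches the SMILES contract", {
  prot <- Protein(uniprot_id = "P1", sequence = "ACD")
  enc <- one_hot_sequence(prot, max_length = 4)
  expect_identical(dim(enc$values), c(4L, 21L))
  expect_identical(rowSums(enc$values), c(1, 1, 1, 0))
  expect_identical(decode_one_hot(enc, affinityforge:::AA_ALPHABET), "ACD")
  for (s in generate_protein_set(4, seed = 2, length_range = c(10, 30))) {
    enc <- one_hot_sequence(Protein(sequence = s), max_length = 40)
    expect_identical(decode_one_hot(enc, affinityforge:::AA_ALPHABET), s)
  }
  expect_error(one_hot_sequence(Protein(uniprot_id = "P1")), "sequence")
  # ambiguous residue: lenient maps to X, strict errors
  expect_error(one_hot_sequence("ACB", max_length = 4), "outside")
  lenient <- one_hot_sequence("ACB", max_length = 4, lenient = TRUE)
  expect_identical(decode_one_hot(lenient, affinityforge:::AA_ALPHABET),
                   "ACX")
})

test_that("template selection maximizes Tanimoto with deterministic ties", {
  query <- Ligand("CC(=O)Oc1ccccc1C(=O)O")  # aspirin
  cands <- generate_template_table(5, seed = 11,
                                   include_smiles = query$smiles)
  hit <- select_template(query, cands)
  expect_equal(hit$similarity, 1.0)
  expect_identical(
    hit$structure_id,
    cands$structure_id[cands$smiles == query$smiles]
  )

  # argmax agrees with an exhaustive scan
  cands2 <- generate_template_table(8, seed = 13)
  qfp <- morgan_fingerprint(query, 2, 2048)
  sims <- vapply(cands2$smiles, function(s) {
    tanimoto(qfp, morgan_fingerprint(s, 2, 2048))
  }, numeric(1), USE.NAMES = FALSE)
  best <- which(sims == max(sims))
  oracle_id <- min(cands2$structure_id[best])
  hit2 <- select_template(query, cands2)
  expect_identical(hit2$structure_id, oracle_id)
  expect_equal(hit2$similarity, max(sims))

  # tie: two identical co-ligands, lexicographically smaller id wins
  tied <- data.frame(structure_id = c("TPLB", "TPLA"),
                     smiles = c("CCO", "OCC"))
  expect_identical(select_template(Ligand("CCCO"), tied)$structure_id,
                   "TPLA")
  expect_error(select_template(query, tied[0, ]), "empty")
})

test_that("pipeline concatenation shape arithmetic holds", {
  pipe <- FeaturizationPipeline(list(
    list(name = "morgan", params = list(radius = 2, n_bits = 8)),
    list(name = "one_hot_smiles", params = list(max_length = 4))
  ))
  systems <- list(System(list(Ligand("CCO"))))
  out <- run_pipeline(pipe, systems)
  expect_length(out, 1L)
  feats <- out[[1]]$features
  expect_length(feats$concat$values,
                8 + 4 * length(default_smiles_alphabet()))
  expect_identical(feats$morgan$name, "morgan")
  # row-major flattening: first alphabet-width block is the first row
  alpha_n <- length(default_smiles_alphabet())
  concat_tail <- feats$concat$values[(8 + 1):(8 + alpha_n)]
  expect_identical(concat_tail, feats$one_hot_smiles$values[1, ])
})

test_that("retain_last_only keeps only the final stage tensor", {
  pipe <- FeaturizationPipeline(list(
    list(name = "morgan", params = list(radius = 2, n_bits = 8)),
    list(name = "one_hot_smiles", params = list(max_length = 4))
  ), retain_last_only = TRUE)
  out <- run_pipeline(pipe, list(System(list(Ligand("CCO")))))
  expect_identical(names(out[[1]]$features), "one_hot_smiles")
})

test_that("pipelines isolate per-system failures and keep going", {
  pipe <- FeaturizationPipeline(list(
    list(name = "morgan", params = list(radius = 1, n_bits = 16))
  ))
  systems <- list(
    System(list(Ligand("CCO"))),
    System(list(Protein(uniprot_id = "P1"))),  # no ligand: must fail
    System(list(Ligand("c1ccccc1")))
  )
  out <- run_pipeline(pipe, systems)
  expect_length(out, 2L)
  failures <- attr(out, "failures")
  expect_identical(failures$index, 2L)
  expect_match(failures$error, "Ligand")
  empty <- run_pipeline(pipe, list())
  expect_length(empty, 0L)
  expect_identical(nrow(attr(empty, "failures")), 0L)
})

test_that("pipeline output is permutation-equivariant", {
  pipe <- FeaturizationPipeline(list(
    list(name = "morgan", params = list(radius = 2, n_bits = 64))
  ))
  smiles <- generate_ligand_set(6, seed = 41)
  systems <- lapply(smiles, function(s) System(list(Ligand(s))))
  perm <- c(4, 1, 6, 2, 5, 3)
  out1 <- run_pipeline(pipe, systems)
  out2 <- run_pipeline(pipe, systems[perm])
  for (i in seq_along(perm)) {
    expect_identical(out2[[i]]$features$concat$values,
                     out1[[perm[i]]]$features$concat$values)
  }
})

test_that("concatenation is associative", {
  tensors <- list(
    morgan_fingerprint("CCO", 1, 8),
    morgan_fingerprint("c1ccccc1", 1, 16),
    one_hot_smiles(Ligand("CCO"), max_length = 3)
  )
  flat <- lapply(tensors, affinityforge:::flatten_tensor)
  left <- c(c(flat[[1]], flat[[2]]), flat[[3]])
  right <- c(flat[[1]], c(flat[[2]], flat[[3]]))
  expect_identical(left, right)
})

test_that("unknown featurizers and malformed steps are rejected upfront", {
  expect_error(FeaturizationPipeline(list(list(name = "docking"))),
               "unknown featurizer")
  expect_error(FeaturizationPipeline(list("morgan")), "name")
  expect_error(FeaturizationPipeline(list()), "length")
})

test_that("bit tensors validate their entries", {
  expect_error(FeatureTensor("x", c(0, 2), dtype = "bit"), "0 or 1")
  expect_error(FeatureTensor("x", c(1, NA)), "finite")
  expect_silent(FeatureTensor("x", matrix(0.5, 2, 2)))
})
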