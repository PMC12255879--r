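test_that("model_config validates its invariants", {
  cfg <- model_config(hidden_dim = 8L)
  expect_equal(cfg$key_dim * cfg$attention_heads, cfg$hidden_dim)
  expect_equal(cfg$protein_dilations, c(1L, 2L, 4L, 8L, 16L))
  expect_equal(cfg$ligand_dilations, c(1L, 2L, 4L, 8L))
  expect_error(model_config(hidden_dim = 9L), "divisible")
  expect_error(model_config(branches = list(bogus = TRUE)), "unknown")
  expect_error(model_config(branches = list(protein = FALSE,
                                            sequence_complex = FALSE,
                                            covalent = FALSE,
                                            noncovalent = FALSE)), "disabled")
})

test_that("protein encoder uses one conv layer per dilation and ignores padding", {
  cfg <- fix_cfg()
  params <- init_model_params(cfg, seed = 1)
  expect_length(params$protein$conv, 5L)

  rec <- fix_record()
  sf <- encode_protein_sequence(rec$protein_seq)
  v1 <- dilated_conv_encode(sf, params, cfg)
  expect_length(v1, cfg$hidden_dim)

  # same valid rows, different padding: identical output
  sf2 <- sf
  sf2$values <- sf$values[1:40, , drop = FALSE]
  sf2$mask <- sf$mask[1:40]
  expect_equal(dilated_conv_encode(sf2, params, cfg), v1)

  # masked convolution does not leak garbage from padded rows
  tp <- ad_tape()
  set.seed(2)
  X <- matrix(rnorm(10 * 8), 10, 8)
  mask <- c(rep(TRUE, 6), rep(FALSE, 4))
  cv <- init_conv1d(8L, 4L)
  bc <- bind_params(tp, list(cv = cv))
  Xg <- X
  Xg[7:10, ] <- 99 # garbage behind the mask
  Xg[7:10, ] <- Xg[7:10, ] * 0 # contract: callers zero masked rows first
  h1 <- ad_value(tp, nn_conv1d_dilated(tp, ad_const(tp, Xg), mask, bc$cv, 2L))
  h2 <- ad_value(tp, nn_conv1d_dilated(tp, ad_const(tp, X[1:6, , drop = FALSE]),
                                       rep(TRUE, 6), bc$cv, 2L))
  expect_equal(h1[1:6, ], h2)

  expect_error(dilated_conv_encode(list(values = matrix(0, 4, 40),
                                        mask = rep(FALSE, 4)), params, cfg),
               "all-masked")
})

test_that("cross-attention follows the scaled dot-product contract", {
  cfg <- fix_cfg()
  params <- init_model_params(cfg, seed = 2)

  # single valid position on both sides: weight exactly 1
  res <- data.frame(aa = "A", x = 0, y = 0, z = 0, sse = "-")
  one_atom <- ligand_molecule(data.frame(element = "C", charge = 0L,
                                         x = 0, y = 0, z = 0), NULL)
  ca <- cross_attention(encode_pocket_sequence("A"),
                        encode_ligand_smiles(one_atom), params, cfg)
  expect_equal(as.numeric(ca$attn_poc), 1.0)
  expect_equal(as.numeric(ca$attn_lig), 1.0)

  # uniform keys: softmax of equal logits = uniform weights = value mean
  ethane <- ligand_molecule(
    data.frame(element = c("C", "C"), charge = 0L, x = c(0, 1.5), y = 0, z = 0),
    data.frame(i = 1, j = 2, order = 1L))
  ca2 <- cross_attention(encode_pocket_sequence("ADK"),
                         encode_ligand_smiles(ethane), params, cfg)
  expect_equal(unname(ca2$attn_poc), matrix(0.5, 3, 2), tolerance = 1e-12)

  # attention rows sum to 1 over unmasked keys
  rec <- fix_record()
  ca3 <- cross_attention(encode_pocket_sequence(rec$pocket_seq),
                         encode_ligand_smiles(rec$ligand), params, cfg)
  expect_equal(rowSums(ca3$attn_poc), rep(1, nrow(ca3$attn_poc)))
  expect_equal(rowSums(ca3$attn_lig), rep(1, nrow(ca3$attn_lig)))
})

test_that("EGNN branch is E(3)- and permutation-invariant", {
  cfg <- fix_cfg()
  params <- init_model_params(cfg, seed = 3)
  rec <- generate_complex(synth_config(n_complexes = 1, seed = 8), 1)
  g <- build_pocket_graph(rec)
  p1 <- egnn_encode(g, params, cfg)
  expect_true(all(is.finite(p1)))

  set.seed(1)
  for (k in 1:3) {
    g2 <- build_pocket_graph(rigid_motion(rec))
    expect_lt(max(abs(egnn_encode(g2, params, cfg) - p1)), 1e-5)
  }

  # permute node order
  n <- nrow(g$node_features)
  perm <- sample(n)
  g3 <- g
  g3$node_features <- g$node_features[perm, , drop = FALSE]
  g3$coords <- g$coords[perm, , drop = FALSE]
  g3$edges <- cbind(match(g$edges[, 1], perm), match(g$edges[, 2], perm))
  expect_lt(max(abs(egnn_encode(g3, params, cfg) - p1)), 1e-9)

  # degree-0 single-node graph still encodes
  res1 <- data.frame(aa = "G", x = 0, y = 0, z = 0, sse = "-")
  rec1 <- complex_record("s", "G", res1, fix_ethanol())
  expect_true(all(is.finite(egnn_encode(build_pocket_graph(rec1), params, cfg))))
})

test_that("attentive fingerprint branch: permutation invariance, degenerate cases", {
  cfg <- fix_cfg()
  params <- init_model_params(cfg, seed = 4)
  mol <- bindgraph:::random_ligand(10L)
  g <- build_ligand_graph(mol)
  l1 <- attentivefp_encode(g, params, cfg)
  expect_true(all(is.finite(l1)))

  # relabel atoms: reversed order
  n <- nrow(mol$atoms)
  perm <- rev(seq_len(n))
  at <- mol$atoms[perm, c("element", "charge", "x", "y", "z")]
  bd <- data.frame(i = match(mol$bonds$i, perm), j = match(mol$bonds$j, perm),
                   order = mol$bonds$order)
  g2 <- build_ligand_graph(ligand_molecule(at, bd))
  expect_lt(max(abs(attentivefp_encode(g2, params, cfg) - l1)), 1e-9)

  # single atom: no edges, readout still defined
  g3 <- build_ligand_graph(ligand_molecule(
    data.frame(element = "C", charge = 0L, x = 0, y = 0, z = 0), NULL))
  expect_true(all(is.finite(attentivefp_encode(g3, params, cfg))))
})

test_that("environment-HGT: step semantics, ablation and degenerate cases", {
  cfg <- fix_cfg()
  cfg_noenv <- model_config(hidden_dim = cfg$hidden_dim,
                            branches = list(environment_nodes = FALSE))
  params <- init_model_params(cfg, seed = 5)
  rec <- generate_complex(synth_config(n_complexes = 1, seed = 9), 1)
  g <- build_complex_graph(rec)

  c_env <- env_hgt_encode(g, params, cfg)
  c_noenv <- env_hgt_encode(g, params, cfg_noenv)
  expect_true(all(is.finite(c_env)))
  # removing the environment nodes changes the embedding (module removal)
  expect_gt(max(abs(c_env - c_noenv)), 1e-8)

  # permuting ligand atoms leaves the embedding unchanged
  mol <- rec$ligand
  n <- nrow(mol$atoms)
  perm <- rev(seq_len(n))
  at <- mol$atoms[perm, c("element", "charge", "x", "y", "z")]
  bd <- data.frame(i = match(mol$bonds$i, perm), j = match(mol$bonds$j, perm),
                   order = mol$bonds$order)
  rec2 <- rec
  rec2$ligand <- ligand_molecule(at, bd)
  g2 <- build_complex_graph(rec2)
  expect_lt(max(abs(env_hgt_encode(g2, params, cfg) - c_env)), 1e-9)

  # no contacts: edge pooling falls back to type-wise node means
  res <- data.frame(aa = "G", x = 0, y = 0, z = 0, sse = "-")
  lig <- ligand_molecule(data.frame(element = "C", charge = 0L, x = 50, y = 0, z = 0), NULL)
  gfar <- build_complex_graph(complex_record("far", "G", res, lig))
  expect_true(all(is.finite(env_hgt_encode(gfar, params, cfg))))
})

test_that("predict_affinity is deterministic, finite, and branch-isolated", {
  cfg <- fix_cfg()
  params <- init_model_params(cfg, seed = 6)
  rec <- generate_complex(synth_config(n_complexes = 1, seed = 10), 1)
  p1 <- predict_affinity(rec, cfg, params)
  expect_true(is.finite(p1))
  expect_identical(predict_affinity(rec, cfg, params), p1)

  # branch isolation: with identical branch parameters, disabling the
  # sequence-complex module leaves the other branch embeddings bit-identical
  cfg_ab <- model_config(hidden_dim = cfg$hidden_dim,
                         branches = list(sequence_complex = FALSE))
  pg <- build_pocket_graph(rec)
  lgr <- build_ligand_graph(rec$ligand)
  cg <- build_complex_graph(rec)
  expect_identical(egnn_encode(pg, params, cfg_ab), egnn_encode(pg, params, cfg))
  expect_identical(attentivefp_encode(lgr, params, cfg_ab),
                   attentivefp_encode(lgr, params, cfg))
  expect_identical(env_hgt_encode(cg, params, cfg_ab),
                   env_hgt_encode(cg, params, cfg))
})

test_that("every enabled branch receives gradient on a 2-sample batch", {
  cfg <- fix_cfg()
  params <- init_model_params(cfg, seed = 7)
  scfg <- synth_config(n_complexes = 2, seed = 12)
  recs <- generate_dataset(scfg)
  tp <- ad_tape()
  bp <- bind_params(tp, params)
  ls <- lapply(recs, function(r) {
    bindgraph:::sample_loss_node(tp, bp, prepare_complex_inputs(r, cfg), cfg,
                                 r$affinity_label)
  })
  loss <- ad_scale(tp, ad_sum(tp, ad_cbind(tp, ls)), 0.5)
  ad_backward(tp, loss)
  g <- collect_grads(tp, bp)
  for (br in names(g)) {
    tot <- sum(unlist(rapply(g[[br]], function(m) sum(abs(m)),
                             classes = c("matrix", "array"), how = "unlist")))
    expect_gt(tot, 0)
  }
})
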