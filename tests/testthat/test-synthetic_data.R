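test_that("generation is deterministic per (seed, index) with distinct ids", {
  cfg <- synth_config(n_complexes = 8, seed = 3)
  r1 <- generate_complex(cfg, 4)
  r2 <- generate_complex(cfg, 4)
  expect_identical(r1$protein_seq, r2$protein_seq)
  expect_identical(r1$ligand$smiles, r2$ligand$smiles)
  expect_identical(r1$affinity_label, r2$affinity_label)
  expect_identical(r1$pocket_residues, r2$pocket_residues)

  recs <- generate_dataset(cfg)
  ids <- vapply(recs, `[[`, character(1), "complex_id")
  expect_length(unique(ids), 8L)
})

test_that("generated records satisfy the domain invariants by construction", {
  recs <- generate_dataset(synth_config(n_complexes = 12, seed = 6))
  caps <- c(C = 4, N = 3, O = 2, S = 2)
  for (r in recs) {
    expect_true(all(is.finite(as.matrix(r$pocket_residues[, c("x", "y", "z")]))))
    expect_true(all(is.finite(as.matrix(r$ligand$atoms[, c("x", "y", "z")]))))
    expect_lte(nrow(r$pocket_residues), 64L)
    expect_lte(nrow(r$ligand$atoms), 150L)
    expect_equal(nchar(r$pocket_seq), nrow(r$pocket_residues))
    # valence correctness: bonded orders never exceed the element cap
    b <- r$ligand$bonds
    for (v in seq_len(nrow(r$ligand$atoms))) {
      bsum <- sum(b$order[b$i == v | b$j == v])
      expect_lte(bsum, caps[[r$ligand$atoms$element[v]]])
    }
    # connectivity (throws inside ligand_molecule otherwise)
    expect_s3_class(r$ligand, "LigandMolecule")
  }
})

test_that("planted law: geometry and determinism", {
  rec <- generate_complex(synth_config(n_complexes = 1, seed = 14), 1)
  # ligand moved 50 A away: contact term falls to zero
  far <- rec
  far$ligand$atoms$x <- far$ligand$atoms$x + 50
  expect_equal(unname(planted_signal_components(far)["contacts"]), 0)
  # zero-noise planted affinity is a pure function of the record
  expect_identical(planted_affinity(rec), planted_affinity(rec))
  s <- planted_signal_components(rec)
  expect_equal(planted_affinity(rec),
               3.5 + 0.02 * s[["contacts"]] + 0.5 * s[["hbd_polar"]] -
                 0.1 * s[["rotatable"]])
})

test_that("least-squares recovery of the planted coefficients within 10%", {
  # n = 500, noise sd 0.2: regressing labels on the true components must
  # recover the generating coefficients
  cfg <- synth_config(n_complexes = 500, noise_sd = 0.2, seed = 33)
  recs <- generate_dataset(cfg)
  labs <- vapply(recs, `[[`, numeric(1), "affinity_label")
  comps <- t(vapply(recs, planted_signal_components, numeric(3)))
  fit <- stats::lm(labs ~ comps)
  est <- unname(coef(fit))
  truth <- c(3.5, 0.02, 0.5, -0.1)
  expect_true(all(abs(est - truth) / abs(truth) < 0.10))
  # affinity variance is non-degenerate under defaults
  expect_gt(stats::sd(labs), 0.5)
})

test_that("on-disk layout round-trips through the real readers", {
  recs <- generate_dataset(synth_config(n_complexes = 4, seed = 9))
  dir <- withr::local_tempdir()
  ipath <- write_synthetic_dataset(recs, dir)
  idx <- read_pdbbind_index(ipath)
  expect_equal(idx$complex_id, vapply(recs, `[[`, character(1), "complex_id"))
  expect_lt(max(abs(idx$affinity -
                      vapply(recs, `[[`, numeric(1), "affinity_label"))), 1e-3)

  back <- read_synthetic_dataset(dir)
  expect_length(back, 4L)
  for (i in seq_along(back)) {
    expect_equal(back[[i]]$pocket_seq, recs[[i]]$pocket_seq)
    expect_equal(nrow(back[[i]]$ligand$atoms), nrow(recs[[i]]$ligand$atoms))
    expect_equal(nrow(back[[i]]$ligand$bonds), nrow(recs[[i]]$ligand$bonds))
    expect_lt(max(abs(as.matrix(back[[i]]$pocket_residues[, c("x", "y", "z")]) -
                        as.matrix(recs[[i]]$pocket_residues[, c("x", "y", "z")]))),
              1e-3)
  }
})
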