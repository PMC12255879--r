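test_that("protein indicators: composition closed forms and charge ordering", {
  g4 <- protein_indicators("GGGG")
  # glycine has no ionizable side chain: termini only, ~0 at pH 7
  expect_lt(abs(g4$net_charge_pH7), 0.2)
  expect_equal(g4$hydropathy_index, -0.4) # Kyte-Doolittle G
  expect_equal(g4$hbd_count, 0)

  expect_gt(protein_indicators("K")$net_charge_pH7,
            protein_indicators("D")$net_charge_pH7)
  expect_error(protein_indicators(""), "empty")
})

test_that("pI bisection agrees with an independent root bracket", {
  # oracle: scan the net-charge curve on a fine grid and bracket the zero
  pi_oracle <- function(seq) {
    ph <- seq(0, 14, by = 1e-3)
    q <- vapply(ph, function(p) bindgraph:::protein_net_charge(seq, p), numeric(1))
    ph[which.min(abs(q))]
  }
  for (s in c("DDDD", "KKKK", "ACDKLM")) {
    expect_lt(abs(protein_indicators(s)$isoelectric_point - pi_oracle(s)), 0.01)
  }
  expect_lt(protein_indicators("DDDD")$isoelectric_point, 7)
  expect_gt(protein_indicators("KKKK")$isoelectric_point, 7)
})

test_that("ligand indicators on known molecules", {
  b <- ligand_indicators(fix_benzene())
  expect_equal(b$aromatic_ring_count, 1L)
  expect_equal(b$rotatable_bond_count, 0L)
  expect_equal(b$hbd_count, 0L)
  expect_equal(b$tpsa, 0)

  e <- ligand_indicators(fix_ethanol())
  expect_equal(e$hbd_count, 1L)
  expect_equal(e$hba_count, 1L)
  expect_equal(e$rotatable_bond_count, 0L)
  expect_equal(e$tpsa, 20.23) # Ertl hydroxyl fragment

  expect_equal(ligand_indicators(fix_butane())$rotatable_bond_count, 1L)
  # amide C-N exclusion
  expect_equal(ligand_indicators(fix_acetamide())$rotatable_bond_count, 0L)
})

test_that("rotatable bonds match a brute-force enumeration of the rule", {
  rot_oracle <- function(mol) {
    b <- mol$bonds
    deg <- bindgraph:::heavy_degree(mol)
    n <- 0L
    for (e in seq_len(nrow(b))) {
      i <- b$i[e]; j <- b$j[e]
      if (b$order[e] != 1L || b$aromatic[e] || b$in_ring[e]) next
      if (deg[i] < 2L || deg[j] < 2L) next
      amide <- function(ci, ni) {
        mol$atoms$element[ci] == "C" && mol$atoms$element[ni] == "N" &&
          any(mol$atoms$element[c(b$j[b$i == ci & b$order == 2L],
                                  b$i[b$j == ci & b$order == 2L])] == "O")
      }
      if (amide(i, j) || amide(j, i)) next
      n <- n + 1L
    }
    n
  }
  set.seed(7)
  for (k in 1:20) {
    mol <- bindgraph:::random_ligand(sample(4:16, 1))
    expect_equal(ligand_indicators(mol)$rotatable_bond_count, rot_oracle(mol))
  }
})

test_that("indicators are invariant to atom reordering and rigid motion", {
  set.seed(11)
  mol <- bindgraph:::random_ligand(12L)
  ind <- ligand_indicators(mol)
  # rigid motion: descriptors are topological
  m2 <- mol
  m2$atoms$x <- mol$atoms$x + 20
  m2$atoms$z <- -mol$atoms$z
  expect_equal(ligand_indicators(m2), ind)
  # reorder atoms (reverse) with remapped bonds
  n <- nrow(mol$atoms)
  perm <- rev(seq_len(n))
  at <- mol$atoms[perm, c("element", "charge", "x", "y", "z")]
  bd <- data.frame(i = match(mol$bonds$i, perm), j = match(mol$bonds$j, perm),
                   order = mol$bonds$order)
  m3 <- ligand_molecule(at, bd)
  ind3 <- ligand_indicators(m3)
  expect_equal(ind3[names(ind3) != "logp"], ind[names(ind) != "logp"])
  expect_lt(abs(ind3$logp - ind$logp), 1e-9)
})

test_that("environment-node matrix is a pure 3x5 packing with 11 slots", {
  rec <- fix_record()
  ind <- biochemical_indicators(rec)
  env <- assemble_env_nodes(ind)
  expect_s3_class(env, "EnvNodeMatrix")
  expect_equal(dim(env), c(3L, 5L))
  # scaled indicators land in [0, 1]
  expect_true(all(env >= 0 & env <= 1))
  # the shared-environment row has exactly its 2 populated slots
  expect_equal(unclass(env)[3, 3:5], c(0, 0, 0))

  # pure packing: same indicators give an identical matrix; zeros give zeros
  expect_identical(unclass(assemble_env_nodes(ind)), unclass(env))
  zero <- list(protein = list(isoelectric_point = 0, hydropathy_index = 0,
                              net_charge_pH7 = 0, hbd_count = 0, hba_count = 0),
               ligand = list(aromatic_ring_count = 0, rotatable_bond_count = 0,
                             tpsa = 0, logp = 0, formal_charge = 0,
                             hbd_count = 0, hba_count = 0))
  expect_true(all(unclass(assemble_env_nodes(zero)) == 0))

  # populated-slot count is 11 for a generic complex
  generic <- list(protein = lapply(zero$protein, function(x) 0.37),
                  ligand = lapply(zero$ligand, function(x) 0.37))
  expect_equal(sum(unclass(assemble_env_nodes(generic)) != 0), 11L)
})
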