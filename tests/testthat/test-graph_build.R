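two_residue_record <- function(sep) {
  res <- data.frame(aa = c("G", "A"), x = c(0, sep), y = 0, z = 0, sse = "-")
  complex_record("two", "GA", res, fix_ethanol())
}

test_that("pocket graph applies the 5 A cutoff inclusively", {
  expect_equal(nrow(build_pocket_graph(two_residue_record(4.9))$edges), 1L)
  expect_equal(nrow(build_pocket_graph(two_residue_record(5.0))$edges), 1L)
  expect_equal(nrow(build_pocket_graph(two_residue_record(5.1))$edges), 0L)

  # 3 collinear residues at 0 / 4 / 8: edges (1,2) and (2,3) only
  res <- data.frame(aa = c("G", "A", "K"), x = c(0, 4, 8), y = 0, z = 0, sse = "-")
  rec <- complex_record("lin", "GAK", res, fix_ethanol())
  pg <- build_pocket_graph(rec)
  expect_equal(pg$edges[order(pg$edges[, 1]), , drop = FALSE],
               matrix(c(1L, 2L, 2L, 3L), 2, 2, dimnames = list(NULL, c("i", "j"))))
  expect_equal(dim(pg$node_features), c(3L, 21L))
})

test_that("pocket/complex edge sets match an all-pairs brute-force oracle", {
  set.seed(5)
  for (k in 1:10) {
    n <- sample(5:50, 1)
    res <- data.frame(aa = sample(c("G", "A", "K", "D"), n, TRUE),
                      x = runif(n, 0, 15), y = runif(n, 0, 15),
                      z = runif(n, 0, 15), sse = "-")
    rec <- complex_record("r", paste(res$aa, collapse = ""), res, fix_ethanol())
    pg <- build_pocket_graph(rec)
    coords <- as.matrix(res[, c("x", "y", "z")])
    want <- 0L
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      if (sqrt(sum((coords[i, ] - coords[j, ])^2)) <= 5.0) want <- want + 1L
    }
    expect_equal(nrow(pg$edges), want)
    # oracle for the complex graph contact relation
    cg <- build_complex_graph(rec)
    pc <- as.matrix(rec$pocket_atoms[, c("x", "y", "z")])
    lc <- as.matrix(rec$ligand$atoms[, c("x", "y", "z")])
    wantc <- 0L
    for (i in seq_len(nrow(pc))) for (j in seq_len(nrow(lc))) {
      if (sqrt(sum((pc[i, ] - lc[j, ])^2)) <= 5.0) wantc <- wantc + 1L
    }
    expect_equal(nrow(cg$pl_edges), wantc)
  }
})

test_that("graph construction is isometry invariant", {
  set.seed(9)
  rec <- generate_complex(synth_config(n_complexes = 1, seed = 3), 1)
  pg <- build_pocket_graph(rec)
  cg <- build_complex_graph(rec)
  for (k in 1:3) {
    r2 <- rigid_motion(rec)
    pg2 <- build_pocket_graph(r2)
    cg2 <- build_complex_graph(r2)
    expect_equal(pg2$edges, pg$edges)
    expect_equal(cg2$pl_edges[, c("p", "l")], cg$pl_edges[, c("p", "l")])
    expect_lt(max(abs(cg2$pl_edges$dist - cg$pl_edges$dist)), 1e-6)
  }
})

test_that("ligand graph edge features are 12-dim with documented content", {
  lg <- build_ligand_graph(fix_benzene())
  expect_equal(ncol(lg$edge_features), 12L)
  expect_equal(nrow(lg$edge_features), 12L) # 6 bonds, directed both ways
  expect_true(all(lg$edge_features[, 4] == 1)) # aromatic one-hot slot
  expect_true(all(lg$edge_features[, 5] == 1)) # in-ring flag
  # ideal hexagon: incident angles are 2*pi/3, bond length 1.39
  expect_lt(max(abs(lg$edge_features[, 8] - 2 * pi / 3)), 1e-6)
  expect_lt(max(abs(lg$edge_features[, 7] - 1.39)), 1e-6)

  eth <- build_ligand_graph(ligand_molecule(
    data.frame(element = c("C", "C"), charge = 0L, x = c(0, 1.54), y = 0, z = 0),
    data.frame(i = 1, j = 2, order = 1L)))
  expect_equal(eth$edge_features[1, 1], 1) # single-bond slot
  expect_equal(eth$edge_features[1, 5], 0) # not in ring
  expect_equal(eth$edge_features[1, 8], 0) # terminal atom: no incident angle
})

test_that("complex graph: env wiring, zero distances and connectivity", {
  # hand-counted: 1 protein atom + 1 ligand atom 3 A apart
  res <- data.frame(aa = "G", x = 0, y = 0, z = 0, sse = "-")
  lig <- ligand_molecule(data.frame(element = "C", charge = 0L, x = 3, y = 0, z = 0), NULL)
  rec <- complex_record("one", "G", res, lig)
  cg <- build_complex_graph(rec)
  expect_equal(nrow(cg$pl_edges), 1L)
  expect_equal(cg$pl_edges$dist, 3.0)
  cnt <- complex_edge_counts(cg)
  expect_equal(cnt$env_pairs, 3L * 2L)
  expect_equal(cnt$directed_total, 2L * (1L + 6L))

  # same pair 12 A apart: no contacts, graph still valid and connected via env
  lig2 <- ligand_molecule(data.frame(element = "C", charge = 0L, x = 12, y = 0, z = 0), NULL)
  rec2 <- complex_record("far", "G", res, lig2)
  cg2 <- build_complex_graph(rec2)
  expect_equal(nrow(cg2$pl_edges), 0L)
  expect_equal(complex_edge_counts(cg2)$env_pairs, 6L)

  # environment nodes are virtual: their edges all carry distance 0 (implicit
  # complete bipartite relations; materialized distances are identically 0)
  expect_equal(nrow(cg$env_nodes), 3L)
  expect_s3_class(cg$env_nodes, "EnvNodeMatrix")
})

test_that("graph archives serialize with documented keys", {
  rec <- fix_record()
  tf <- withr::local_tempfile(fileext = ".json")
  write_graph_archive(build_complex_graph(rec), tf)
  back <- jsonlite::read_json(tf, simplifyVector = TRUE)
  expect_setequal(names(back),
                  c("protein_nodes", "ligand_nodes", "env_nodes", "pl_edges",
                    "protein_coords", "ligand_coords", ".class"))
  expect_equal(back$.class, "ComplexGraph")
  expect_equal(dim(back$env_nodes), c(3L, 5L))
})
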