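# Graph construction: the residue-level pocket graph (5 A contact edges),
# the ligand covalent graph with 12-dim bond features, and the heterogeneous
# complex graph over {protein, ligand, environment} node types.

#' Build the pocket residue graph
#'
#' Nodes are pocket residues (21-dim amino-acid one-hot features, C-alpha
#' coordinates); an undirected edge joins every residue pair at Euclidean
#' distance `<= cutoff` Angstrom. Isolated residues are kept as degree-0
#' nodes.
#'
#' @param record a `ComplexRecord`.
#' @param cutoff contact distance in Angstrom (default 5.0, inclusive).
#' @return object of class `PocketGraph`: list with `node_features` (n x 21),
#'   `edges` (e x 2 matrix, i < j), `coords` (n x 3).
#' @export
build_pocket_graph <- function(record, cutoff = 5.0) {
  stopifnot(inherits(record, "ComplexRecord"))
  res <- record$pocket_residues
  n <- nrow(res)
  if (n == 0L) stop("pocket has zero residues")
  feats <- matrix(0, n, 21L)
  aa_idx <- match(res$aa, AA_ORDER)
  aa_idx[is.na(aa_idx)] <- 21L
  feats[cbind(seq_len(n), aa_idx)] <- 1
  coords <- as.matrix(res[, c("x", "y", "z")])
  dimnames(coords) <- NULL
  d <- as.matrix(stats::dist(coords))
  adj <- d <= cutoff
  adj[lower.tri(adj, diag = TRUE)] <- FALSE
  idx <- which(adj, arr.ind = TRUE)
  edges <- matrix(as.integer(idx), ncol = 2L)
  colnames(edges) <- c("i", "j")
  structure(list(node_features = feats, edges = edges, coords = coords),
            class = "PocketGraph")
}

# mean angle (radians) at atom v between bond (v,w) and the other bonds at v
mean_incident_angle <- function(coords, v, w, nbrs) {
  others <- setdiff(nbrs, w)
  if (length(others) == 0L) return(0)
  u1 <- coords[w, ] - coords[v, ]
  n1 <- sqrt(sum(u1^2))
  if (n1 < 1e-9) return(0)
  angs <- vapply(others, function(o) {
    u2 <- coords[o, ] - coords[v, ]
    n2 <- sqrt(sum(u2^2))
    if (n2 < 1e-9) return(0)
    acos(max(-1, min(1, sum(u1 * u2) / (n1 * n2))))
  }, numeric(1))
  mean(angs)
}

#' Build the ligand covalent graph
#'
#' Nodes are heavy atoms (18-dim atom features); edges mirror the bond list,
#' stored directed (both orientations) with a 12-dim feature row each:
#' `[bond-order one-hot single/double/triple/aromatic (4) | in-ring |
#' conjugated | bond length A | mean incident bond angle at source and at
#' target (radians, 0 for terminal atoms) | length z-score within molecule |
#' reserved zeros (2)]`.
#'
#' @param mol a `LigandMolecule`.
#' @return object of class `LigandGraph`: list with `node_features` (m x 18),
#'   `edges` (2e x 2 directed pairs), `edge_features` (2e x 12),
#'   `coords` (m x 3).
#' @export
build_ligand_graph <- function(mol) {
  stopifnot(inherits(mol, "LigandMolecule"))
  at <- mol$atoms
  b <- mol$bonds
  m <- nrow(at)
  coords <- as.matrix(at[, c("x", "y", "z")])
  dimnames(coords) <- NULL
  feats <- atom_feature_rows(mol)
  nb <- nrow(b)
  nbrs <- lapply(seq_len(m), function(v) c(b$j[b$i == v], b$i[b$j == v]))
  if (nb == 0L) {
    return(structure(list(node_features = feats,
                          edges = matrix(integer(0), 0L, 2L),
                          edge_features = matrix(0, 0L, 12L),
                          coords = coords), class = "LigandGraph"))
  }
  lens <- sqrt(rowSums((coords[b$i, , drop = FALSE] - coords[b$j, , drop = FALSE])^2))
  lz <- if (nb > 1L && stats::sd(lens) > 1e-9) (lens - mean(lens)) / stats::sd(lens) else rep(0, nb)
  sp2ish <- at$hyb <= 2L | at$aromatic
  efeat_one <- function(e, src, dst) {
    v <- numeric(12L)
    slot <- if (b$aromatic[e]) 4L else min(b$order[e], 3L)
    v[slot] <- 1
    v[5L] <- as.numeric(b$in_ring[e])
    v[6L] <- as.numeric(b$aromatic[e] || b$order[e] > 1L ||
                          (sp2ish[src] && sp2ish[dst]))
    v[7L] <- lens[e]
    v[8L] <- mean_incident_angle(coords, src, dst, nbrs[[src]])
    v[9L] <- mean_incident_angle(coords, dst, src, nbrs[[dst]])
    v[10L] <- lz[e]
    v
  }
  edges <- rbind(cbind(b$i, b$j), cbind(b$j, b$i))
  ef <- matrix(0, 2L * nb, 12L)
  for (e in seq_len(nb)) {
    ef[e, ] <- efeat_one(e, b$i[e], b$j[e])
    ef[nb + e, ] <- efeat_one(e, b$j[e], b$i[e])
  }
  structure(list(node_features = feats, edges = edges, edge_features = ef,
                 coords = coords), class = "LigandGraph")
}

# Coarse 18-dim featurization of pocket heavy atoms (no covalent perception
# is attempted for the protein side: element identity plus residue-level
# aromatic/polarity context; same layout as atom_feature_rows).
protein_atom_features <- function(pocket_atoms, pocket_residues) {
  n <- nrow(pocket_atoms)
  out <- matrix(0, n, 18L)
  arom_res <- pocket_residues$aa %in% c("F", "W", "Y", "H")
  polar_res <- pocket_residues$aa %in% c("R", "N", "D", "C", "Q", "E", "H",
                                         "K", "S", "T", "Y")
  for (v in seq_len(n)) {
    el <- pocket_atoms$element[v]
    slot <- switch(el, B = 1L, C = 2L, N = 3L, O = 4L, P = 5L, S = 6L,
                   Se = 7L, if (el %in% HALOGENS) 8L else 9L)
    out[v, slot] <- 1
    ri <- pocket_atoms$res_index[v]
    out[v, 10L] <- 1           # sp3 default
    out[v, 11L] <- 0.5         # typical heavy-neighbor count, unknown bonds
    out[v, 13L] <- as.numeric(arom_res[ri])
    out[v, 14L] <- as.numeric(el == "C" && !polar_res[ri])
    out[v, 15L] <- as.numeric(arom_res[ri])
    out[v, 16L] <- as.numeric(el %in% c("N", "O"))
    out[v, 17L] <- as.numeric(el %in% c("N", "O") && polar_res[ri])
    out[v, 18L] <- as.numeric(arom_res[ri])
  }
  out
}

#' Build the heterogeneous complex graph
#'
#' Three node types: pocket heavy atoms (18-dim), ligand heavy atoms
#' (18-dim) and the three virtual environment nodes (3 x 5 indicator
#' matrix). Three bidirectional edge relations: protein-ligand contacts
#' (atom pairs within `contact_cutoff`, 1-dim Euclidean-distance feature),
#' environment-protein and environment-ligand (every environment node to
#' every atom, distance exactly 0). With at least one protein and one ligand
#' node the graph is always connected through the environment nodes.
#'
#' @param record a `ComplexRecord`.
#' @param env an `EnvNodeMatrix` (defaults to the record's own scaled
#'   indicators).
#' @param contact_cutoff protein-ligand contact distance, Angstrom
#'   (default 5.0, inclusive).
#' @return object of class `ComplexGraph`: list with `protein_nodes`,
#'   `ligand_nodes`, `env_nodes`, `pl_edges` (data.frame `p`, `l`, `dist`),
#'   `protein_coords`, `ligand_coords`.
#' @export
build_complex_graph <- function(record, env = NULL, contact_cutoff = 5.0) {
  stopifnot(inherits(record, "ComplexRecord"))
  pa <- record$pocket_atoms
  la <- record$ligand$atoms
  if (nrow(pa) == 0L || nrow(la) == 0L) stop("complex graph needs protein and ligand atoms")
  if (is.null(env)) env <- assemble_env_nodes(biochemical_indicators(record))
  stopifnot(inherits(env, "EnvNodeMatrix"))
  pc <- as.matrix(pa[, c("x", "y", "z")])
  lc <- as.matrix(la[, c("x", "y", "z")])
  dimnames(pc) <- NULL
  dimnames(lc) <- NULL
  # all-pairs protein-ligand distances
  d2 <- outer(rowSums(pc^2), rowSums(lc^2), "+") - 2 * pc %*% t(lc)
  d <- sqrt(pmax(d2, 0))
  hit <- which(d <= contact_cutoff, arr.ind = TRUE)
  pl <- data.frame(p = as.integer(hit[, 1L]), l = as.integer(hit[, 2L]),
                   dist = d[hit])
  pl <- pl[order(pl$p, pl$l), , drop = FALSE]
  rownames(pl) <- NULL
  structure(list(
    protein_nodes = protein_atom_features(pa, record$pocket_residues),
    ligand_nodes = atom_feature_rows(record$ligand),
    env_nodes = env,
    pl_edges = pl,
    protein_coords = pc,
    ligand_coords = lc
  ), class = "ComplexGraph")
}

#' Edge counts of a complex graph, including the implicit environment edges
#'
#' Environment-protein and environment-ligand relations are complete
#' bipartite by construction (distance 0) and stored implicitly; this helper
#' materialises the counts.
#'
#' @param g a `ComplexGraph`.
#' @return list with `pl_pairs` (undirected protein-ligand contact pairs),
#'   `env_pairs` (undirected environment-atom pairs) and `directed_total`.
#' @export
complex_edge_counts <- function(g) {
  stopifnot(inherits(g, "ComplexGraph"))
  np <- nrow(g$protein_nodes)
  nl <- nrow(g$ligand_nodes)
  env_pairs <- 3L * (np + nl)
  list(pl_pairs = nrow(g$pl_edges), env_pairs = env_pairs,
       directed_total = 2L * (nrow(g$pl_edges) + env_pairs))
}

#' Materialise the environment edge relations of a complex graph
#'
#' The environment-protein and environment-ligand relations are complete
#' bipartite with every edge carrying distance exactly 0 (the environment
#' nodes are virtual). They are stored implicitly; this expands them.
#'
#' @param g a `ComplexGraph`.
#' @return data.frame with columns `env` (1..3), `kind`
#'   (`"protein"`/`"ligand"`), `node` (atom index within its type) and
#'   `dist` (identically 0).
#' @export
env_edges <- function(g) {
  stopifnot(inherits(g, "ComplexGraph"))
  np <- nrow(g$protein_nodes)
  nl <- nrow(g$ligand_nodes)
  out <- expand.grid(env = 1:3, node = seq_len(np + nl))
  out$kind <- ifelse(out$node <= np, "protein", "ligand")
  out$node <- ifelse(out$node <= np, out$node, out$node - np)
  out$dist <- 0
  out[, c("env", "kind", "node", "dist")]
}

#' Serialize a graph object to a JSON archive
#'
#' Writes a key-value tensor store with documented keys (node features per
#' type, edge indices, edge attributes, coordinates) readable by any JSON
#' client.
#'
#' @param g a `PocketGraph`, `LigandGraph` or `ComplexGraph`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_graph_archive <- function(g, path) {
  payload <- lapply(unclass(g), function(x) {
    if (is.matrix(x)) unclass(x) else x
  })
  payload$.class <- class(g)[1L]
  jsonlite::write_json(payload, path, digits = NA, matrix = "rowmajor")
  invisible(path)
}
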