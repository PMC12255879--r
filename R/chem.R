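# Small-molecule model and descriptor chemistry.
#
# No cheminformatics toolkit exists in the pre-installed R stack, so the
# package carries its own light-weight molecule representation plus the
# classical descriptor algorithms it needs: ring perception, implicit-H
# accounting from a standard valence model, rotatable-bond counting, Ertl
# fragment TPSA, a reduced Wildman-Crippen atomic logP, and a deterministic
# (non-canonical) SMILES writer.

DEFAULT_VALENCE <- c(B = 3, C = 4, N = 3, O = 2, P = 3, S = 2, Se = 2,
                     F = 1, Cl = 1, Br = 1, I = 1)

HALOGENS <- c("F", "Cl", "Br", "I")

#' Construct a ligand molecule
#'
#' The in-memory small-molecule container used throughout the package: heavy
#' atoms with 3-D coordinates and bonds with integer orders (4 = aromatic).
#' Ring membership, aromaticity (marked order-4 bonds plus Kekule perception
#' of alternating 6-rings), hybridization and implicit hydrogen counts are
#' derived on construction.
#'
#' @param atoms data.frame with columns `element`, `charge`, `x`, `y`, `z`.
#' @param bonds data.frame with columns `i`, `j`, `order` (1, 2, 3 or 4 for
#'   aromatic). May have zero rows for a single-atom molecule.
#' @param smiles optional SMILES string; generated if omitted.
#' @return object of class `LigandMolecule` with derived columns
#'   `aromatic`, `in_ring`, `hyb`, `n_h` on `atoms` and `aromatic`, `in_ring`
#'   on `bonds`.
#' @export
ligand_molecule <- function(atoms, bonds, smiles = NULL) {
  stopifnot(is.data.frame(atoms), nrow(atoms) >= 1L)
  if (is.null(atoms$charge)) atoms$charge <- 0L
  n <- nrow(atoms)
  if (is.null(bonds) || nrow(bonds) == 0L) {
    bonds <- data.frame(i = integer(0), j = integer(0), order = integer(0))
  }
  if (nrow(bonds) > 0L && (max(bonds$i, bonds$j) > n || min(bonds$i, bonds$j) < 1L)) {
    stop("bond indices out of atom range")
  }
  if (any(!is.finite(as.matrix(atoms[, c("x", "y", "z")])))) {
    stop("non-finite atom coordinates")
  }
  bonds$in_ring <- ring_bond_flags(n, bonds)
  arom <- perceive_aromatic(atoms, bonds)
  bonds$aromatic <- arom$bond
  atoms$aromatic <- arom$atom
  atoms$in_ring <- atom_ring_flags(n, bonds)
  atoms$hyb <- atom_hybridization(atoms, bonds)
  atoms$n_h <- implicit_h_counts(atoms, bonds)
  mol <- structure(list(atoms = atoms, bonds = bonds, smiles = smiles),
                   class = "LigandMolecule")
  if (n > 1L && !mol_connected(mol)) stop("molecule is not connected")
  if (is.null(smiles)) mol$smiles <- write_smiles(mol)
  mol
}

#' @export
print.LigandMolecule <- function(x, ...) {
  cat(sprintf("<LigandMolecule: %d heavy atoms, %d bonds, %s>\n",
              nrow(x$atoms), nrow(x$bonds), x$smiles))
  invisible(x)
}

mol_igraph <- function(n, bonds) {
  igraph::graph_from_data_frame(
    data.frame(from = bonds$i, to = bonds$j),
    directed = FALSE,
    vertices = data.frame(name = seq_len(n))
  )
}

mol_connected <- function(mol) {
  g <- mol_igraph(nrow(mol$atoms), mol$bonds)
  igraph::is_connected(g)
}

# a bond lies on a cycle iff its endpoints stay connected after removing it
ring_bond_flags <- function(n, bonds) {
  nb <- nrow(bonds)
  if (nb == 0L) return(logical(0))
  g <- mol_igraph(n, bonds)
  vapply(seq_len(nb), function(e) {
    g2 <- igraph::delete_edges(g, e)
    !is.infinite(igraph::distances(g2, v = bonds$i[e], to = bonds$j[e])[1, 1])
  }, logical(1))
}

atom_ring_flags <- function(n, bonds) {
  fl <- logical(n)
  rb <- bonds[bonds$in_ring, , drop = FALSE]
  fl[c(rb$i, rb$j)] <- TRUE
  fl
}

# enumerate simple cycles of length <= maxlen containing each ring bond
find_small_rings <- function(n, bonds, maxlen = 6L) {
  adj <- vector("list", n)
  for (e in seq_len(nrow(bonds))) {
    adj[[bonds$i[e]]] <- c(adj[[bonds$i[e]]], bonds$j[e])
    adj[[bonds$j[e]]] <- c(adj[[bonds$j[e]]], bonds$i[e])
  }
  rings <- list()
  seen <- character(0)
  dfs <- function(path, target) {
    v <- path[length(path)]
    for (w in adj[[v]]) {
      if (w == target && length(path) >= 3L) {
        key <- paste(sort(path), collapse = "-")
        if (!(key %in% seen)) {
          seen <<- c(seen, key)
          rings[[length(rings) + 1L]] <<- path
        }
      } else if (!(w %in% path) && length(path) < maxlen) {
        dfs(c(path, w), target)
      }
    }
  }
  for (s in seq_len(n)) if (length(adj[[s]]) >= 2L) dfs(s, s)
  rings
}

# aromatic = bonds marked order 4, plus 5/6-rings of C/N/O/S whose ring bonds
# alternate single/double (a pragmatic Kekule test, not full Hueckel counting)
perceive_aromatic <- function(atoms, bonds) {
  n <- nrow(atoms)
  nb <- nrow(bonds)
  barom <- if (nb > 0L) bonds$order == 4L else logical(0)
  if (nb > 0L) {
    bkey <- function(i, j) paste(pmin(i, j), pmax(i, j))
    bmap <- stats::setNames(seq_len(nb), bkey(bonds$i, bonds$j))
    rings <- find_small_rings(n, bonds[bonds$in_ring, , drop = FALSE], 6L)
    for (r in rings) {
      if (length(r) != 6L && length(r) != 5L) next
      if (!all(atoms$element[r] %in% c("C", "N", "O", "S"))) next
      eb <- bmap[bkey(r, c(r[-1L], r[1L]))]
      if (any(is.na(eb))) next
      ords <- bonds$order[eb]
      if (all(ords == 4L)) { barom[eb] <- TRUE; next }
      if (length(r) == 6L && all(ords %in% c(1L, 2L)) &&
          sum(ords == 2L) == 3L && all(abs(diff(ords)) == 1L)) {
        barom[eb] <- TRUE
      }
    }
  }
  aarom <- logical(n)
  if (nb > 0L) aarom[c(bonds$i[barom], bonds$j[barom])] <- TRUE
  list(bond = barom, atom = aarom)
}

# 1 = sp, 2 = sp2, 3 = sp3, from incident bond orders
atom_hybridization <- function(atoms, bonds) {
  n <- nrow(atoms)
  hyb <- rep(3L, n)
  if (nrow(bonds) == 0L) return(hyb)
  for (v in seq_len(n)) {
    ords <- c(bonds$order[bonds$i == v], bonds$order[bonds$j == v])
    arom <- c(bonds$aromatic[bonds$i == v], bonds$aromatic[bonds$j == v])
    if (length(ords) == 0L) next
    if (any(ords == 3L) || sum(ords == 2L) >= 2L) hyb[v] <- 1L
    else if (any(ords == 2L) || any(arom)) hyb[v] <- 2L
  }
  hyb
}

# standard valence minus bonded electron pairs; aromatic bonds count 1.5
implicit_h_counts <- function(atoms, bonds) {
  n <- nrow(atoms)
  nh <- integer(n)
  for (v in seq_len(n)) {
    el <- atoms$element[v]
    dv <- DEFAULT_VALENCE[el]
    if (is.na(dv)) { nh[v] <- 0L; next }
    sel <- bonds$i == v | bonds$j == v
    ords <- bonds$order[sel]
    arom <- bonds$aromatic[sel]
    bsum <- sum(ifelse(arom, 1.5, pmin(ords, 3L)))
    # lone aromatic perception can give x.5 sums; round up to the Kekule value
    nh[v] <- max(0L, as.integer(floor(dv + atoms$charge[v] - bsum + 0.5)))
  }
  nh
}

heavy_degree <- function(mol) {
  n <- nrow(mol$atoms)
  deg <- integer(n)
  if (nrow(mol$bonds) > 0L) {
    tb <- table(factor(c(mol$bonds$i, mol$bonds$j), levels = seq_len(n)))
    deg <- as.integer(tb)
  }
  deg
}

# non-ring single bonds between two heavy atoms that each carry at least one
# further heavy neighbor; amide C-N bonds excluded
rotatable_bond_count <- function(mol) {
  b <- mol$bonds
  if (nrow(b) == 0L) return(0L)
  deg <- heavy_degree(mol)
  is_amide_cn <- function(ci, ni) {
    if (mol$atoms$element[ci] != "C" || mol$atoms$element[ni] != "N") return(FALSE)
    sel <- (b$i == ci | b$j == ci) & b$order == 2L
    o2 <- c(b$j[b$i == ci & b$order == 2L], b$i[b$j == ci & b$order == 2L])
    any(mol$atoms$element[o2] == "O")
  }
  cnt <- 0L
  for (e in seq_len(nrow(b))) {
    if (b$order[e] != 1L || b$aromatic[e] || b$in_ring[e]) next
    i <- b$i[e]; j <- b$j[e]
    if (deg[i] < 2L || deg[j] < 2L) next
    if (is_amide_cn(i, j) || is_amide_cn(j, i)) next
    cnt <- cnt + 1L
  }
  cnt
}

# independent cycles of the aromatic-bond subgraph (benzene 1, naphthalene 2)
aromatic_ring_count <- function(mol) {
  ab <- mol$bonds[mol$bonds$aromatic, , drop = FALSE]
  if (nrow(ab) == 0L) return(0L)
  verts <- sort(unique(c(ab$i, ab$j)))
  g <- igraph::graph_from_data_frame(
    data.frame(from = match(ab$i, verts), to = match(ab$j, verts)),
    directed = FALSE, vertices = data.frame(name = seq_along(verts)))
  nrow(ab) - length(verts) + igraph::count_components(g)
}

# Ertl fragment TPSA (Angstrom^2): published contributions for the common
# neutral/charged N, O, S, P environments; unrecognized polar environments
# fall back to the closest generic class
ertl_tpsa <- function(mol) {
  at <- mol$atoms
  b <- mol$bonds
  total <- 0
  for (v in seq_len(nrow(at))) {
    el <- at$element[v]
    if (!(el %in% c("N", "O", "S", "P"))) next
    sel <- b$i == v | b$j == v
    ords <- b$order[sel]
    arom <- at$aromatic[v]
    nh <- at$n_h[v]
    ch <- at$charge[v]
    n1 <- sum(ords == 1L | b$aromatic[sel])
    n2 <- sum(ords == 2L & !b$aromatic[sel])
    n3 <- sum(ords == 3L)
    contrib <- if (el == "N") {
      if (arom) { if (nh > 0) 15.79 else 12.89 }
      else if (ch > 0) { if (nh >= 3) 27.64 else 4.44 }
      else if (n3 == 1L) 23.79
      else if (n2 >= 1L) { if (nh > 0) 23.85 else 12.36 }
      else if (nh >= 2L) 26.02
      else if (nh == 1L) 12.03
      else 3.24
    } else if (el == "O") {
      if (arom) 13.14
      else if (ch < 0) 23.06
      else if (n2 >= 1L) 17.07
      else if (nh > 0L) 20.23
      else 9.23
    } else if (el == "S") {
      if (arom) 28.24
      else if (n2 >= 1L) 32.09
      else if (nh > 0L) 38.80
      else 25.30
    } else { # P
      if (n2 >= 1L) 34.14 else 13.59
    }
    total <- total + contrib
  }
  total
}

# Reduced Wildman-Crippen atomic logP: the published class values for the
# dominant atom environments (full table keys on SMARTS types; without a
# SMARTS engine the classes are resolved from the molecular graph directly).
crippen_logp <- function(mol) {
  at <- mol$atoms
  b <- mol$bonds
  n <- nrow(at)
  nbrs <- function(v) c(b$j[b$i == v], b$i[b$j == v])
  total <- 0
  for (v in seq_len(n)) {
    el <- at$element[v]
    het <- any(!(at$element[nbrs(v)] %in% c("C", "H")))
    contrib <- switch(el,
      C = if (at$aromatic[v]) 0.1581
          else if (at$hyb[v] == 3L && !het) 0.1441
          else if (at$hyb[v] == 3L) -0.2035
          else if (het) -0.2783
          else 0.1551,
      N = if (at$aromatic[v]) -0.3239 else -1.0190,
      O = if (at$aromatic[v]) 0.1552
          else if (at$n_h[v] > 0L) -0.3567
          else if (any(b$order[b$i == v | b$j == v] == 2L)) -0.1526
          else -0.2893,
      S = 0.6482,
      P = 0.8612,
      B = -0.3187,
      Se = 0.6482,
      F = 0.4202, Cl = 0.6895, Br = 0.8456, I = 0.8857,
      -0.0025)
    # implicit hydrogens: hydrocarbon vs polar attachment
    hcon <- if (el %in% c("N", "O", "S")) -0.2677 else 0.1230
    total <- total + contrib + at$n_h[v] * hcon
  }
  total
}

lipinski_hbd <- function(mol) {
  sum(mol$atoms$n_h[mol$atoms$element %in% c("N", "O")])
}

lipinski_hba <- function(mol) {
  sum(mol$atoms$element %in% c("N", "O"))
}

# ---- SMILES writer ---------------------------------------------------------

#' Write a SMILES string for a molecule
#'
#' Deterministic DFS writer (lowercase aromatic atoms, numeric ring closures,
#' bracket atoms for formal charges). The output is valid SMILES but not
#' canonical across atom reorderings; it is stable for a fixed atom order.
#'
#' @param mol a `LigandMolecule` (ring/aromatic flags already derived).
#' @return a SMILES string.
#' @export
write_smiles <- function(mol) {
  at <- mol$atoms
  b <- mol$bonds
  n <- nrow(at)
  if (n == 0L) return("")
  adj <- vector("list", n)
  for (e in seq_len(nrow(b))) {
    adj[[b$i[e]]] <- c(adj[[b$i[e]]], list(c(b$j[e], e)))
    adj[[b$j[e]]] <- c(adj[[b$j[e]]], list(c(b$i[e], e)))
  }
  # pass 1: classify tree vs back (ring-closure) edges by DFS from atom 1
  visited <- logical(n)
  used_edge <- logical(nrow(b))
  back <- integer(0)
  dfs1 <- function(v, from_e) {
    visited[v] <<- TRUE
    for (p in adj[[v]]) {
      w <- p[1L]; e <- p[2L]
      if (!is.null(from_e) && e == from_e) next
      if (!visited[w]) {
        used_edge[e] <<- TRUE
        dfs1(w, e)
      } else if (!used_edge[e]) {
        used_edge[e] <<- TRUE
        back[length(back) + 1L] <<- e
      }
    }
  }
  dfs1(1L, NULL)
  digit_of <- rep(NA_integer_, nrow(b))
  digit_of[back] <- seq_along(back)
  bond_sym <- function(e) {
    if (b$aromatic[e]) return("")
    switch(b$order[e], "", "=", "#", "")
  }
  atom_sym <- function(v) {
    el <- at$element[v]
    sym <- if (at$aromatic[v] && el %in% c("C", "N", "O", "S")) tolower(el) else el
    ch <- at$charge[v]
    if (ch != 0L) {
      chs <- if (ch > 0L) strrep("+", ch) else strrep("-", -ch)
      sym <- paste0("[", sym, chs, "]")
    }
    sym
  }
  # pass 2: emit along tree edges, attaching ring digits at both endpoints
  visited <- logical(n)
  emit <- function(v, from_e) {
    visited[v] <<- TRUE
    out <- atom_sym(v)
    for (p in adj[[v]]) {
      e <- p[2L]
      if (!is.na(digit_of[e])) out <- paste0(out, bond_sym(e), digit_of[e])
    }
    branches <- character(0)
    for (p in adj[[v]]) {
      w <- p[1L]; e <- p[2L]
      if (!is.null(from_e) && e == from_e) next
      if (!is.na(digit_of[e])) next
      if (!visited[w]) branches <- c(branches, paste0(bond_sym(e), emit(w, e)))
    }
    if (length(branches) > 1L) {
      out <- paste0(out, paste0("(", branches[-length(branches)], ")", collapse = ""),
                    branches[length(branches)])
    } else if (length(branches) == 1L) {
      out <- paste0(out, branches)
    }
    out
  }
  emit(1L, NULL)
}
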