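# Fully synthetic protein-ligand complexes with a planted affinity law, so
# every pipeline stage is testable without external downloads. The planted
# signal depends only on quantities the model's branches can observe:
# protein-ligand contacts (heterogeneous graph), H-bond/polarity descriptors
# (environment nodes) and rotatable bonds (environment nodes).

# chosen so the affinity distribution looks like real pKd/pKi data
# (mean ~6, sd ~1.5, range ~3-10 with the default generator geometry)
PLANTED_COEF <- c(base = 3.5, contacts = 0.02, hbd_polar = 0.5,
                  rotatable = 0.1)

#' Synthetic-dataset configuration
#'
#' The defaults define the package's reference synthetic world: 200
#' complexes, compact pockets (16-32 residues) and fragment-sized ligands
#' (8-18 heavy atoms) - deliberately desk-scale so a full train/evaluate
#' cycle runs in minutes on one CPU - with placement geometry that produces a
#' wide contact-count distribution and affinity noise of 0.2 log units.
#'
#' @param n_complexes number of complexes.
#' @param residues_range min/max pocket residues (<= 64).
#' @param atoms_range min/max ligand heavy atoms (<= 150).
#' @param contact_scale Angstrom scale of the ligand placement offset; larger
#'   values spread the contact-count distribution.
#' @param noise_sd standard deviation of the affinity noise (log units).
#' @param seed master RNG seed; each complex derives its own stream from
#'   `(seed, index)`.
#' @return object of class `SynthConfig`.
#' @export
synth_config <- function(n_complexes = 200L, residues_range = c(16L, 32L),
                         atoms_range = c(8L, 18L), contact_scale = 3.0,
                         noise_sd = 0.2, seed = 1L) {
  stopifnot(n_complexes >= 1L, residues_range[1] >= 2L,
            residues_range[2] <= 64L, residues_range[1] <= residues_range[2],
            atoms_range[1] >= 1L, atoms_range[2] <= 150L,
            atoms_range[1] <= atoms_range[2],
            contact_scale > 0, noise_sd >= 0)
  structure(list(n_complexes = as.integer(n_complexes),
                 residues_range = as.integer(residues_range),
                 atoms_range = as.integer(atoms_range),
                 contact_scale = contact_scale,
                 noise_sd = noise_sd,
                 seed = as.integer(seed)), class = "SynthConfig")
}

# valence-capped random molecular tree with optional ring closure; chemically
# valid by construction (degrees never exceed default valences)
random_ligand <- function(n_atoms) {
  caps <- c(C = 4L, N = 3L, O = 2L, S = 2L)
  els <- character(n_atoms)
  used <- integer(n_atoms)
  els[1] <- "C"
  coords <- matrix(0, n_atoms, 3L)
  bonds <- data.frame(i = integer(0), j = integer(0), order = integer(0))
  if (n_atoms > 1L) {
    for (v in 2L:n_atoms) {
      els[v] <- sample(names(caps), 1L, prob = c(0.70, 0.12, 0.12, 0.06))
      open <- which(used[seq_len(v - 1L)] < caps[els[seq_len(v - 1L)]])
      parent <- if (length(open) == 1L) open else sample(open, 1L)
      ord <- 1L
      if (els[v] == "C" && els[parent] == "C" &&
          caps[els[parent]] - used[parent] >= 2L && stats::runif(1) < 0.10) {
        ord <- 2L
      }
      bonds <- rbind(bonds, data.frame(i = parent, j = v, order = ord))
      used[parent] <- used[parent] + ord
      used[v] <- used[v] + ord
      dir <- stats::rnorm(3L)
      coords[v, ] <- coords[parent, ] + 1.5 * dir / sqrt(sum(dir^2))
    }
    # one ring closure attempt between distant atoms with spare valence
    if (n_atoms >= 5L && stats::runif(1) < 0.5) {
      open <- which(used < caps[els])
      if (length(open) >= 2L) {
        cand <- utils::combn(open, 2L)
        g <- igraph::graph_from_data_frame(bonds[, 1:2], directed = FALSE,
                                           vertices = data.frame(name = seq_len(n_atoms)))
        dd <- igraph::distances(g)
        ok <- which(dd[t(cand)] >= 3)
        if (length(ok) > 0L) {
          pick <- cand[, if (length(ok) == 1L) ok else sample(ok, 1L)]
          bonds <- rbind(bonds, data.frame(i = pick[1], j = pick[2], order = 1L))
          used[pick] <- used[pick] + 1L
        }
      }
    }
  }
  ligand_molecule(data.frame(element = els, charge = 0L,
                             x = coords[, 1], y = coords[, 2], z = coords[, 3]),
                  bonds)
}

#' Generate one synthetic complex
#'
#' Pocket residues on a jittered lattice (C-alpha spacing ~4.5 A) with
#' backbone-like N/CA/O heavy atoms; a random valence-correct ligand placed
#' at a randomized offset from the pocket surface; random amino-acid and
#' 8-state SSE strings. Deterministic per `(cfg$seed, index)`. The affinity
#' label is the planted law of [planted_affinity()] plus Gaussian noise.
#'
#' @param cfg a [synth_config()].
#' @param index complex index (1-based).
#' @return a `ComplexRecord` with `affinity_label` set.
#' @export
generate_complex <- function(cfg, index) {
  stopifnot(inherits(cfg, "SynthConfig"))
  set.seed((cfg$seed * 10007L + index * 7919L) %% .Machine$integer.max)
  n_res <- sample(cfg$residues_range[1]:cfg$residues_range[2], 1L)
  # jittered cubic lattice of C-alpha positions
  side <- ceiling(n_res^(1 / 3))
  grid <- expand.grid(x = seq_len(side), y = seq_len(side), z = seq_len(side))
  grid <- grid[seq_len(n_res), ] * 4.5 + matrix(stats::rnorm(3L * n_res, 0, 0.6),
                                                n_res, 3L)
  aa <- sample(rownames(RESIDUE_PROPS), n_res, replace = TRUE)
  sse <- sample(SSE_ORDER, n_res, replace = TRUE)
  residues <- data.frame(aa = aa, x = grid[, 1], y = grid[, 2], z = grid[, 3],
                         sse = sse)
  # backbone-like heavy atoms: N and O near each C-alpha
  pa <- do.call(rbind, lapply(seq_len(n_res), function(i) {
    ca <- as.numeric(grid[i, ])
    rbind(
      data.frame(element = "N", x = ca[1] + 1.3, y = ca[2], z = ca[3], res_index = i),
      data.frame(element = "C", x = ca[1], y = ca[2], z = ca[3], res_index = i),
      data.frame(element = "O", x = ca[1], y = ca[2] + 1.2, z = ca[3], res_index = i)
    )
  }))
  # full protein sequence embeds the pocket
  extra <- sample(30:80, 1L)
  protein_seq <- paste(c(sample(rownames(RESIDUE_PROPS), extra, replace = TRUE), aa),
                       collapse = "")
  n_atoms <- sample(cfg$atoms_range[1]:cfg$atoms_range[2], 1L)
  lig <- random_ligand(n_atoms)
  # place the ligand near a random pocket residue at a randomized distance
  anchor <- as.numeric(grid[sample(n_res, 1L), ])
  dir <- stats::rnorm(3L)
  dir <- dir / sqrt(sum(dir^2))
  offset <- anchor + dir * stats::runif(1, 1.0, 2.0 + 2 * cfg$contact_scale)
  cen <- colMeans(as.matrix(lig$atoms[, c("x", "y", "z")]))
  lig$atoms$x <- lig$atoms$x - cen[1] + offset[1]
  lig$atoms$y <- lig$atoms$y - cen[2] + offset[2]
  lig$atoms$z <- lig$atoms$z - cen[3] + offset[3]
  rec <- complex_record(sprintf("synth%04d", index), protein_seq, residues,
                        lig, pocket_atoms = pa)
  rec$affinity_label <- planted_affinity(rec, noise_sd = cfg$noise_sd)
  rec
}

#' Planted signal components of a complex
#'
#' @param record a `ComplexRecord`.
#' @return named vector: `contacts` (protein-ligand heavy-atom pairs within
#'   5 A), `hbd_polar` (ligand H-bond donors times pocket polar-residue
#'   fraction), `rotatable` (ligand rotatable bonds).
#' @export
planted_signal_components <- function(record) {
  pc <- as.matrix(record$pocket_atoms[, c("x", "y", "z")])
  lc <- as.matrix(record$ligand$atoms[, c("x", "y", "z")])
  d2 <- outer(rowSums(pc^2), rowSums(lc^2), "+") - 2 * pc %*% t(lc)
  contacts <- sum(d2 <= 25 + 1e-12)
  polar <- mean(strsplit(record$pocket_seq, "")[[1]] %in%
                  c("R", "N", "D", "C", "Q", "E", "H", "K", "S", "T", "Y"))
  c(contacts = contacts,
    hbd_polar = lipinski_hbd(record$ligand) * polar,
    rotatable = rotatable_bond_count(record$ligand))
}

#' Planted affinity law
#'
#' `affinity = 3.5 + 0.02 * contacts + 0.5 * hbd_polar - 0.1 * rotatable
#' + noise`, with the components of [planted_signal_components()]. The
#' deterministic part depends on exactly the signals the model's branches
#' see; noise (if any) is drawn from the current RNG stream.
#'
#' @param record a `ComplexRecord`.
#' @param noise_sd Gaussian noise standard deviation (0 = deterministic).
#' @return scalar affinity in -log10 units.
#' @export
planted_affinity <- function(record, noise_sd = 0) {
  s <- planted_signal_components(record)
  val <- PLANTED_COEF[["base"]] +
    PLANTED_COEF[["contacts"]] * s[["contacts"]] +
    PLANTED_COEF[["hbd_polar"]] * s[["hbd_polar"]] -
    PLANTED_COEF[["rotatable"]] * s[["rotatable"]]
  if (noise_sd > 0) val <- val + stats::rnorm(1L, 0, noise_sd)
  val
}

#' Generate a synthetic dataset
#'
#' @param cfg a [synth_config()].
#' @return list of `ComplexRecord`s of length `cfg$n_complexes`.
#' @export
generate_dataset <- function(cfg) {
  lapply(seq_len(cfg$n_complexes), function(i) generate_complex(cfg, i))
}

# ---- on-disk form (exercises the real readers) -----------------------------

write_pocket_pdb <- function(record, path) {
  pa <- record$pocket_atoms
  res <- record$pocket_residues
  aa3 <- names(AA3TO1)[match(res$aa, AA3TO1)]
  aa3[is.na(aa3)] <- "UNK"
  lines <- character(0)
  serial <- 0L
  for (i in seq_len(nrow(pa))) {
    serial <- serial + 1L
    ri <- pa$res_index[i]
    nm <- if (pa$element[i] == "C") "CA" else pa$element[i]
    lines <- c(lines, sprintf(
      "ATOM  %5d %-4s %3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
      serial, substr(paste0(" ", nm), 1, 4), aa3[ri], ri,
      pa$x[i], pa$y[i], pa$z[i], pa$element[i]))
  }
  writeLines(c(lines, "END"), path)
  invisible(path)
}

write_ligand_sdf <- function(mol, path, title = "ligand") {
  at <- mol$atoms
  b <- mol$bonds
  lines <- c(title, "  bindgraph", "",
             sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                     nrow(at), nrow(b)))
  for (i in seq_len(nrow(at))) {
    lines <- c(lines, sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                              at$x[i], at$y[i], at$z[i], at$element[i]))
  }
  for (e in seq_len(nrow(b))) {
    lines <- c(lines, sprintf("%3d%3d%3d  0  0  0  0", b$i[e], b$j[e],
                              min(b$order[e], 4L)))
  }
  writeLines(c(lines, "M  END", "$$$$"), path)
  invisible(path)
}

#' Write a synthetic dataset in PDBbind-like on-disk layout
#'
#' One directory per complex (`<id>_pocket.pdb`, `<id>_ligand.sdf`) plus an
#' `INDEX.txt` in PDBbind format, so the package's own readers are exercised
#' end to end.
#'
#' @param records list of `ComplexRecord`s.
#' @param dir output directory (created if needed).
#' @return the index-file path, invisibly.
#' @export
write_synthetic_dataset <- function(records, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  idx <- c("# synthetic complex index",
           "# id  resolution  year  -logKd/Ki")
  for (rec in records) {
    cdir <- file.path(dir, rec$complex_id)
    dir.create(cdir, showWarnings = FALSE)
    write_pocket_pdb(rec, file.path(cdir, paste0(rec$complex_id, "_pocket.pdb")))
    write_ligand_sdf(rec$ligand, file.path(cdir, paste0(rec$complex_id, "_ligand.sdf")),
                     title = rec$complex_id)
    idx <- c(idx, sprintf("%s  2.00  2024  %.4f", rec$complex_id,
                          rec$affinity_label))
  }
  ipath <- file.path(dir, "INDEX.txt")
  writeLines(idx, ipath)
  invisible(ipath)
}

#' Load a dataset written by [write_synthetic_dataset()]
#'
#' Reads the index, pocket PDBs and ligand SDFs back into `ComplexRecord`s.
#' The full protein sequence is not stored in the on-disk layout, so the
#' pocket sequence stands in for it (a documented limitation of the
#' PDBbind-like layout; real runs supply protein FASTA separately).
#'
#' @param dir dataset directory.
#' @return list of `ComplexRecord`s.
#' @export
read_synthetic_dataset <- function(dir) {
  idx <- read_pdbbind_index(file.path(dir, "INDEX.txt"))
  lapply(seq_len(nrow(idx)), function(i) {
    id <- idx$complex_id[i]
    cdir <- file.path(dir, id)
    pk <- read_pocket_pdb(file.path(cdir, paste0(id, "_pocket.pdb")))
    lig <- read_ligand_file(file.path(cdir, paste0(id, "_ligand.sdf")))
    complex_record(id, paste(pk$pocket_residues$aa, collapse = ""),
                   pk$pocket_residues, lig, pocket_atoms = pk$pocket_atoms,
                   affinity_label = idx$affinity[i])
  })
}
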