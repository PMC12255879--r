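# Fixed-shape padded sequence featurization: protein (1024 x 40),
# pocket (64 x 40) and ligand atoms (150 x 18).
#
# Residue rows are [AA one-hot (21) | SSE one-hot (8) | physicochemical (11)];
# ligand rows are the 18-dim atom scheme [type one-hot (9) | atomic
# properties (4) | substructure flags (5)].

AA_ORDER <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
              "M", "F", "P", "S", "T", "W", "Y", "V", "X") # X = unknown/nonstandard
SSE_ORDER <- c("H", "B", "E", "G", "I", "T", "S", "-")     # DSSP 8-state; '-' = coil/unknown

SEQFEAT_SHAPES <- list(protein = c(1024L, 40L), pocket = c(64L, 40L),
                       ligand = c(150L, 18L))

# per-residue physicochemical table (20 standard AAs).
# hydro: Kyte-Doolittle hydropathy; charge: net charge at pH 7 (His +0.1);
# pi: residue isoelectric point; mw: residue molecular weight (Da);
# polar/aromatic/aliphatic: class flags; hbd/hba: side-chain H-bond donor and
# acceptor group counts; vol: side-chain volume (A^3);
# flex: Bhaskaran-Ponnuswamy average flexibility index.
RESIDUE_PROPS <- local({
  m <- rbind(
    #        hydro charge    pi    mw polar arom aliph hbd hba   vol  flex
    A = c(  1.8,  0.0,  6.00,  89.1, 0, 0, 1, 0, 0,  88.6, 0.357),
    R = c( -4.5,  1.0, 10.76, 174.2, 1, 0, 0, 4, 0, 173.4, 0.529),
    N = c( -3.5,  0.0,  5.41, 132.1, 1, 0, 0, 2, 1, 114.1, 0.463),
    D = c( -3.5, -1.0,  2.77, 133.1, 1, 0, 0, 0, 2, 111.1, 0.511),
    C = c(  2.5,  0.0,  5.07, 121.2, 1, 0, 0, 1, 0, 108.5, 0.346),
    Q = c( -3.5,  0.0,  5.65, 146.2, 1, 0, 0, 2, 1, 143.8, 0.493),
    E = c( -3.5, -1.0,  3.22, 147.1, 1, 0, 0, 0, 2, 138.4, 0.497),
    G = c( -0.4,  0.0,  5.97,  75.1, 0, 0, 1, 0, 0,  60.1, 0.544),
    H = c( -3.2,  0.1,  7.59, 155.2, 1, 1, 0, 1, 1, 153.2, 0.323),
    I = c(  4.5,  0.0,  6.02, 131.2, 0, 0, 1, 0, 0, 166.7, 0.462),
    L = c(  3.8,  0.0,  5.98, 131.2, 0, 0, 1, 0, 0, 166.7, 0.365),
    K = c( -3.9,  1.0,  9.74, 146.2, 1, 0, 0, 3, 0, 168.6, 0.466),
    M = c(  1.9,  0.0,  5.74, 149.2, 0, 0, 0, 0, 0, 162.9, 0.295),
    F = c(  2.8,  0.0,  5.48, 165.2, 0, 1, 0, 0, 0, 189.9, 0.314),
    P = c( -1.6,  0.0,  6.30, 115.1, 0, 0, 1, 0, 0, 112.7, 0.509),
    S = c( -0.8,  0.0,  5.68, 105.1, 1, 0, 0, 1, 1,  89.0, 0.507),
    T = c( -0.7,  0.0,  5.60, 119.1, 1, 0, 0, 1, 1, 116.1, 0.444),
    W = c( -0.9,  0.0,  5.89, 204.2, 0, 1, 0, 1, 0, 227.8, 0.305),
    Y = c( -1.3,  0.0,  5.66, 181.2, 1, 1, 0, 1, 1, 193.6, 0.420),
    V = c(  4.2,  0.0,  5.96, 117.1, 0, 0, 1, 0, 0, 140.0, 0.386)
  )
  colnames(m) <- c("hydro", "charge", "pi", "mw", "polar", "aromatic",
                   "aliphatic", "hbd", "hba", "vol", "flex")
  m
})

# min-max scaled to [0,1] over the 20 standard AAs
RESIDUE_PROPS_SCALED <- local({
  rng <- apply(RESIDUE_PROPS, 2L, range)
  span <- rng[2L, ] - rng[1L, ]
  span[span == 0] <- 1
  sweep(sweep(RESIDUE_PROPS, 2L, rng[1L, ], "-"), 2L, span, "/")
})

#' Encode one residue into a 40-dim feature vector
#'
#' `[AA one-hot (21) | SSE one-hot (8) | scaled physicochemical (11)]`.
#' Unknown amino-acid letters map to the 21st (unknown) class with an all-zero
#' physicochemical block; unknown SSE letters map to `"-"`.
#'
#' @param aa single amino-acid letter.
#' @param sse single 8-state SSE letter (default unknown).
#' @return numeric vector of length 40.
#' @export
encode_residue <- function(aa, sse = "-") {
  aa <- toupper(aa)
  if (!(aa %in% AA_ORDER)) aa <- "X"
  if (!(sse %in% SSE_ORDER)) sse <- "-"
  v <- numeric(40L)
  v[match(aa, AA_ORDER)] <- 1
  v[21L + match(sse, SSE_ORDER)] <- 1
  if (aa != "X") v[30L:40L] <- RESIDUE_PROPS_SCALED[aa, ]
  v
}

new_seqfeat <- function(values, mask, kind) {
  structure(list(values = values, mask = mask, kind = kind),
            class = "SequenceFeatureMatrix")
}

#' @export
print.SequenceFeatureMatrix <- function(x, ...) {
  cat(sprintf("<SequenceFeatureMatrix %s: %d x %d, %d valid rows>\n",
              x$kind, nrow(x$values), ncol(x$values), sum(x$mask)))
  invisible(x)
}

encode_aa_sequence <- function(seq, sse, kind) {
  shp <- SEQFEAT_SHAPES[[kind]]
  if (!nzchar(seq)) stop("empty sequence")
  letters_ <- strsplit(seq, "")[[1]]
  L <- length(letters_)
  if (is.null(sse)) {
    sse_ <- rep("-", L)
  } else {
    sse_ <- strsplit(sse, "")[[1]]
    if (length(sse_) != L) stop("SSE string length does not match sequence")
  }
  if (L > shp[1L]) {
    warning(sprintf("%s sequence of length %d truncated to %d (C-terminal residues dropped)",
                    kind, L, shp[1L]))
    letters_ <- letters_[seq_len(shp[1L])]
    sse_ <- sse_[seq_len(shp[1L])]
    L <- shp[1L]
  }
  values <- matrix(0, shp[1L], shp[2L])
  for (i in seq_len(L)) values[i, ] <- encode_residue(letters_[i], sse_[i])
  mask <- c(rep(TRUE, L), rep(FALSE, shp[1L] - L))
  new_seqfeat(values, mask, kind)
}

#' Encode a full protein sequence (1024 x 40)
#'
#' Sequences longer than 1024 residues are truncated from the C-terminus with
#' a warning; shorter sequences are zero padded with a validity mask.
#'
#' @param seq amino-acid string.
#' @param sse optional 8-state SSE string of equal length (default unknown).
#' @return `SequenceFeatureMatrix` of kind `"protein"`.
#' @export
encode_protein_sequence <- function(seq, sse = NULL) {
  encode_aa_sequence(seq, sse, "protein")
}

#' Encode a pocket sequence (64 x 40)
#' @inheritParams encode_protein_sequence
#' @return `SequenceFeatureMatrix` of kind `"pocket"`.
#' @export
encode_pocket_sequence <- function(seq, sse = NULL) {
  encode_aa_sequence(seq, sse, "pocket")
}

#' 18-dim atom feature row(s) for a molecule
#'
#' Layout: atom-type one-hot over {B, C, N, O, P, S, Se, halogen, other} (9),
#' atomic properties `[hybridization/3 | heavy-neighbor count/4 capped |
#' formal charge | aromatic flag]` (4), and substructure flags `[hydrophobic
#' carbon | aromatic-ring member | H-bond acceptor | H-bond donor | ring
#' member]` (5).
#'
#' @param mol a `LigandMolecule`.
#' @return matrix with one 18-dim row per heavy atom, in atom order.
#' @export
atom_feature_rows <- function(mol) {
  at <- mol$atoms
  n <- nrow(at)
  deg <- heavy_degree(mol)
  out <- matrix(0, n, 18L)
  type_slot <- function(el) {
    switch(el, B = 1L, C = 2L, N = 3L, O = 4L, P = 5L, S = 6L, Se = 7L,
           if (el %in% HALOGENS) 8L else 9L)
  }
  b <- mol$bonds
  for (v in seq_len(n)) {
    el <- at$element[v]
    out[v, type_slot(el)] <- 1
    out[v, 10L] <- at$hyb[v] / 3
    out[v, 11L] <- min(deg[v], 4L) / 4
    out[v, 12L] <- at$charge[v]
    out[v, 13L] <- as.numeric(at$aromatic[v])
    nbr <- c(b$j[b$i == v], b$i[b$j == v])
    hydrophobic <- el == "C" && all(at$element[nbr] %in% c("C", "H"))
    out[v, 14L] <- as.numeric(hydrophobic)
    out[v, 15L] <- as.numeric(at$aromatic[v] && at$in_ring[v])
    out[v, 16L] <- as.numeric(el %in% c("N", "O") && at$charge[v] <= 0L)
    out[v, 17L] <- as.numeric(el %in% c("N", "O", "S") && at$n_h[v] > 0L)
    out[v, 18L] <- as.numeric(at$in_ring[v])
  }
  out
}

#' Encode ligand atoms into the padded 150 x 18 matrix
#'
#' One row per heavy atom in the molecule's atom order (the "SMILES sequence"
#' representation is atom-wise: the 18-dim scheme types atoms, not
#' characters). Molecules with more than 150 heavy atoms are truncated with a
#' warning.
#'
#' @param mol a `LigandMolecule`.
#' @return `SequenceFeatureMatrix` of kind `"ligand"`.
#' @export
encode_ligand_smiles <- function(mol) {
  stopifnot(inherits(mol, "LigandMolecule"))
  shp <- SEQFEAT_SHAPES[["ligand"]]
  rows <- atom_feature_rows(mol)
  n <- nrow(rows)
  if (n > shp[1L]) {
    warning(sprintf("ligand with %d heavy atoms truncated to %d", n, shp[1L]))
    rows <- rows[seq_len(shp[1L]), , drop = FALSE]
    n <- shp[1L]
  }
  values <- matrix(0, shp[1L], shp[2L])
  values[seq_len(n), ] <- rows
  new_seqfeat(values, c(rep(TRUE, n), rep(FALSE, shp[1L] - n)), "ligand")
}
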