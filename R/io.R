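# Readers and writers for the standard input formats: PDBbind-style index
# files, pocket PDB files, ligand SDF/mol2 files, and prediction CSVs.

AA3TO1 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
            GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
            MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
            TYR = "Y", VAL = "V")

#' Construct a per-complex record
#'
#' The central domain container: one protein-ligand complex with its pocket
#' geometry and (optionally) a binding-affinity label in -log10 Kd/Ki units.
#'
#' @param complex_id identifier string.
#' @param protein_seq full protein amino-acid sequence (1-letter codes).
#' @param pocket_residues data.frame with columns `aa` (1-letter code),
#'   `x`, `y`, `z` (C-alpha coordinates, Angstrom) and `sse` (8-state label,
#'   `"-"`/`"?"` for unknown).
#' @param ligand a [ligand_molecule()].
#' @param pocket_atoms optional data.frame of pocket heavy atoms (`element`,
#'   `x`, `y`, `z`, `res_index`); defaults to the C-alpha set.
#' @param affinity_label optional numeric label (dimensionless -log10 Kd/Ki).
#' @return object of class `ComplexRecord`.
#' @export
complex_record <- function(complex_id, protein_seq, pocket_residues, ligand,
                           pocket_atoms = NULL, affinity_label = NULL) {
  stopifnot(is.character(complex_id), nchar(protein_seq) > 0L,
            is.data.frame(pocket_residues), nrow(pocket_residues) > 0L,
            inherits(ligand, "LigandMolecule"))
  coords <- as.matrix(pocket_residues[, c("x", "y", "z")])
  if (any(!is.finite(coords))) stop("non-finite pocket coordinates")
  if (is.null(pocket_residues$sse)) pocket_residues$sse <- "-"
  if (is.null(pocket_atoms)) {
    pocket_atoms <- data.frame(element = "C",
                               x = pocket_residues$x, y = pocket_residues$y,
                               z = pocket_residues$z,
                               res_index = seq_len(nrow(pocket_residues)))
  }
  structure(list(
    complex_id = complex_id,
    protein_seq = protein_seq,
    pocket_seq = paste(pocket_residues$aa, collapse = ""),
    pocket_residues = pocket_residues,
    pocket_atoms = pocket_atoms,
    ligand = ligand,
    affinity_label = affinity_label
  ), class = "ComplexRecord")
}

#' @export
print.ComplexRecord <- function(x, ...) {
  cat(sprintf("<ComplexRecord %s: %d pocket residues, %d ligand atoms, label %s>\n",
              x$complex_id, nrow(x$pocket_residues), nrow(x$ligand$atoms),
              if (is.null(x$affinity_label)) "NA" else format(x$affinity_label)))
  invisible(x)
}

#' Read a PDBbind-style index file
#'
#' Lines are `<id> <resolution> <year> <-logKd/Ki> ...`; `#` starts a comment.
#'
#' @param path path to the index file.
#' @return data.frame with columns `complex_id` and `affinity`.
#' @export
read_pdbbind_index <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  out <- data.frame(complex_id = character(0), affinity = numeric(0))
  for (ln in which(keep)) {
    f <- strsplit(trimws(lines[ln]), "\\s+")[[1]]
    if (length(f) < 4L) stop(sprintf("index line %d: fewer than 4 fields", ln))
    aff <- suppressWarnings(as.numeric(f[4]))
    if (is.na(aff)) stop(sprintf("index line %d: malformed affinity field '%s'", ln, f[4]))
    out <- rbind(out, data.frame(complex_id = f[1], affinity = aff))
  }
  out
}

#' Read a pocket PDB file
#'
#' One residue per C-alpha atom; the residue representative coordinate is the
#' C-alpha position. Residues lacking a C-alpha are dropped with a warning.
#' All heavy atoms are retained in `pocket_atoms` for atom-level graph
#' construction. Secondary-structure labels come from `sse_map` when supplied
#' (named by `<chain><resnum><icode>`), otherwise every residue gets the
#' unknown class `"-"`.
#'
#' @param path path to a PDB file with ATOM records.
#' @param sse_map optional named character vector of 8-state SSE labels.
#' @return list with `pocket_residues` (data.frame `aa`,`x`,`y`,`z`,`sse`) and
#'   `pocket_atoms` (data.frame `element`,`x`,`y`,`z`,`res_index`).
#' @export
read_pocket_pdb <- function(path, sse_map = NULL) {
  stopifnot(file.exists(path))
  lines <- readLines(path, warn = FALSE)
  atom <- lines[startsWith(lines, "ATOM")]
  if (length(atom) == 0L) stop("no ATOM records in PDB file")
  fx <- function(l, a, b) trimws(substr(l, a, b))
  rec <- data.frame(
    name = fx(atom, 13, 16),
    resname = fx(atom, 18, 20),
    chain = fx(atom, 22, 22),
    resnum = fx(atom, 23, 26),
    icode = fx(atom, 27, 27),
    x = as.numeric(fx(atom, 31, 38)),
    y = as.numeric(fx(atom, 39, 46)),
    z = as.numeric(fx(atom, 47, 54)),
    element = fx(atom, 77, 78)
  )
  noel <- !nzchar(rec$element)
  rec$element[noel] <- substr(gsub("[0-9]", "", rec$name[noel]), 1, 1)
  rec <- rec[toupper(rec$element) != "H", , drop = FALSE]
  if (nrow(rec) == 0L) stop("no heavy atoms in PDB file")
  rkey <- paste(rec$chain, rec$resnum, rec$icode, sep = "|")
  # stable residue order: file order of first occurrence (PDB files list
  # residues sequentially; insertion codes follow file order)
  rlev <- unique(rkey)
  residues <- data.frame(aa = character(0), x = numeric(0), y = numeric(0),
                         z = numeric(0), sse = character(0))
  res_of_key <- integer(0)
  dropped <- character(0)
  for (k in rlev) {
    rows <- rec[rkey == k, , drop = FALSE]
    ca <- rows[rows$name == "CA", , drop = FALSE]
    if (nrow(ca) == 0L) { dropped <- c(dropped, k); next }
    aa <- AA3TO1[rows$resname[1]]
    if (is.na(aa)) aa <- "X"
    lbl <- "-"
    if (!is.null(sse_map)) {
      mk <- paste0(rec$chain[rkey == k][1], trimws(rows$resnum[1]), rows$icode[1])
      if (mk %in% names(sse_map)) lbl <- sse_map[[mk]]
    }
    residues <- rbind(residues, data.frame(
      aa = unname(aa), x = ca$x[1], y = ca$y[1], z = ca$z[1], sse = lbl))
    res_of_key[k] <- nrow(residues)
  }
  if (length(dropped) > 0L) {
    warning(sprintf("dropped %d residue(s) lacking a C-alpha atom", length(dropped)))
  }
  if (nrow(residues) == 0L) stop("no residues with C-alpha atoms")
  keepat <- rkey %in% names(res_of_key)
  atoms <- data.frame(
    element = toupper(substr(rec$element[keepat], 1, 1)),
    x = rec$x[keepat], y = rec$y[keepat], z = rec$z[keepat],
    res_index = as.integer(res_of_key[rkey[keepat]])
  )
  list(pocket_residues = residues, pocket_atoms = atoms)
}

#' Read a ligand structure file (SDF/MOL V2000 or MOL2)
#'
#' Hydrogens are stripped; heavy atoms, bonds, 3-D coordinates and a
#' generated SMILES are returned.
#'
#' @param path path to a `.sdf`, `.mol` or `.mol2` file.
#' @return a [ligand_molecule()].
#' @export
read_ligand_file <- function(path) {
  stopifnot(file.exists(path))
  if (grepl("\\.mol2$", path, ignore.case = TRUE)) {
    read_mol2(path)
  } else {
    read_sdf(path)
  }
}

read_sdf <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 4L) stop("truncated SDF file")
  counts <- lines[4]
  na <- suppressWarnings(as.integer(substr(counts, 1, 3)))
  nb <- suppressWarnings(as.integer(substr(counts, 4, 6)))
  if (is.na(na) || is.na(nb) || na < 1L) stop("malformed SDF counts line")
  if (length(lines) < 4L + na + nb) stop("SDF atom/bond block truncated")
  ablock <- lines[5:(4 + na)]
  atoms <- suppressWarnings(data.frame(
    element = trimws(substr(ablock, 32, 34)),
    charge = 0L,
    x = as.numeric(substr(ablock, 1, 10)),
    y = as.numeric(substr(ablock, 11, 20)),
    z = as.numeric(substr(ablock, 21, 30))
  ))
  if (any(is.na(atoms$x) | is.na(atoms$y) | is.na(atoms$z))) {
    stop("SDF coordinates missing or malformed")
  }
  bonds <- if (nb > 0L) {
    bblock <- lines[(5 + na):(4 + na + nb)]
    data.frame(
      i = as.integer(substr(bblock, 1, 3)),
      j = as.integer(substr(bblock, 4, 6)),
      order = as.integer(substr(bblock, 7, 9))
    )
  } else data.frame(i = integer(0), j = integer(0), order = integer(0))
  # M  CHG lines override charges
  for (ln in grep("^M  CHG", lines, value = TRUE)) {
    f <- as.integer(strsplit(trimws(sub("^M  CHG", "", ln)), "\\s+")[[1]])
    npairs <- f[1]
    for (p in seq_len(npairs)) {
      atoms$charge[f[2 * p]] <- f[2 * p + 1]
    }
  }
  strip_hydrogens(atoms, bonds)
}

read_mol2 <- function(path) {
  lines <- readLines(path, warn = FALSE)
  ai <- grep("^@<TRIPOS>ATOM", lines)
  bi <- grep("^@<TRIPOS>BOND", lines)
  if (length(ai) == 0L) stop("mol2 file lacks ATOM section")
  sec_end <- function(start) {
    nxt <- grep("^@<TRIPOS>", lines)
    nxt <- nxt[nxt > start]
    if (length(nxt) == 0L) length(lines) else min(nxt) - 1L
  }
  arows <- lines[(ai[1] + 1L):sec_end(ai[1])]
  arows <- arows[nzchar(trimws(arows))]
  af <- do.call(rbind, strsplit(trimws(arows), "\\s+"))
  if (ncol(af) < 6L) stop("malformed mol2 ATOM section")
  atoms <- data.frame(
    element = sub("\\..*$", "", af[, 6]),
    charge = if (ncol(af) >= 9L) as.integer(round(as.numeric(af[, 9]))) else 0L,
    x = as.numeric(af[, 3]), y = as.numeric(af[, 4]), z = as.numeric(af[, 5])
  )
  if (any(!is.finite(atoms$x))) stop("malformed mol2 coordinates")
  bonds <- data.frame(i = integer(0), j = integer(0), order = integer(0))
  if (length(bi) > 0L) {
    brows <- lines[(bi[1] + 1L):sec_end(bi[1])]
    brows <- brows[nzchar(trimws(brows))]
    if (length(brows) > 0L) {
      bf <- do.call(rbind, strsplit(trimws(brows), "\\s+"))
      ord <- bf[, 4]
      bonds <- data.frame(
        i = as.integer(bf[, 2]), j = as.integer(bf[, 3]),
        order = ifelse(ord == "ar", 4L, ifelse(ord == "am", 1L,
                       suppressWarnings(as.integer(ord))))
      )
      if (any(is.na(bonds$order))) bonds$order[is.na(bonds$order)] <- 1L
    }
  }
  strip_hydrogens(atoms, bonds)
}

strip_hydrogens <- function(atoms, bonds) {
  heavy <- toupper(atoms$element) != "H"
  if (!any(heavy)) stop("molecule has zero heavy atoms")
  remap <- cumsum(heavy)
  keepb <- heavy[bonds$i] & heavy[bonds$j]
  bonds <- bonds[keepb, , drop = FALSE]
  bonds$i <- remap[bonds$i]
  bonds$j <- remap[bonds$j]
  ligand_molecule(atoms[heavy, , drop = FALSE], bonds)
}

#' Write predictions to CSV
#'
#' @param predictions data.frame with columns `complex_id` and `prediction`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_predictions <- function(predictions, path) {
  stopifnot(all(c("complex_id", "prediction") %in% names(predictions)))
  utils::write.csv(predictions[, c("complex_id", "prediction")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a prediction CSV written by [write_predictions()]
#' @param path path to the CSV.
#' @return data.frame with columns `complex_id` and `prediction`.
#' @export
read_predictions <- function(path) {
  stopifnot(file.exists(path))
  utils::read.csv(path, colClasses = c(complex_id = "character",
                                       prediction = "numeric"))
}
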