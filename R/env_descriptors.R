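# Global biochemical indicators of the protein and ligand, packed into the
# 3 x 5 environment-node feature matrix carried by the complex graph.

# ionizable-group pKa values (Lehninger): used for both net charge and pI
PKA_TABLE <- list(
  nterm = 9.69, cterm = 2.34,
  positive = c(K = 10.53, R = 12.48, H = 6.00),
  negative = c(D = 3.86, E = 4.25, C = 8.33, Y = 10.07)
)

# Henderson-Hasselbalch net charge of a sequence at a given pH
protein_net_charge <- function(seq, ph) {
  aa <- strsplit(toupper(seq), "")[[1]]
  pos_q <- function(pka) 1 / (1 + 10^(ph - pka))
  neg_q <- function(pka) -1 / (1 + 10^(pka - ph))
  q <- pos_q(PKA_TABLE$nterm) + neg_q(PKA_TABLE$cterm)
  for (a in names(PKA_TABLE$positive)) {
    q <- q + sum(aa == a) * pos_q(PKA_TABLE$positive[[a]])
  }
  for (a in names(PKA_TABLE$negative)) {
    q <- q + sum(aa == a) * neg_q(PKA_TABLE$negative[[a]])
  }
  q
}

# isoelectric point by bisection on the monotone net-charge curve
protein_pi <- function(seq, tol = 1e-4) {
  lo <- 0; hi <- 14
  for (it in seq_len(100L)) {
    mid <- (lo + hi) / 2
    if (protein_net_charge(seq, mid) > 0) lo <- mid else hi <- mid
    if (hi - lo < tol) break
  }
  (lo + hi) / 2
}

#' Protein-side biochemical indicators
#'
#' Five sequence-level descriptors: isoelectric point (bisection on the
#' Henderson-Hasselbalch net-charge curve with a standard pKa table), GRAVY
#' (mean Kyte-Doolittle hydropathy), net charge at pH 7, and total side-chain
#' H-bond donor/acceptor group counts.
#'
#' @param seq amino-acid string (1-letter codes; unknown letters contribute
#'   nothing to composition-based terms).
#' @return list with `isoelectric_point`, `hydropathy_index`,
#'   `net_charge_pH7`, `hbd_count`, `hba_count`, `length`.
#' @export
protein_indicators <- function(seq) {
  if (!nzchar(seq)) stop("empty protein sequence")
  aa <- strsplit(toupper(seq), "")[[1]]
  known <- aa[aa %in% rownames(RESIDUE_PROPS)]
  gravy <- if (length(known) > 0L) mean(RESIDUE_PROPS[known, "hydro"]) else 0
  list(
    isoelectric_point = protein_pi(seq),
    hydropathy_index = gravy,
    net_charge_pH7 = protein_net_charge(seq, 7),
    hbd_count = if (length(known) > 0L) sum(RESIDUE_PROPS[known, "hbd"]) else 0,
    hba_count = if (length(known) > 0L) sum(RESIDUE_PROPS[known, "hba"]) else 0,
    length = length(aa)
  )
}

#' Ligand-side biochemical indicators
#'
#' Six molecule-level descriptors: aromatic ring count, rotatable-bond count
#' (non-ring single bonds between non-terminal heavy atoms, amide C-N
#' excluded), Ertl TPSA, Wildman-Crippen-style logP, net formal charge, and
#' Lipinski H-bond donor/acceptor counts.
#'
#' @param mol a `LigandMolecule`.
#' @return list with `aromatic_ring_count`, `rotatable_bond_count`, `tpsa`,
#'   `logp`, `formal_charge`, `hbd_count`, `hba_count`.
#' @export
ligand_indicators <- function(mol) {
  stopifnot(inherits(mol, "LigandMolecule"))
  list(
    aromatic_ring_count = aromatic_ring_count(mol),
    rotatable_bond_count = rotatable_bond_count(mol),
    tpsa = ertl_tpsa(mol),
    logp = crippen_logp(mol),
    formal_charge = sum(mol$atoms$charge),
    hbd_count = lipinski_hbd(mol),
    hba_count = lipinski_hba(mol)
  )
}

#' All 11 biochemical indicators for a complex
#'
#' @param record a `ComplexRecord`.
#' @param scale if `TRUE` (default), min-max scale every indicator to `[0, 1]`
#'   using the documented `ENV_SCALING` constants (per-residue normalisation
#'   for the protein charge and H-bond counts), so the environment-node matrix
#'   carries comparable magnitudes.
#' @return list with `protein` ([protein_indicators()] of the full protein
#'   sequence) and `ligand` ([ligand_indicators()]).
#' @export
biochemical_indicators <- function(record, scale = TRUE) {
  stopifnot(inherits(record, "ComplexRecord"))
  ind <- list(protein = protein_indicators(record$protein_seq),
              ligand = ligand_indicators(record$ligand))
  if (scale) scale_indicators(ind) else ind
}

#' Min-max scale a raw indicator set
#'
#' @param ind raw output of [protein_indicators()] / [ligand_indicators()]
#'   combined as `list(protein = ..., ligand = ...)`.
#' @return the same structure with every indicator mapped into `[0, 1]`.
#' @export
scale_indicators <- function(ind) {
  p <- ind$protein
  l <- ind$ligand
  len <- max(1, p$length)
  list(
    protein = list(
      isoelectric_point = env_scale(p$isoelectric_point, "pi"),
      hydropathy_index = env_scale(p$hydropathy_index, "gravy"),
      net_charge_pH7 = env_scale(p$net_charge_pH7 / len, "charge_per_res"),
      hbd_count = env_scale(p$hbd_count / len, "hbd_per_res"),
      hba_count = env_scale(p$hba_count / len, "hba_per_res"),
      length = p$length
    ),
    ligand = list(
      aromatic_ring_count = env_scale(l$aromatic_ring_count, "aromatic_rings"),
      rotatable_bond_count = env_scale(l$rotatable_bond_count, "rotatable"),
      tpsa = env_scale(l$tpsa, "tpsa"),
      logp = env_scale(l$logp, "logp"),
      formal_charge = env_scale(l$formal_charge, "ligand_charge"),
      hbd_count = env_scale(l$hbd_count, "ligand_hbd"),
      hba_count = env_scale(l$hba_count, "ligand_hba")
    )
  )
}

# documented scaling constants mapping each indicator to roughly [0, 1]:
# value_scaled = clip((value - lo) / (hi - lo), 0, 1). Per-residue H-bond
# counts are normalised by sequence length before scaling.
ENV_SCALING <- list(
  pi = c(0, 14), gravy = c(-4.5, 4.5), charge_per_res = c(-0.5, 0.5),
  hbd_per_res = c(0, 4), hba_per_res = c(0, 2),
  aromatic_rings = c(0, 5), rotatable = c(0, 15), tpsa = c(0, 200),
  logp = c(-5, 10), ligand_charge = c(-3, 3), ligand_hbd = c(0, 10),
  ligand_hba = c(0, 15)
)

env_scale <- function(x, key) {
  rg <- ENV_SCALING[[key]]
  min(1, max(0, (x - rg[1]) / (rg[2] - rg[1])))
}

#' Assemble the 3 x 5 environment-node feature matrix
#'
#' A pure, deterministic packing of the 11 indicators into 15 slots (4 are
#' structurally zero). Row 1 (protein environment) = (pI, GRAVY, net charge,
#' HBD, HBA); row 2 (ligand environment) = (aromatic rings, rotatable bonds,
#' TPSA, logP, 0); row 3 (shared environment) = (ligand HBD, ligand HBA, 0,
#' 0, 0). Charge enters once (the protein net charge at pH 7); the ligand
#' formal charge is still computed by [ligand_indicators()] but is not a
#' matrix slot, keeping the indicator count at exactly 11. The values are
#' packed exactly as given; pass the scaled indicators from
#' [biochemical_indicators()] for comparable magnitudes.
#'
#' @param ind output of [biochemical_indicators()] (or any list with the same
#'   `protein`/`ligand` indicator names).
#' @return object of class `EnvNodeMatrix`: a 3 x 5 numeric matrix with a
#'   `node_roles` attribute.
#' @export
assemble_env_nodes <- function(ind) {
  p <- ind$protein
  l <- ind$ligand
  m <- rbind(
    c(p$isoelectric_point, p$hydropathy_index, p$net_charge_pH7,
      p$hbd_count, p$hba_count),
    c(l$aromatic_ring_count, l$rotatable_bond_count, l$tpsa, l$logp, 0),
    c(l$hbd_count, l$hba_count, 0, 0, 0)
  )
  structure(m, class = c("EnvNodeMatrix", class(m)),
            node_roles = c("protein_env", "ligand_env", "shared_env"))
}
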