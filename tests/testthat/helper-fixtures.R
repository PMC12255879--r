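# Shared fixtures: known molecules, a toy complex, and small model configs.
# Everything is built in code; no binary data.

fix_benzene <- function() {
  ligand_molecule(
    data.frame(element = rep("C", 6), charge = 0L,
               x = cos(2 * pi * (0:5) / 6) * 1.39,
               y = sin(2 * pi * (0:5) / 6) * 1.39, z = 0),
    data.frame(i = 1:6, j = c(2:6, 1), order = c(1L, 2L, 1L, 2L, 1L, 2L))
  )
}

fix_ethanol <- function() {
  ligand_molecule(
    data.frame(element = c("C", "C", "O"), charge = 0L,
               x = c(0, 1.5, 2.2), y = c(0, 0, 1.0), z = 0),
    data.frame(i = c(1, 2), j = c(2, 3), order = 1L)
  )
}

fix_butane <- function() {
  ligand_molecule(
    data.frame(element = rep("C", 4), charge = 0L, x = (0:3) * 1.5, y = 0, z = 0),
    data.frame(i = 1:3, j = 2:4, order = 1L)
  )
}

fix_acetamide <- function() {
  ligand_molecule(
    data.frame(element = c("C", "C", "O", "N"), charge = 0L,
               x = c(0, 1.5, 2.2, 2.2), y = c(0, 0, 1, -1), z = 0),
    data.frame(i = c(1, 2, 2), j = c(2, 3, 4), order = c(1L, 2L, 1L))
  )
}

# small complex with a known geometry; ligand sits 3-4 A from the pocket
fix_record <- function(seed = 42L) {
  set.seed(seed)
  lig <- ligand_molecule(
    data.frame(element = c("C", "C", "O", "N", "C"), charge = 0L,
               x = c(0, 1.5, 2.2, 2.2, -1.5), y = c(0, 0, 1, -1, 0.5),
               z = c(0, 0, 0, 0, 0.3)),
    data.frame(i = c(1, 2, 2, 1), j = c(2, 3, 4, 5), order = c(1L, 2L, 1L, 1L))
  )
  res <- data.frame(aa = c("G", "A", "K", "F", "D", "S"),
                    x = c(0, 4, 8, 2, 5, 3), y = c(3, 1, 0, 3, 4, -2),
                    z = c(1, 0, 2, 1, 0, 1),
                    sse = c("H", "H", "-", "E", "T", "S"))
  complex_record("fix1", "GAKFDSLMNPQW", res, lig, affinity_label = 5.2)
}

fix_cfg <- function(h = 8L) model_config(hidden_dim = h)

# apply a random rigid motion to all coordinates of a record
rigid_motion <- function(rec) {
  th <- stats::runif(3, 0, 2 * pi)
  shift <- stats::rnorm(3, 0, 15)
  Rx <- matrix(c(1, 0, 0, 0, cos(th[1]), -sin(th[1]), 0, sin(th[1]), cos(th[1])), 3, byrow = TRUE)
  Ry <- matrix(c(cos(th[2]), 0, sin(th[2]), 0, 1, 0, -sin(th[2]), 0, cos(th[2])), 3, byrow = TRUE)
  Rz <- matrix(c(cos(th[3]), -sin(th[3]), 0, sin(th[3]), cos(th[3]), 0, 0, 0, 1), 3, byrow = TRUE)
  R <- Rx %*% Ry %*% Rz
  tx <- function(df) {
    m <- as.matrix(df[, c("x", "y", "z")]) %*% t(R)
    sweep(m, 2L, shift, "+")
  }
  r2 <- rec
  r2$pocket_residues[, c("x", "y", "z")] <- tx(rec$pocket_residues)
  r2$pocket_atoms[, c("x", "y", "z")] <- tx(rec$pocket_atoms)
  r2$ligand$atoms[, c("x", "y", "z")] <- tx(rec$ligand$atoms)
  r2
}

# finite-difference gradient of a scalar-valued forward closure
numeric_grad <- function(fun, P, eps = 1e-6) {
  num <- array(0, dim(P))
  for (i in seq_len(nrow(P))) {
    for (j in seq_len(ncol(P))) {
      Pp <- P; Pp[i, j] <- Pp[i, j] + eps
      Pm <- P; Pm[i, j] <- Pm[i, j] - eps
      num[i, j] <- (fun(Pp) - fun(Pm)) / (2 * eps)
    }
  }
  num
}
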