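# Shared fixtures and independent oracles used across the test files.
# Oracles are deliberately implemented with different math than the code
# they check.

# independent dihedral: angle between the two plane normals, signed by the
# central bond direction
oracle_dihedral <- function(p1, p2, p3, p4) {
  n1 <- pracma_cross(p2 - p1, p3 - p2)
  n2 <- pracma_cross(p3 - p2, p4 - p3)
  b <- (p3 - p2) / sqrt(sum((p3 - p2)^2))
  cosang <- sum(n1 * n2) / sqrt(sum(n1^2) * sum(n2^2))
  cosang <- max(-1, min(1, cosang))
  ang <- acos(cosang) * 180 / pi
  # IUPAC sign: positive when n1 x n2 opposes the central bond direction
  if (sum(pracma_cross(n1, n2) * b) > 0) ang <- -ang
  ang
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# build the standard two-spectrum noiseless scenario used by several files
noiseless_scenario <- function(preset = "hairpin12", seed = 7) {
  make_scenario(preset, seed = seed,
                spectra = list(noesy_spec("noesyN", C = 64 * 4^6, sigma = 0,
                                          class = "N"),
                               noesy_spec("noesyC", C = 40 * 4^6, sigma = 0,
                                          class = "C")))
}

# assignment + exact-C calibration of a scenario into one restraint set
scenario_restraints <- function(sc, d_min = 1.0, d_max = 10.0) {
  sets <- list()
  offset <- 0L
  for (sp in sc$spectra) {
    cand <- match_assignments(sc$peaks[[sp$id]], sc$shifts)
    rs <- calibrate(cand, calibration_model(sp$id, sp$C, d_min, d_max))
    if (nrow(rs)) rs$group <- rs$group + offset
    offset <- offset + length(unique(rs$group))
    sets[[sp$id]] <- rs
  }
  out <- do.call(rbind, unname(sets))
  class(out) <- c("restraint_set", "data.frame")
  out
}

# small single-group restraint between two named atoms
simple_restraint <- function(res_i, atom_i, res_j, atom_j, upper,
                             lower = 1.0, group = 1L) {
  out <- data.frame(group = group, res_i = res_i, restype_i = "XXX",
                    atom_i = atom_i, res_j = res_j, restype_j = "XXX",
                    atom_j = atom_j, upper = upper, lower = lower,
                    stringsAsFactors = FALSE)
  class(out) <- c("restraint_set", "data.frame")
  out
}

backbone_rmsd <- function(a, b) {
  kabsch_superpose(a, b, select_atoms(a, "backbone"))$rmsd
}
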