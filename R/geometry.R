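# Residue geometry templates: idealized internal coordinates for building
# polypeptides in torsion space.  Each atom is defined by a bonding parent c,
# two further reference atoms b and a, a bond length (Angstrom), a bond angle
# b-c-d (degrees), and an a-b-c-d dihedral (degrees) that is either fixed or
# tied to a named rotatable torsion (phi, psi, chi1, chi2) plus an offset.
# Reference names prefixed "-" resolve to the previous residue.  The peptide
# bond omega is fixed at 180 degrees (trans); side chains are rotatable up to
# chi2, with more distal torsions frozen at anti (180 degree) values.

.row <- function(name, c, b, a, bond, ang, tor, dof = "") {
  data.frame(name = name, refC = c, refB = b, refA = a, bond = bond,
             angle = ang, tor = tor, dof = dof, stringsAsFactors = FALSE)
}

# L-alpha chirality constants: dihedral(C, N, CA, CB) and (C, N, CA, HA).
.TOR_CB <- 122.5
.TOR_HA <- -119.0

.bb_rows <- function(has_h = TRUE) {
  rows <- rbind(
    .row("N",  "-C", "-CA", "-N", 1.329, 116.2, 0,   "psi-"),
    .row("CA", "N",  "-C",  "-CA", 1.458, 121.7, 180, ""),
    .row("C",  "CA", "N",   "-C", 1.525, 111.2, 0,   "phi"),
    .row("O",  "C",  "CA",  "N",  1.231, 120.8, 180, "psi"))
  if (has_h)
    rows <- rbind(rows, .row("H", "N", "-C", "-CA", 1.020, 119.5, 0, ""))
  rows
}

.methyl <- function(cname, c, b, a) {
  stem <- paste0("H", substring(cname, 2))
  rbind(.row(paste0(stem, "1"), cname, c, b, 1.090, 109.5, 60, ""),
        .row(paste0(stem, "2"), cname, c, b, 1.090, 109.5, 180, ""),
        .row(paste0(stem, "3"), cname, c, b, 1.090, 109.5, -60, ""))
}

# two protons on a CH2 carbon, staggered around the continuing chain torsion
.ch2 <- function(cname, c, b, tor_next, dof) {
  stem <- paste0("H", substring(cname, 2))
  rbind(.row(paste0(stem, "2"), cname, c, b, 1.090, 109.5, tor_next + 120, dof),
        .row(paste0(stem, "3"), cname, c, b, 1.090, 109.5, tor_next - 120, dof))
}

.sc <- list()

.sc$GLY <- rbind(
  .row("HA2", "CA", "N", "C", 1.090, 109.5, .TOR_CB, ""),
  .row("HA3", "CA", "N", "C", 1.090, 109.5, .TOR_HA, ""))

.cb_ha <- rbind(
  .row("HA", "CA", "N", "C", 1.090, 109.0, .TOR_HA, ""),
  .row("CB", "CA", "N", "C", 1.530, 110.5, .TOR_CB, ""))

.sc$ALA <- rbind(.cb_ha, .methyl("CB", "CA", "N"))

.sc$SER <- rbind(.cb_ha,
  .row("OG", "CB", "CA", "N", 1.417, 110.8, 0, "chi1"),
  .ch2("CB", "CA", "N", 0, "chi1"),
  .row("HG", "OG", "CB", "CA", 0.960, 108.5, 180, ""))

.sc$CYS <- rbind(.cb_ha,
  .row("SG", "CB", "CA", "N", 1.808, 113.8, 0, "chi1"),
  .ch2("CB", "CA", "N", 0, "chi1"),
  .row("HG", "SG", "CB", "CA", 1.340, 96.0, 180, ""))

.sc$THR <- rbind(.cb_ha,
  .row("OG1", "CB", "CA", "N", 1.433, 109.6, 0, "chi1"),
  .row("CG2", "CB", "CA", "N", 1.521, 110.5, -122.3, "chi1"),
  .row("HB", "CB", "CA", "N", 1.090, 109.0, 118.0, "chi1"),
  .row("HG1", "OG1", "CB", "CA", 0.960, 108.5, 180, ""),
  .methyl("CG2", "CB", "CA"))

.sc$VAL <- rbind(.cb_ha,
  .row("CG1", "CB", "CA", "N", 1.521, 110.5, 0, "chi1"),
  .row("CG2", "CB", "CA", "N", 1.521, 110.5, -122.3, "chi1"),
  .row("HB", "CB", "CA", "N", 1.090, 109.0, 118.0, "chi1"),
  .methyl("CG1", "CB", "CA"),
  .methyl("CG2", "CB", "CA"))

.sc$LEU <- rbind(.cb_ha,
  .row("CG", "CB", "CA", "N", 1.530, 116.3, 0, "chi1"),
  .ch2("CB", "CA", "N", 0, "chi1"),
  .row("CD1", "CG", "CB", "CA", 1.521, 110.7, 0, "chi2"),
  .row("CD2", "CG", "CB", "CA", 1.521, 110.7, 122.3, "chi2"),
  .row("HG", "CG", "CB", "CA", 1.090, 109.0, -118.0, "chi2"),
  .methyl("CD1", "CG", "CB"),
  .methyl("CD2", "CG", "CB"))

.sc$ILE <- rbind(.cb_ha,
  .row("CG1", "CB", "CA", "N", 1.530, 110.4, 0, "chi1"),
  .row("CG2", "CB", "CA", "N", 1.521, 110.5, -122.3, "chi1"),
  .row("HB", "CB", "CA", "N", 1.090, 109.0, 118.0, "chi1"),
  .row("CD1", "CG1", "CB", "CA", 1.513, 113.8, 0, "chi2"),
  .ch2("CG1", "CB", "CA", 0, "chi2"),
  .methyl("CG2", "CB", "CA"),
  .methyl("CD1", "CG1", "CB"))

.sc$MET <- rbind(.cb_ha,
  .row("CG", "CB", "CA", "N", 1.520, 114.1, 0, "chi1"),
  .ch2("CB", "CA", "N", 0, "chi1"),
  .row("SD", "CG", "CB", "CA", 1.803, 112.7, 0, "chi2"),
  .ch2("CG", "CB", "CA", 0, "chi2"),
  .row("CE", "SD", "CG", "CB", 1.791, 100.9, 180, ""),
  .methyl("CE", "SD", "CG"))

.sc$LYS <- rbind(.cb_ha,
  .row("CG", "CB", "CA", "N", 1.520, 114.1, 0, "chi1"),
  .ch2("CB", "CA", "N", 0, "chi1"),
  .row("CD", "CG", "CB", "CA", 1.520, 111.3, 0, "chi2"),
  .ch2("CG", "CB", "CA", 0, "chi2"),
  .row("CE", "CD", "CG", "CB", 1.520, 111.3, 180, ""),
  .ch2("CD", "CG", "CB", 180, ""),
  .row("NZ", "CE", "CD", "CG", 1.489, 111.9, 180, ""),
  .ch2("CE", "CD", "CG", 180, ""),
  .methyl("NZ", "CE", "CD"))

.sc$ARG <- rbind(.cb_ha,
  .row("CG", "CB", "CA", "N", 1.520, 114.1, 0, "chi1"),
  .ch2("CB", "CA", "N", 0, "chi1"),
  .row("CD", "CG", "CB", "CA", 1.520, 111.3, 0, "chi2"),
  .ch2("CG", "CB", "CA", 0, "chi2"),
  .row("NE", "CD", "CG", "CB", 1.460, 111.5, 180, ""),
  .ch2("CD", "CG", "CB", 180, ""),
  .row("CZ", "NE", "CD", "CG", 1.330, 124.0, 180, ""),
  .row("HE", "NE", "CD", "CG", 1.020, 118.0, 0, ""),
  .row("NH1", "CZ", "NE", "CD", 1.330, 120.0, 0, ""),
  .row("NH2", "CZ", "NE", "CD", 1.330, 120.0, 180, ""))

.sc$ASP <- rbind(.cb_ha,
  .row("CG", "CB", "CA", "N", 1.516, 112.6, 0, "chi1"),
  .ch2("CB", "CA", "N", 0, "chi1"),
  .row("OD1", "CG", "CB", "CA", 1.249, 118.4, 0, "chi2"),
  .row("OD2", "CG", "CB", "CA", 1.249, 118.4, 180, "chi2"))

.sc$ASN <- rbind(.cb_ha,
  .row("CG", "CB", "CA", "N", 1.516, 112.6, 0, "chi1"),
  .ch2("CB", "CA", "N", 0, "chi1"),
  .row("OD1", "CG", "CB", "CA", 1.231, 120.8, 0, "chi2"),
  .row("ND2", "CG", "CB", "CA", 1.328, 116.4, 180, "chi2"),
  .row("HD21", "ND2", "CG", "CB", 1.020, 120.0, 0, ""),
  .row("HD22", "ND2", "CG", "CB", 1.020, 120.0, 180, ""))

.sc$GLU <- rbind(.cb_ha,
  .row("CG", "CB", "CA", "N", 1.520, 114.1, 0, "chi1"),
  .ch2("CB", "CA", "N", 0, "chi1"),
  .row("CD", "CG", "CB", "CA", 1.516, 112.6, 0, "chi2"),
  .ch2("CG", "CB", "CA", 0, "chi2"),
  .row("OE1", "CD", "CG", "CB", 1.249, 118.4, 0, ""),
  .row("OE2", "CD", "CG", "CB", 1.249, 118.4, 180, ""))

.sc$GLN <- rbind(.cb_ha,
  .row("CG", "CB", "CA", "N", 1.520, 114.1, 0, "chi1"),
  .ch2("CB", "CA", "N", 0, "chi1"),
  .row("CD", "CG", "CB", "CA", 1.516, 112.6, 0, "chi2"),
  .ch2("CG", "CB", "CA", 0, "chi2"),
  .row("OE1", "CD", "CG", "CB", 1.231, 120.8, 0, ""),
  .row("NE2", "CD", "CG", "CB", 1.328, 116.4, 180, ""),
  .row("HE21", "NE2", "CD", "CG", 1.020, 120.0, 0, ""),
  .row("HE22", "NE2", "CD", "CG", 1.020, 120.0, 180, ""))

.sc$HIS <- rbind(.cb_ha,
  .row("CG", "CB", "CA", "N", 1.497, 113.8, 0, "chi1"),
  .ch2("CB", "CA", "N", 0, "chi1"),
  .row("ND1", "CG", "CB", "CA", 1.378, 122.7, 0, "chi2"),
  .row("CD2", "CG", "CB", "CA", 1.356, 131.2, 180, "chi2"),
  .row("CE1", "ND1", "CG", "CB", 1.321, 109.0, 180, ""),
  .row("NE2", "CD2", "CG", "CB", 1.373, 107.0, 180, ""),
  .row("HD1", "ND1", "CG", "CB", 1.020, 126.0, 0, ""),
  .row("HD2", "CD2", "CG", "CB", 1.080, 126.4, 0, ""),
  .row("HE1", "CE1", "ND1", "CG", 1.080, 125.5, 180, ""))

.ring6 <- function() rbind(
  .row("CD1", "CG", "CB", "CA", 1.390, 120.8, 0, "chi2"),
  .row("CD2", "CG", "CB", "CA", 1.390, 120.8, 180, "chi2"),
  .row("CE1", "CD1", "CG", "CB", 1.390, 120.0, 180, ""),
  .row("CE2", "CD2", "CG", "CB", 1.390, 120.0, 180, ""),
  .row("CZ", "CE1", "CD1", "CG", 1.390, 120.0, 0, ""),
  .row("HD1", "CD1", "CG", "CB", 1.080, 120.0, 0, ""),
  .row("HD2", "CD2", "CG", "CB", 1.080, 120.0, 0, ""),
  .row("HE1", "CE1", "CD1", "CG", 1.080, 120.0, 180, ""),
  .row("HE2", "CE2", "CD2", "CG", 1.080, 120.0, 180, ""))

.sc$PHE <- rbind(.cb_ha,
  .row("CG", "CB", "CA", "N", 1.508, 113.8, 0, "chi1"),
  .ch2("CB", "CA", "N", 0, "chi1"),
  .ring6(),
  .row("HZ", "CZ", "CE1", "CD1", 1.080, 120.0, 180, ""))

.sc$TYR <- rbind(.cb_ha,
  .row("CG", "CB", "CA", "N", 1.512, 113.8, 0, "chi1"),
  .ch2("CB", "CA", "N", 0, "chi1"),
  .ring6(),
  .row("OH", "CZ", "CE1", "CD1", 1.376, 119.9, 180, ""),
  .row("HH", "OH", "CZ", "CE1", 0.960, 109.0, 180, ""))

.sc$TRP <- rbind(.cb_ha,
  .row("CG", "CB", "CA", "N", 1.498, 113.6, 0, "chi1"),
  .ch2("CB", "CA", "N", 0, "chi1"),
  .row("CD1", "CG", "CB", "CA", 1.365, 126.9, 0, "chi2"),
  .row("CD2", "CG", "CB", "CA", 1.433, 126.6, 180, "chi2"),
  .row("NE1", "CD1", "CG", "CB", 1.374, 110.1, 180, ""),
  .row("CE2", "CD2", "CG", "CB", 1.409, 107.3, 180, ""),
  .row("CE3", "CD2", "CG", "CB", 1.398, 133.9, 0, ""),
  .row("CZ2", "CE2", "CD2", "CG", 1.394, 122.4, 180, ""),
  .row("CZ3", "CE3", "CD2", "CG", 1.382, 118.8, 180, ""),
  .row("CH2", "CZ3", "CE3", "CD2", 1.368, 121.1, 0, ""),
  .row("HD1", "CD1", "CG", "CB", 1.080, 125.0, 0, ""),
  .row("HE1", "NE1", "CD1", "CG", 1.020, 125.0, 180, ""),
  .row("HE3", "CE3", "CD2", "CG", 1.080, 120.0, 180, ""),
  .row("HZ2", "CZ2", "CE2", "CD2", 1.080, 120.0, 180, ""),
  .row("HZ3", "CZ3", "CE3", "CD2", 1.080, 120.0, 180, ""),
  .row("HH2", "CH2", "CZ3", "CE3", 1.080, 120.0, 180, ""))

# Proline: ring geometry frozen near a C-gamma-endo pucker; the CD-N closure
# bond is recorded separately (see .ring_bonds) and no amide H is present.
.sc$PRO <- rbind(.cb_ha,
  .row("CG", "CB", "CA", "N", 1.495, 104.5, 28.0, ""),
  .ch2("CB", "CA", "N", 28.0, ""),
  .row("CD", "CG", "CB", "CA", 1.507, 106.1, -38.0, ""),
  .ch2("CG", "CB", "CA", -38.0, ""),
  .ch2("CD", "CG", "CB", 155.0, ""))

# ring-closure bonds absent from the parent tree (used for the nonbonded
# exclusion graph)
.ring_bonds <- list(
  PHE = list(c("CE2", "CZ")), TYR = list(c("CE2", "CZ")),
  HIS = list(c("CE1", "NE2")), PRO = list(c("CD", "N")),
  TRP = list(c("NE1", "CE2"), c("CZ2", "CH2")))

# atom that defines each measurable side-chain torsion
.chi1_atom <- c(SER = "OG", CYS = "SG", THR = "OG1", VAL = "CG1",
                ILE = "CG1", LEU = "CG", MET = "CG", LYS = "CG", ARG = "CG",
                ASP = "CG", ASN = "CG", GLU = "CG", GLN = "CG", HIS = "CG",
                PHE = "CG", TYR = "CG", TRP = "CG")
.chi2_atom <- c(LEU = "CD1", ILE = "CD1", MET = "SD", LYS = "CD",
                ARG = "CD", ASP = "OD1", ASN = "OD1", GLU = "CD",
                GLN = "CD", HIS = "ND1", PHE = "CD1", TYR = "CD1",
                TRP = "CD1")

.aa1to3 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS",
             Q = "GLN", E = "GLU", G = "GLY", H = "HIS", I = "ILE",
             L = "LEU", K = "LYS", M = "MET", F = "PHE", P = "PRO",
             S = "SER", T = "THR", V = "VAL", W = "TRP", Y = "TYR")

#' Residue geometry table
#'
#' Returns the internal-coordinate template for one residue type: one row per
#' atom with its three reference atoms, bond length (Angstrom), bond angle and
#' dihedral (degrees), and the rotatable torsion (if any) the dihedral is tied
#' to.
#'
#' @param res_type three-letter residue code (one-letter codes are accepted).
#' @return a data.frame with columns \code{name, refC, refB, refA, bond,
#'   angle, tor, dof}.
#' @export
geometry_template <- function(res_type) {
  res_type <- normalize_res_type(res_type)
  rbind(.bb_rows(has_h = res_type != "PRO"), .sc[[res_type]])
}

#' @rdname geometry_template
#' @export
residue_types <- function() names(.sc)

normalize_res_type <- function(res_type) {
  res_type <- toupper(res_type)
  if (nchar(res_type) == 1) {
    if (!res_type %in% names(.aa1to3))
      stop("unknown residue type: ", res_type)
    res_type <- .aa1to3[[res_type]]
  }
  if (!res_type %in% names(.sc))
    stop("unknown residue type: ", res_type)
  res_type
}

#' Expand a sequence into three-letter residue codes
#'
#' @param sequence character vector of three-letter codes, or a single string
#'   of one-letter codes.
#' @export
as_residue_codes <- function(sequence) {
  if (length(sequence) == 1 && nchar(sequence) > 3 ||
      (length(sequence) == 1 && nchar(sequence) <= 3 &&
       !toupper(sequence) %in% names(.sc)))
    sequence <- strsplit(sequence, "")[[1]]
  vapply(sequence, normalize_res_type, character(1), USE.NAMES = FALSE)
}

#' Names of the rotatable torsions of a sequence
#'
#' Torsions are ordered residue by residue as phi (absent for the first
#' residue), psi, chi1, chi2.
#'
#' @inheritParams as_residue_codes
#' @return character vector like \code{c("psi_1", "chi1_1", "phi_2", ...)}.
#' @export
torsion_names <- function(sequence) {
  seq3 <- as_residue_codes(sequence)
  out <- character(0)
  for (i in seq_along(seq3)) {
    nm <- character(0)
    if (i > 1) nm <- "phi"
    nm <- c(nm, "psi")
    if (seq3[i] %in% names(.chi1_atom)) nm <- c(nm, "chi1")
    if (seq3[i] %in% names(.chi2_atom)) nm <- c(nm, "chi2")
    out <- c(out, paste0(nm, "_", i))
  }
  out
}

# Compile a sequence into the flat atom plan consumed by the C++ builder.
# Cached per sequence within a session.
.plan_cache <- new.env(parent = emptyenv())

atom_plan <- function(sequence) {
  seq3 <- as_residue_codes(sequence)
  key <- paste(seq3, collapse = ".")
  if (!is.null(.plan_cache[[key]])) return(.plan_cache[[key]])

  dof_names <- torsion_names(seq3)
  dof_index <- stats::setNames(seq_along(dof_names) - 1L, dof_names)

  name <- resno <- resname <- character(0)
  refA <- refB <- refC <- dof <- integer(0)
  bond <- angle <- tor <- numeric(0)
  lookup <- new.env(parent = emptyenv())  # "resno:name" -> 0-based index

  idx_of <- function(i, nm) {
    v <- lookup[[paste0(i, ":", nm)]]
    if (is.null(v)) stop("atom plan reference not found: residue ", i,
                         " atom ", nm)
    v
  }

  n_atoms <- 0L
  for (i in seq_along(seq3)) {
    tpl <- geometry_template(seq3[i])
    for (r in seq_len(nrow(tpl))) {
      a <- tpl[r, ]
      resolve <- function(nm) {
        if (startsWith(nm, "-")) {
          if (i == 1) return(NA_integer_)
          idx_of(i - 1L, substring(nm, 2))
        } else idx_of(i, nm)
      }
      iC <- resolve(a$refC); iB <- resolve(a$refB); iA <- resolve(a$refA)
      di <- -1L
      t0 <- a$tor
      if (nzchar(a$dof)) {
        dn <- if (a$dof == "psi-") {
          if (i > 1) paste0("psi_", i - 1) else NA_character_
        } else paste0(a$dof, "_", i)
        if (!is.na(dn) && dn %in% names(dof_index)) di <- dof_index[[dn]]
      }
      if (is.na(iC)) {  # first residue seed atoms and N-terminal fixups
        if (a$name == "N") { iC <- -1L; iB <- -1L; iA <- -1L }
        else if (a$name == "CA") { iC <- idx_of(1L, "N"); iB <- -1L; iA <- -1L }
        else if (a$name == "H") {
          iC <- idx_of(1L, "N"); iB <- idx_of(1L, "CA"); iA <- idx_of(1L, "C")
          t0 <- 180; di <- -1L
        } else stop("unresolvable reference for ", a$name, " in residue 1")
      } else if (is.na(iB)) {  # CA of residue 1
        iB <- -1L; iA <- -1L; t0 <- 0; di <- -1L
      } else if (is.na(iA)) {  # C of residue 1: seed the xy-plane
        iA <- -1L; t0 <- 0; di <- -1L
      }
      n_atoms <- n_atoms + 1L
      lookup[[paste0(i, ":", a$name)]] <- n_atoms - 1L
      name <- c(name, a$name); resno <- c(resno, i); resname <- c(resname, seq3[i])
      refA <- c(refA, iA); refB <- c(refB, iB); refC <- c(refC, iC)
      bond <- c(bond, a$bond); angle <- c(angle, a$angle * pi / 180)
      tor <- c(tor, t0 * pi / 180); dof <- c(dof, di)
    }
  }

  # bond graph: parent bonds plus ring-closure bonds
  bonds_i <- refC[refC >= 0] + 1L
  bonds_j <- which(refC >= 0)
  for (i in seq_along(seq3)) {
    extra <- .ring_bonds[[seq3[i]]]
    for (bnd in extra) {
      bonds_i <- c(bonds_i, idx_of(i, bnd[1]) + 1L)
      bonds_j <- c(bonds_j, idx_of(i, bnd[2]) + 1L)
    }
  }

  plan <- list(sequence = seq3, n_atoms = n_atoms,
               atom = data.frame(name = name, resno = as.integer(resno),
                                 resname = resname,
                                 element = substring(name, 1, 1),
                                 stringsAsFactors = FALSE),
               refA = as.integer(refA), refB = as.integer(refB),
               refC = as.integer(refC), bond = bond, angle = angle,
               tor0 = tor, dof = as.integer(dof),
               dof_names = dof_names,
               bonds = cbind(bonds_i, bonds_j))
  plan$lookup <- local({
    key2 <- paste0(plan$atom$resno, ":", plan$atom$name)
    stats::setNames(seq_len(n_atoms), key2)
  })
  .plan_cache[[key]] <- plan
  plan
}

# 1-based atom index in the plan for (residue, atom name); NA if absent
plan_atom_index <- function(plan, resno, atom_name) {
  idx <- plan$lookup[paste0(resno, ":", atom_name)]
  unname(idx)
}
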