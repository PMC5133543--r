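# Torsion-space polypeptide model: conformers, torsion <-> Cartesian
# conversion, and a simplified physical prior energy.

#' Create a torsion-space conformer
#'
#' @param sequence residue codes (one- or three-letter).
#' @param angles torsion angles in degrees, one per rotatable torsion in the
#'   order given by [torsion_names()]; a single value is recycled.
#' @return object of class \code{torsion_conformer}.
#' @export
torsion_conformer <- function(sequence, angles) {
  seq3 <- as_residue_codes(sequence)
  nms <- torsion_names(seq3)
  if (length(angles) == 1) angles <- rep(angles, length(nms))
  if (length(angles) != length(nms))
    stop("expected ", length(nms), " torsion angles, got ", length(angles))
  angles <- wrap_angle(as.numeric(angles))
  structure(list(sequence = seq3,
                 angles = stats::setNames(angles, nms)),
            class = "torsion_conformer")
}

#' @export
print.torsion_conformer <- function(x, ...) {
  cat("torsion_conformer:", length(x$sequence), "residues,",
      length(x$angles), "rotatable torsions\n")
  invisible(x)
}

# wrap to (-180, 180]
wrap_angle <- function(a) {
  a <- a %% 360
  ifelse(a > 180, a - 360, a)
}

#' Random conformer with uniform torsions
#'
#' Torsion angles are drawn i.i.d. uniform on (-180, 180], the starting
#' condition of the conventional multi-start structure calculation.
#'
#' @inheritParams torsion_conformer
#' @param seed integer seed; the draw is deterministic given the seed.
#' @export
random_conformer <- function(sequence, seed = NULL) {
  seq3 <- as_residue_codes(sequence)
  n <- length(torsion_names(seq3))
  if (!is.null(seed)) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old))
    set.seed(seed)
  }
  torsion_conformer(seq3, stats::runif(n, -180, 180))
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", state, envir = globalenv())
}

#' Build Cartesian coordinates from torsion angles
#'
#' Sequential internal-to-Cartesian placement over the idealized geometry
#' table.  The first residue is placed in a canonical frame: N at the origin,
#' CA on the +x axis, C in the xy-plane.  Placement is deterministic and
#' local: changing a torsion of residue i leaves all atoms that precede the
#' torsion in the build order bit-identical.
#'
#' @param conformer a \code{torsion_conformer}.
#' @return object of class \code{cartesian_structure}: a list with an
#'   \code{atoms} data.frame (name, resno, resname, element, x, y, z) and the
#'   source sequence.
#' @export
build_coordinates <- function(conformer) {
  stopifnot(inherits(conformer, "torsion_conformer"))
  plan <- atom_plan(conformer$sequence)
  xyz <- nerf_build_cpp(plan$refA, plan$refB, plan$refC, plan$bond,
                        plan$angle, plan$tor0, plan$dof,
                        conformer$angles * pi / 180)
  atoms <- plan$atom
  atoms$x <- xyz[, 1]; atoms$y <- xyz[, 2]; atoms$z <- xyz[, 3]
  structure(list(atoms = atoms, sequence = plan$sequence),
            class = "cartesian_structure")
}

#' @export
print.cartesian_structure <- function(x, ...) {
  cat("cartesian_structure:", length(x$sequence), "residues,",
      nrow(x$atoms), "atoms\n")
  invisible(x)
}

struct_xyz <- function(structure) {
  as.matrix(structure$atoms[, c("x", "y", "z")])
}

#' Locate an atom in a structure
#'
#' @param structure a \code{cartesian_structure}.
#' @param resno 1-based residue index.
#' @param atom_name atom name (e.g. "CA", "HB2").
#' @return row index into \code{structure$atoms}, or NA if absent.
#' @export
atom_index <- function(structure, resno, atom_name) {
  idx <- which(structure$atoms$resno == resno &
               structure$atoms$name == atom_name)
  if (length(idx) == 0) NA_integer_ else idx[1]
}

#' Measure a dihedral angle from four atomic positions
#'
#' Standard IUPAC sign convention; result in (-180, 180] degrees.  The four
#' collinear-degenerate case returns NA with a warning.
#'
#' @param p1,p2,p3,p4 numeric xyz vectors.
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  if (sum(n1^2) < 1e-12 || sum(n2^2) < 1e-12) {
    warning("degenerate (collinear) dihedral")
    return(NA_real_)
  }
  b2n <- b2 / sqrt(sum(b2^2))
  m1 <- c(n1[2] * b2n[3] - n1[3] * b2n[2],
          n1[3] * b2n[1] - n1[1] * b2n[3],
          n1[1] * b2n[2] - n1[2] * b2n[1])
  ang <- atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
  wrap_angle(ang)
}

#' Measure the rotatable torsions of a structure
#'
#' Inverse of [build_coordinates()]: returns phi/psi/chi1/chi2 values in the
#' same order and naming as [torsion_names()].  psi of the final residue is
#' measured through the carbonyl O (N-CA-C-O minus 180 degrees); all other
#' torsions use their standard heavy-atom quadruples.
#'
#' @param structure a \code{cartesian_structure}.
#' @return named numeric vector of angles in degrees, range (-180, 180].
#' @export
measure_torsions <- function(structure) {
  stopifnot(inherits(structure, "cartesian_structure"))
  seq3 <- structure$sequence
  n <- length(seq3)
  xyz <- struct_xyz(structure)
  pos <- function(i, nm) {
    k <- atom_index(structure, i, nm)
    if (is.na(k)) stop("missing atom ", nm, " in residue ", i)
    xyz[k, ]
  }
  out <- numeric(0); nms <- character(0)
  for (i in seq_len(n)) {
    if (i > 1) {
      out <- c(out, dihedral_angle(pos(i - 1, "C"), pos(i, "N"),
                                   pos(i, "CA"), pos(i, "C")))
      nms <- c(nms, paste0("phi_", i))
    }
    psi <- if (i < n)
      dihedral_angle(pos(i, "N"), pos(i, "CA"), pos(i, "C"), pos(i + 1, "N"))
    else
      wrap_angle(dihedral_angle(pos(i, "N"), pos(i, "CA"), pos(i, "C"),
                                pos(i, "O")) - 180)
    out <- c(out, psi); nms <- c(nms, paste0("psi_", i))
    if (seq3[i] %in% names(.chi1_atom)) {
      out <- c(out, dihedral_angle(pos(i, "N"), pos(i, "CA"), pos(i, "CB"),
                                   pos(i, .chi1_atom[[seq3[i]]])))
      nms <- c(nms, paste0("chi1_", i))
    }
    if (seq3[i] %in% names(.chi2_atom)) {
      g <- .chi1_atom[[seq3[i]]]
      out <- c(out, dihedral_angle(pos(i, "CA"), pos(i, "CB"), pos(i, g),
                                   pos(i, .chi2_atom[[seq3[i]]])))
      nms <- c(nms, paste0("chi2_", i))
    }
  }
  stats::setNames(out, nms)
}

#' Default parameters of the simplified physical prior
#'
#' The prior replaces an atomistic force field with two terms: a soft-sphere
#' repulsion over nonbonded atom pairs, E_rep = k_rep * sum max(0, r_min -
#' r)^2 with r_min the scaled sum of per-element radii, and a three-fold
#' torsion potential k_tor * (1 + cos 3 theta) over the rotatable torsions.
#' Energies are dimensionless (units of kT at the reference temperature).
#' The solvent dielectric constant 78.5 is recorded for completeness but the
#' surrogate has no electrostatic term.
#'
#' @export
prior_params <- function() {
  list(k_rep = 1.0, k_tor = 0.05,
       radii = c(H = 1.10, C = 1.70, N = 1.55, O = 1.52, S = 1.80),
       radius_scale = 0.62,
       exclusion_depth = 4L,
       heavy_only = TRUE,
       dielectric = 78.5)
}

# nonbonded pair list with bond-graph exclusion, cached per (sequence, params)
.pair_cache <- new.env(parent = emptyenv())

nonbonded_pairs <- function(plan, params = prior_params()) {
  if (is.null(params$heavy_only)) params$heavy_only <- TRUE
  key <- paste(paste(plan$sequence, collapse = "."), params$radius_scale,
               params$exclusion_depth, params$heavy_only, sep = "|")
  if (!is.null(.pair_cache[[key]])) return(.pair_cache[[key]])
  n <- plan$n_atoms
  adj <- vector("list", n)
  for (k in seq_len(nrow(plan$bonds))) {
    i <- plan$bonds[k, 1]; j <- plan$bonds[k, 2]
    adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
  }
  # atoms within exclusion_depth bonds of each atom (BFS)
  excl <- vector("list", n)
  for (s in seq_len(n)) {
    dist <- rep(NA_integer_, n); dist[s] <- 0L; frontier <- s
    for (d in seq_len(params$exclusion_depth)) {
      nxt <- unique(unlist(adj[frontier]))
      nxt <- nxt[is.na(dist[nxt])]
      if (length(nxt) == 0) break
      dist[nxt] <- d; frontier <- nxt
    }
    excl[[s]] <- which(!is.na(dist))
  }
  heavy <- plan$atom$element != "H"
  pi_ <- integer(0); pj_ <- integer(0)
  for (i in seq_len(n - 1)) {
    if (params$heavy_only && !heavy[i]) next
    js <- setdiff((i + 1):n, excl[[i]])
    if (params$heavy_only) js <- js[heavy[js]]
    pi_ <- c(pi_, rep.int(i, length(js))); pj_ <- c(pj_, js)
  }
  rad <- params$radii[plan$atom$element]
  rmin <- params$radius_scale * (rad[pi_] + rad[pj_])
  out <- list(i = pi_ - 1L, j = pj_ - 1L, rmin = unname(rmin))
  .pair_cache[[key]] <- out
  out
}

#' Simplified physical prior energy
#'
#' @param structure a \code{cartesian_structure} (or a
#'   \code{torsion_conformer}, which is built first).
#' @param params parameter list from [prior_params()].
#' @param angles optional torsion angles (degrees) for the torsion term; when
#'   omitted they are measured from the structure.
#' @return non-negative energy in kT units.  Zero for a clash-free conformer
#'   with all rotatable torsions at staggered (180 or +/-60 degree) minima.
#' @export
prior_energy <- function(structure, params = prior_params(), angles = NULL) {
  if (inherits(structure, "torsion_conformer")) {
    if (is.null(angles)) angles <- structure$angles
    structure <- build_coordinates(structure)
  }
  plan <- atom_plan(structure$sequence)
  if (is.null(angles)) angles <- measure_torsions(structure)
  pairs <- nonbonded_pairs(plan, params)
  e_rep <- params$k_rep *
    repulsion_cpp(struct_xyz(structure), pairs$i, pairs$j, pairs$rmin)
  e_tor <- params$k_tor * sum(1 + cos(3 * angles * pi / 180))
  e_rep + e_tor
}

#' Repulsion term of the prior alone (clash score)
#' @inheritParams prior_energy
#' @export
clash_energy <- function(structure, params = prior_params()) {
  if (inherits(structure, "torsion_conformer"))
    structure <- build_coordinates(structure)
  plan <- atom_plan(structure$sequence)
  pairs <- nonbonded_pairs(plan, params)
  params$k_rep *
    repulsion_cpp(struct_xyz(structure), pairs$i, pairs$j, pairs$rmin)
}
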