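# Posterior-ensemble analytics: Kabsch superposition, iterative mean
# structure, global and per-residue RMSD, coordinate PCA, and display
# subsampling.

#' Build Cartesian structures from a posterior ensemble
#'
#' @param ensemble a \code{posterior_ensemble} (from [burn_and_thin()]).
#' @return list of \code{cartesian_structure}, one per state, with the
#'   per-member log-posterior attached as an attribute.
#' @export
ensemble_structures <- function(ensemble) {
  stopifnot(inherits(ensemble, "posterior_ensemble"))
  lapply(ensemble$states, function(st) {
    s <- build_coordinates(torsion_conformer(ensemble$sequence, st$angles))
    attr(s, "log_posterior") <- st$log_posterior
    s
  })
}

# selection helpers -------------------------------------------------------

.backbone_names <- c("N", "CA", "C")
.sidechain_names <- c("CB", "CG", "CG1", "CG2", "CD", "CD1", "CD2", "CE",
                      "CE1", "CE2", "CE3", "ND1", "ND2", "NE", "NE1", "NE2",
                      "NZ", "NH1", "NH2")

#' Atom selection for ensemble statistics
#'
#' \code{backbone}: N, CA, C.  \code{sidechain}: the beta-epsilon carbons
#' and side-chain nitrogens.  \code{heavy}: all non-hydrogen atoms.
#'
#' @param structure a \code{cartesian_structure}.
#' @param mode selection mode.
#' @param resno optional residue filter.
#' @return integer row indices into \code{structure$atoms}.
#' @export
select_atoms <- function(structure, mode = c("backbone", "sidechain",
                                             "heavy", "all"),
                         resno = NULL) {
  mode <- match.arg(mode)
  at <- structure$atoms
  keep <- switch(mode,
                 backbone = at$name %in% .backbone_names,
                 sidechain = at$name %in% .sidechain_names,
                 heavy = at$element != "H",
                 all = rep(TRUE, nrow(at)))
  if (!is.null(resno)) keep <- keep & at$resno %in% resno
  which(keep)
}

#' Kabsch superposition
#'
#' Least-squares rigid-body superposition of \code{mobile} onto
#' \code{reference} over the selected atoms, via SVD with a reflection
#' guard (the returned rotation is always proper, det = +1).
#'
#' @param mobile,reference coordinate matrices (n x 3) or
#'   \code{cartesian_structure}s sharing atom ordering.
#' @param atom_selection indices of the atoms used for the fit (default:
#'   all rows); at least 3 non-collinear atoms.
#' @return list with \code{rotation} (3 x 3), \code{translation} (length
#'   3), \code{rmsd} (over the selection), and \code{xyz}, the whole mobile
#'   coordinate set after superposition.
#' @export
kabsch_superpose <- function(mobile, reference, atom_selection = NULL) {
  if (inherits(mobile, "cartesian_structure")) mobile <- struct_xyz(mobile)
  if (inherits(reference, "cartesian_structure"))
    reference <- struct_xyz(reference)
  if (is.null(atom_selection)) atom_selection <- seq_len(nrow(mobile))
  if (length(atom_selection) < 3)
    stop("need at least 3 atoms to superpose")
  X <- mobile[atom_selection, , drop = FALSE]
  Y <- reference[atom_selection, , drop = FALSE]
  cx <- colMeans(X); cy <- colMeans(Y)
  X0 <- sweep(X, 2, cx); Y0 <- sweep(Y, 2, cy)
  sv <- svd(crossprod(X0, Y0))
  if (sv$d[2] < 1e-8 * max(sv$d[1], 1e-300))
    stop("degenerate (collinear) atom selection")
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  moved_sel <- sweep(X0 %*% t(R), 2, cy, "+")
  rmsd <- sqrt(mean(rowSums((moved_sel - Y)^2)))
  moved_all <- sweep(sweep(mobile, 2, cx) %*% t(R), 2, cy, "+")
  list(rotation = R, translation = as.numeric(cy - cx %*% t(R)),
       rmsd = rmsd, xyz = moved_all)
}

# coordinates of all members as a list of matrices
.ens_xyz <- function(structures) lapply(structures, struct_xyz)

#' Iterative mean structure of an ensemble
#'
#' Superposes every member on the current mean over the selection,
#' re-averages, and repeats until the mean moves by less than \code{tol}
#' (max coordinate change, Angstrom).
#'
#' @param structures list of \code{cartesian_structure} (shared atom
#'   ordering), e.g. from [ensemble_structures()].
#' @param selection atom indices used for superposition (default:
#'   backbone).
#' @param tol convergence tolerance (Angstrom).
#' @return list with \code{mean} (n x 3 matrix over all atoms),
#'   \code{superposed} (list of superposed full coordinate sets), and the
#'   iteration count.
#' @export
mean_structure <- function(structures, selection = NULL, tol = 1e-6) {
  if (is.null(selection)) selection <- select_atoms(structures[[1]],
                                                    "backbone")
  xyzs <- .ens_xyz(structures)
  ref <- xyzs[[1]]
  for (it in 1:200) {
    sup <- lapply(xyzs, function(x)
      kabsch_superpose(x, ref, selection)$xyz)
    m <- Reduce(`+`, sup) / length(sup)
    if (max(abs(m - ref)) < tol) {
      return(list(mean = m, superposed = sup, iterations = it))
    }
    ref <- m
  }
  warning("mean structure did not converge in 200 iterations")
  list(mean = m, superposed = sup, iterations = it)
}

#' Average RMSD of an ensemble to its mean coordinates
#'
#' Mean over members of the Kabsch RMSD to the converged mean structure,
#' over the selected atoms (default backbone N, CA, C).
#'
#' @inheritParams mean_structure
#' @export
rmsd_to_mean <- function(structures, selection = NULL) {
  if (is.null(selection)) selection <- select_atoms(structures[[1]],
                                                    "backbone")
  ms <- mean_structure(structures, selection)
  mean(vapply(.ens_xyz(structures), function(x)
    kabsch_superpose(x, ms$mean, selection)$rmsd, numeric(1)))
}

#' Per-residue RMSD profile against a reference
#'
#' Members are globally superposed on the reference over the backbone;
#' for each residue the RMSD of the mode-selected atoms is computed per
#' member, and the across-member mean and standard deviation are reported.
#' Residues with no atoms in the selection (glycine in side-chain mode)
#' yield NA.
#'
#' @param structures list of \code{cartesian_structure}.
#' @param reference a \code{cartesian_structure} with the same atom
#'   ordering.
#' @param mode \code{"backbone"} (N, CA, C) or \code{"sidechain"}
#'   (beta-epsilon carbons and side-chain N).
#' @return data.frame with columns \code{resno, rmsd, sd, n_atoms}.
#' @export
per_residue_rmsd <- function(structures, reference,
                             mode = c("backbone", "sidechain")) {
  mode <- match.arg(mode)
  bb <- select_atoms(reference, "backbone")
  ref_xyz <- struct_xyz(reference)
  sup <- lapply(.ens_xyz(structures), function(x)
    kabsch_superpose(x, ref_xyz, bb)$xyz)
  resnos <- sort(unique(reference$atoms$resno))
  out <- lapply(resnos, function(r) {
    sel <- select_atoms(reference, mode, resno = r)
    if (length(sel) == 0)
      return(data.frame(resno = r, rmsd = NA_real_, sd = NA_real_,
                        n_atoms = 0L))
    per_member <- vapply(sup, function(x)
      sqrt(mean(rowSums((x[sel, , drop = FALSE] -
                         ref_xyz[sel, , drop = FALSE])^2))), numeric(1))
    data.frame(resno = r, rmsd = mean(per_member), sd = stats::sd(per_member),
               n_atoms = length(sel))
  })
  do.call(rbind, out)
}

#' Principal component analysis of an ensemble
#'
#' Members are superposed on the iterative mean over the selection; the
#' flattened selected-atom coordinates are then decomposed by PCA (no mass
#' weighting).  Projections are centered; explained-variance fractions are
#' non-increasing; component vectors are orthonormal.
#'
#' @inheritParams mean_structure
#' @return list with \code{components} (columns = orthonormal component
#'   vectors), \code{variance_fraction}, and \code{projections} (members x
#'   components).
#' @export
pca_ensemble <- function(structures, selection = NULL) {
  if (is.null(selection)) selection <- select_atoms(structures[[1]],
                                                    "backbone")
  ms <- mean_structure(structures, selection)
  M <- do.call(rbind, lapply(ms$superposed, function(x)
    as.numeric(t(x[selection, , drop = FALSE]))))
  M <- sweep(M, 2, colMeans(M))
  sv <- svd(M)
  lam <- sv$d^2 / max(nrow(M) - 1, 1)
  total <- sum(lam)
  vf <- if (total > 0) lam / total else rep(0, length(lam))
  proj <- M %*% sv$v
  colnames(proj) <- paste0("PC", seq_len(ncol(proj)))
  list(components = sv$v, variance_fraction = vf, projections = proj)
}

#' Random subsample of an ensemble
#'
#' Retains \code{floor(fraction * N)} members chosen uniformly without
#' replacement, preserving original order; deterministic given the seed.
#'
#' @param ensemble a \code{posterior_ensemble} or a list of structures.
#' @param fraction fraction in (0, 1].
#' @param seed integer seed.
#' @export
subsample <- function(ensemble, fraction, seed = 1) {
  stopifnot(fraction > 0, fraction <= 1)
  members <- if (inherits(ensemble, "posterior_ensemble"))
    ensemble$states else ensemble
  n <- length(members)
  m <- floor(fraction * n)
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(seed)
  keep <- sort(sample.int(n, m))
  if (inherits(ensemble, "posterior_ensemble")) {
    ensemble$states <- members[keep]
    ensemble
  } else members[keep]
}
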