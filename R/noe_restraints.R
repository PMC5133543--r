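# NOESY peak interpretation: chemical-shift matching with ambiguity, a
# network-support filter, intensity-to-distance calibration, sequence-range
# classification, and the restraint target function.

# proton-name aliases accepted in restraint files
.atom_alias <- c(HN = "H")

resolve_atom_name <- function(name) {
  ifelse(name %in% names(.atom_alias), .atom_alias[name], name)
}

#' Match NOESY peaks against a shift table
#'
#' An assignment option (a proton pair) is included for a peak iff every
#' peak dimension lies within the matching tolerance of the corresponding
#' atom's chemical shift.  Both dimensions are matched against proton
#' shifts (the desk-scale representation reduces 3D NOESY spectra to classed
#' 2D 1H-1H peak lists); the heavy-atom tolerance applies when a shift table
#' entry for a heavy-atom dimension is matched in 3D lists.
#'
#' @param peaks a \code{peak_list} (2D: columns w1, w2).
#' @param shifts a \code{shift_table}.
#' @param tol_H matching tolerance for 1H dimensions (ppm).
#' @param tol_heavy matching tolerance for 13C/15N dimensions (ppm).
#' @return list of assignment candidates, one per peak: list(peak = row,
#'   options = data.frame(res_i, atom_i, res_j, atom_j, dev1, dev2)).
#'   Peaks with zero options carry \code{assigned = FALSE}.
#' @export
match_assignments <- function(peaks, shifts, tol_H = 0.04, tol_heavy = 0.4) {
  stopifnot(tol_H > 0, tol_heavy > 0)
  protons <- shifts[startsWith(resolve_atom_name(shifts$atom), "H") |
                    startsWith(shifts$atom, "Q"), , drop = FALSE]
  out <- vector("list", nrow(peaks))
  eps <- 1e-9  # guard against ties at the tolerance boundary
  for (k in seq_len(nrow(peaks))) {
    dev1 <- abs(protons$shift - peaks$w1[k])
    dev2 <- abs(protons$shift - peaks$w2[k])
    m1 <- which(dev1 <= tol_H + eps)
    m2 <- which(dev2 <= tol_H + eps)
    opts <- NULL
    if (length(m1) && length(m2)) {
      grid <- expand.grid(a = m1, b = m2)
      # a proton does not cross-relax with itself
      grid <- grid[!(protons$resno[grid$a] == protons$resno[grid$b] &
                     protons$atom[grid$a] == protons$atom[grid$b]), ,
                   drop = FALSE]
      if (nrow(grid)) {
        opts <- data.frame(
          res_i = protons$resno[grid$a], atom_i = protons$atom[grid$a],
          restype_i = protons$restype[grid$a],
          res_j = protons$resno[grid$b], atom_j = protons$atom[grid$b],
          restype_j = protons$restype[grid$b],
          dev1 = dev1[grid$a], dev2 = dev2[grid$b],
          stringsAsFactors = FALSE)
      }
    }
    if (is.null(opts))
      opts <- data.frame(res_i = integer(0), atom_i = character(0),
                         restype_i = character(0), res_j = integer(0),
                         atom_j = character(0), restype_j = character(0),
                         dev1 = numeric(0), dev2 = numeric(0))
    out[[k]] <- list(peak = peaks[k, , drop = FALSE], options = opts,
                     assigned = nrow(opts) > 0)
  }
  class(out) <- "assignment_candidates"
  out
}

#' @export
print.assignment_candidates <- function(x, ...) {
  n_opt <- vapply(x, function(c) nrow(c$options), integer(1))
  cat("assignment_candidates:", length(x), "peaks;",
      sum(n_opt > 0), "assigned,", sum(n_opt > 1), "ambiguous\n")
  invisible(x)
}

#' Network-support filter for long-range assignment options
#'
#' A simplified network-anchoring rule: an option linking residues (i, j)
#' with |i - j| >= 2 is retained only if at least \code{min_support} other
#' candidate peaks carry an option linking a residue pair (i', j') with
#' |i - i'| <= 1 and |j - j'| <= 1 (in either orientation).  Options between
#' adjacent residues are always kept; \code{min_support = 0} is the
#' identity.
#'
#' @param candidates output of [match_assignments()].
#' @param min_support required number of supporting candidates (>= 0).
#' @export
network_filter <- function(candidates, min_support = 1) {
  stopifnot(min_support >= 0)
  if (min_support == 0) return(candidates)
  pair_of <- function(opt) {
    cbind(pmin(opt$res_i, opt$res_j), pmax(opt$res_i, opt$res_j))
  }
  all_pairs <- do.call(rbind, lapply(seq_along(candidates), function(k) {
    o <- candidates[[k]]$options
    if (nrow(o) == 0) return(NULL)
    cbind(pair_of(o), k)
  }))
  out <- lapply(seq_along(candidates), function(k) {
    cand <- candidates[[k]]
    o <- cand$options
    if (nrow(o) == 0) return(cand)
    keep <- vapply(seq_len(nrow(o)), function(r) {
      i <- min(o$res_i[r], o$res_j[r]); j <- max(o$res_i[r], o$res_j[r])
      if (abs(i - j) < 2) return(TRUE)
      sup <- all_pairs[, 3] != k &
        abs(all_pairs[, 1] - i) <= 1 & abs(all_pairs[, 2] - j) <= 1
      sum(sup) >= min_support
    }, logical(1))
    cand$options <- o[keep, , drop = FALSE]
    cand$assigned <- nrow(cand$options) > 0
    cand
  })
  class(out) <- "assignment_candidates"
  out
}

#' NOE calibration model
#'
#' The isolated-spin-pair relation I = C / r^6 converts a peak intensity to
#' an upper distance bound \code{clip((C/I)^(1/6), d_min, d_max)}.
#'
#' @param spectrum_id spectrum label the model applies to.
#' @param C calibration constant (intensity * Angstrom^6), > 0.
#' @param d_min,d_max clipping bounds of the derived upper bound (Angstrom).
#' @export
calibration_model <- function(spectrum_id, C, d_min = 2.4, d_max = 6.0) {
  stopifnot(C > 0, d_min < d_max)
  structure(list(spectrum_id = spectrum_id, C = C, d_min = d_min,
                 d_max = d_max),
            class = "calibration_model")
}

#' Auto-calibrate against a target median distance
#'
#' Chooses C so that the median of (C/I)^(1/6) over the peak intensities
#' equals \code{target_median} (default 4.0 Angstrom, the midrange of
#' observable NOEs): \code{C = median(I) * target^6}.
#'
#' @param intensities positive peak intensities of one spectrum.
#' @inheritParams calibration_model
#' @param target_median target median upper bound (Angstrom).
#' @export
auto_calibrate <- function(intensities, spectrum_id = "spectrum",
                           target_median = 4.0, d_min = 2.4, d_max = 6.0) {
  intensities <- intensities[intensities > 0]
  if (length(intensities) == 0) stop("no positive intensities to calibrate")
  calibration_model(spectrum_id, stats::median(intensities) * target_median^6,
                    d_min = d_min, d_max = d_max)
}

#' Convert assigned peaks into calibrated distance restraints
#'
#' Each assigned peak becomes one restraint group; an ambiguous candidate
#' becomes a single ambiguous restraint carrying all its options.  Peaks
#' with nonpositive intensity are skipped with a warning; unassigned peaks
#' are dropped.
#'
#' @param candidates output of [match_assignments()] / [network_filter()].
#' @param model a \code{calibration_model}.
#' @return a \code{restraint_set} with provenance columns \code{peak_id},
#'   \code{spectrum_id}, \code{intensity} and a \code{class} column from
#'   [classify_range()] (computed on the sequence separation of the closest
#'   option pair).
#' @export
calibrate <- function(candidates, model) {
  stopifnot(inherits(model, "calibration_model"))
  rows <- list()
  g <- 0L
  for (cand in candidates) {
    if (!cand$assigned) next
    I <- cand$peak$intensity
    if (I <= 0) {
      warning("skipping peak ", cand$peak$peak_id,
              ": nonpositive intensity")
      next
    }
    g <- g + 1L
    d <- min(max((model$C / I)^(1 / 6), model$d_min), model$d_max)
    o <- cand$options
    sep <- abs(o$res_i - o$res_j)
    rows[[g]] <- data.frame(
      group = g, res_i = o$res_i, restype_i = o$restype_i, atom_i = o$atom_i,
      res_j = o$res_j, restype_j = o$restype_j, atom_j = o$atom_j,
      upper = d, lower = 1.0,
      class = classify_range(o$res_i[which.min(sep)],
                             o$res_j[which.min(sep)]),
      peak_id = cand$peak$peak_id, spectrum_id = cand$peak$spectrum_id,
      intensity = I, stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else empty_restraint_set()
  class(out) <- c("restraint_set", "data.frame")
  out
}

#' Sequence-range class of a residue pair
#'
#' |i - j| = 0: intra; 1: sequential; 2-4: medium; >= 5: long.
#'
#' @param res_i,res_j residue indices (vectorized).
#' @export
classify_range <- function(res_i, res_j) {
  d <- abs(res_i - res_j)
  c("intra", "sequential", "medium", "medium", "medium",
    "long")[pmin(d, 5) + 1]
}

# Resolve restraint option atoms to plan indices; pseudo-atom names (Q*) map
# to the first matching proton set is not supported -- options must name
# real atoms.
restraint_indices <- function(restraints, structure) {
  idx <- function(res, atom) {
    a <- resolve_atom_name(atom)
    i <- mapply(function(r, an) atom_index(structure, r, an), res, a)
    if (any(is.na(i)))
      stop("restraint references missing atom: residue ",
           res[which(is.na(i))[1]], " ", a[which(is.na(i))[1]])
    as.integer(i)
  }
  groups <- sort(unique(restraints$group))
  gmap <- match(restraints$group, groups)
  list(oi = idx(restraints$res_i, restraints$atom_i) - 1L,
       oj = idx(restraints$res_j, restraints$atom_j) - 1L,
       grp = gmap - 1L, ngroup = length(groups))
}

# per-group upper/lower in group order (groups sorted ascending)
restraint_bounds <- function(restraints) {
  groups <- sort(unique(restraints$group))
  first <- match(groups, restraints$group)
  list(upper = restraints$upper[first], lower = restraints$lower[first],
       groups = groups)
}

#' Ambiguity-aware effective distance
#'
#' r_eff = (sum over options r^-6)^(-1/6); equals the plain distance for a
#' single option and is never larger than the smallest option distance.
#'
#' @param structure a \code{cartesian_structure}.
#' @param restraints a \code{restraint_set} (one or more groups).
#' @return named numeric vector of effective distances, one per group (in
#'   ascending group order).
#' @export
effective_distance <- function(structure, restraints) {
  if (nrow(restraints) == 0) return(numeric(0))
  ri <- restraint_indices(restraints, structure)
  d <- reff_cpp(struct_xyz(structure), ri$oi, ri$oj, ri$grp, ri$ngroup)
  stats::setNames(d, sort(unique(restraints$group)))
}

#' Restraint target function
#'
#' Sum of squared violations over restraint groups,
#' sum max(0, r_eff - upper)^2 + sum max(0, lower - r_eff)^2, plus (when
#' dihedral restraints are given) weighted squared dihedral-interval
#' violations in degrees^2.
#'
#' @param structure a \code{cartesian_structure}.
#' @param restraints a \code{restraint_set}.
#' @param aco optional \code{dihedral_restraints}.
#' @param dihedral_weight weight of the dihedral term (Angstrom^2 per
#'   degree^2).
#' @return non-negative scalar; 0 iff every restraint is satisfied.
#' @export
target_function <- function(structure, restraints, aco = NULL,
                            dihedral_weight = 0.0025) {
  tf <- 0
  if (nrow(restraints) > 0) {
    bounds <- restraint_bounds(restraints)
    reff <- effective_distance(structure, restraints)
    tf <- sum(pmax(0, reff - bounds$upper)^2) +
      sum(pmax(0, bounds$lower - reff)^2)
  }
  if (!is.null(aco) && nrow(aco) > 0) {
    tor <- measure_torsions(structure)
    for (k in seq_len(nrow(aco))) {
      nm <- paste0(tolower(aco$angle[k]), "_", aco$resno[k])
      if (!nm %in% names(tor)) next
      v <- dihedral_violation(tor[[nm]], aco$lower[k], aco$upper[k])
      tf <- tf + dihedral_weight * v^2
    }
  }
  tf
}

# smallest angular distance (deg) from angle a to the interval [lo, hi]
dihedral_violation <- function(a, lo, hi) {
  if (a >= lo && a <= hi) return(0)
  dlo <- abs(wrap_angle(a - lo)); dhi <- abs(wrap_angle(a - hi))
  min(dlo, dhi)
}
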