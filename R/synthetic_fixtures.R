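# Synthetic ground-truth generators: reference structures with known
# torsions, chemical-shift tables with controllable degeneracy, NOE peak
# lists following I = C / r^6 with multiplicative log-normal noise, and
# non-uniformly sampled time-domain data.  Every generator is deterministic
# given its seed, so each pipeline stage can be tested against known truth
# without experimental data.

# Preset torsion tables.  Backbone: canonical secondary-structure values
# (beta strands near (-139, 125), alpha helices at exactly (-60, -45)) with
# a tight chain-reversing turn; side-chain rotamers were relaxed once, at
# packaging time, to make every preset exactly clash-free (zero repulsion)
# while keeping at least ten long-range (|i-j| >= 5) proton pairs under
# 5 Angstrom.  The numbers below are frozen; they are the ground truth the
# synthetic scenarios are built from.
.presets <- list(
  hairpin12 = list(
    sequence = c("LYS", "THR", "PHE", "THR", "VAL", "ASN", "GLY", "LYS",
                 "THR", "TYR", "THR", "GLU"),
    # two antiparallel strands (1-5, 8-12) joined by a type-I'-like turn
    angles = c(125, -59.12, -174.23, -139, 125, -67.22, -139, 125, -56.67,
               -171.81, -139, 103.63, -56.05, -138.23, 118.02, -57.51,
               49.14, 31.79, 159.7, 170.88, 75.24, 29.54, 179.65, 148.02,
               155.66, -110.79, -139, 125, -67.11, -139, 125, -47.87,
               -173.85, -139, 125, -67.17, -139, 125, -60.92, 172.42)),
  helixturn16 = list(
    sequence = c("ALA", "GLU", "LEU", "LYS", "ALA", "LEU", "ALA", "GLY",
                 "ASN", "ALA", "LEU", "GLU", "ALA", "LEU", "LYS", "ALA"),
    # two alpha-helices (1-7, 10-16) at exactly (-60, -45), turn at 8-9
    angles = c(-45, -60, -45, 60, 180, -60, -45, 60, 180, -60, -45, 180,
               180, -60, -45, -60, -45, 60, 180, -60, -45, 80, 60, -90, 0,
               165, 180, -60, -45, -60, -45, 60, 180, -60, -45, 60, 180,
               -60, -45, -60, -45, 60, 180, -60, -45, 60, 180, -60, -45)),
  mixed20 = list(
    sequence = c("MET", "GLN", "ILE", "PHE", "VAL", "LYS", "THR", "LEU",
                 "THR", "GLY", "LYS", "THR", "ILE", "THR", "LEU", "GLU",
                 "VAL", "GLU", "SER", "SER"),
    # strand pair (1-9, 12-20) with a tight turn at 10-11
    angles = c(125.93, -40.83, 139.49, -138.07, 125.93, -57.62, 167.69,
               -138.07, 124.97, -67.29, -138.88, -138.89, 125.93, -48.01,
               -172.9, -138.07, 125.17, -63.98, -138.91, 125.93, -52.8,
               157.61, -138.07, 125.01, -67.5, -138.07, 122.74, 81.27,
               80.75, -143.4, 145.62, 71.74, 46.5, 31.55, 75.68, -46.99,
               -45.16, -135.38, -136.71, 114.61, -58.77, -138.07, 124.99,
               -67.35, -140.72, -138.07, 125.03, -67.63, -138.07, 125.05,
               179.03, 146.75, -138.07, 125.93, -57.66, 153.19, -138.07,
               125.16, -63.89, -138.07, 125.93, -53.01, 150.79, -138.07,
               125.93, -42.95, -138.07, 125.93, -59.5)))

#' Reference structures with known torsions
#'
#' Shipped presets: \code{hairpin12} (12-mer beta-hairpin),
#' \code{helixturn16} (16-mer helix-turn-helix), \code{mixed20} (20-mer
#' two-strand fold).  All presets are clash-free (zero repulsion energy) and
#' deterministic; their torsion tables are embedded in the package.
#'
#' @param name preset name.
#' @return a \code{torsion_conformer}.
#' @export
make_reference_structure <- function(name = c("hairpin12", "helixturn16",
                                              "mixed20")) {
  name <- match.arg(name)
  p <- .presets[[name]]
  torsion_conformer(p$sequence, p$angles)
}

# per-proton-class chemical shift distributions (ppm)
.shift_class <- function(restype, atom) {
  if (atom == "H") return(c(8.3, 0.6))
  if (startsWith(atom, "HA")) return(c(4.4, 0.4))
  aromatic <- restype %in% c("PHE", "TYR", "TRP", "HIS") &&
    grepl("^H[DEZH]", atom)
  if (aromatic) return(c(7.2, 0.4))
  if (grepl("^H[GB][0-9]*$", atom) || grepl("^H[B]", atom))
    return(c(1.8, 0.5))
  c(1.1, 0.5)  # distal aliphatic and methyl protons
}

#' Simulate a chemical-shift table
#'
#' Draws one shift per proton from per-class normal distributions.  With
#' \code{degeneracy_fraction = 0} the table is resampled until every pair of
#' proton shifts differs by more than \code{min_sep} (constructive
#' non-degeneracy); a positive fraction then forces that fraction of protons
#' into near-degenerate pairs (within 0.02 ppm) to create assignment
#' ambiguity.
#'
#' @param sequence residue codes.
#' @param seed integer seed.
#' @param degeneracy_fraction fraction of protons placed in near-degenerate
#'   pairs.
#' @param min_sep minimal pairwise separation enforced when
#'   \code{degeneracy_fraction = 0} (ppm).
#' @return a \code{shift_table} covering every proton of the built structure.
#' @export
simulate_shift_table <- function(sequence, seed = 1,
                                 degeneracy_fraction = 0, min_sep = 0.045) {
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(seed)
  plan <- atom_plan(sequence)
  at <- plan$atom[plan$atom$element == "H", , drop = FALSE]
  n <- nrow(at)
  draw <- function(k, inflate = 1) {
    cl <- .shift_class(at$resname[k], at$name[k])
    stats::rnorm(1, cl[1], cl[2] * inflate)
  }
  shift <- vapply(seq_len(n), draw, numeric(1))
  # enforce pairwise separation, widening the class ranges if the packing
  # is too tight for the requested separation
  for (rep in 1:400) {
    d <- abs(outer(shift, shift, "-")); diag(d) <- Inf
    bad <- which(apply(d, 1, min) < min_sep)
    if (length(bad) == 0) break
    for (k in bad) shift[k] <- draw(k, inflate = 1 + rep / 50)
  }
  if (degeneracy_fraction > 0) {
    n_pairs <- round(degeneracy_fraction * n / 2)
    if (n_pairs > 0) {
      pick <- matrix(sample(n, 2 * n_pairs), ncol = 2)
      shift[pick[, 2]] <- shift[pick[, 1]] +
        stats::runif(n_pairs, -0.01, 0.01)
    }
  }
  out <- data.frame(resno = at$resno, restype = at$resname, atom = at$name,
                    shift = round(shift, 4), error = 0.0,
                    stringsAsFactors = FALSE)
  class(out) <- c("shift_table", "data.frame")
  out
}

#' Specification of simulated NOESY spectra
#'
#' Desk-scale stand-in for the three 3D NOESY types: 2D 1H-1H peak lists
#' partitioned by the attached-heavy-atom class of the first proton
#' (\code{"N"}: amide protons; \code{"C"}: carbon-bound protons).
#'
#' @param id spectrum label.
#' @param C true calibration constant (intensity * Angstrom^6).
#' @param sigma log-normal intensity noise (sd of log intensity).
#' @param class \code{"N"} or \code{"C"}.
#' @export
noesy_spec <- function(id, C, sigma = 0, class = c("N", "C")) {
  class <- match.arg(class)
  stopifnot(C > 0, sigma >= 0)
  list(id = id, C = C, sigma = sigma, class = class)
}

.default_spectra <- function() list(
  noesy_spec("noesyN", C = 64 * 4^6, sigma = 0.1, class = "N"),
  noesy_spec("noesyC", C = 40 * 4^6, sigma = 0.1, class = "C"))

# attached-heavy-atom class of a proton: parent element in the plan
.proton_class <- function(plan) {
  parent <- plan$refC + 1L
  cls <- rep(NA_character_, plan$n_atoms)
  isH <- plan$atom$element == "H"
  cls[isH] <- plan$atom$element[parent[isH]]
  cls
}

#' Simulate NOESY peak lists from a structure
#'
#' Enumerates all proton pairs closer than \code{r_max}, assigns each pair
#' to every spectrum whose class contains at least one of its protons, and
#' emits a peak at the two protons' chemical shifts with intensity
#' \code{I = C / r^6 * eps}, \code{log(eps) ~ N(0, sigma^2)}.
#'
#' @param structure a \code{cartesian_structure} (or conformer).
#' @param shifts a \code{shift_table} from [simulate_shift_table()].
#' @param spectra list of [noesy_spec()] entries.
#' @param seed integer seed for the intensity noise.
#' @param r_max distance cutoff (Angstrom) beyond which no peak is observed.
#' @return list with \code{peaks} (named list of \code{peak_list}s, one per
#'   spectrum) and \code{truth} (data.frame of the generating proton pairs
#'   with true distances and intensities).
#' @export
simulate_noe_peaks <- function(structure, shifts, spectra = .default_spectra(),
                               seed = 1, r_max = 5.5) {
  if (inherits(structure, "torsion_conformer"))
    structure <- build_coordinates(structure)
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(seed)
  plan <- atom_plan(structure$sequence)
  cls <- .proton_class(plan)
  hidx <- which(plan$atom$element == "H")
  # only protons with a simulated shift are observable
  skey <- paste(shifts$resno, shifts$atom)
  hkey <- paste(plan$atom$resno[hidx], plan$atom$name[hidx])
  hidx <- hidx[hkey %in% skey]
  np <- length(hidx)
  pairs <- which(upper.tri(matrix(TRUE, np, np)), arr.ind = TRUE)
  ii <- hidx[pairs[, 1]]; jj <- hidx[pairs[, 2]]
  r <- pair_dist_cpp(struct_xyz(structure), ii - 1L, jj - 1L)
  keep <- r <= r_max
  ii <- ii[keep]; jj <- jj[keep]; r <- r[keep]
  shift_of <- stats::setNames(shifts$shift, skey)
  truth <- list(); peak_lists <- list()
  for (sp in spectra) {
    in_class_i <- cls[ii] == sp$class
    in_class_j <- cls[jj] == sp$class
    sel <- which(in_class_i | in_class_j)
    # put the class-defining proton on dimension 1
    a <- ifelse(in_class_i[sel], ii[sel], jj[sel])
    b <- ifelse(in_class_i[sel], jj[sel], ii[sel])
    eps <- exp(stats::rnorm(length(sel), 0, sp$sigma))
    inten <- sp$C / r[sel]^6 * eps
    key_a <- paste(plan$atom$resno[a], plan$atom$name[a])
    key_b <- paste(plan$atom$resno[b], plan$atom$name[b])
    pk <- data.frame(peak_id = seq_along(sel),
                     w1 = unname(shift_of[key_a]),
                     w2 = unname(shift_of[key_b]),
                     intensity = inten, spectrum_id = sp$id,
                     stringsAsFactors = FALSE)
    class(pk) <- c("peak_list", "data.frame")
    peak_lists[[sp$id]] <- pk
    truth[[sp$id]] <- data.frame(
      spectrum_id = sp$id, peak_id = seq_along(sel),
      res_i = plan$atom$resno[a], atom_i = plan$atom$name[a],
      res_j = plan$atom$resno[b], atom_j = plan$atom$name[b],
      r_true = r[sel], intensity = inten, C_true = sp$C,
      sigma_true = sp$sigma, stringsAsFactors = FALSE)
  }
  list(peaks = peak_lists, truth = do.call(rbind, unname(truth)))
}

#' Simulate non-uniformly sampled time-domain data
#'
#' Complex 2D exponentially decaying sinusoids evaluated at the scheduled
#' grid points plus i.i.d. complex Gaussian noise.  The noiseless full-grid
#' signal DFTs to (phase-twisted) Lorentzian lines at the specified
#' frequency bins.
#'
#' @param peak_spec data.frame with columns \code{f1, f2} (frequency in
#'   0-based grid bins), \code{amp}, and optional \code{r1, r2} (decay rates
#'   per increment, default 0).
#' @param schedule a \code{nus_schedule}.
#' @param noise_sigma standard deviation of the real and imaginary noise
#'   components.
#' @param seed integer seed.
#' @return a \code{time_domain_data} with \code{noise_sigma} recorded.
#' @export
simulate_fid <- function(peak_spec, schedule, noise_sigma = 0, seed = 1) {
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(seed)
  t1 <- schedule$points[, 1]; t2 <- schedule$points[, 2]
  vals <- complex(length.out = length(t1))
  for (k in seq_len(nrow(peak_spec))) {
    r1 <- if ("r1" %in% names(peak_spec)) peak_spec$r1[k] else 0
    r2 <- if ("r2" %in% names(peak_spec)) peak_spec$r2[k] else 0
    vals <- vals + peak_spec$amp[k] *
      exp(2i * pi * (peak_spec$f1[k] * t1 / schedule$n1 +
                     peak_spec$f2[k] * t2 / schedule$n2)) *
      exp(-(r1 * t1 + r2 * t2))
  }
  if (noise_sigma > 0)
    vals <- vals + complex(real = stats::rnorm(length(t1), 0, noise_sigma),
                           imaginary = stats::rnorm(length(t1), 0,
                                                    noise_sigma))
  time_domain_data(vals, schedule, noise_sigma = noise_sigma)
}

#' Assemble a complete synthetic scenario
#'
#' Bundles a reference structure, shift table, NOE peak lists with truth
#' table, and (optionally) NUS time-domain data under one master seed.
#' Regenerating with the same arguments is bit-identical.
#'
#' @param preset reference structure preset name.
#' @param seed master seed; stage seeds are derived deterministically.
#' @param spectra list of [noesy_spec()]s.
#' @param degeneracy_fraction shift-table degeneracy (see
#'   [simulate_shift_table()]).
#' @param r_max NOE observability cutoff (Angstrom).
#' @export
make_scenario <- function(preset = "hairpin12", seed = 1,
                          spectra = .default_spectra(),
                          degeneracy_fraction = 0, r_max = 5.5) {
  conf <- make_reference_structure(preset)
  struct <- build_coordinates(conf)
  shifts <- simulate_shift_table(conf$sequence, seed = seed + 1000L,
                                 degeneracy_fraction = degeneracy_fraction)
  noe <- simulate_noe_peaks(struct, shifts, spectra = spectra,
                            seed = seed + 2000L, r_max = r_max)
  structure(list(preset = preset, seed = seed, conformer = conf,
                 structure = struct, shifts = shifts, peaks = noe$peaks,
                 truth = noe$truth, spectra = spectra),
            class = "scenario")
}

#' @export
print.scenario <- function(x, ...) {
  cat("scenario:", x$preset, "(seed", paste0(x$seed, "),"),
      length(x$conformer$sequence), "residues;", nrow(x$truth),
      "true NOE pairs over", length(x$peaks), "spectra\n")
  invisible(x)
}
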