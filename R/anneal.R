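# Conventional structure calculation: multi-start Metropolis simulated
# annealing in torsion space against the restraint target function plus a
# weak physical prior.  This stands in for torsion-angle dynamics: the same
# search role (global minimization of the CYANA-style target function from
# random starts), implemented as single-torsion Metropolis moves under a
# geometric temperature and move-width schedule.

# Flat argument bundle consumed by the compiled Monte Carlo kernels: the
# atom plan, the nonbonded pair list, restraint options resolved to 0-based
# atom indices (grouped), and dihedral restraints resolved to torsion dofs.
mc_model_args <- function(sequence, restraints, aco = NULL,
                          params = prior_params()) {
  plan <- atom_plan(sequence)
  pairs <- nonbonded_pairs(plan, params)
  if (!is.null(restraints) && nrow(restraints) > 0) {
    look <- function(res, atom) {
      a <- resolve_atom_name(atom)
      idx <- plan$lookup[paste0(res, ":", a)]
      if (any(is.na(idx)))
        stop("restraint references missing atom: residue ",
             res[which(is.na(idx))[1]], " ", a[which(is.na(idx))[1]])
      unname(idx)
    }
    groups <- sort(unique(restraints$group))
    first <- match(groups, restraints$group)
    rest <- list(oi = look(restraints$res_i, restraints$atom_i) - 1L,
                 oj = look(restraints$res_j, restraints$atom_j) - 1L,
                 grp = match(restraints$group, groups) - 1L,
                 ngroup = length(groups),
                 upper = restraints$upper[first],
                 lower = restraints$lower[first],
                 groups = groups)
  } else {
    rest <- list(oi = integer(0), oj = integer(0), grp = integer(0),
                 ngroup = 0L, upper = numeric(0), lower = numeric(0),
                 groups = integer(0))
  }
  if (!is.null(aco) && nrow(aco) > 0) {
    aco_idx <- match(paste0(tolower(aco$angle), "_", aco$resno),
                     plan$dof_names)
    keep <- !is.na(aco_idx)
    aco_args <- list(dof = aco_idx[keep] - 1L, lo = aco$lower[keep],
                     hi = aco$upper[keep])
  } else {
    aco_args <- list(dof = integer(0), lo = numeric(0), hi = numeric(0))
  }
  list(plan = plan, pairs = pairs, rest = rest, aco = aco_args,
       params = params, n_dof = length(plan$dof_names))
}

# Fast closure evaluating (restraint target, prior energy, r_eff) from a
# torsion angle vector, bypassing the data.frame structure container.
torsion_evaluator <- function(sequence, restraints, aco = NULL,
                              params = prior_params(),
                              dihedral_weight = 0.0025) {
  ma <- mc_model_args(sequence, restraints, aco, params)
  plan <- ma$plan
  deg <- pi / 180
  function(angles) {
    xyz <- nerf_build_cpp(plan$refA, plan$refB, plan$refC, plan$bond,
                          plan$angle, plan$tor0, plan$dof, angles * deg)
    target <- 0
    reff <- NULL
    if (ma$rest$ngroup > 0) {
      reff <- reff_cpp(xyz, ma$rest$oi, ma$rest$oj, ma$rest$grp,
                       ma$rest$ngroup)
      target <- sum(pmax(0, reff - ma$rest$upper)^2) +
        sum(pmax(0, ma$rest$lower - reff)^2)
    }
    if (length(ma$aco$dof) > 0) {
      a <- angles[ma$aco$dof + 1L]
      v <- vapply(seq_along(a),
                  function(k) dihedral_violation(a[k], ma$aco$lo[k],
                                                 ma$aco$hi[k]),
                  numeric(1))
      target <- target + dihedral_weight * sum(v^2)
    }
    prior <- params$k_rep * repulsion_cpp(xyz, ma$pairs$i, ma$pairs$j,
                                          ma$pairs$rmin) +
      params$k_tor * sum(1 + cos(3 * angles * deg))
    list(target = target, prior = prior, reff = reff)
  }
}

#' Annealing configuration
#'
#' @param n_starts number of random starting conformers.
#' @param n_steps Metropolis steps per start.
#' @param t_start,t_end geometric temperature schedule (target-function
#'   units).
#' @param move_start,move_end geometric single-torsion move width schedule
#'   (degrees).
#' @param prior_weight weight of the physical prior in the annealing
#'   objective (the reported target values exclude it).
#' @param seed master seed; start s uses a deterministic derived seed.
#' @export
anneal_config <- function(n_starts = 100, n_steps = 10000, t_start = 50,
                          t_end = 0.1, move_start = 30, move_end = 2,
                          prior_weight = 0.05, seed = 1) {
  stopifnot(n_starts >= 1, n_steps >= 1, t_start > 0, t_end > 0)
  list(n_starts = as.integer(n_starts), n_steps = as.integer(n_steps),
       t_start = t_start, t_end = t_end, move_start = move_start,
       move_end = move_end, prior_weight = prior_weight,
       seed = as.integer(seed))
}

#' Multi-start simulated annealing against the restraint target
#'
#' Each start draws a random conformer and anneals it by single-torsion
#' Metropolis moves on \code{target + prior_weight * prior}; the best
#' conformer (lowest restraint target) seen along each trajectory is
#' retained, so the final target never exceeds the initial one.
#'
#' @param sequence residue codes.
#' @param restraints a \code{restraint_set} (may be empty).
#' @param config an [anneal_config()].
#' @param aco optional \code{dihedral_restraints}.
#' @return list of results sorted by ascending target value; each element
#'   has \code{conformer}, \code{target} and \code{prior}.
#' @export
run_annealing <- function(sequence, restraints, config = anneal_config(),
                          aco = NULL) {
  seq3 <- as_residue_codes(sequence)
  ma <- mc_model_args(seq3, restraints, aco)
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  temps <- config$t_start *
    (config$t_end / config$t_start)^(seq_len(config$n_steps) / config$n_steps)
  widths <- config$move_start *
    (config$move_end / config$move_start)^(seq_len(config$n_steps) /
                                           config$n_steps)
  results <- vector("list", config$n_starts)
  for (s in seq_len(config$n_starts)) {
    set.seed(config$seed * 10000L + s)
    ang <- stats::runif(ma$n_dof, -180, 180)
    r <- anneal_chain_cpp(ma$plan, ma$pairs, ma$rest, ma$aco, ang, temps,
                          widths, ma$params$k_rep, ma$params$k_tor,
                          config$prior_weight, 0.0025, ma$n_dof)
    results[[s]] <- list(conformer = torsion_conformer(seq3, r$angles),
                         target = r$target, prior = r$prior,
                         accept_rate = r$accept_rate)
  }
  results[order(vapply(results, `[[`, numeric(1), "target"))]
}

#' Select the annealing seed conformer
#'
#' Returns the conformer with the lowest target value (ties broken by the
#' lowest index), the starting point of the Bayesian refinement.
#'
#' @param conformers output of [run_annealing()].
#' @export
select_seed <- function(conformers) {
  targets <- vapply(conformers, `[[`, numeric(1), "target")
  conformers[[which.min(targets)]]$conformer
}
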