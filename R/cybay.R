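# Bayesian refinement of a seed conformer against NOE intensities.
#
# Joint posterior over the conformation X and per-spectrum nuisance
# parameters (log-calibration c_s = ln C_s, noise scale sigma_s):
#
#   log pi(X, c, sigma) =
#     sum_s sum_{k in s} [ -(ln I_k - (c_s - 6 ln r_eff,k(X)))^2/(2 sigma_s^2)
#                          - ln sigma_s ]
#     + sum_s log N(c_s; mu0, tau0^2)
#     + sum_s log IG(sigma_s^2; alpha0, beta0)
#     - E_prior(X)  + const
#
# The normal-on-log-intensity likelihood makes the normal prior on c_s and
# the inverse-gamma prior on sigma_s^2 exactly conjugate, so both nuisance
# parameters admit Gibbs updates.  Conformations are sampled by Metropolis
# moves in torsion space; K replicas at temperatures T_1..T_K temper the
# full log-posterior by beta_k = T_1/T_k and exchange states periodically.

#' Hyperparameters of the nuisance priors
#'
#' @param mu0,tau0 mean and sd of the normal prior on the log-calibration
#'   constants (log intensity units).
#' @param alpha0,beta0 shape and scale of the inverse-gamma prior on the
#'   per-spectrum noise variance sigma_s^2.
#' @export
cybay_hyper <- function(mu0 = 0, tau0 = 2, alpha0 = 2, beta0 = 0.5) {
  stopifnot(tau0 > 0, alpha0 > 0, beta0 > 0)
  list(mu0 = mu0, tau0 = tau0, alpha0 = alpha0, beta0 = beta0)
}

# log inverse-gamma density for the variance v
dinvgamma_log <- function(v, alpha, beta) {
  alpha * log(beta) - lgamma(alpha) - (alpha + 1) * log(v) - beta / v
}

# restraint bookkeeping for the likelihood: one observation per restraint
# group, with its spectrum and log intensity
likelihood_data <- function(restraints) {
  if (!all(c("intensity", "spectrum_id") %in% names(restraints)))
    stop("Bayesian refinement needs restraints with 'intensity' and ",
         "'spectrum_id' provenance columns (see calibrate())")
  groups <- sort(unique(restraints$group))
  first <- match(groups, restraints$group)
  spectra <- unique(restraints$spectrum_id[first])
  list(groups = groups,
       log_I = log(restraints$intensity[first]),
       spectrum = match(restraints$spectrum_id[first], spectra),
       spectra = spectra)
}

#' Joint log-posterior of a refinement state
#'
#' @param state list with \code{conformer} (a \code{torsion_conformer}) and
#'   \code{nuisance} (list with numeric vectors \code{c} and \code{sigma},
#'   one entry per spectrum).
#' @param restraints a \code{restraint_set} with intensity provenance.
#' @param hyper a [cybay_hyper()].
#' @param params physical prior parameters.
#' @return the (unnormalized) log-posterior; finite whenever all
#'   \code{sigma > 0}.
#' @export
log_posterior <- function(state, restraints, hyper = cybay_hyper(),
                          params = prior_params()) {
  if (any(state$nuisance$sigma <= 0)) stop("sigma must be positive")
  ld <- if (nrow(restraints) > 0) likelihood_data(restraints) else NULL
  ev <- torsion_evaluator(state$conformer$sequence, restraints)
  e <- ev(state$conformer$angles)
  .log_posterior_fast(e, ld, state$nuisance, hyper)
}

# core computation from evaluator output; reff is in group order
.log_posterior_fast <- function(e, ld, nuisance, hyper) {
  lp <- -e$prior
  if (!is.null(ld)) {
    mu <- nuisance$c[ld$spectrum] - 6 * log(e$reff)
    sig <- nuisance$sigma[ld$spectrum]
    lp <- lp + sum(-(ld$log_I - mu)^2 / (2 * sig^2) - log(sig))
  }
  lp + sum(stats::dnorm(nuisance$c, hyper$mu0, hyper$tau0, log = TRUE)) +
    sum(dinvgamma_log(nuisance$sigma^2, hyper$alpha0, hyper$beta0))
}

#' Gibbs update of a log-calibration constant
#'
#' Conjugate normal draw: with n_s observations of residual
#' \code{ln I_k + 6 ln r_eff,k}, the conditional posterior of c_s is normal
#' with precision \code{beta * (1/tau0^2 + n_s/sigma_s^2)} and mean
#' \code{(mu0/tau0^2 + sum_k (ln I_k + 6 ln r_eff,k)/sigma_s^2) /
#' (1/tau0^2 + n_s/sigma_s^2)}.  With no observations the draw falls back
#' to the (tempered) prior.
#'
#' @param log_I log intensities of the spectrum's restraints.
#' @param log_reff log effective distances (same order).
#' @param sigma current noise scale of the spectrum.
#' @param hyper a [cybay_hyper()].
#' @param beta inverse temperature scaling of the tempered posterior.
#' @export
gibbs_update_c <- function(log_I, log_reff, sigma, hyper = cybay_hyper(),
                           beta = 1) {
  n <- length(log_I)
  prec0 <- 1 / hyper$tau0^2
  prec <- prec0 + n / sigma^2
  m <- (hyper$mu0 * prec0 +
        (if (n > 0) sum(log_I + 6 * log_reff) else 0) / sigma^2) / prec
  stats::rnorm(1, m, 1 / sqrt(beta * prec))
}

#' Gibbs update of a noise scale
#'
#' Conjugate inverse-gamma draw for sigma_s^2: with sum of squared
#' residuals SS over n_s observations the untempered conditional is
#' \code{IG(alpha0 + n/2, beta0 + SS/2)}; tempering by beta maps
#' \code{IG(a, b)} to \code{IG(beta (a + 1) - 1, beta b)}.
#'
#' @param resid residuals \code{ln I_k - (c_s - 6 ln r_eff,k)}.
#' @inheritParams gibbs_update_c
#' @return the new sigma (not the variance).
#' @export
gibbs_update_sigma <- function(resid, hyper = cybay_hyper(), beta = 1) {
  n <- length(resid)
  a <- hyper$alpha0 + n / 2
  b <- hyper$beta0 + sum(resid^2) / 2
  a_t <- beta * (a + 1) - 1
  b_t <- beta * b
  sqrt(1 / stats::rgamma(1, shape = a_t, rate = b_t))
}

#' Geometric replica temperature ladder
#'
#' \code{T_k = T_min * (T_max/T_min)^((k-1)/(K-1))}; inverse scales
#' \code{beta_k = T_1/T_k} so the coldest replica samples the target
#' posterior.
#'
#' @param K number of replicas (>= 1).
#' @param T_min,T_max temperature endpoints (K).
#' @export
build_ladder <- function(K = 10, T_min = 300, T_max = 400) {
  stopifnot(K >= 1, T_min > 0, T_max >= T_min)
  temps <- if (K == 1) T_min
           else T_min * (T_max / T_min)^((seq_len(K) - 1) / (K - 1))
  structure(list(temperatures = temps, beta = T_min / temps),
            class = "replica_ladder")
}

#' Replica exchange attempt
#'
#' Swaps two replica states with probability
#' \code{min(1, exp((beta_i - beta_j) * (U_i - U_j)))} where
#' \code{U = -log_posterior} at beta = 1.  The swap is atomic: conformer and
#' nuisance parameters move together.
#'
#' @param state_i,state_j replica states carrying \code{log_posterior}.
#' @param beta_i,beta_j inverse temperature scales.
#' @return list with \code{swapped} (logical), \code{p_accept}, and the two
#'   (possibly exchanged) states.
#' @export
exchange_attempt <- function(state_i, state_j, beta_i, beta_j) {
  U_i <- -state_i$log_posterior
  U_j <- -state_j$log_posterior
  p <- min(1, exp((beta_i - beta_j) * (U_i - U_j)))
  swapped <- stats::runif(1) < p
  if (swapped) { tmp <- state_i; state_i <- state_j; state_j <- tmp }
  list(swapped = swapped, p_accept = p, state_i = state_i,
       state_j = state_j)
}

#' One hybrid Monte Carlo move on a torsion vector
#'
#' A mixture proposal: with probability \code{1 - collective_prob} a single
#' torsion receives a Gaussian perturbation; otherwise all torsions receive
#' a small correlated Gaussian kick (the collective surrogate for the MD
#' leg).  Both proposals are symmetric, so the Metropolis acceptance
#' \code{min(1, exp(beta * (logpost' - logpost)))} is detailed-balance
#' correct.  A rejected move returns the input state unchanged.
#'
#' @param angles current torsion vector (degrees).
#' @param logpost current log-posterior value.
#' @param logpost_fn function(angles) -> log-posterior.
#' @param beta inverse temperature scale.
#' @param width single-torsion proposal sd (degrees).
#' @param collective_prob probability of the collective move.
#' @param collective_width per-torsion sd of the collective move (degrees).
#' @export
hybrid_move <- function(angles, logpost, logpost_fn, beta = 1, width = 10,
                        collective_prob = 0.2, collective_width = 1.5) {
  n <- length(angles)
  if (stats::runif(1) < collective_prob) {
    prop <- wrap_angle(angles + stats::rnorm(n, 0, collective_width))
    type <- "collective"
  } else {
    k <- sample.int(n, 1)
    prop <- angles
    prop[k] <- wrap_angle(prop[k] + stats::rnorm(1, 0, width))
    type <- "single"
  }
  lp_prop <- logpost_fn(prop)
  accept <- log(stats::runif(1)) < beta * (lp_prop - logpost)
  if (accept) list(angles = prop, logpost = lp_prop, accepted = TRUE,
                   type = type)
  else list(angles = angles, logpost = logpost, accepted = FALSE,
            type = type)
}

#' Replica-exchange Monte Carlo configuration
#'
#' Desk-scale defaults: 4 replicas over 300-400 K, 2e5 steps, exchange
#' attempts every 100 steps, Gibbs updates every 10 steps, snapshots every
#' 100 steps, the first fifth discarded as burn-in.
#'
#' @param n_steps total MC steps per replica.
#' @param ladder a [build_ladder()].
#' @param exchange_every,gibbs_every,stride step intervals for exchange
#'   attempts, Gibbs updates, and snapshot recording.
#' @param burn steps discarded before snapshots enter the ensemble.
#' @param width,collective_prob,collective_width see [hybrid_move()].
#' @param seed integer seed; the whole run is deterministic given it.
#' @export
rexmc_config <- function(n_steps = 2e5, ladder = build_ladder(4, 300, 400),
                         exchange_every = 100, gibbs_every = 10,
                         stride = 100, burn = floor(n_steps / 5),
                         width = 10, collective_prob = 0.2,
                         collective_width = 1.5, seed = 1) {
  list(n_steps = as.integer(n_steps), ladder = ladder,
       exchange_every = as.integer(exchange_every),
       gibbs_every = as.integer(gibbs_every), stride = as.integer(stride),
       burn = as.integer(burn), width = width,
       collective_prob = collective_prob,
       collective_width = collective_width, seed = as.integer(seed))
}

#' Replica-exchange Monte Carlo refinement
#'
#' Samples the joint posterior over conformation and nuisance parameters.
#' All replicas start from the seed conformer; snapshots are recorded only
#' from the beta = 1 (coldest) chain, every \code{stride} steps.  Exchange
#' acceptance counters are kept per adjacent ladder pair.
#'
#' @param seed_conformer a \code{torsion_conformer} (typically from
#'   [select_seed()]).
#' @param restraints a \code{restraint_set} with intensity and spectrum
#'   provenance, or a function(angles) -> log-posterior for analytic toy
#'   problems (no nuisance parameters are sampled then).
#' @param config a [rexmc_config()].
#' @param hyper a [cybay_hyper()]; \code{mu0 = NA} is replaced by the
#'   median-based auto-calibration estimate of ln C.
#' @return object of class \code{rexmc_trace}: snapshot list, per-replica
#'   log-posterior trace, exchange counters, and the resolved configuration.
#' @export
run_rexmc <- function(seed_conformer, restraints, config = rexmc_config(),
                      hyper = cybay_hyper()) {
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(config$seed)
  beta <- config$ladder$beta
  K <- length(beta)
  custom <- is.function(restraints)
  if (custom) {
    ang0 <- if (inherits(seed_conformer, "torsion_conformer"))
      seed_conformer$angles else as.numeric(seed_conformer)
    ld <- NULL
    lp_of <- function(angles, nuis) restraints(angles)
  } else {
    stopifnot(inherits(seed_conformer, "torsion_conformer"))
    ang0 <- seed_conformer$angles
    ld <- if (nrow(restraints) > 0) likelihood_data(restraints) else NULL
    if (is.na(hyper$mu0)) {
      hyper$mu0 <- log(stats::median(restraints$intensity) * 4^6)
    }
  }
  n_spec <- if (is.null(ld)) 0L else length(ld$spectra)
  init_nuis <- list(c = rep(if (n_spec) hyper$mu0 else numeric(0),
                            length.out = n_spec),
                    sigma = rep(0.5, n_spec))
  ex_attempts <- integer(max(K - 1, 1)); ex_accepts <- integer(max(K - 1, 1))
  n_snap_max <- config$n_steps %/% config$stride
  snapshots <- vector("list", n_snap_max)
  log_step <- integer(n_snap_max); log_lp <- matrix(NA_real_, n_snap_max, K)
  isnap <- 0L
  record <- function(step, reps) {
    isnap <<- isnap + 1L
    log_step[isnap] <<- step
    log_lp[isnap, ] <<- vapply(reps, `[[`, numeric(1), "lp")
    snapshots[[isnap]] <<- list(step = step, angles = reps[[1]]$angles,
                                nuisance = reps[[1]]$nuisance,
                                log_posterior = reps[[1]]$lp)
  }
  try_exchange <- function(step, reps) {
    start <- if ((step %/% config$exchange_every) %% 2 == 0) 1L else 2L
    if (K < 2 || start > K - 1) return(reps)
    for (k in seq(start, K - 1, by = 2)) {
      ex_attempts[k] <<- ex_attempts[k] + 1L
      p <- min(1, exp((beta[k] - beta[k + 1]) *
                      (-reps[[k]]$lp + reps[[k + 1]]$lp)))
      if (stats::runif(1) < p) {
        tmp <- reps[[k]]; reps[[k]] <- reps[[k + 1]]; reps[[k + 1]] <- tmp
        ex_accepts[k] <<- ex_accepts[k] + 1L
      }
    }
    reps
  }
  if (custom) {
    reps <- lapply(seq_len(K), function(k)
      list(angles = ang0, nuisance = NULL, lp = restraints(ang0)))
    for (step in seq_len(config$n_steps)) {
      for (k in seq_len(K)) {
        st <- reps[[k]]
        mv <- hybrid_move(st$angles, st$lp, restraints, beta = beta[k],
                          width = config$width,
                          collective_prob = config$collective_prob,
                          collective_width = config$collective_width)
        reps[[k]] <- list(angles = mv$angles, nuisance = NULL,
                          lp = mv$logpost)
      }
      if (K > 1 && step %% config$exchange_every == 0)
        reps <- try_exchange(step, reps)
      if (step %% config$stride == 0) record(step, reps)
    }
  } else {
    # compiled batches of torsion moves between Gibbs/exchange epochs
    ma <- mc_model_args(seed_conformer$sequence, restraints)
    spec0 <- if (is.null(ld)) integer(0) else ld$spectrum - 1L
    logI <- if (is.null(ld)) numeric(0) else ld$log_I
    nuis_prior <- function(nu) {
      if (n_spec == 0) return(0)
      sum(stats::dnorm(nu$c, hyper$mu0, hyper$tau0, log = TRUE)) +
        sum(dinvgamma_log(nu$sigma^2, hyper$alpha0, hyper$beta0))
    }
    block <- config$gibbs_every
    stopifnot(config$exchange_every %% block == 0,
              config$stride %% block == 0)
    sel_list <- lapply(seq_len(n_spec), function(s) which(ld$spectrum == s))
    logI_list <- lapply(sel_list, function(sel) logI[sel])
    reps <- vector("list", K)
    for (k in seq_len(K)) {
      r0 <- rexmc_batch_cpp(ma$plan, ma$pairs, ma$rest, ma$aco, ang0, logI,
                            spec0, init_nuis$c, init_nuis$sigma, 0L,
                            beta[k], config$width, config$collective_prob,
                            config$collective_width, ma$params$k_rep,
                            ma$params$k_tor, 0.0025, ma$n_dof)
      reps[[k]] <- list(angles = ang0, nuisance = init_nuis,
                        core = r0$core_lp, reff = r0$reff,
                        lp = r0$core_lp + nuis_prior(init_nuis))
    }
    n_blocks <- config$n_steps %/% block
    for (b in seq_len(n_blocks)) {
      step <- b * block
      for (k in seq_len(K)) {
        st <- reps[[k]]
        r <- rexmc_batch_cpp(ma$plan, ma$pairs, ma$rest, ma$aco, st$angles,
                             logI, spec0, st$nuisance$c, st$nuisance$sigma,
                             block, beta[k], config$width,
                             config$collective_prob,
                             config$collective_width, ma$params$k_rep,
                             ma$params$k_tor, 0.0025, ma$n_dof)
        st$angles <- r$angles; st$core <- r$core_lp; st$reff <- r$reff
        if (n_spec > 0) {  # Gibbs pass on the nuisance parameters
          lr <- log(st$reff)
          dcore <- 0
          for (s in seq_len(n_spec)) {
            sel <- sel_list[[s]]
            lrs <- lr[sel]; lis <- logI_list[[s]]; ns <- length(sel)
            c_new <- gibbs_update_c(lis, lrs, st$nuisance$sigma[s], hyper,
                                    beta = beta[k])
            resid <- lis - (c_new - 6 * lrs)
            sig_new <- gibbs_update_sigma(resid, hyper, beta = beta[k])
            # likelihood delta from the nuisance update
            resid_old <- lis - (st$nuisance$c[s] - 6 * lrs)
            dcore <- dcore +
              (-sum(resid^2) / (2 * sig_new^2) - ns * log(sig_new)) -
              (-sum(resid_old^2) / (2 * st$nuisance$sigma[s]^2) -
                 ns * log(st$nuisance$sigma[s]))
            st$nuisance$c[s] <- c_new
            st$nuisance$sigma[s] <- sig_new
          }
          st$core <- st$core + dcore
        }
        st$lp <- st$core + nuis_prior(st$nuisance)
        reps[[k]] <- st
      }
      if (K > 1 && step %% config$exchange_every == 0)
        reps <- try_exchange(step, reps)
      if (step %% config$stride == 0) record(step, reps)
    }
  }
  structure(list(snapshots = snapshots[seq_len(isnap)],
                 log = data.frame(step = log_step[seq_len(isnap)],
                                  log_lp[seq_len(isnap), , drop = FALSE]),
                 exchange = data.frame(pair = seq_len(max(K - 1, 0)),
                                       attempts = ex_attempts[seq_len(max(K - 1, 0))],
                                       accepts = ex_accepts[seq_len(max(K - 1, 0))]),
                 config = config, hyper = if (custom) NULL else hyper,
                 sequence = if (custom) NULL else seed_conformer$sequence,
                 custom = custom),
            class = "rexmc_trace")
}

#' @export
print.rexmc_trace <- function(x, ...) {
  cat("rexmc_trace:", length(x$snapshots), "snapshots,",
      length(x$config$ladder$beta), "replicas,", x$config$n_steps,
      "steps\n")
  if (nrow(x$exchange) > 0) {
    rate <- ifelse(x$exchange$attempts > 0,
                   x$exchange$accepts / x$exchange$attempts, NA)
    cat("exchange acceptance:", paste(round(rate, 2), collapse = " "), "\n")
  }
  invisible(x)
}

#' Burn-in and thinning of a trace
#'
#' Keeps every snapshot whose MC step index exceeds \code{burn} and is a
#' multiple of \code{stride}.
#'
#' @param trace a \code{rexmc_trace}.
#' @param burn steps to discard.
#' @param stride thinning interval in MC steps (a multiple of the recording
#'   stride).
#' @return object of class \code{posterior_ensemble}.
#' @export
burn_and_thin <- function(trace, burn = trace$config$burn,
                          stride = trace$config$stride) {
  steps <- vapply(trace$snapshots, `[[`, numeric(1), "step")
  keep <- steps > burn & steps %% stride == 0
  if (!any(keep)) warning("burn-in leaves an empty ensemble")
  structure(list(states = trace$snapshots[keep],
                 sequence = trace$sequence),
            class = "posterior_ensemble")
}

#' @export
print.posterior_ensemble <- function(x, ...) {
  cat("posterior_ensemble:", length(x$states), "states\n")
  invisible(x)
}

#' Maximum a posteriori state of an ensemble
#'
#' The member with the highest recorded log-posterior; ties break to the
#' lowest index.
#'
#' @param ensemble a \code{posterior_ensemble}.
#' @export
map_state <- function(ensemble) {
  lp <- vapply(ensemble$states, `[[`, numeric(1), "log_posterior")
  ensemble$states[[which.max(lp)]]
}
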