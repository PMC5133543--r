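# toy structure + restraints reused across blocks
toy_state <- function(c_s = 12, sigma_s = 0.3, n_rest = 5, seed = 8) {
  conf <- make_reference_structure("hairpin12")
  s <- build_coordinates(conf)
  set.seed(seed)
  pairs <- list(c(3, "HA", 9, "H"), c(1, "HA", 12, "H"),
                c(2, "H", 10, "HA"), c(4, "HB", 8, "HA"),
                c(5, "HA", 8, "H"))[seq_len(n_rest)]
  rs <- do.call(rbind, lapply(seq_along(pairs), function(g) {
    p <- pairs[[g]]
    simple_restraint(as.integer(p[1]), p[2], as.integer(p[3]), p[4],
                     upper = 6, group = as.integer(g))
  }))
  class(rs) <- c("restraint_set", "data.frame")
  reff <- effective_distance(s, rs)
  rs$spectrum_id <- "s1"
  rs$intensity <- exp(c_s - 6 * log(reff[as.character(rs$group)]) +
                      rnorm(n_rest, 0, 0.0))
  list(conf = conf, s = s, rs = rs, reff = unname(reff))
}

test_that("the log-posterior decomposes into likelihood, nuisance priors and
           physical prior", {
  tt <- toy_state()
  hyper <- cybay_hyper(mu0 = 11, tau0 = 2, alpha0 = 2, beta0 = 0.5)
  nuis <- list(c = 12, sigma = 0.3)
  state <- list(conformer = tt$conf, nuisance = nuis)

  # zero restraints: exactly the nuisance priors minus the prior energy
  lp0 <- log_posterior(list(conformer = tt$conf, nuisance = nuis),
                       empty_restraint_set(), hyper)
  expected0 <- dnorm(12, 11, 2, log = TRUE) +
    (hyper$alpha0 * log(hyper$beta0) - lgamma(hyper$alpha0) -
     (hyper$alpha0 + 1) * log(0.3^2) - hyper$beta0 / 0.3^2) -
    prior_energy(tt$conf)
  expect_equal(lp0, expected0, tolerance = 1e-10)

  # a zero-residual restraint contributes exactly -log(sigma)
  one <- tt$rs[tt$rs$group == 1, ]
  class(one) <- c("restraint_set", "data.frame")
  lp1 <- log_posterior(state, one, hyper)
  expect_equal(lp1 - lp0, -log(0.3), tolerance = 1e-10)

  # five-restraint case against an independent term-by-term summation
  lp5 <- log_posterior(state, tt$rs, hyper)
  byhand <- lp0
  for (g in 1:5) {
    r_g <- tt$reff[g]
    I_g <- tt$rs$intensity[tt$rs$group == g][1]
    byhand <- byhand - (log(I_g) - (12 - 6 * log(r_g)))^2 / (2 * 0.3^2) -
      log(0.3)
  }
  expect_equal(lp5, byhand, tolerance = 1e-10)

  expect_error(log_posterior(list(conformer = tt$conf,
                                  nuisance = list(c = 12, sigma = -1)),
                             tt$rs, hyper), "sigma")
})

test_that("the conjugate c update matches 1-D quadrature of prior times
           likelihood", {
  hyper <- cybay_hyper(mu0 = 10, tau0 = 1.5, alpha0 = 2, beta0 = 0.5)
  log_I <- c(11.2, 10.8, 11.5, 10.9)
  log_r <- c(1.1, 1.3, 0.9, 1.2)
  sigma <- 0.4
  # analytic conjugate posterior
  prec <- 1 / hyper$tau0^2 + length(log_I) / sigma^2
  mean_a <- (hyper$mu0 / hyper$tau0^2 +
             sum(log_I + 6 * log_r) / sigma^2) / prec
  dens <- function(c) dnorm(c, hyper$mu0, hyper$tau0) *
    vapply(c, function(ci)
      prod(dnorm(log_I, ci - 6 * log_r, sigma)), numeric(1))
  Z <- integrate(dens, mean_a - 10, mean_a + 10, rel.tol = 1e-12)$value
  m_q <- integrate(function(c) c * dens(c) / Z, mean_a - 10, mean_a + 10,
                   rel.tol = 1e-12)$value
  v_q <- integrate(function(c) (c - m_q)^2 * dens(c) / Z, mean_a - 10,
                   mean_a + 10, rel.tol = 1e-12)$value
  expect_equal(m_q, mean_a, tolerance = 1e-6)
  expect_equal(v_q, 1 / prec, tolerance = 1e-6)

  # draws follow that posterior
  set.seed(31)
  draws <- replicate(4000, gibbs_update_c(log_I, log_r, sigma, hyper))
  expect_equal(mean(draws), mean_a, tolerance = 0.01)
  expect_equal(var(draws), 1 / prec, tolerance = 0.08)

  # no observations: the prior
  set.seed(32)
  prior_draws <- replicate(4000, gibbs_update_c(numeric(0), numeric(0),
                                                sigma, hyper))
  expect_equal(mean(prior_draws), hyper$mu0, tolerance = 0.1)
  expect_equal(sd(prior_draws), hyper$tau0, tolerance = 0.1)

  # flat-prior limit with one observation centers on ln I + 6 ln r
  flat <- cybay_hyper(mu0 = 0, tau0 = 1e6)
  set.seed(33)
  d1 <- replicate(4000, gibbs_update_c(11.2, 1.1, 0.4, flat))
  expect_equal(mean(d1), 11.2 + 6 * 1.1, tolerance = 0.05)
})

test_that("the conjugate sigma update matches quadrature and is consistent
           at large n", {
  hyper <- cybay_hyper(alpha0 = 2, beta0 = 0.5)
  resid <- c(0.25, -0.4, 0.1)
  a_post <- hyper$alpha0 + length(resid) / 2
  b_post <- hyper$beta0 + sum(resid^2) / 2
  # quadrature of prior x likelihood over the variance v
  dens <- function(v) exp((-(hyper$alpha0 + 1)) * log(v) -
                          hyper$beta0 / v) *
    vapply(v, function(vi)
      prod(dnorm(resid, 0, sqrt(vi))), numeric(1))
  Z <- integrate(dens, 1e-8, Inf, rel.tol = 1e-12)$value
  m_q <- integrate(function(v) v * dens(v) / Z, 1e-8, Inf,
                   rel.tol = 1e-12)$value
  # analytic IG mean b/(a-1)
  expect_equal(m_q, b_post / (a_post - 1), tolerance = 1e-6)

  set.seed(41)
  draws <- replicate(6000, gibbs_update_sigma(resid, hyper))^2
  expect_equal(mean(draws), b_post / (a_post - 1), tolerance = 0.05)

  # large-n: posterior mean of sigma^2 near the true residual variance
  set.seed(42)
  big <- rnorm(1e4, 0, sqrt(0.7))
  s2 <- mean(replicate(200, gibbs_update_sigma(big, hyper))^2)
  expect_lt(abs(s2 - 0.7) / 0.7, 0.05)
})

test_that("the replica ladder is geometric with exact endpoints", {
  lad <- build_ladder(10, 300, 400)
  expect_length(lad$temperatures, 10)
  expect_equal(lad$temperatures[1], 300)
  expect_equal(lad$temperatures[10], 400)
  ratios <- lad$temperatures[-1] / lad$temperatures[-10]
  expect_lt(max(ratios) - min(ratios), 1e-12)
  expect_equal(lad$beta[1], 1)
  expect_equal(build_ladder(2, 300, 400)$temperatures, c(300, 400))
})

test_that("exchange acceptance follows min(1, exp((beta_i - beta_j)(U_i -
           U_j))) empirically", {
  si <- list(log_posterior = 0)    # U_i = 0
  sj <- list(log_posterior = -2)   # U_j = 2, so U_i - U_j = -2
  r0 <- exchange_attempt(si, si, 1, 0.5)
  expect_equal(r0$p_accept, 1)

  set.seed(77)
  acc <- replicate(1e5, exchange_attempt(si, sj, 1, 0.5)$swapped)
  p <- exp(-1)
  se <- sqrt(p * (1 - p) / 1e5)
  expect_lt(abs(mean(acc) - p), 3 * se)

  # swap moves the full states atomically
  set.seed(1)
  repeat {
    r <- exchange_attempt(list(log_posterior = 0, tag = "a"),
                          list(log_posterior = 5, tag = "b"), 1, 0.5)
    if (r$swapped) break
  }
  expect_equal(r$state_i$tag, "b")
  expect_equal(r$state_j$tag, "a")
})

test_that("hybrid moves accept equal-posterior proposals, leave rejected
           states bit-identical, and match the analytic acceptance rate on a
           quadratic posterior", {
  flat <- function(a) 0
  set.seed(5)
  for (k in 1:50)
    expect_true(hybrid_move(c(10, 20), 0, flat)$accepted)

  # a rejected move returns the input unchanged
  set.seed(6)
  angles <- c(12.5, -37.25)
  out <- hybrid_move(angles, 0, function(a) -Inf)
  expect_false(out$accepted)
  expect_identical(out$angles, angles)

  # empirical acceptance vs a quadrature oracle for a 1-torsion Gaussian
  s2 <- 100; w <- 8
  lp <- function(a) -a^2 / (2 * s2)
  # oracle: E_x E_d[min(1, exp(lp(x+d) - lp(x)))] under the stationary law
  xs <- seq(-60, 60, length.out = 401)
  ds <- seq(-40, 40, length.out = 401)
  px <- dnorm(xs, 0, sqrt(s2)); pd <- dnorm(ds, 0, w)
  acc_mat <- outer(xs, ds, function(x, d)
    pmin(1, exp((x^2 - (x + d)^2) / (2 * s2))))
  oracle <- sum((px %o% pd) * acc_mat) * diff(xs)[1] * diff(ds)[1]

  set.seed(8)
  x <- 0; n_acc <- 0; lpx <- lp(x); n <- 2e4
  for (i in seq_len(n)) {
    mv <- hybrid_move(x, lpx, lp, width = w, collective_prob = 0)
    if (mv$accepted) n_acc <- n_acc + 1
    x <- mv$angles; lpx <- mv$logpost
  }
  se <- sqrt(oracle * (1 - oracle) / n)
  expect_lt(abs(n_acc / n - oracle), 5 * se)
})

test_that("REXMC on an analytic quadratic posterior reproduces the marginal
           variance", {
  s2 <- 64
  lp <- function(a) -sum(a^2) / (2 * s2)
  cfg <- rexmc_config(n_steps = 1e5, ladder = build_ladder(1, 300, 300),
                      stride = 10, burn = 5000, width = 12,
                      collective_prob = 0, seed = 17)
  tr <- run_rexmc(0, lp, cfg)
  ens <- burn_and_thin(tr)
  draws <- vapply(ens$states, `[[`, numeric(1), "angles")
  expect_lt(abs(var(draws) - s2) / s2, 0.05)
})

test_that("identical-temperature replicas always exchange and snapshot
           counts follow the stride arithmetic", {
  lp <- function(a) -sum(a^2) / 50
  cfg <- rexmc_config(n_steps = 2000, ladder = build_ladder(2, 300, 300),
                      stride = 100, burn = 0, exchange_every = 100,
                      seed = 3, collective_prob = 0)
  tr <- run_rexmc(c(0, 0), lp, cfg)
  expect_equal(tr$exchange$accepts, tr$exchange$attempts)
  expect_equal(length(tr$snapshots), 2000 / 100)
})

test_that("burn-in and thinning keep exactly the post-burn stride
           multiples", {
  fake_trace <- function(steps) {
    structure(list(snapshots = lapply(steps, function(s)
      list(step = s, angles = 0, nuisance = NULL, log_posterior = -s)),
      config = list(burn = 0, stride = 1), sequence = NULL),
      class = "rexmc_trace")
  }
  # production-scale bookkeeping: 1e7 steps, burn 1e6, one every 5000 -> 1800
  tr <- fake_trace(seq(5000, 1e7, by = 5000))
  ens <- burn_and_thin(tr, burn = 1e6, stride = 5000)
  expect_length(ens$states, 1800)

  tr2 <- fake_trace(1:100)
  expect_length(burn_and_thin(tr2, burn = 30, stride = 1)$states, 70)
  expect_warning(e <- burn_and_thin(tr2, burn = 100, stride = 1), "empty")
  expect_length(e$states, 0)
})

test_that("the MAP state maximizes the recorded log-posterior with
           first-index tie-break", {
  mk <- function(lps) structure(list(states = lapply(seq_along(lps),
    function(i) list(angles = i, log_posterior = lps[i])),
    sequence = NULL), class = "posterior_ensemble")
  expect_equal(map_state(mk(c(-5, -1, -3)))$angles, 2)
  expect_equal(map_state(mk(c(-1, -1)))$angles, 1)
  set.seed(12)
  for (k in 1:10) {
    lps <- rnorm(9)
    expect_equal(map_state(mk(lps))$angles, which(lps == max(lps))[1])
  }
})
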