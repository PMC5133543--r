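# random rigid motion applied to a coordinate matrix
rigid <- function(xyz, seed) {
  set.seed(seed)
  th <- runif(3, -pi, pi)
  Rx <- matrix(c(1, 0, 0, 0, cos(th[1]), -sin(th[1]),
                 0, sin(th[1]), cos(th[1])), 3, 3, byrow = TRUE)
  Rz <- matrix(c(cos(th[2]), -sin(th[2]), 0, sin(th[2]), cos(th[2]), 0,
                 0, 0, 1), 3, 3, byrow = TRUE)
  sweep(xyz %*% t(Rx %*% Rz), 2, runif(3, -10, 10), "+")
}

apply_rigid <- function(s, seed) {
  xyz <- rigid(as.matrix(s$atoms[, c("x", "y", "z")]), seed)
  s$atoms$x <- xyz[, 1]; s$atoms$y <- xyz[, 2]; s$atoms$z <- xyz[, 3]
  s
}

# brute-force superposition oracle: coarse random rotation scan plus local
# Nelder-Mead refinement over Euler angles
oracle_rmsd <- function(X, Y) {
  rot <- function(e) {
    cz <- cos(e[1]); sz <- sin(e[1]); cy <- cos(e[2]); sy <- sin(e[2])
    cx <- cos(e[3]); sx <- sin(e[3])
    matrix(c(cz * cy, cz * sy * sx - sz * cx, cz * sy * cx + sz * sx,
             sz * cy, sz * sy * sx + cz * cx, sz * sy * cx - cz * sx,
             -sy, cy * sx, cy * cx), 3, 3, byrow = TRUE)
  }
  X0 <- sweep(X, 2, colMeans(X)); Y0 <- sweep(Y, 2, colMeans(Y))
  f <- function(e) sqrt(mean(rowSums((X0 %*% t(rot(e)) - Y0)^2)))
  set.seed(1)
  starts <- matrix(runif(3 * 200, -pi, pi), ncol = 3)
  vals <- apply(starts, 1, f)
  best <- starts[which.min(vals), ]
  o <- optim(best, f, control = list(reltol = 1e-14, maxit = 5000))
  o$value
}

test_that("Kabsch superposition is exact on rigid copies and optimal on
           random point sets", {
  s <- build_coordinates(make_reference_structure("hairpin12"))
  sel <- select_atoms(s, "backbone")
  expect_equal(kabsch_superpose(s, s, sel)$rmsd, 0, tolerance = 1e-12)

  moved <- apply_rigid(s, 4)
  fit <- kabsch_superpose(moved, s, sel)
  expect_lt(fit$rmsd, 1e-9)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-9)

  set.seed(9)
  for (k in 1:5) {
    X <- matrix(rnorm(15), 5, 3)
    Y <- matrix(rnorm(15), 5, 3)
    r <- kabsch_superpose(X, Y)$rmsd
    expect_equal(r, oracle_rmsd(X, Y), tolerance = 1e-3)
    expect_lte(r, oracle_rmsd(X, Y) + 1e-9)  # never worse than the scan
  }

  collinear <- cbind(1:5, 2 * (1:5), -(1:5))
  expect_error(kabsch_superpose(collinear, collinear + 1), "degenerate")
})

test_that("the iterative mean structure reproduces exact and symmetric
           cases, independent of member order", {
  s <- build_coordinates(make_reference_structure("hairpin12"))
  same <- list(s, s, s)
  ms <- mean_structure(same)
  expect_equal(ms$mean, as.matrix(s$atoms[, c("x", "y", "z")]),
               tolerance = 1e-9, ignore_attr = TRUE)

  # two members symmetric about a midpoint (perturbation orthogonal to
  # rigid motions) average to the midpoint
  X <- as.matrix(s$atoms[, c("x", "y", "z")])
  set.seed(3)
  d <- matrix(rnorm(length(X), 0, 1e-4), nrow(X), 3)
  d <- sweep(d, 2, colMeans(d))              # no net translation
  Xc <- sweep(X, 2, colMeans(X))
  # remove the infinitesimal-rotation component (net torque)
  tq <- colSums(cbind(Xc[, 2] * d[, 3] - Xc[, 3] * d[, 2],
                      Xc[, 3] * d[, 1] - Xc[, 1] * d[, 3],
                      Xc[, 1] * d[, 2] - Xc[, 2] * d[, 1]))
  I3 <- diag(sum(Xc^2), 3) - crossprod(Xc)
  om <- solve(I3, tq)
  d <- d - cbind(om[2] * Xc[, 3] - om[3] * Xc[, 2],
                 om[3] * Xc[, 1] - om[1] * Xc[, 3],
                 om[1] * Xc[, 2] - om[2] * Xc[, 1])
  mk <- function(xyz) { t <- s; t$atoms$x <- xyz[, 1]
                        t$atoms$y <- xyz[, 2]; t$atoms$z <- xyz[, 3]; t }
  pair <- list(mk(X + d), mk(X - d))
  ms2 <- mean_structure(pair, selection = seq_len(nrow(X)))
  expect_equal(ms2$mean, X, tolerance = 1e-6, ignore_attr = TRUE)

  # member order does not change the converged mean (up to rigid motion,
  # which the initial reference frame sets)
  ens <- lapply(1:4, function(k) mk(X + matrix(rnorm(length(X), 0, 0.3),
                                               nrow(X), 3)))
  m1 <- mean_structure(ens)$mean
  m2 <- mean_structure(rev(ens))$mean
  expect_lt(kabsch_superpose(m1, m2)$rmsd, 1e-6)
})

test_that("rmsd_to_mean is zero on identical copies, agrees with direct
           recomputation, and is rigid-motion invariant", {
  s <- build_coordinates(make_reference_structure("hairpin12"))
  expect_equal(rmsd_to_mean(list(s, s, s)), 0, tolerance = 1e-9)

  set.seed(5)
  ens <- lapply(1:5, function(k) {
    t <- s
    t$atoms$x <- t$atoms$x + rnorm(nrow(t$atoms), 0, 0.4)
    t$atoms$y <- t$atoms$y + rnorm(nrow(t$atoms), 0, 0.4)
    t$atoms$z <- t$atoms$z + rnorm(nrow(t$atoms), 0, 0.4)
    t
  })
  sel <- select_atoms(s, "backbone")
  r <- rmsd_to_mean(ens)
  ms <- mean_structure(ens, sel)
  direct <- mean(vapply(ens, function(e)
    kabsch_superpose(as.matrix(e$atoms[, c("x", "y", "z")]), ms$mean,
                     sel)$rmsd, numeric(1)))
  expect_equal(r, direct, tolerance = 1e-9)

  moved <- lapply(seq_along(ens), function(k) apply_rigid(ens[[k]], k))
  expect_equal(rmsd_to_mean(moved), r, tolerance = 1e-7)
})

test_that("per-residue RMSD localizes a constructed side-chain displacement
           and flags glycine in side-chain mode", {
  s <- build_coordinates(make_reference_structure("hairpin12"))
  ens <- lapply(1:4, function(k) {
    t <- s
    sel <- which(t$atoms$resno == 7 &
                 t$atoms$name %in% c("CB", "CG", "CG1", "CG2", "CD",
                                     "CD1", "CD2"))
    sel <- which(t$atoms$resno == 10 & !t$atoms$name %in%
                   c("N", "CA", "C", "O", "H", "HA"))
    t$atoms$x[sel] <- t$atoms$x[sel] + 2
    t
  })
  prof <- per_residue_rmsd(ens, s, "sidechain")
  expect_equal(prof$resno[which.max(prof$rmsd)], 10)

  bb <- per_residue_rmsd(list(s, s), s, "backbone")
  expect_true(all(bb$rmsd < 1e-9))

  # glycine has no side-chain selection
  gly <- which(s$sequence == "GLY")
  sc <- per_residue_rmsd(list(s, s), s, "sidechain")
  expect_true(is.na(sc$rmsd[sc$resno == gly]))
})

test_that("ensemble PCA separates a constructed one-dimensional family", {
  s <- build_coordinates(make_reference_structure("hairpin12"))
  X <- as.matrix(s$atoms[, c("x", "y", "z")])
  expect_true(all(pca_ensemble(list(s, s, s))$variance_fraction == 0))

  set.seed(11)
  dirn <- matrix(rnorm(length(X)), nrow(X), 3)
  dirn <- dirn / sqrt(sum(dirn^2))
  ens <- lapply(rnorm(12, 0, 1.5), function(a) {
    t <- s; Y <- X + a * dirn
    t$atoms$x <- Y[, 1]; t$atoms$y <- Y[, 2]; t$atoms$z <- Y[, 3]; t
  })
  pca <- pca_ensemble(ens, selection = seq_len(nrow(X)))
  expect_gte(pca$variance_fraction[1], 0.99)
  expect_true(all(diff(pca$variance_fraction) <= 1e-12))
  G <- crossprod(pca$components[, 1:3])
  expect_equal(G, diag(3), tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("subsampling matches the production-scale ensemble counts and preserves
           order", {
  mk <- function(n) structure(list(states = lapply(seq_len(n), function(i)
    list(angles = i, log_posterior = 0)), sequence = NULL),
    class = "posterior_ensemble")
  expect_length(subsample(mk(1900), 0.2, seed = 1)$states, 380)
  expect_length(subsample(mk(1800), 0.2, seed = 1)$states, 360)
  full <- subsample(mk(25), 1.0, seed = 2)
  expect_equal(vapply(full$states, `[[`, numeric(1), "angles"), 1:25)

  sub <- subsample(mk(100), 0.3, seed = 3)
  ids <- vapply(sub$states, `[[`, numeric(1), "angles")
  expect_length(ids, 30)
  expect_false(is.unsorted(ids))
  expect_true(all(ids %in% 1:100))
  sub2 <- subsample(mk(100), 0.3, seed = 3)
  expect_identical(ids, vapply(sub2$states, `[[`, numeric(1), "angles"))
})
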