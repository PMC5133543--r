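shift_fixture <- function() {
  sh <- data.frame(
    resno = c(3L, 9L, 5L, 6L, 7L),
    restype = c("ALA", "LYS", "VAL", "LEU", "SER"),
    atom = c("HA", "H", "HA", "HB2", "HA"),
    shift = c(4.20, 8.50, 4.80, 1.60, 4.805),
    error = 0, stringsAsFactors = FALSE)
  class(sh) <- c("shift_table", "data.frame")
  sh
}

peak_row <- function(w1, w2, intensity = 1000, id = 1L) {
  pk <- data.frame(peak_id = id, w1 = w1, w2 = w2, intensity = intensity,
                   spectrum_id = "s1", stringsAsFactors = FALSE)
  class(pk) <- c("peak_list", "data.frame")
  pk
}

test_that("chemical-shift matching applies the per-dimension tolerance", {
  sh <- shift_fixture()
  # exact hit on (HA res 3, H res 9)
  cand <- match_assignments(peak_row(4.20, 8.50), sh)
  opts <- cand[[1]]$options
  expect_true(any(opts$res_i == 3 & opts$atom_i == "HA" &
                  opts$res_j == 9 & opts$atom_j == "H"))

  # 0.05 ppm off in a 1H dimension with tolerance 0.04 is excluded
  cand2 <- match_assignments(peak_row(4.25, 8.50), sh)
  expect_false(any(cand2[[1]]$options$res_i == 3 &
                   cand2[[1]]$options$atom_i == "HA"))
  expect_true(nrow(match_assignments(peak_row(4.24, 8.50),
                                     sh)[[1]]$options) > 0)

  # two degenerate shifts in dimension 1 (4.80 vs 4.805), one option in
  # dimension 2 -> exactly 2 options (cross-product oracle)
  cand3 <- match_assignments(peak_row(4.80, 8.50), sh)
  expect_equal(nrow(cand3[[1]]$options), 2)

  # a peak matching nothing is flagged unassigned
  cand4 <- match_assignments(peak_row(2.0, 3.0), sh)
  expect_false(cand4[[1]]$assigned)
})

test_that("the network-support filter removes unsupported long-range options
           and keeps supported ones", {
  sh <- shift_fixture()
  cand <- match_assignments(peak_row(4.20, 8.50), sh)  # lone 3-9 contact
  expect_identical(network_filter(cand, 0), cand)
  filt <- network_filter(cand, 1)
  expect_false(filt[[1]]$assigned)

  # three mutually supporting contacts: 3-9, 4-9, 4-10 each have the other
  # two as (i +/- 1, j +/- 1) neighbors
  pk3 <- rbind(peak_row(4.20, 8.50, id = 1L),
               peak_row(4.80, 8.50, id = 2L),
               peak_row(1.60, 8.90, id = 3L))
  class(pk3) <- c("peak_list", "data.frame")
  sh2 <- shift_fixture()
  sh2$resno <- c(3L, 9L, 4L, 4L, 10L)
  sh2$atom <- c("HA", "H", "HA", "HB2", "H")
  sh2$shift <- c(4.20, 8.50, 4.80, 1.60, 8.90)
  cand3 <- match_assignments(pk3, sh2)
  filt3 <- network_filter(cand3, 2)
  expect_true(all(vapply(filt3, `[[`, logical(1), "assigned")))
})

test_that("calibration follows I = C/r^6 with clipping and skips nonpositive
           intensities", {
  sh <- shift_fixture()
  cand <- match_assignments(peak_row(4.20, 8.50, intensity = 1), sh)
  rs <- calibrate(cand, calibration_model("s1", C = 64, d_min = 1,
                                          d_max = 10))
  expect_equal(rs$upper[1], 2.0, tolerance = 1e-12)

  # I = C gives d = 1, clipped up to d_min = 2.4
  cand2 <- match_assignments(peak_row(4.20, 8.50, intensity = 64), sh)
  rs2 <- calibrate(cand2, calibration_model("s1", C = 64))
  expect_equal(rs2$upper[1], 2.4)

  cand3 <- match_assignments(peak_row(4.20, 8.50, intensity = -5), sh)
  expect_warning(rs3 <- calibrate(cand3, calibration_model("s1", 64)),
                 "nonpositive")
  expect_equal(nrow(rs3), 0)
})

test_that("auto-calibration places the median derived distance at the
           target", {
  I <- c(10, 55, 3.2, 800, 120, 41, 7.7)
  model <- auto_calibrate(I, target_median = 4.0, d_min = 1, d_max = 10)
  expect_equal(model$C, stats::median(I) * 4^6)
  d <- pmin(pmax((model$C / I)^(1 / 6), model$d_min), model$d_max)
  expect_equal(stats::median(d), 4.0, tolerance = 1e-12)
})

test_that("sequence-range classification follows the |i-j| convention", {
  expect_equal(classify_range(5, 5), "intra")
  expect_equal(classify_range(5, 6), "sequential")
  expect_equal(classify_range(6, 5), "sequential")
  expect_equal(classify_range(5, 8), "medium")
  expect_equal(classify_range(3, 9), "long")
  expect_equal(classify_range(c(1, 1, 1), c(1, 3, 20)),
               c("intra", "medium", "long"))
})

test_that("effective distance implements the r^-6 sum over options", {
  s <- build_coordinates(make_reference_structure("hairpin12"))
  r1 <- simple_restraint(3, "HA", 9, "H", 6.0)
  d_true <- sqrt(sum((as.matrix(s$atoms[atom_index(s, 3, "HA"),
                                        c("x", "y", "z")]) -
                      as.matrix(s$atoms[atom_index(s, 9, "H"),
                                        c("x", "y", "z")]))^2))
  expect_equal(unname(effective_distance(s, r1)), d_true,
               tolerance = 1e-10)

  # two identical options give r * 2^(-1/6)
  r2 <- rbind(simple_restraint(3, "HA", 9, "H", 6.0),
              simple_restraint(3, "HA", 9, "H", 6.0))
  class(r2) <- c("restraint_set", "data.frame")
  expect_equal(unname(effective_distance(s, r2)),
               d_true * 2^(-1 / 6), tolerance = 1e-10)
  # and r_eff never exceeds the closest option
  expect_lt(effective_distance(s, r2), d_true)
})

test_that("effective distance matches direct evaluation for 3.0 and 6.0
           Angstrom options", {
  expect_equal((3^-6 + 6^-6)^(-1 / 6), 2.99199, tolerance = 1e-4)
})

test_that("the target function sums squared violations and is zero iff
           satisfied", {
  s <- build_coordinates(make_reference_structure("hairpin12"))
  d <- unname(effective_distance(s, simple_restraint(3, "HA", 9, "H", 6)))

  sat <- simple_restraint(3, "HA", 9, "H", d + 1)
  expect_equal(target_function(s, sat), 0)

  viol <- simple_restraint(3, "HA", 9, "H", d - 0.5)
  expect_equal(target_function(s, viol), 0.25, tolerance = 1e-9)

  two <- rbind(simple_restraint(3, "HA", 9, "H", d - 0.3, group = 1L),
               simple_restraint(3, "HA", 5, "HA", NA, group = 2L))
  d2 <- unname(effective_distance(s, simple_restraint(3, "HA", 5, "HA", 9)))
  two$upper[2] <- d2 - 0.4
  class(two) <- c("restraint_set", "data.frame")
  expect_equal(target_function(s, two), 0.09 + 0.16, tolerance = 1e-9)
})

test_that("dihedral restraints contribute weighted squared violations", {
  s <- build_coordinates(make_reference_structure("hairpin12"))
  tors <- measure_torsions(s)
  aco <- data.frame(resno = 3L, restype = "PHE", angle = "PHI",
                    lower = tors[["phi_3"]] - 10,
                    upper = tors[["phi_3"]] + 10)
  expect_equal(target_function(s, empty_restraint_set(), aco = aco), 0)
  aco2 <- data.frame(resno = 3L, restype = "PHE", angle = "PHI",
                     lower = tors[["phi_3"]] + 20,
                     upper = tors[["phi_3"]] + 40)
  expect_equal(target_function(s, empty_restraint_set(), aco = aco2,
                               dihedral_weight = 0.0025),
               0.0025 * 400, tolerance = 1e-9)
})

test_that("restraints derived from a structure's own distances give zero
           target on that structure (self-consistency)", {
  sc <- noiseless_scenario()
  rs <- scenario_restraints(sc)
  expect_equal(target_function(sc$structure, rs), 0, tolerance = 1e-12)
})

test_that("tightening an upper bound never decreases the target and adding
           an option never increases a violation", {
  sc <- noiseless_scenario()
  s <- sc$structure
  rs <- simple_restraint(3, "HA", 9, "H",
                         unname(effective_distance(
                           s, simple_restraint(3, "HA", 9, "H", 9))) - 0.2)
  base <- target_function(s, rs)
  for (dd in c(0.1, 0.3, 0.7)) {
    tighter <- rs; tighter$upper <- rs$upper - dd
    expect_gte(target_function(s, tighter), base)
  }
  wider <- rbind(rs, simple_restraint(1, "HA", 12, "H", rs$upper))
  wider$group <- 1L
  class(wider) <- c("restraint_set", "data.frame")
  expect_lte(target_function(s, wider), base)
})
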