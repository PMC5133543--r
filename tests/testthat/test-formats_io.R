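test_that("peak list round trip is the identity and the documented column
           layout parses", {
  pk <- data.frame(peak_id = 1:3, w1 = c(7.82, 8.1, 4.5),
                   w2 = c(4.31, 1.2, 2.2),
                   intensity = c(153000, 2.5e4, 9.1e3),
                   spectrum_id = "noesy15N", stringsAsFactors = FALSE)
  class(pk) <- c("peak_list", "data.frame")
  f <- withr::local_tempfile(fileext = ".peaks")
  write_peak_list(pk, f)
  back <- read_peak_list(f)
  expect_equal(back$peak_id, pk$peak_id)
  expect_equal(back$w1, pk$w1, tolerance = 1e-8)
  expect_equal(back$intensity, pk$intensity, tolerance = 1e-8)
  expect_equal(back$spectrum_id, pk$spectrum_id)

  # documented layout, hand-parsed
  f2 <- withr::local_tempfile()
  writeLines("1  7.82  4.31  153000.0  noesy15N", f2)
  one <- read_peak_list(f2)
  expect_equal(one$peak_id, 1L)
  expect_equal(c(one$w1, one$w2), c(7.82, 4.31))
  expect_equal(one$intensity, 153000.0)

  # comments-only file -> empty list
  f3 <- withr::local_tempfile()
  writeLines(c("# a comment", "", "# another"), f3)
  expect_equal(nrow(read_peak_list(f3)), 0)
})

test_that("peak list parser rejects malformed rows with line numbers", {
  f <- withr::local_tempfile()
  writeLines(c("1 7.8 4.3 1000 s1", "2 oops 4.1 900 s1"), f)
  expect_error(read_peak_list(f), "line 2")
  f2 <- withr::local_tempfile()
  writeLines(c("1 7.8 4.3 1000 s1", "2 4.1 900 s1"), f2)
  expect_error(read_peak_list(f2), "column")
})

test_that("shift list round trips, rejects duplicates, parses the
           documented layout", {
  sh <- data.frame(resno = c(3L, 3L, 9L, 9L, 4L),
                   restype = c("ALA", "ALA", "LYS", "LYS", "GLY"),
                   atom = c("HA", "H", "H", "HB2", "HA2"),
                   shift = c(4.31, 8.2, 8.9, 1.7, 3.9),
                   error = 0, stringsAsFactors = FALSE)
  class(sh) <- c("shift_table", "data.frame")
  f <- withr::local_tempfile(fileext = ".prot")
  write_shift_list(sh, f)
  back <- read_shift_list(f)
  expect_equal(back$resno, sh$resno)
  expect_equal(back$atom, sh$atom)
  expect_equal(back$shift, sh$shift, tolerance = 1e-6)
  expect_equal(back$restype, sh$restype)

  f2 <- withr::local_tempfile()
  writeLines("12  4.310  0.000  HA  3", f2)
  one <- read_shift_list(f2)
  expect_equal(one$resno, 3L)
  expect_equal(one$atom, "HA")
  expect_equal(one$shift, 4.310)

  f3 <- withr::local_tempfile()
  writeLines(c("1 4.1 0 HA 3 ALA", "2 4.2 0 HA 3 ALA"), f3)
  expect_error(read_shift_list(f3), "duplicate")

  f4 <- withr::local_tempfile()
  writeLines("1 4.1 0 HA 3 ZZZ", f4)
  expect_error(read_shift_list(f4), "unknown residue")
})

test_that("upl round trips (with ambiguity groups) and parses the
           documented layout", {
  rs <- rbind(simple_restraint(3, "HA", 9, "H", 4.5, group = 1L),
              simple_restraint(4, "HB2", 9, "H", 5.0, group = 2L),
              simple_restraint(4, "HB3", 9, "H", 5.0, group = 2L))
  class(rs) <- c("restraint_set", "data.frame")
  f <- withr::local_tempfile(fileext = ".upl")
  write_upl(rs, f)
  back <- read_upl(f)
  expect_equal(back$group, rs$group)
  expect_equal(back$res_i, rs$res_i)
  expect_equal(back$atom_j, rs$atom_j)
  expect_equal(back$upper, rs$upper, tolerance = 1e-6)

  f2 <- withr::local_tempfile()
  writeLines("3 ALA HA  9 LYS HN  4.50", f2)
  one <- read_upl(f2)
  expect_equal(one$upper, 4.5)
  expect_equal(one$res_i, 3L)
  expect_equal(one$atom_i, "HA")
})

test_that("aco round trips, parses the documented layout and rejects bound
           inversion", {
  aco <- data.frame(resno = c(5L, 6L), restype = c("VAL", "ALA"),
                    angle = c("PHI", "PSI"), lower = c(-120, 100),
                    upper = c(-60, 160), stringsAsFactors = FALSE)
  class(aco) <- c("dihedral_restraints", "data.frame")
  f <- withr::local_tempfile(fileext = ".aco")
  write_aco(aco, f)
  back <- read_aco(f)
  expect_equal(back$resno, aco$resno)
  expect_equal(back$lower, aco$lower, tolerance = 1e-6)

  f2 <- withr::local_tempfile()
  writeLines("5 VAL PHI  -120.0  -60.0", f2)
  one <- read_aco(f2)
  expect_equal(one$angle, "PHI")
  expect_equal(c(one$lower, one$upper), c(-120, -60))

  f3 <- withr::local_tempfile()
  writeLines("5 VAL PHI  -60.0  -120.0", f3)
  expect_error(read_aco(f3), "inversion")
})

test_that("PDB write/read round trips coordinates to 1e-3 and places fields
           at the fixed byte offsets", {
  s <- build_coordinates(random_conformer("AKG", seed = 3))
  f <- withr::local_tempfile(fileext = ".pdb")
  write_pdb_model(s, f)
  back <- read_pdb_model(f)
  expect_length(back, 1)
  expect_equal(back[[1]]$atoms$name, s$atoms$name)
  expect_equal(struct_xyz <- as.matrix(back[[1]]$atoms[, c("x", "y", "z")]),
               as.matrix(s$atoms[, c("x", "y", "z")]), tolerance = 1.1e-3,
               ignore_attr = TRUE)

  # byte-offset check of one ATOM line with known x
  s$atoms$x[1] <- 1.234
  write_pdb_model(s, f)
  line <- readLines(f)[1]
  expect_equal(substring(line, 1, 6), "ATOM  ")
  expect_equal(substring(line, 31, 38), "   1.234")
  expect_equal(nchar(line), 80 - 2)  # two-char element field ends at 78
})

test_that("multi-model PDB files return one structure per MODEL", {
  s <- build_coordinates(random_conformer("AK", seed = 1))
  models <- lapply(1:20, function(i) s)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_pdb_model(models, f)
  back <- read_pdb_model(f)
  expect_length(back, 20)
})

test_that("schedule files round trip, reject duplicates and out-of-grid
           points", {
  sch <- generate_schedule(48, 22, 0.25, seed = 9)
  f <- withr::local_tempfile()
  write_schedule(sch, f)
  back <- read_schedule(f)
  expect_equal(back$points, sch$points)
  expect_equal(back$n1, 48L)

  full <- generate_schedule(4, 4, 1.0)
  write_schedule(full, f)
  expect_equal(nrow(read_schedule(f)$points), 16)

  f2 <- withr::local_tempfile()
  writeLines(c("# nus schedule n1=4 n2=4 fraction=1", "0 0", "0 0"), f2)
  expect_error(read_schedule(f2), "duplicate")
  f3 <- withr::local_tempfile()
  writeLines(c("0 0", "4 1"), f3)
  expect_error(read_schedule(f3, n1 = 4, n2 = 4), "outside")
})

test_that("round trips hold property-style on randomized records", {
  set.seed(42)
  for (rep in 1:5) {
    n <- sample(3:12, 1)
    pk <- data.frame(peak_id = seq_len(n),
                     w1 = round(runif(n, 0, 10), 4),
                     w2 = round(runif(n, 0, 10), 4),
                     intensity = round(runif(n, 1, 1e6), 3),
                     spectrum_id = sample(c("a", "b"), n, replace = TRUE),
                     stringsAsFactors = FALSE)
    class(pk) <- c("peak_list", "data.frame")
    f <- withr::local_tempfile()
    write_peak_list(pk, f)
    back <- read_peak_list(f)
    expect_equal(back$w1, pk$w1, tolerance = 1e-9)
    expect_equal(back$intensity, pk$intensity, tolerance = 1e-9)

    sch <- generate_schedule(sample(4:30, 1), sample(4:30, 1),
                             runif(1, 0.1, 1), seed = rep)
    write_schedule(sch, f)
    expect_equal(read_schedule(f)$points, sch$points)
  }
})

test_that("fid and spectrum text formats round trip", {
  sch <- generate_schedule(8, 8, 0.5, seed = 2)
  fid <- simulate_fid(data.frame(f1 = 2, f2 = 3, amp = 1), sch,
                      noise_sigma = 0.05, seed = 4)
  f <- withr::local_tempfile()
  write_fid(fid, f)
  back <- read_fid(f)
  expect_equal(back$values, fid$values, tolerance = 1e-9)
  expect_equal(back$schedule$points, sch$points)
  expect_equal(back$noise_sigma, 0.05)

  sp <- new_spectrum2d(matrix(runif(24), 4, 6), id = "t")
  write_spectrum(sp, f)
  back2 <- read_spectrum(f)
  expect_equal(back2$intensities, sp$intensities, tolerance = 1e-6)
})

test_that("written PDB files are readable by an independent parser", {
  s <- build_coordinates(make_reference_structure("hairpin12"))
  f <- withr::local_tempfile(fileext = ".pdb")
  write_pdb_model(s, f)
  pdb <- bio3d::read.pdb(f)
  expect_equal(nrow(pdb$atom), nrow(s$atoms))
  expect_equal(pdb$atom$x, round(s$atoms$x, 3), tolerance = 1e-9)
  expect_equal(pdb$atom$elety, s$atoms$name)
  expect_equal(pdb$atom$resid[1], s$atoms$resname[1])
})
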