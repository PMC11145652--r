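test_that("proton counting converts counts to molar concentration", {
  conf <- ball_conformer(394, radius = 2.5, seed = 1)
  conc <- local_proton_concentration(conf, site = 1, radius = 2.5)
  vol_l <- (4 / 3) * pi * 2.5^3 * 1e-24
  expect_equal(conc, 394 / (6.02214076e23 * vol_l), tolerance = 1e-12)
  expect_equal(conc, 10.0, tolerance = 0.05 / 10)
  # no hydrogens in range
  empty <- conformer(c("N", "C"), rbind(c(0, 0, 0), c(1, 0, 0)), 1L)
  expect_equal(local_proton_concentration(empty, 1), 0)
  expect_error(local_proton_concentration(conf, 500), "out of range")
  expect_error(local_proton_concentration(conf, 1, radius = -1), "radius")
})

test_that("exchangeable hydrogens are excluded by default", {
  # one O-H pair (bond 0.1 nm) and one C-H pair inside the shell
  conf <- conformer(c("N", "O", "H", "C", "H"),
                    rbind(c(0, 0, 0), c(1, 0, 0), c(1.1, 0, 0),
                          c(0, 1, 0), c(0, 1.1, 0)),
                    1L)
  vol_l <- (4 / 3) * pi * 2.5^3 * 1e-24
  expect_equal(local_proton_concentration(conf, 1),
               1 / (6.02214076e23 * vol_l))
  expect_equal(local_proton_concentration(conf, 1, include_exchangeable = TRUE),
               2 / (6.02214076e23 * vol_l))
})

test_that("concentration is invariant under rigid motions", {
  conf <- ball_conformer(150, radius = 2.5, seed = 3)
  base <- local_proton_concentration(conf, 1)
  for (s in 1:5) {
    tf <- withr::with_seed(s, {
      M <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
      if (det(M) < 0) M[, 1] <- -M[, 1]
      list(R = M, shift = stats::rnorm(3, 0, 5))
    })
    moved <- conformer(conf$elements,
                       sweep(conf$xyz %*% tf$R, 2, tf$shift, `+`),
                       conf$label_sites)
    expect_equal(local_proton_concentration(moved, 1), base, tolerance = 1e-12)
  }
})

test_that("uniform proton density is radius-independent up to counting noise", {
  conf <- ball_conformer(4000, radius = 5, seed = 5)
  c_inner <- local_proton_concentration(conf, 1, radius = 2.5)
  c_full <- local_proton_concentration(conf, 1, radius = 5)
  expect_equal(c_inner / c_full, 1, tolerance = 0.15)
})

test_that("ensemble histograms pool sites and conserve mass", {
  vol_l <- (4 / 3) * pi * 2.5^3 * 1e-24
  n4 <- round(4 * 6.02214076e23 * vol_l)
  n8 <- round(8 * 6.02214076e23 * vol_l)
  two_sites <- conformer(
    c("N", "N", rep("H", n4 + n8)),
    rbind(c(0, 0, 0), c(100, 0, 0),
          ball_conformer(n4, 2.5, seed = 7)$xyz[-1, , drop = FALSE],
          sweep(ball_conformer(n8, 2.5, seed = 8)$xyz[-1, , drop = FALSE],
                2, c(100, 0, 0), `+`)),
    label_sites = c(1L, 2L))
  h <- ensemble_histogram(list(two_sites), c_grid = seq(0.5, 20, by = 0.25))
  expect_equal(sum(h$p) * h$dc, 1, tolerance = 1e-12)
  vals <- attr(h, "values")
  expect_length(vals, 2L)
  expect_equal(sort(vals), c(4, 8), tolerance = 0.05)
  # two sites, equal mass in two bins
  expect_equal(sum(h$p[abs(h$c_grid - 4) <= 0.2]) * h$dc, 0.5)
  expect_equal(sum(h$p[abs(h$c_grid - 8) <= 0.2]) * h$dc, 0.5)
  # histogram mean matches pooled mean within half a bin
  expect_equal(density_mean(h), mean(vals), tolerance = h$dc / 2 / mean(vals))
  # single conformer, single site: point mass
  one <- ball_conformer(200, 2.5, seed = 9)
  h1 <- ensemble_histogram(list(one), c_grid = seq(0.5, 20, by = 0.25))
  expect_equal(max(h1$p) * h1$dc, 1)
  expect_error(ensemble_histogram(list()), "non-empty")
})

test_that("XYZ conformer files round-trip through the reader", {
  path <- tempfile(fileext = ".xyz")
  # two frames, coordinates in Angstrom
  writeLines(c("3", "frame 1",
               "N 0.0 0.0 0.0", "H 1.0 0.0 0.0", "H 0.0 25.0 0.0",
               "3", "frame 2",
               "N 0.0 0.0 0.0", "H 2.0 0.0 0.0", "H 3.0 0.0 0.0"), path)
  ens <- read_conformers_xyz(path, label_sites = 1L)
  expect_length(ens, 2L)
  expect_equal(ens[[1]]$xyz[2, 1], 0.1)   # 1 A -> 0.1 nm
  # frame 1: one H inside 2.5 nm (the other sits 2.5 nm away exactly at 25 A)
  vol_l <- (4 / 3) * pi * 2.5^3 * 1e-24
  expect_equal(local_proton_concentration(ens[[2]], 1),
               2 / (6.02214076e23 * vol_l))
  writeLines(c("2", "bad", "N 0 0 0"), path)
  expect_error(read_conformers_xyz(path, 1L), "truncated")
})

test_that("multi-model PDB files become one conformer per model", {
  skip_if_not_installed("bio3d")
  path <- tempfile(fileext = ".pdb")
  atom_line <- function(serial, name, el, x, y, z) {
    sprintf("ATOM  %5d %-4s MOL A   1    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
            serial, name, x, y, z, el)
  }
  writeLines(c(
    "MODEL        1",
    atom_line(1, "N1", "N", 0, 0, 0),
    atom_line(2, "H1", "H", 5, 0, 0),
    atom_line(3, "H2", "H", 50, 0, 0),
    "ENDMDL",
    "MODEL        2",
    atom_line(1, "N1", "N", 0, 0, 0),
    atom_line(2, "H1", "H", 3, 0, 0),
    atom_line(3, "H2", "H", 4, 0, 0),
    "ENDMDL",
    "END"), path)
  ens <- read_conformers_pdb(path, label_serials = 1L)
  expect_length(ens, 2L)
  vol_l <- (4 / 3) * pi * 2.5^3 * 1e-24
  expect_equal(local_proton_concentration(ens[[1]], 1),
               1 / (6.02214076e23 * vol_l))
  expect_equal(local_proton_concentration(ens[[2]], 1),
               2 / (6.02214076e23 * vol_l))
  expect_error(read_conformers_pdb(path, label_serials = 99L), "not found")
})
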