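test_that("parsing counts residues per chain and skips non-polymer records", {
  st <- toy_native(seed = 11, lengths = c(5, 4))
  txt <- write_pdb(st)
  parsed <- parse_structure(txt, "two_chain")
  expect_equal(nrow(parsed), 9)
  expect_equal(unique(parsed$chain), c("A", "B"))
  expect_equal(target_id(parsed), "two_chain")

  hetatm_only <- paste(
    "HETATM    1  O   HOH A   1       0.000   0.000   0.000  1.00  0.00",
    "END", sep = "\n")
  expect_error(parse_structure(hetatm_only, "waters"), "no ATOM records")
})

test_that("write/parse round-trips coordinates to PDB precision", {
  st <- toy_native(seed = 12)
  parsed <- parse_structure(write_pdb(st), "rt")
  expect_equal(nrow(parsed), nrow(st))
  for (col in c("ca_x", "ca_y", "ca_z", "cb_x", "n_z", "o_y")) {
    expect_lt(max(abs(parsed[[col]] - st[[col]]), na.rm = TRUE), 1e-3)
  }
  expect_equal(is.na(parsed$cb_x), st$res_type == "GLY")
})

test_that("altloc duplicates resolve to highest occupancy", {
  lines <- c(
    "ATOM      1  N  AALA A   1       0.000   0.000   0.000  0.40  0.00           N",
    "ATOM      2  N  BALA A   1       9.000   0.000   0.000  0.60  0.00           N",
    "ATOM      3  CA AALA A   1       1.458   0.000   0.000  0.40  0.00           C",
    "ATOM      4  CA BALA A   1       9.458   0.000   0.000  0.60  0.00           C",
    "ATOM      5  CA  GLY A   2       4.000   1.000   0.000  1.00  0.00           C",
    "END")
  st <- parse_structure(lines, "alt")
  expect_equal(nrow(st), 2)
  expect_equal(st$ca_x[1], 9.458)
})

test_that("non-standard residues map to substitutions or UNK", {
  expect_equal(ggtqa:::normalize_res_type(c("MSE", "ALA", "XYZ")),
               c("MET", "ALA", "UNK"))
})

test_that("ideal helix torsions match the generator's internal coordinates", {
  st <- compute_torsions(toy_native(seed = 13, lengths = c(10, 8)))
  interior_phi <- st$phi[!is.na(st$phi)]
  interior_psi <- st$psi[!is.na(st$psi)]
  expect_true(all(abs(interior_phi - (-57)) < 5))
  expect_true(all(abs(interior_psi - (-47)) < 5))
  # phi undefined at chain starts, psi at chain ends, defined elsewhere
  starts <- which(st$seq_index == 0)
  ends <- which(st$chain != c(st$chain[-1], "?"))
  expect_true(all(is.na(st$phi[starts])))
  expect_true(all(is.na(st$psi[ends])))
  expect_true(all(!is.na(st$phi[-starts])))
  expect_true(all(!is.na(st$psi[-ends])))
})

test_that("dihedral agrees with an independent formula and bio3d", {
  set.seed(5)
  for (i in 1:20) {
    p <- matrix(rnorm(12, sd = 3), 4, 3)
    mine <- ggtqa:::dihedral_angle(p[1, ], p[2, ], p[3, ], p[4, ])
    expect_equal(mine, ref_dihedral(p[1, ], p[2, ], p[3, ], p[4, ]),
                 tolerance = 1e-8)
    expect_equal(mine, as.numeric(bio3d::torsion.xyz(as.numeric(t(p)),
                                                     atm.inc = 4)),
                 tolerance = 1e-6)
  }
  # collinear geometry returns a defined value, no NaN
  expect_true(is.finite(ggtqa:::dihedral_angle(c(0, 0, 0), c(1, 0, 0),
                                               c(2, 0, 0), c(3, 0, 0))))
})

test_that("secondary structure follows the Ramachandran-region rule", {
  helix <- assign_ss3(compute_torsions(toy_native(seed = 14)))
  expect_true(all(helix$ss3[!is.na(helix$phi) & !is.na(helix$psi)] ==
                    "helix"))
  strand <- assign_ss3(compute_torsions(
    toy_native(seed = 15, geometry = "extended")))
  expect_true(all(strand$ss3[!is.na(strand$phi) & !is.na(strand$psi)] ==
                    "strand"))
  # undefined torsions (termini) fall back to coil
  expect_true(all(helix$ss3[is.na(helix$phi) & is.na(helix$psi)] == "coil"))
})

test_that("Shrake-Rupley matches the analytic two-sphere burial", {
  r1 <- 1.7; r2 <- 1.55; probe <- 1.4; d <- 2.6
  asa <- ggtqa:::shrake_rupley(rbind(c(0, 0, 0), c(d, 0, 0)), c(r1, r2),
                               probe = probe, n_points = 2000)
  R1 <- r1 + probe; R2 <- r2 + probe
  cos_theta <- (d^2 + R1^2 - R2^2) / (2 * d * R1)
  exact <- 4 * pi * R1^2 * (1 - (1 - cos_theta) / 2)
  expect_equal(asa[1], exact, tolerance = 0.01)
})

test_that("relative surface area is clamped, exposed and buried correctly", {
  one <- toy_native(seed = 16, lengths = c(6, 4))[1, ]
  one <- ggtqa:::new_complex_structure(one, "iso")
  expect_equal(compute_rsa(one)$rsa, 1.0)  # isolated residue fully exposed

  st <- compute_rsa(toy_native(seed = 16))
  expect_true(all(st$rsa >= 0 & st$rsa <= 1))

  # a residue enclosed by a dense shell of neighbours is nearly buried
  centre <- toy_native(seed = 17, lengths = c(3, 3))
  grid <- expand.grid(x = c(-4, 0, 4), y = c(-4, 0, 4), z = c(-4, 0, 4))
  rows <- centre[rep(1, nrow(grid) + 1), ]
  for (i in seq_len(nrow(grid))) {
    sh <- as.numeric(grid[i, ])
    for (g in list(c("n_x", "n_y", "n_z"), c("ca_x", "ca_y", "ca_z"),
                   c("c_x", "c_y", "c_z"), c("o_x", "o_y", "o_z"),
                   c("cb_x", "cb_y", "cb_z"))) {
      rows[i + 1, g] <- rows[i + 1, g] + as.list(sh)
    }
  }
  rows$resno <- seq_len(nrow(rows))
  rows$seq_index <- seq_len(nrow(rows)) - 1L
  cluster <- ggtqa:::new_complex_structure(rows, "cluster")
  rsa <- compute_rsa(cluster)$rsa
  expect_lt(rsa[1 + 14], 0.1)  # row 15 sits at the grid centre (0,0,0)
})

test_that("virtual C-beta honours observed atoms, geometry and fallbacks", {
  st <- toy_native(seed = 18)
  cb <- suppressMessages(virtual_cbeta(st))
  obs <- !is.na(st$cb_x)
  expect_equal(cb[obs, 1], st$cb_x[obs], ignore_attr = TRUE)
  gly <- which(st$res_type == "GLY")
  ca <- as.matrix(st[, c("ca_x", "ca_y", "ca_z")])
  dist_gly <- sqrt(rowSums((cb[gly, , drop = FALSE] -
                            ca[gly, , drop = FALSE])^2))
  expect_true(all(abs(dist_gly - 1.522) < 0.01))
  # missing backbone N: fall back to CA
  st2 <- st
  st2$cb_x[1] <- NA; st2$n_x[1] <- NA
  cb2 <- suppressMessages(virtual_cbeta(st2))
  expect_equal(cb2[1, ], ca[1, ], ignore_attr = TRUE)
})

test_that("derived per-residue quantities are rigid-motion invariant", {
  st <- annotate_structure(toy_native(seed = 19))
  moved <- annotate_structure(rigid_move(st))
  expect_equal(moved$phi, st$phi, tolerance = 1e-6)
  expect_equal(moved$psi, st$psi, tolerance = 1e-6)
  expect_identical(moved$ss3, st$ss3)
  expect_equal(moved$rsa, st$rsa, tolerance = 1e-6)
})
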