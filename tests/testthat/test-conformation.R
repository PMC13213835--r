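test_that("torsion convention: cis zero, trans 180, reversal-symmetric", {
  o <- c(0, 0, 0)
  expect_equal(dihedral_angle(c(1, 0, 0), o, c(0, 0, 1), c(1, 0, 1)), 0)
  expect_equal(dihedral_angle(c(1, 0, 0), o, c(0, 0, 1), c(-1, 0, 1)), 180)
  expect_equal(dihedral_angle(c(1, 0, 0), o, c(0, 0, 1), c(0, 1, 1)), 90)
  expect_error(dihedral_angle(c(1, 0, 0), o, c(2, 0, 0), c(3, 0, 0)), "collinear")
})

test_that("torsions agree with two independent constructions on random points", {
  skip_if_not_installed("bio3d")
  set.seed(31)
  for (r in 1:50) {
    p <- matrix(rnorm(12), 4, 3)
    got <- dihedral_angle(p[1, ], p[2, ], p[3, ], p[4, ])
    expect_equal(got, oracle_dihedral(p[1, ], p[2, ], p[3, ], p[4, ]),
                 tolerance = 1e-9)
    expect_equal(got, bio3d::torsion.xyz(as.numeric(t(p))), tolerance = 1e-6,
                 ignore_attr = TRUE)
    expect_equal(got, dihedral_angle(p[4, ], p[3, ], p[2, ], p[1, ]),
                 tolerance = 1e-9)
  }
})

make_two_atom_traj <- function() {
  # frame 2 displaces atom 2 by 2 A along x
  c1 <- rbind(c(0, 0, 0), c(1, 0, 0))
  c2 <- rbind(c(0, 0, 0), c(3, 0, 0))
  coords <- array(c(c1, c2), c(2, 3, 2))
  atoms <- data.frame(name = c("C1", "C2"), element = c("C", "C"),
                      resno = 1L, resname = "LIG", chain = "L")
  md_trajectory(coords, atoms)
}

test_that("RMSD: zero on reference, rigid-motion invariant, hand value", {
  tr <- make_two_atom_traj()
  rs <- rmsd_series(tr, superpose = FALSE)
  expect_equal(rs$rmsd[1], 0)
  expect_equal(rs$rmsd[2], sqrt(4 / 2))  # one atom displaced 2 A, two atoms

  # rigidly moved copy superposes back to zero
  set.seed(4)
  X <- matrix(rnorm(30), 10, 3)
  Y <- rotate_z(X, 73) + matrix(rep(c(5, -2, 1), each = 10), 10, 3)
  coords <- array(c(X, Y), c(10, 3, 2))
  atoms <- data.frame(name = paste0("C", 1:10), element = "C",
                      resno = 1L, resname = "LIG", chain = "L")
  tr2 <- md_trajectory(coords, atoms)
  expect_lt(rmsd_series(tr2, superpose = TRUE)$rmsd[2], 1e-9)
  expect_gt(rmsd_series(tr2, superpose = FALSE)$rmsd[2], 1)
})

test_that("superposed RMSD agrees with bio3d fit on noisy frames", {
  skip_if_not_installed("bio3d")
  set.seed(12)
  X <- matrix(rnorm(30), 10, 3)
  Y <- rotate_z(X + matrix(rnorm(30, 0, 0.3), 10, 3), 40)
  coords <- array(c(X, Y), c(10, 3, 2))
  atoms <- data.frame(name = paste0("C", 1:10), element = "C",
                      resno = 1L, resname = "LIG", chain = "L")
  got <- rmsd_series(md_trajectory(coords, atoms), superpose = TRUE)$rmsd[2]
  ref <- bio3d::rmsd(as.numeric(t(X)), as.numeric(t(Y)), fit = TRUE)
  expect_equal(got, ref, tolerance = 1e-3)
})

test_that("Cremer-Pople: planar ring, pure chair pattern, z-negation symmetry", {
  j <- 0:5
  hex <- cbind(cos(-2 * pi * j / 6), sin(-2 * pi * j / 6), 0) * 1.52
  flat <- cremer_pople(hex)   # planar is flagged, not an error
  expect_true(flat$planar)
  expect_equal(flat$Q, 0, tolerance = 1e-12)
  expect_true(is.na(flat$theta))

  chair <- hex + cbind(0, 0, 0.25 * (-1)^j)
  cp <- cremer_pople(chair)
  expect_equal(cp$q2, 0, tolerance = 1e-9)
  expect_equal(cp$Q, 0.25 * sqrt(6), tolerance = 1e-9)
  expect_equal(cp$theta, 0, tolerance = 1e-7)

  # negating displacements: theta -> 180 - theta, phi -> phi + 180
  mixed <- gen_ring_coords("4H3", Q = 0.55, n_frames = 1)[, , 1]
  cp1 <- cremer_pople(mixed)
  flipped <- mixed; flipped[, 3] <- -flipped[, 3]
  cp3 <- cremer_pople(flipped)
  expect_equal(cp3$theta, 180 - cp1$theta, tolerance = 1e-7)
  expect_equal((cp3$phi - (cp1$phi + 180)) %% 360, 0, tolerance = 1e-6)
})

test_that("Q equals the root sum of squared displacements", {
  set.seed(77)
  for (r in 1:20) {
    lab <- sample(conformer_table()$label, 1)
    ring <- gen_ring_coords(lab, Q = runif(1, 0.3, 0.8), angular_noise = 5,
                            n_frames = 1, seed = r)[, , 1]
    cp <- cremer_pople(ring)
    expect_equal(cp$Q, sqrt(sum(cp$z^2)), tolerance = 1e-12)
    expect_equal(cp$Q, sqrt(cp$q2^2 + cp$q3^2), tolerance = 1e-9)
  }
})

test_that("canonical conformer table has the expected structure", {
  tab <- conformer_table()
  expect_equal(nrow(tab), 38L)
  expect_equal(as.vector(table(tab$class)[c("chair", "boat", "skew",
                                            "envelope", "half-chair")]),
               c(2L, 6L, 6L, 12L, 12L))
  expect_equal(tab$theta[tab$label == "4C1"], 0, tolerance = 1e-9)
  expect_equal(tab$theta[tab$label == "1C4"], 180, tolerance = 1e-9)
  expect_true(all(abs(tab$theta[tab$class %in% c("boat", "skew")] - 90) < 1e-9))
  expect_equal(tab$phi[tab$label == "2SO"], 150, tolerance = 1e-9)
  expect_equal(tab$phi[tab$label == "1S3"], 210, tolerance = 1e-9)
})

test_that("CP classifier: poles, skew vertex, and tolerance to phase error", {
  expect_equal(assign_conformer_cp(list(Q = 0.55, theta = 0, phi = 0)), "4C1")
  expect_equal(assign_conformer_cp(list(Q = 0.55, theta = 180, phi = 0)), "1C4")
  expect_equal(assign_conformer_cp(list(Q = 0.55, theta = 90, phi = 150)), "2SO")
  expect_equal(assign_conformer_cp(list(Q = 0.55, theta = 90, phi = 164)), "2SO")
  expect_equal(assign_conformer_cp(list(Q = 0.05, theta = 90, phi = 150)), "planar")
})

test_that("round trip: generated conformers recover coordinates and labels", {
  tab <- conformer_table()
  for (lab in tab$label) {
    ring <- gen_ring_coords(lab, Q = 0.55, n_frames = 1)[, , 1]
    cp <- cremer_pople(ring)
    expect_equal(cp$Q, 0.55, tolerance = 1e-6)
    expect_equal(cp$theta, tab$theta[tab$label == lab], tolerance = 1e-6)
    if (is.finite(cp$phi) && tab$theta[tab$label == lab] %% 180 != 0) {
      dphi <- (cp$phi - tab$phi[tab$label == lab] + 180) %% 360 - 180
      expect_lt(abs(dphi), 1e-6)
    }
    expect_equal(assign_conformer_cp(cp), lab)
  }
})

test_that("two-dihedral classifier matches CP labels on ideal geometries", {
  for (lab in c("4C1", "1C4", "2SO", "1S3")) {
    ring <- gen_ring_coords(lab, Q = 0.55, n_frames = 1)[, , 1]
    d1 <- dihedral_angle(ring[2, ], ring[3, ], ring[4, ], ring[5, ])
    d2 <- dihedral_angle(ring[2, ], ring[1, ], ring[6, ], ring[5, ])
    expect_equal(assign_conformer_dihedral(d1, d2), lab)
  }
  expect_equal(assign_conformer_dihedral(100, -100), "other")
})

test_that("pucker populations: pure, mixed and conservation", {
  pure <- gen_ring_trajectory("4C1", n_frames = 50, seed = 3)
  fr <- pucker_populations(pure$traj, "G:1")
  expect_equal(fr, c("4C1" = 1.0))

  mix <- gen_ring_trajectory(c("4C1", "1C4"), weights = c(0.7, 0.3),
                             n_frames = 1000, angular_noise = 4, seed = 8)
  fr2 <- pucker_populations(mix$traj, "G:1")
  truth <- mean(mix$labels == "4C1")
  # recovered fraction matches the realized mixture at low noise
  expect_equal(unname(fr2["4C1"]), truth, tolerance = 0.01)
  expect_equal(sum(fr2), 1, tolerance = 1e-12)

  frd <- pucker_populations(mix$traj, "G:1", classifier = "dihedral")
  expect_equal(sum(frd), 1, tolerance = 1e-12)
  expect_equal(unname(frd["4C1"]), truth, tolerance = 0.02)
  expect_error(pucker_populations(mix$traj, "G:9"), "ring annotation")
})

test_that("glycosidic series: static, two-state and count conservation", {
  # 3-residue toy GAG chain with explicit ring atoms
  nres <- 3L
  atoms <- do.call(rbind, lapply(seq_len(nres), function(r)
    data.frame(name = c("O5", "C1", "C2", "C3", "C4", "O4"),
               element = c("O", "C", "C", "C", "C", "O"),
               resno = r, resname = "SUG", chain = "G")))
  base <- matrix(rnorm(nrow(atoms) * 3, sd = 3), ncol = 3)
  nf <- 40L
  coords <- array(rep(base, nf), c(nrow(atoms), 3, nf))
  tr <- md_trajectory(coords, atoms)
  tr <- gag_linkages(tr, "G", types = "1-4")
  gs <- glycosidic_series(tr)
  expect_length(gs$series, 2L)
  for (H in gs$histogram) {
    expect_equal(sum(H), nf)          # counts conserve frames
    expect_equal(sum(H > 0), 1L)      # static: single occupied bin
  }
  # histogram marginals reproduce independently binned 1-D histograms
  df <- gs$series[[1]]
  br <- gs$breaks
  h1 <- hist(df$phi, breaks = br, plot = FALSE)$counts
  expect_equal(unname(rowSums(gs$histogram[[1]])), h1)
})

test_that("failed linkages are isolated, others still processed", {
  atoms <- data.frame(name = c("O5", "C1", "C2", "C3", "C4", "O4",
                               "O5", "C1", "C2", "C3", "C4", "O4"),
                      element = rep(c("O", "C", "C", "C", "C", "O"), 2),
                      resno = rep(1:2, each = 6), resname = "SUG", chain = "G")
  coords <- array(rnorm(36 * 2), c(12, 3, 2))
  # make one linkage degenerate by collapsing its atoms onto a line
  coords[1:4, , ] <- 0
  tr <- md_trajectory(coords, atoms)
  tr <- define_linkage(tr, "bad", phi = c(1, 1, 2, 3), psi = c(1, 2, 3, 4))
  tr <- define_linkage(tr, "good", phi = c(7, 8, 9, 10), psi = c(8, 9, 10, 11))
  gs <- suppressWarnings(glycosidic_series(tr))
  expect_true("bad" %in% names(gs$errors))
  expect_true("good" %in% names(gs$series))
})

test_that("contact map averages mass-weighted residue COM distances", {
  # two single-atom residues 5 A apart -> 5; second frame at 7 -> mean 6
  atoms <- data.frame(name = c("CA", "C1"), element = c("C", "C"),
                      resno = c(1L, 1L), resname = c("GLY", "SUG"),
                      chain = c("A", "G"))
  f1 <- rbind(c(0, 0, 0), c(5, 0, 0))
  f2 <- rbind(c(0, 0, 0), c(7, 0, 0))
  tr <- md_trajectory(array(c(f1, f2), c(2, 3, 2)), atoms)
  M <- contact_map(tr, "A", "G")
  expect_equal(as.numeric(M), 6)

  # two-atom residue with masses 12 and 1: COM sits 1/13 from the heavy atom
  atoms2 <- data.frame(name = c("CA", "C1", "H1"), element = c("C", "C", "H"),
                       resno = c(1L, 1L, 1L), resname = c("GLY", "SUG", "SUG"),
                       chain = c("A", "G", "G"))
  xyz <- rbind(c(0, 0, 0), c(5, 0, 0), c(6, 0, 0))
  tr2 <- md_trajectory(array(xyz, c(3, 3, 1)), atoms2)
  com <- (5 * 12.011 + 6 * 1.008) / (12.011 + 1.008)
  expect_equal(as.numeric(contact_map(tr2, "A", "G")), com)
  expect_error(contact_map(tr2, "Z", "G"), "protein chain")
})
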