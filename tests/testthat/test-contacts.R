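# Contact stability, buried SASA, RDF and RMSF.

# tiny two-residue "peptide" over a static 3-atom surface strip
make_contact_traj <- function(z_near, z_far, n_frames = 10,
                              near_frames = seq_len(n_frames)) {
  frames <- lapply(seq_len(n_frames), function(f) {
    z1 <- if (f %in% near_frames) z_near else z_far
    rbind(c(0, 0, z1), c(1.5, 0, z1),       # residue A
          c(10, 0, z_far), c(11.5, 0, z_far)) # residue B (always far)
  })
  trajectory(frames, element = "C",
             residues = list(RESA1 = 1:2, RESB2 = 3:4))
}

surface_strip <- atom_set("C", rbind(c(0, 0, 0), c(1.42, 0, 0),
                                     c(2.84, 0, 0)), group_label = "NANO")

test_that("contact stability counts frames with any atom under the cutoff", {
  tr <- make_contact_traj(z_near = 3.0, z_far = 10)
  cs <- contact_stability(tr, surface_strip)
  expect_equal(cs$stability[cs$residue == "RESA1"], 100)
  expect_equal(cs$stability[cs$residue == "RESB2"], 0)

  tr7 <- make_contact_traj(z_near = 3.0, z_far = 10, near_frames = 1:7)
  cs7 <- contact_stability(tr7, surface_strip)
  expect_equal(cs7$stability[cs7$residue == "RESA1"], 70)

  # strict inequality at the cutoff: exactly 4.0 A is not a contact
  tr4 <- make_contact_traj(z_near = 4.0, z_far = 10)
  cs4 <- contact_stability(tr4, surface_strip)
  expect_equal(cs4$stability[cs4$residue == "RESA1"], 0)

  # monotone in the cutoff
  cs_small <- contact_stability(tr7, surface_strip, cutoff = 3.2)
  cs_large <- contact_stability(tr7, surface_strip, cutoff = 6.0)
  expect_true(all(cs_large$stability >= cs_small$stability))

  expect_error(contact_stability(trajectory(list(), element = "C"),
                                 surface_strip), "empty")
})

test_that("buried contact area vanishes at separation and is symmetric", {
  set.seed(11)
  pep <- atom_set(c("C", "N", "O", "H"), matrix(rnorm(12, sd = 1.5), 4, 3))
  far <- pep; far$coords <- sweep(far$coords, 2, -c(50, 0, 0))
  surf <- atom_set("C", rbind(c(0, 0, 0), c(1.42, 0, 0), c(0.71, 1.23, 0)))
  expect_lt(abs(buried_contact_area(far, surf)), 0.5)

  near <- pep; near$coords <- sweep(near$coords, 2, -c(0, 0, 3.4))
  b1 <- buried_contact_area(near, surf)
  b2 <- buried_contact_area(surf, near)
  expect_gt(b1, 1)
  expect_equal(b1, b2, tolerance = 1e-12)

  # identical overlapping atoms are a geometry error
  expect_error(buried_contact_area(surf, surf), "overlap")
})

test_that("SASA point sampling is converged at the default density", {
  pep <- atom_set(c("C", "N", "O"), rbind(c(0, 0, 3.2), c(1.4, 0, 3.4),
                                          c(0.7, 1.2, 3.3)))
  surf <- atom_set("C", rbind(c(0, 0, 0), c(1.42, 0, 0), c(0.71, 1.23, 0)))
  b960 <- buried_contact_area(pep, surf, n_points = 960)
  b1920 <- buried_contact_area(pep, surf, n_points = 1920)
  expect_lt(abs(b960 - b1920) / b1920, 0.01)

  # symmetric dimer: two identical atoms in contact bury the same area on
  # each side, up to the angular resolution of the fixed point lattice
  dimer <- atom_set("C", rbind(c(0, 0, 0), c(3.0, 0, 0)))
  s <- sasa(dimer)
  expect_equal(s[1], s[2], tolerance = 0.02)
  s2 <- sasa(dimer, n_points = 4000)
  expect_equal(s2[1], s2[2], tolerance = 0.005)
  # single free atom recovers the analytic sphere area
  lone <- sasa(atom_set("C", matrix(0, 1, 3)))
  expect_equal(lone, 4 * pi * (1.70 + 1.4)^2, tolerance = 1e-9)
})

test_that("rdf normalises an ideal gas to unity and recovers delta shells", {
  set.seed(17)
  box <- c(24, 24, 24)
  na <- 400; nb <- 5000
  co <- rbind(matrix(runif(na * 3, 0, 24), na, 3),
              matrix(runif(nb * 3, 0, 24), nb, 3))
  tr <- trajectory(list(co), element = "O", cell = box,
                   periodic = c(TRUE, TRUE, TRUE))
  g <- rdf(tr, seq_len(na), na + seq_len(nb), r_max = 10, bin_width = 0.25)
  sel <- g$r >= 3
  expect_true(all(abs(g$g[sel] - 1) < 0.05))

  # total pair count within r_max matches the ideal-gas expectation to 1%
  expected <- na * nb * (4 / 3 * pi * 10^3) / prod(box)
  expect_lt(abs(sum(g$count) - expected) / expected, 0.01)

  # all B atoms exactly 1.9 A from A (a bin centre) -> one occupied bin
  a <- matrix(c(12, 12, 12), 1, 3)
  dirs <- matrix(rnorm(300), 100, 3)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  tr2 <- trajectory(list(rbind(a, sweep(dirs * 1.9, 2, -a[1, ]))),
                    element = "O", cell = box,
                    periodic = c(TRUE, TRUE, TRUE))
  g2 <- rdf(tr2, 1, 1 + seq_len(100), r_max = 10, bin_width = 0.2)
  expect_equal(sum(g2$count > 0), 1L)
  expect_equal(g2$r[which.max(g2$count)], 1.9, tolerance = 1e-9)

  expect_error(rdf(tr, 1:10, 11:20, r_max = 15), "half the smallest")
})

test_that("synthetic hydration shell peaks at the prescribed radius", {
  box <- c(30, 30, 30)
  solute <- atom_set("C", matrix(15, 1, 3))
  wat <- synth_hydration_shell(solute, shell_radius = 2.0,
                               shell_sigma = 0.2, n_shell = 12000,
                               box = box, n_background = 2000, seed = 5)
  tr <- trajectory(list(rbind(solute$coords, wat$coords)),
                   element = "O", cell = box, periodic = c(TRUE, TRUE, TRUE))
  g <- rdf(tr, 1, 1 + seq_len(n_atoms(wat)), r_max = 8, bin_width = 0.2)
  expect_equal(g$r[which.max(g$g)], 2.0, tolerance = 0.2 + 1e-9)

  # determinism and background-only mode
  wat2 <- synth_hydration_shell(solute, shell_radius = 2.0,
                                shell_sigma = 0.2, n_shell = 12000,
                                box = box, n_background = 2000, seed = 5)
  expect_identical(wat$coords, wat2$coords)
  bg <- synth_hydration_shell(solute, n_shell = 0, box = box,
                              n_background = 500, seed = 2)
  expect_equal(n_atoms(bg), 500L)
})

test_that("rmsf is zero for static input and matches the closed form", {
  base <- matrix(rnorm(30), 10, 3)
  static <- trajectory(rep(list(base), 5), element = "C",
                       residues = list(R1 = 1:4, R2 = 5:10))
  r0 <- rmsf(static)
  expect_equal(r0$rmsf, c(0, 0), tolerance = 1e-12)

  # one atom oscillating +/-1 A about its mean, without superposition:
  # residue RMSF = sqrt(atom MSF averaged over the residue) = 1/sqrt(n_res)
  frames <- lapply(1:6, function(f) {
    co <- base
    co[1, 1] <- co[1, 1] + c(1, -1)[(f %% 2) + 1]
    co
  })
  osc <- trajectory(frames, element = "C",
                    residues = list(R1 = 1:4, R2 = 5:10))
  ro <- rmsf(osc, superpose = FALSE)
  expect_equal(ro$rmsf[1], 1 / sqrt(4), tolerance = 1e-12)
  expect_equal(ro$rmsf[2], 0, tolerance = 1e-12)

  # invariant under a global rigid rotation of every frame
  R <- pistack:::rotation_matrix(c(1, 2, 3), 40)
  rot <- trajectory(lapply(frames, function(co)
    sweep(co %*% t(R), 2, -c(5, 5, 5))), element = "C",
    residues = list(R1 = 1:4, R2 = 5:10))
  expect_equal(rmsf(osc)$rmsf, rmsf(rot)$rmsf, tolerance = 1e-9)

  expect_error(rmsf(trajectory(list(base), element = "C",
                               residues = list(R1 = 1:10))), "two frames")
})
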