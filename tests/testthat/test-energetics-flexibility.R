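test_that("the PMF transform matches hand-evaluated values and round-trips", {
  r <- seq(0.05, 5.95, by = 0.1)
  g <- rep(1, length(r))
  g[20:25] <- 2
  g[40:45] <- 0
  rdf <- structure(data.frame(r_lo = r - 0.05, r_hi = r + 0.05, r = r,
                              g = g, cn = cumsum(g), counts = g),
                   class = c("rdf", "data.frame"))
  pmf <- pmf_from_rdf(rdf, T = 298.15)
  expect_equal(pmf$w[1], 0)                       # g = 1 -> w = 0
  expect_equal(pmf$w[22], -8.314 * 298.15 * log(2) / 1000)
  expect_equal(pmf$w[22], -1.718, tolerance = 1e-3)
  expect_true(all(is.na(pmf$w[40:45])))           # masked, not -Inf
  # round trip g -> w -> g on the unmasked grid
  g_back <- exp(-pmf$w * 1000 / (8.314 * 298.15))
  ok <- !is.na(pmf$w)
  expect_equal(g_back[ok], g[ok], tolerance = 1e-12)
  expect_error(pmf_from_rdf(rdf, T = -1), "positive|> 0")
})

test_that("PMF well depths are located per shell", {
  r <- seq(0.025, 5.975, by = 0.05)
  g <- 4 * exp(-(r - 2.2)^2 / (2 * 0.2^2)) + 2 * exp(-(r - 4.0)^2 / (2 * 0.3^2))
  g[g < 0.02] <- 0
  rdf <- structure(data.frame(r_lo = r - 0.025, r_hi = r + 0.025, r = r,
                              g = g, cn = cumsum(g), counts = g),
                   class = c("rdf", "data.frame"))
  part <- detect_shell_boundaries(rdf, 5, 1)
  pmf <- pmf_from_rdf(rdf, 298.15, part)
  wells <- attr(pmf, "wells")
  first <- r < part$boundaries[1]
  expect_equal(wells$r_min[1], r[first][which.max(g[first])])
  expect_equal(wells$w_min[1], -8.314 * 298.15 * log(max(g[first])) / 1000)
})

test_that("single-sphere SASA matches the analytic area within 2%", {
  top <- topology(data.frame(element = "C", name = "C1"))
  top$atoms$vdw_radius <- 1.5
  s <- compute_sasa(matrix(0, 1, 3), top, probe_radius = 1.4,
                    n_points = 960L)
  expect_rel(s$total, 4 * pi * 2.9^2 / 100, 0.02)
  expect_equal(s$total, 1.057, tolerance = 0.03)
  expect_equal(s$hydrophobic + s$hydrophilic, s$total, tolerance = 1e-10)
})

test_that("coincident and fused sphere pairs match closed-form areas", {
  top <- topology(data.frame(element = c("C", "C"), name = c("C1", "C2")))
  top$atoms$vdw_radius <- c(1.5, 1.5)
  # fully overlapping identical atoms = one sphere
  s0 <- compute_sasa(matrix(0, 2, 3), top, 1.4, 960L)
  expect_rel(s0$total, 4 * pi * 2.9^2 / 100, 0.02)
  # fused pair at several separations vs the spherical-cap formula
  for (d in c(1.0, 2.5, 4.0, 5.5)) {
    s <- compute_sasa(rbind(c(0, 0, 0), c(d, 0, 0)), top, 1.4, 960L)
    expect_rel(s$total, two_sphere_area(2.9, 2.9, d) / 100, 0.02)
  }
  # unequal radii, one engulfing regime
  top$atoms$vdw_radius <- c(0.5, 2.5)
  s <- compute_sasa(rbind(c(0, 0, 0), c(0.5, 0, 0)), top, 1.4, 960L)
  expect_rel(s$total, two_sphere_area(1.9, 3.9, 0.5) / 100, 0.02)
})

test_that("SASA decomposition is exact and the polarity split follows the classes", {
  sc <- generate_porphyrin_scaffold(1.98)
  s <- compute_sasa(sc$coords, sc$topology)
  expect_equal(s$hydrophobic + s$hydrophilic, s$total, tolerance = 1e-10)
  expect_gt(s$hydrophobic, s$hydrophilic)   # mostly C/H surface
  expect_gt(s$hydrophilic, 0)               # buried-but-not-zero N + metal
  bad <- sc$topology
  bad$atoms$vdw_radius[3] <- NA
  expect_error(compute_sasa(sc$coords, bad), "radius for atom")
})

test_that("SASA shrinks with probe size for a convex solute and is rigid-motion invariant", {
  top <- topology(data.frame(element = "C", name = "C1"))
  top$atoms$vdw_radius <- 1.5
  areas <- vapply(c(0, 0.7, 1.4, 2.8), function(p)
    compute_sasa(matrix(0, 1, 3), top, p, 480L)$total, numeric(1))
  # single convex sphere: exact analytic scaling with the probe radius
  expect_equal(areas, 4 * pi * (1.5 + c(0, 0.7, 1.4, 2.8))^2 / 100,
               tolerance = 0.02)
  # rigid motion changes the area only at the level of the point-grid
  # discretisation (the sampling sphere does not rotate with the solute)
  sc <- generate_porphyrin_scaffold(1.98)
  rt <- generate_rigid_body_trajectory(sc, 3L, seed = 40)
  s1 <- compute_sasa(frame_coords(rt, 1), sc$topology)
  s2 <- compute_sasa(frame_coords(rt, 2), sc$topology)
  expect_rel(s2$total, s1$total, 0.01)
  ts <- time_averaged_sasa(rt, sc$topology)
  expect_rel(ts$total, s1$total, 0.01)
  expect_equal(ts$hydrophobic + ts$hydrophilic, ts$total, tolerance = 1e-10)
})

test_that("time-averaged SASA of a static trajectory equals the single frame", {
  sc <- generate_porphyrin_scaffold(1.98)
  coords <- array(0, c(4, nrow(sc$coords), 3))
  for (f in 1:4) coords[f, , ] <- sc$coords
  traj <- trajectory(coords, dt = 1, topology = sc$topology)
  ts <- time_averaged_sasa(traj)
  s1 <- compute_sasa(sc$coords, sc$topology)
  expect_equal(ts$total, s1$total)
  expect_equal(ts$per_atom, s1$per_atom)
})

test_that("RMSF vanishes for rigid motion and matches the isotropic-jitter closed form", {
  sc <- generate_porphyrin_scaffold(1.98)
  rt <- generate_rigid_body_trajectory(sc, 40L, seed = 41)
  rmsf <- compute_rmsf(kabsch_align(rt))
  expect_lt(max(rmsf$rmsf), 1e-6)
  # metal and hydrogens excluded by default
  expect_false(any(rmsf$role %in% c("metal", "ring_H")))
  sigma <- 0.1
  jt <- generate_rigid_body_trajectory(sc, 2000L, seed = 42,
                                       jitter_sd = sigma)
  rmsf_j <- compute_rmsf(kabsch_align(jt, ref = 1:37))
  expect_rel(mean(rmsf_j$rmsf), sigma * sqrt(3), 0.05)
})

test_that("adding a common rigid motion to every frame leaves RMSF unchanged", {
  sc <- generate_porphyrin_scaffold(1.98)
  jt <- generate_rigid_body_trajectory(sc, 60L, seed = 43, jitter_sd = 0.05)
  base <- compute_rmsf(kabsch_align(jt))
  moved <- jt
  set.seed(44)
  th <- runif(1, 0, 2 * pi)
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3,
              byrow = TRUE)
  for (f in seq_len(n_frames(moved)))
    moved$coords[f, , ] <- sweep(frame_coords(jt, f) %*% t(R), 2,
                                 c(5, -3, 2), `+`)
  after <- compute_rmsf(kabsch_align(moved))
  expect_lt(max(abs(after$rmsf - base$rmsf)), 1e-6)
})

test_that("dihedral angles follow the IUPAC sign convention", {
  expect_equal(dihedral_angle(c(1, 1, 0), c(1, 0, 0), c(0, 0, 0),
                              c(0, 1, 0)), 0)                 # cis
  expect_equal(abs(dihedral_angle(c(1, 1, 0), c(1, 0, 0), c(0, 0, 0),
                                  c(0, -1, 0))), 180)         # trans
  # right-handed quarter twist: +90 by the cross-product construction
  expect_equal(dihedral_angle(c(1, 1, 0), c(1, 0, 0), c(0, 0, 0),
                              c(0, 0, 1)), -90)
  expect_equal(dihedral_angle(c(1, 1, 0), c(1, 0, 0), c(0, 0, 0),
                              c(0, 0, -1)), 90)
  expect_error(dihedral_angle(c(0, 0, 0), c(0, 0, 0), c(1, 0, 0),
                              c(1, 1, 0)), "degenerate")
  expect_error(dihedral_angle(c(2, 0, 0), c(1, 0, 0), c(0, 0, 0),
                              c(-1, 0, 0)), "degenerate")
})

test_that("the dihedral sign matches an independent cross-product oracle", {
  set.seed(45)
  for (i in 1:20) {
    p <- matrix(rnorm(12, sd = 2), 4, 3)
    ok <- tryCatch({
      ang <- dihedral_angle(p[1, ], p[2, ], p[3, ], p[4, ])
      b1 <- p[2, ] - p[1, ]; b2 <- p[3, ] - p[2, ]; b3 <- p[4, ] - p[3, ]
      cr <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                             a[3] * b[1] - a[1] * b[3],
                             a[1] * b[2] - a[2] * b[1])
      n1 <- cr(b1, b2); n2 <- cr(b2, b3)
      cosang <- sum(n1 * n2) / sqrt(sum(n1^2) * sum(n2^2))
      mag <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
      sgn <- sign(sum(cr(n1, n2) * b2))
      expect_equal(abs(ang), mag, tolerance = 1e-8)
      if (sgn != 0) expect_equal(sign(ang), sgn)
      TRUE
    }, error = function(e) FALSE)
    expect_true(ok)
  }
})

test_that("torsional distributions of the planar scaffold sit at zero and widen with jitter", {
  sc <- generate_porphyrin_scaffold(1.98)
  rt <- generate_rigid_body_trajectory(sc, 30L, seed = 46)
  tor <- torsion_distribution(rt, bin_width = 5)
  # planar ring: the N-N-N-N proper dihedral mass is entirely in the
  # zero-containing bin
  nn <- tor$`freq_N-N-N-N`
  expect_equal(sum(nn), 1)
  expect_equal(nn[tor$theta == -2.5 | tor$theta == 2.5][1] +
                 nn[tor$theta == -2.5 | tor$theta == 2.5][2], 1)
  # all four improper quadruples of the symmetric scaffold agree: the
  # planar angle is exactly 0, so each quadruple's mass sits in the two
  # bins flanking zero and the circular means coincide
  imp <- as.matrix(tor[abs(tor$theta) < 5, grep("M-CA-CA", names(tor))])
  expect_true(all(colSums(imp) == 1))
  cm0 <- attr(tor, "circular_mean")
  expect_lt(max(abs(cm0)), 1e-6)
  # jitter widens the distribution around a ~zero circular mean
  jt <- generate_rigid_body_trajectory(sc, 400L, seed = 47, jitter_sd = 0.05)
  tj <- torsion_distribution(jt, bin_width = 5)
  cm <- attr(tj, "circular_mean")
  expect_lt(max(abs(cm)), 3)
  spread <- function(d) sum(d$freq_mean * pmin(abs(d$theta),
                                               360 - abs(d$theta))^2)
  expect_gt(spread(tj), spread(tor))
  jt2 <- generate_rigid_body_trajectory(sc, 400L, seed = 47, jitter_sd = 0.15)
  tj2 <- torsion_distribution(jt2, bin_width = 5)
  expect_gt(spread(tj2), spread(tj))
})
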