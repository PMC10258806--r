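test_that("optimized pair histogram equals the brute-force double loop bit-exactly", {
  set.seed(31)
  # periodic and non-periodic random instances
  for (box in list(10, NULL)) {
    coords <- array(runif(2 * 50 * 3, 0, 10), c(2, 50, 3))
    top <- topology(data.frame(element = rep("Ar", 50),
                               name = paste0("A", 1:50), role = "other"))
    traj <- trajectory(coords, dt = 1, box_length = box, topology = top)
    rdf <- compute_rdf(traj, 1:50, 1:50, 5, 0.05,
                       density = if (is.null(box)) 0.05 else NULL)
    expect_identical(rdf$counts,
                     rdf_counts_bruteforce(traj, 1:50, 1:50, 5, 0.05))
  }
})

test_that("a lone axial water occupies a single bin and integrates to one", {
  snap <- coordination_snapshot(1)
  rdf <- compute_rdf(snap, "metal", "water_O", 6, 0.05, density = 0.0332)
  occ <- which(rdf$counts > 0)
  expect_length(occ, 1L)
  expect_true(rdf$r_lo[occ] <= 2.3 && rdf$r_hi[occ] > 2.3)
  expect_equal(integrate_coordination(rdf, 2.67), 1.0)
  expect_equal(integrate_coordination(rdf, 1.0), 0.0)
})

test_that("r_max beyond half the box and empty selections are rejected", {
  gas <- generate_ideal_gas_box(20, 10, 2, seed = 1)
  expect_error(compute_rdf(gas, 1:20, 1:20, 6, 0.05), "half the box")
  expect_error(compute_rdf(gas, "metal", "other", 4, 0.05), "empty selection")
})

test_that("shell boundaries land at the zero-gap midpoint of well-separated peaks", {
  # two Gaussian peaks at 2.2 and 4.2 A with zero density between
  r <- seq(0.025, 6, by = 0.05)
  g <- 5 * exp(-(r - 2.2)^2 / (2 * 0.1^2)) + 3 * exp(-(r - 4.2)^2 / (2 * 0.15^2))
  g[g < 1e-3] <- 0
  rdf <- structure(data.frame(r_lo = r - 0.025, r_hi = r + 0.025, r = r,
                              g = g, cn = cumsum(g), counts = g),
                   class = c("rdf", "data.frame"))
  part <- detect_shell_boundaries(rdf, 5, 1)
  expect_equal(part$boundaries[1], 3.2, tolerance = 0.05)
  expect_true(part$zero_minimum[1])
  expect_gt(part$boundaries[1], part$peaks[1])
})

test_that("overlapping peak tails give a nonzero smoothed minimum", {
  r <- seq(0.025, 6, by = 0.05)
  g <- 5 * exp(-(r - 2.2)^2 / (2 * 0.35^2)) + 3 * exp(-(r - 4.0)^2 / (2 * 0.45^2))
  rdf <- structure(data.frame(r_lo = r - 0.025, r_hi = r + 0.025, r = r,
                              g = g, cn = cumsum(g), counts = g),
                   class = c("rdf", "data.frame"))
  part <- detect_shell_boundaries(rdf, 5, 1)
  expect_false(part$zero_minimum[1])
  expect_gt(part$boundaries[1], 2.5)
  expect_lt(part$boundaries[1], 3.7)
  # boundary sits at the smoothed minimum of the bimodal profile
  expect_equal(part$boundaries[1], r[which.min(g[r > 2.2 & r < 4.0])[1] +
                                       sum(r <= 2.2)], tolerance = 0.2)
})

test_that("monotone g(r) yields no shell boundary", {
  r <- seq(0.025, 6, by = 0.05)
  rdf <- structure(data.frame(r_lo = r - 0.025, r_hi = r + 0.025, r = r,
                              g = r, cn = cumsum(r), counts = r),
                   class = c("rdf", "data.frame"))
  expect_error(detect_shell_boundaries(rdf, 5, 1), "cannot define")
})

test_that("ADF of exact coordination geometries matches combinatorial enumeration", {
  oct <- coordination_snapshot(2)
  adf <- compute_adf(oct, "metal", c("ring_N", "water_O"), 2.67, 2)
  occupied <- adf[adf$freq > 0, ]
  # 15 vertex pairs: 12 at 90 deg, 3 at 180 deg
  expect_equal(nrow(occupied), 2L)
  expect_setequal(floor(occupied$theta_lo), c(90, 178))
  expect_equal(occupied$freq[occupied$theta_lo == 90], 12 / 15)
  expect_equal(occupied$freq[occupied$theta_lo > 90], 3 / 15)
  pyr <- coordination_snapshot(1)
  adf2 <- compute_adf(pyr, "metal", c("ring_N", "water_O"), 2.67, 2)
  occ2 <- adf2[adf2$freq > 0, ]
  expect_equal(occ2$freq[occ2$theta_lo == 90], 8 / 10)
  expect_equal(occ2$freq[occ2$theta_lo > 90], 2 / 10)
  expect_equal(attr(adf2, "n_angles"), 10L)
})

test_that("ADF is invariant under global rigid motion and errors without ligand pairs", {
  sc <- generate_porphyrin_scaffold(1.98)
  # random (non-axial) directions keep all angles away from bin edges
  snap <- generate_shell_snapshot(sc, shell_spec(1.93, 2.67, 4L),
                                  seed = 6, axial = FALSE)
  adf <- compute_adf(snap, "metal", "water_O", 2.67, 2)
  set.seed(41)
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  R <- with(list(w = q[1], x = q[2], y = q[3], z = q[4]),
            matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
                     2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
                     2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
                   3, 3, byrow = TRUE))
  rot <- snap
  rot$coords[1, , ] <- sweep(frame_coords(snap, 1) %*% t(R), 2, c(3, -1, 7), `+`)
  adf_rot <- compute_adf(rot, "metal", "water_O", 2.67, 2)
  expect_equal(adf_rot$freq, adf$freq, tolerance = 1e-12)
  expect_error(compute_adf(snap, "metal", "water_O", 0.5), "no frame")
})

test_that("CND concentrates at six for a static octahedral complex", {
  oct <- coordination_snapshot(2)
  oct$coords <- oct$coords[rep(1, 50), , , drop = FALSE]  # replicate frames
  traj <- trajectory(oct$coords, dt = 0.1, topology = oct$topology)
  cnd <- compute_cnd(traj, "metal", c("ring_N", "water_O"), 2.67)
  expect_equal(cnd$p[cnd$cn == 6], 1.0)
  expect_equal(attr(cnd, "mean"), 6.0)
  # r_cut -> 0 pushes everything to zero coordination
  cnd0 <- compute_cnd(traj, "metal", c("ring_N", "water_O"), 1e-9)
  expect_equal(cnd0$p[cnd0$cn == 0], 1.0)
})

test_that("CND of an exchange trajectory recounts the ground-truth occupancy", {
  sc <- generate_porphyrin_scaffold(1.98)
  ex <- generate_exchange_trajectory(
    sc, exchange_spec(1, 2L, 30, 0.02, seed = 8),
    shell_spec(c(1.93, 2.67), c(2.67, 5.2)), axial_pair = TRUE)
  cnd <- compute_cnd(ex$trajectory, "metal", c("ring_N", "water_O"), 2.67)
  truth_counts <- 4L + rowSums(ex$shell_index == 1L)
  expect_equal(attr(cnd, "mean"), mean(truth_counts))
  for (k in unique(truth_counts))
    expect_equal(cnd$p[cnd$cn == k], mean(truth_counts == k))
  # coordination only ever 4 N plus 0-2 first-shell waters
  expect_true(all(cnd$cn[cnd$p > 0] %in% 4:6))
  expect_gt(sum(cnd$p[cnd$cn %in% 5:6]), 0)
})

test_that("mean CND equals the coordination integral at the same cutoff", {
  sc <- generate_porphyrin_scaffold(1.98)
  snap <- generate_shell_snapshot(sc, shell_spec(c(1.93, 2.67),
                                                 c(2.67, 5.2), c(2L, 6L)),
                                  seed = 10)
  rdf <- compute_rdf(snap, "metal", "water_O", 6, 0.05, density = 0.0332)
  cnd <- compute_cnd(snap, "metal", "water_O", 2.67)
  expect_equal(attr(cnd, "mean"), integrate_coordination(rdf, 2.67),
               tolerance = 1e-10)
})

test_that("N-H coordination counting matches a brute-force recount", {
  sc <- generate_porphyrin_scaffold(1.98)
  snap <- generate_shell_snapshot(sc, shell_spec(c(1.93, 2.67),
                                                 c(2.67, 5.2), c(2L, 8L)),
                                  seed = 13, orientation = "random")
  traj <- trajectory(snap$coords[rep(1, 10), , , drop = FALSE], dt = 1,
                     topology = snap$topology)
  cnd <- compute_nh_cnd(traj, h_bond_cutoff = 3.5)
  X <- frame_coords(traj, 1)
  ni <- which(traj$topology$atoms$role == "ring_N")
  hi <- which(traj$topology$atoms$role == "water_H")
  manual <- sum(vapply(hi, function(h)
    any(sqrt(colSums((t(X[ni, ]) - X[h, ])^2)) < 3.5), logical(1)))
  expect_equal(attr(cnd, "mean"), manual)
  # metal-repelled hydrogens cannot hydrogen-bond to the ring nitrogens
  away <- generate_shell_snapshot(sc, shell_spec(1.93, 2.67, 2L),
                                  seed = 2, orientation = "away")
  cnd_away <- compute_nh_cnd(away, 2.5)
  expect_equal(cnd_away$p[cnd_away$cn == 0], 1.0)
})

test_that("a hydrogen pinned near a nitrogen registers one contact per frame", {
  sc <- generate_porphyrin_scaffold(1.98)
  snap <- generate_shell_snapshot(sc, shell_spec(1.93, 2.67, 1L), seed = 1)
  X <- frame_coords(snap, 1)
  ni <- which(snap$topology$atoms$role == "ring_N")[1]
  hi <- which(snap$topology$atoms$role == "water_H")[1]
  X[hi, ] <- X[ni, ] + c(1.9, 0, 0)
  snap$coords[1, , ] <- X
  cnd <- compute_nh_cnd(snap, 2.5)
  expect_equal(cnd$p[cnd$cn == 1], 1.0)
})
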