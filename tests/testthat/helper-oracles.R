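# Independent oracles and fixture builders used across the test files.
# Each oracle is deliberately implemented differently from the package
# routine it checks.

# Plain-R double-loop pair histogram (same arithmetic order as the
# optimized path, so counts must agree bit-exactly).
rdf_counts_bruteforce <- function(traj, ci, ti, r_max, dr) {
  box <- traj$box_length
  nb <- ceiling(r_max / dr)
  counts <- numeric(nb)
  for (f in seq_len(n_frames(traj))) {
    X <- frame_coords(traj, f)
    for (i in ci) {
      for (j in ti) {
        if (i == j) next
        d <- X[j, ] - X[i, ]
        if (!is.null(box)) d <- d - box * floor(d / box + 0.5)
        dist <- sqrt(sum(d * d))
        if (dist < r_max) {
          b <- floor(dist / dr) + 1L
          counts[b] <- counts[b] + 1
        }
      }
    }
  }
  counts
}

# Minimum-image displacement by explicit enumeration of the 27 neighbour
# images.
min_image_oracle <- function(a, b, box) {
  best <- NULL
  bn <- Inf
  for (i in -4:4) for (j in -4:4) for (k in -4:4) {
    d <- (b + box * c(i, j, k)) - a
    nn <- sqrt(sum(d^2))
    if (nn < bn) { bn <- nn; best <- d }
  }
  best
}

# Departure counter on a ground-truth shell-index matrix, written as a
# per-crossing forward scan (structurally unlike the rle-based package
# routine).
oracle_nex <- function(truth, shell, t_star, dt) {
  need <- floor(t_star / dt)
  tot <- 0L
  for (l in seq_len(ncol(truth))) {
    inn <- truth[, l] == shell
    n <- length(inn)
    outs <- which(!inn & c(FALSE, inn[-n]))
    for (o in outs) {
      ret <- which(inn & seq_len(n) > o)
      len <- (if (length(ret)) min(ret) else n + 1L) - o
      if (len > need) tot <- tot + 1L
    }
  }
  tot
}

# Closed-form solvent accessible area of two fused spheres (radii include
# the probe), in A^2.
two_sphere_area <- function(R1, R2, d) {
  if (d >= R1 + R2) return(4 * pi * (R1^2 + R2^2))      # disjoint
  if (d <= abs(R1 - R2))                                # one engulfs the other
    return(4 * pi * max(R1, R2)^2)
  x1 <- (d^2 + R1^2 - R2^2) / (2 * d)
  x2 <- d - x1
  (4 * pi * R1^2 - 2 * pi * R1 * (R1 - x1)) +
    (4 * pi * R2^2 - 2 * pi * R2 * (R2 - x2))
}

# Tiny single-model PDB writer (water boxes and ad-hoc solutes).
write_test_pdb <- function(path, names, elements, resids, resnos, xyz) {
  lines <- sprintf(
    "ATOM  %5d %-4s %-3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
    seq_along(names), names, resids, resnos,
    xyz[, 1], xyz[, 2], xyz[, 3], toupper(elements))
  writeLines(c(lines, "END"), path)
  path
}

# n-water PDB on a grid (OW/HW1/HW2 per residue).
write_water_pdb <- function(path, n_water, solute = TRUE) {
  names <- character(0); elements <- character(0)
  resids <- character(0); resnos <- integer(0)
  xyz <- matrix(0, 0, 3)
  resno <- 0L
  if (solute) {
    resno <- 1L
    s <- rbind(c(0, 0, 0), c(2, 0, 0), c(0, 2, 0), c(-2, 0, 0), c(0, -2, 0))
    names <- c("CO", "N1", "N2", "N3", "N4")
    elements <- c("Co", "N", "N", "N", "N")
    resids <- rep("POR", 5); resnos <- rep(1L, 5)
    xyz <- s
  }
  side <- ceiling(n_water^(1 / 3))
  idx <- 0L
  for (i in seq_len(side)) for (j in seq_len(side)) for (k in seq_len(side)) {
    if (idx >= n_water) break
    idx <- idx + 1L
    O <- c(i, j, k) * 3.1 + 5
    names <- c(names, "OW", "HW1", "HW2")
    elements <- c(elements, "O", "H", "H")
    resids <- c(resids, rep("HOH", 3))
    resnos <- c(resnos, rep(resno + idx, 3))
    xyz <- rbind(xyz, O, O + c(0.96, 0, 0), O + c(-0.24, 0.93, 0))
  }
  write_test_pdb(path, names, elements, resids, resnos, xyz)
}

# Octahedral / square-pyramidal coordination snapshots (exact geometry).
coordination_snapshot <- function(n_axial, metal_N = 2.0, water_r = 2.3) {
  sc <- generate_porphyrin_scaffold(metal_N)
  generate_shell_snapshot(sc, shell_spec(1.93, 2.67, as.integer(n_axial),
                                         jitter = 0),
                          seed = 1, axial = TRUE)
}

expect_rel <- function(actual, expected, tol) {
  expect_lt(abs(actual - expected) / abs(expected), tol)
}
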