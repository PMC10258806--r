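## Solute-frame alignment and 3D / angular-radial solvent density maps.

# Optimal proper rotation (Kabsch, via SVD) mapping P onto Q after
# centroid removal; returns list(R, rmsd-minimising transform pieces).
kabsch_rotation <- function(P, Q) {
  cp <- colMeans(P); cq <- colMeans(Q)
  H <- t(sweep(P, 2, cp)) %*% sweep(Q, 2, cq)
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  D <- diag(c(1, 1, d))
  R <- s$v %*% D %*% t(s$u)
  list(R = R, center_from = cp, center_to = cq)
}

#' Rigid-body superposition of every frame onto a reference frame
#'
#' Kabsch alignment: each frame is rotated (proper rotations only) and
#' translated to minimise the RMSD of the reference atom set against the
#' same set in `ref_frame`.  The transform derived from the reference set
#' is applied to all atoms.  Used before RMSF and spatial-density
#' analyses, which need the solute-fixed frame.
#'
#' @param traj [trajectory()] (treated as non-periodic: unwrap first if
#'   needed)
#' @param ref reference selection; default all heavy ring atoms + metal
#' @param ref_frame frame to superpose onto (default 1)
#' @return aligned [trajectory()] (box metadata dropped: an aligned frame
#'   is no longer periodic)
#' @export
kabsch_align <- function(traj,
                         ref = c("metal", "ring_N", "ring_C_alpha",
                                 "ring_C_beta", "ring_C_meso"),
                         ref_frame = 1L) {
  ri <- resolve_selection(traj$topology, ref)
  if (length(ri) < 3) stop("alignment needs >= 3 reference atoms")
  Q <- frame_coords(traj, ref_frame)[ri, , drop = FALSE]
  sv <- svd(sweep(Q, 2, colMeans(Q)))$d
  if (sv[2] < 1e-8 * sv[1])
    stop("reference atoms are (nearly) collinear; alignment is degenerate")
  out <- traj$coords
  for (f in seq_len(n_frames(traj))) {
    X <- frame_coords(traj, f)
    k <- kabsch_rotation(X[ri, , drop = FALSE], Q)
    out[f, , ] <- sweep(sweep(X, 2, k$center_from) %*% t(k$R),
                        2, k$center_to, `+`)
  }
  trajectory(out, dt = traj$dt, box_length = NULL,
             velocities = traj$velocities, topology = traj$topology)
}

#' Least-squares plane through the four pyrrole nitrogens
#'
#' Fits the macrocycle plane (total least squares via SVD of the centred
#' nitrogen positions).  The normal's sign is chosen for continuity with
#' `prev_normal` when given, otherwise to have a positive z-component —
#' preventing spurious theta <-> 180-theta flips for near-planar motion.
#'
#' @param frame `n x 3` coordinate matrix
#' @param ring_N_ids indices of the four nitrogens
#' @param prev_normal optional previous-frame normal for sign continuity
#' @return list with `normal` (unit) and `centroid`
#' @export
fit_ring_plane <- function(frame, ring_N_ids, prev_normal = NULL) {
  P <- frame[ring_N_ids, , drop = FALSE]
  if (nrow(P) < 3) stop("need >= 3 ring nitrogens to fit a plane")
  ctr <- colMeans(P)
  s <- svd(sweep(P, 2, ctr))
  if (s$d[2] < 1e-8) stop("ring nitrogens are collinear; plane undefined")
  nrm <- s$v[, 3]
  flip <- if (!is.null(prev_normal)) sum(nrm * prev_normal) < 0
          else nrm[3] < 0
  if (flip) nrm <- -nrm
  list(normal = nrm, centroid = ctr)
}

#' Spatial distribution function on a regular 3D grid
#'
#' Voxel histogram of target-atom positions over an aligned trajectory,
#' converted to a mean number density (atoms/angstrom^3): summing
#' `density * voxel_volume` recovers the mean in-grid atom count exactly.
#'
#' @param traj aligned [trajectory()] (see [kabsch_align()])
#' @param target selection to accumulate (e.g. `"water_O"`)
#' @param origin grid corner, length-3, angstrom
#' @param spacing voxel edge, angstrom (default 0.5)
#' @param dims integer length-3 voxel counts
#' @return object of class `sdf_grid`: list with `density` (3D array),
#'   `origin`, `spacing`, `dims`, `n_frames`
#' @export
compute_sdf <- function(traj, target, origin, spacing = 0.5, dims) {
  nfr <- n_frames(traj)
  if (!nfr) stop("zero frames")
  ti <- resolve_selection(traj$topology, target)
  dims <- as.integer(dims)
  counts <- array(0, dims)
  mi <- which(traj$topology$atoms$role == "metal")
  if (length(mi)) {
    m0 <- frame_coords(traj, 1L)[mi[1], ]
    v <- floor((m0 - origin) / spacing)
    if (any(v < 0 | v >= dims))
      warning("metal centre lies outside the SDF grid")
  }
  for (f in seq_len(nfr)) {
    X <- frame_coords(traj, f)[ti, , drop = FALSE]
    v <- floor(sweep(X, 2, origin) / spacing)
    keep <- rowSums(v >= 0) == 3 & v[, 1] < dims[1] & v[, 2] < dims[2] &
      v[, 3] < dims[3]
    v <- v[keep, , drop = FALSE] + 1L
    for (i in seq_len(nrow(v)))
      counts[v[i, 1], v[i, 2], v[i, 3]] <- counts[v[i, 1], v[i, 2], v[i, 3]] + 1
  }
  structure(list(density = counts / (nfr * spacing^3), origin = origin,
                 spacing = spacing, dims = dims, n_frames = nfr),
            class = "sdf_grid")
}

#' Write an SDF grid as an OpenDX scalar field
#' @param grid from [compute_sdf()]
#' @param path output path
#' @export
write_sdf_dx <- function(grid, path) {
  con <- file(path, "w"); on.exit(close(con))
  d <- grid$dims
  writeLines(c(
    sprintf("object 1 class gridpositions counts %d %d %d", d[1], d[2], d[3]),
    sprintf("origin %g %g %g", grid$origin[1], grid$origin[2], grid$origin[3]),
    sprintf("delta %g 0 0", grid$spacing),
    sprintf("delta 0 %g 0", grid$spacing),
    sprintf("delta 0 0 %g", grid$spacing),
    sprintf("object 2 class gridconnections counts %d %d %d",
            d[1], d[2], d[3]),
    sprintf("object 3 class array type double rank 0 items %d data follows",
            prod(d))), con)
  vals <- as.vector(aperm(grid$density, c(3, 2, 1)))  # z fastest
  writeLines(apply(matrix(c(vals, rep(NA, (3 - length(vals) %% 3) %% 3)),
                          nrow = 3), 2,
                   function(r) paste(stats::na.omit(r), collapse = " ")), con)
  writeLines('attribute "dep" string "positions"', con)
  invisible(path)
}

#' Angular-radial distribution of solvent density about the ring normal
#'
#' Joint histogram of the metal-target distance r and the angle theta
#' between the metal-to-target vector and the macrocycle-plane normal
#' (refit per frame from the four nitrogens, sign-continuous across
#' frames).  Densities are normalised by the azimuthally integrated
#' volume element `(2 pi / 3)(r_hi^3 - r_lo^3)(cos th_lo - cos th_hi)`;
#' the polar bins at 0 and 180 degrees use this exact integrated solid
#' angle, so no sin(theta) singularity arises.
#'
#' @param traj [trajectory()] (non-periodic or pre-unwrapped about the
#'   solute)
#' @param target selection, e.g. `"water_O"`
#' @param r_max radial range, angstrom
#' @param dr radial bin, angstrom (default 0.1)
#' @param dtheta polar bin, degrees (default 2)
#' @return object of class `ard_grid`: list with `density`
#'   (n_r x n_theta matrix, atoms/angstrom^3), `counts`, `r_edges`,
#'   `theta_edges`, `n_frames`
#' @export
compute_ard <- function(traj, target, r_max, dr = 0.1, dtheta = 2) {
  nfr <- n_frames(traj)
  if (!nfr) stop("zero frames")
  ti <- resolve_selection(traj$topology, target)
  mi <- resolve_selection(traj$topology, "metal")[1]
  ni <- resolve_selection(traj$topology, "ring_N")
  n_r <- ceiling(r_max / dr)
  n_t <- ceiling(180 / dtheta)
  counts <- matrix(0, n_r, n_t)
  nrm_prev <- NULL
  for (f in seq_len(nfr)) {
    X <- frame_coords(traj, f)
    pl <- fit_ring_plane(X, ni, nrm_prev)
    nrm_prev <- pl$normal
    v <- sweep(X[ti, , drop = FALSE], 2, X[mi, ])
    d <- sqrt(rowSums(v^2))
    keep <- d > 0 & d < r_max
    if (!any(keep)) next
    cosang <- (v[keep, , drop = FALSE] %*% pl$normal) / d[keep]
    th <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
    ir <- floor(d[keep] / dr) + 1L
    it <- pmin(n_t, floor(th / dtheta) + 1L)
    for (i in seq_along(ir)) counts[ir[i], it[i]] <- counts[ir[i], it[i]] + 1
  }
  r_edges <- dr * (0:n_r)
  t_edges <- dtheta * (0:n_t)
  vol <- outer(r_edges[-1]^3 - r_edges[-(n_r + 1)]^3,
               cos(t_edges[-(n_t + 1)] * pi / 180) -
                 cos(t_edges[-1] * pi / 180)) * (2 * pi / 3)
  structure(list(density = counts / (nfr * vol), counts = counts,
                 r_edges = r_edges, theta_edges = t_edges, n_frames = nfr),
            class = "ard_grid")
}

#' Remove the first-shell band from an ARD grid
#'
#' Zeroes every cell whose radial bin lies below `shell_r_limit`, leaving
#' outer-shell structure (which the intense metal-coordinated density
#' would otherwise dominate).  A radius band is removed — molecules are
#' not tracked individually — so cells straddling the limit are zeroed
#' whenever their lower edge is below it.
#'
#' @param ard from [compute_ard()]
#' @param shell_r_limit angstrom
#' @return modified `ard_grid`
#' @export
subtract_first_shell <- function(ard, shell_r_limit) {
  if (shell_r_limit > max(ard$r_edges))
    stop("shell_r_limit outside the ARD grid")
  cut <- ard$r_edges[-length(ard$r_edges)] < shell_r_limit
  ard$density[cut, ] <- 0
  ard$counts[cut, ] <- 0
  ard$subtracted_below <- shell_r_limit
  ard
}
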