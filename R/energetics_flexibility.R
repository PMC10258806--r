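## Potentials of mean force, solvent accessible surface area,
## root-mean-square fluctuations and torsional distributions.

#' Bondi van der Waals radii (angstrom)
#'
#' Standard Bondi set for the common elements, 2.0 for transition metals
#' and unknown elements (a conventional fallback for SASA work).
#' @param element character vector of element symbols
#' @return numeric radii
#' @export
bondi_radius <- function(element) {
  tab <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
           F = 1.47, Cl = 1.75, Br = 1.85, I = 1.98, Na = 2.27, K = 2.75,
           Mg = 1.73, Ar = 1.88, X = 1.50)
  r <- unname(tab[element])
  r[is.na(r)] <- 2.0
  r
}

#' Potential of mean force from a pair correlation function
#'
#' `w(r) = -R T ln g(r)` in kJ/mol (R = 8.314 J K^-1 mol^-1).  Bins with
#' g = 0 are masked (`NA`) rather than mapped to infinity; w = 0 wherever
#' g = 1, making bulk water the free-energy reference.  When a shell
#' partition is supplied, the well depth (minimum w) and its position are
#' reported per shell.
#'
#' @param rdf from [compute_rdf()]
#' @param T temperature, K (default 298.15)
#' @param partition optional [detect_shell_boundaries()] result
#' @return object of class `pmf`: data.frame with `r`, `g`, `w` (kJ/mol);
#'   attributes `T`, `wells` (data.frame `shell`, `r_min`, `w_min`)
#' @export
pmf_from_rdf <- function(rdf, T = 298.15, partition = NULL) {
  if (T <= 0) stop("temperature must be > 0")
  w <- ifelse(rdf$g > 0, -R_GAS * T * log(rdf$g) / 1000, NA_real_)
  out <- data.frame(r = rdf$r, g = rdf$g, w = w)
  wells <- NULL
  if (!is.null(partition)) {
    b <- c(0, if (inherits(partition, "shell_partition"))
               partition$boundaries else partition)
    wells <- do.call(rbind, lapply(seq_len(length(b) - 1L), function(s) {
      i <- which(out$r >= b[s] & out$r < b[s + 1L] & !is.na(out$w))
      if (!length(i)) return(NULL)
      j <- i[which.min(out$w[i])]
      data.frame(shell = s, r_min = out$r[j], w_min = out$w[j])
    }))
  }
  structure(out, class = c("pmf", "data.frame"), T = T, wells = wells)
}

# Deterministic quasi-uniform points on the unit sphere (Fibonacci spiral).
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- pi * (3 - sqrt(5)) * i
  z <- 1 - 2 * i / n
  rho <- sqrt(pmax(0, 1 - z^2))
  cbind(rho * cos(phi), rho * sin(phi), z)
}

#' Shrake-Rupley solvent accessible surface area of one frame
#'
#' Each solute atom's sphere of radius `r_vdw + probe` is sampled with
#' `n_points` quasi-uniform points; the accessible fraction times the
#' sphere area gives the per-atom SASA, reported in nm^2 and decomposed
#' by the topology's `polarity_class` (hydrophobic + hydrophilic = total
#' exactly).  Water atoms are excluded from the solute surface.
#'
#' @param frame `n x 3` coordinate matrix (angstrom) or 1-frame
#'   [trajectory()]
#' @param top [topology()] with radii and polarity classes
#' @param probe_radius solvent probe, angstrom (default 1.4, a water-sized
#'   probe)
#' @param n_points sphere sample points per atom (default 960)
#' @param solute atom selection defining the surface; default all
#'   non-water atoms
#' @return object of class `sasa`: list with `per_atom` (nm^2, NA for
#'   non-solute atoms), `hydrophobic`, `hydrophilic`, `total` (nm^2),
#'   `probe_radius`, `n_points`
#' @export
compute_sasa <- function(frame, top, probe_radius = 1.4, n_points = 960L,
                         solute = NULL) {
  X <- if (inherits(frame, "trajectory")) frame_coords(frame, 1L) else frame
  a <- top$atoms
  si <- if (!is.null(solute)) resolve_selection(top, solute)
        else which(!a$role %in% c("water_O", "water_H"))
  if (!length(si)) stop("empty solute selection")
  rad <- a$vdw_radius[si]
  if (any(is.na(rad)))
    stop("missing van der Waals radius for atom(s) ",
         paste(si[is.na(rad)], collapse = ", "))
  S <- X[si, , drop = FALSE]
  R <- rad + probe_radius
  pts <- sphere_points(n_points)
  ns <- length(si)
  area <- numeric(ns)
  for (i in seq_len(ns)) {
    P <- sweep(pts * R[i], 2, S[i, ], `+`)
    acc <- rep(TRUE, n_points)
    for (j in seq_len(ns)) {
      if (j == i) next
      dij <- sqrt(sum((S[i, ] - S[j, ])^2))
      if (dij >= R[i] + R[j]) next
      # fully engulfed sphere contributes nothing; exactly coincident
      # identical spheres keep a single copy of the shared surface
      if (dij + R[i] < R[j] ||
          (dij + R[i] == R[j] && (R[i] < R[j] || j < i))) {
        acc[] <- FALSE
        break
      }
      # sphere j contained in (or touching from inside) sphere i cannot
      # block any of i's surface
      if (dij + R[j] <= R[i]) next
      d2 <- (P[, 1] - S[j, 1])^2 + (P[, 2] - S[j, 2])^2 +
        (P[, 3] - S[j, 3])^2
      acc <- acc & d2 >= R[j]^2
      if (!any(acc)) break
    }
    area[i] <- 4 * pi * R[i]^2 * sum(acc) / n_points
  }
  area_nm2 <- area / 100                           # A^2 -> nm^2
  per_atom <- rep(NA_real_, nrow(a)); per_atom[si] <- area_nm2
  phil <- sum(area_nm2[a$polarity_class[si] == "hydrophilic"])
  phob <- sum(area_nm2[a$polarity_class[si] == "hydrophobic"])
  structure(list(per_atom = per_atom, hydrophobic = phob,
                 hydrophilic = phil, total = phob + phil,
                 probe_radius = probe_radius, n_points = n_points),
            class = "sasa")
}

#' @export
print.sasa <- function(x, ...) {
  cat(sprintf(paste0("<sasa> total %.3f nm^2 (hydrophobic %.3f, ",
                     "hydrophilic %.3f); probe %.2f A, %d points\n"),
              x$total, x$hydrophobic, x$hydrophilic, x$probe_radius,
              x$n_points))
  invisible(x)
}

#' Time-averaged SASA over a trajectory
#'
#' Mean of the per-frame Shrake-Rupley totals (and per-atom areas) over
#' strided frames.
#'
#' @param traj [trajectory()]
#' @param top topology (default: the trajectory's)
#' @param stride analyse every `stride`-th frame
#' @inheritParams compute_sasa
#' @return object of class `sasa` with an `n_frames_used` field
#' @export
time_averaged_sasa <- function(traj, top = traj$topology, stride = 1L,
                               probe_radius = 1.4, n_points = 960L,
                               solute = NULL) {
  frames <- seq(1L, n_frames(traj), by = stride)
  acc <- NULL
  for (f in frames) {
    s <- compute_sasa(frame_coords(traj, f), top, probe_radius, n_points,
                      solute)
    if (is.null(acc)) {
      acc <- s
    } else {
      acc$per_atom <- acc$per_atom + s$per_atom
      acc$hydrophobic <- acc$hydrophobic + s$hydrophobic
      acc$hydrophilic <- acc$hydrophilic + s$hydrophilic
      acc$total <- acc$total + s$total
    }
  }
  nf <- length(frames)
  acc$per_atom <- acc$per_atom / nf
  acc$hydrophobic <- acc$hydrophobic / nf
  acc$hydrophilic <- acc$hydrophilic / nf
  acc$total <- acc$total / nf
  acc$n_frames_used <- nf
  acc
}

#' Root-mean-square fluctuations of an aligned trajectory
#'
#' `RMSF_i = sqrt( mean_t | x_i(t) - <x_i> |^2 )` per selected atom.  The
#' trajectory must already be in the solute-fixed frame (see
#' [kabsch_align()]).  The conventional selection is all heavy atoms
#' excluding the metal ion, which is the default.
#'
#' @param traj aligned [trajectory()]
#' @param selection atoms to report (roles or indices); default heavy
#'   atoms minus the metal
#' @return data.frame with `atom`, `name`, `role`, `rmsf` (angstrom)
#' @export
compute_rmsf <- function(traj, selection = NULL) {
  top <- traj$topology
  sel <- if (!is.null(selection)) resolve_selection(top, selection)
         else which(top$atoms$element != "H" & top$atoms$role != "metal")
  if (!length(sel)) stop("empty RMSF selection")
  rmsf <- vapply(sel, function(i) {
    xi <- traj$coords[, i, , drop = FALSE]
    dim(xi) <- c(dim(traj$coords)[1], 3L)
    mu <- colMeans(xi)
    sqrt(mean(rowSums(sweep(xi, 2, mu)^2)))
  }, numeric(1))
  data.frame(atom = sel,
             name = if (!is.null(top)) top$atoms$name[sel] else NA,
             role = if (!is.null(top)) top$atoms$role[sel] else NA,
             rmsf = rmsf)
}

#' Signed dihedral angle of four points
#'
#' IUPAC convention about the p2-p3 axis via the atan2 formulation:
#' 0 for cis-planar, 180 for trans-planar, positive for a right-handed
#' (clockwise looking from p2 to p3) rotation of the far bond.  Result in
#' (-180, 180].
#'
#' @param p1,p2,p3,p4 length-3 positions, angstrom
#' @return degrees
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  if (sqrt(sum(b2^2)) < 1e-10) stop("degenerate dihedral: p2 == p3")
  cr <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                         a[3] * b[1] - a[1] * b[3],
                         a[1] * b[2] - a[2] * b[1])
  n1 <- cr(b1, b2); n2 <- cr(b2, b3)
  if (sqrt(sum(n1^2)) < 1e-10 || sqrt(sum(n2^2)) < 1e-10)
    stop("degenerate dihedral: collinear triple")
  x <- sum(cr(n1, n2) * b2) / sqrt(sum(b2^2))
  ang <- atan2(x, sum(n1 * n2)) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

#' Torsional distributions over a trajectory
#'
#' Histograms each torsion quadruple's dihedral over frames on bins
#' covering (-180, 180], then averages the per-quadruple histograms (for
#' a porphyrin: the single N-N-N-N proper dihedral and the four
#' metal-Ca-Ca-N impropers, one per pyrrole) and attaches a moving-average
#' smoothing of the averaged curve.
#'
#' @param traj [trajectory()]
#' @param quadruples list of `list(ids, label, name)`; default: the
#'   topology's torsions
#' @param bin_width degrees (default 5)
#' @param running_window moving-average width in bins for the smoothed
#'   curve (default 5)
#' @return object of class `torsion_distribution`: data.frame with
#'   `theta`, one `freq_<name>` column per quadruple, `freq_mean`,
#'   `freq_smooth`; attribute `circular_mean` (degrees, per quadruple)
#' @export
torsion_distribution <- function(traj, quadruples = traj$topology$torsions,
                                 bin_width = 5, running_window = 5L) {
  if (!length(quadruples)) stop("no torsion quadruples defined")
  nb <- ceiling(360 / bin_width)
  edges <- seq(-180, 180, length.out = nb + 1L)
  mids <- (edges[-1] + edges[-(nb + 1)]) / 2
  nfr <- n_frames(traj)
  H <- matrix(0, nb, length(quadruples))
  cmean <- numeric(length(quadruples))
  for (q in seq_along(quadruples)) {
    ids <- quadruples[[q]]$ids
    ang <- vapply(seq_len(nfr), function(f) {
      X <- frame_coords(traj, f)
      dihedral_angle(X[ids[1], ], X[ids[2], ], X[ids[3], ], X[ids[4], ])
    }, numeric(1))
    # (-180, 180]: bin i covers (edges[i], edges[i+1]]
    bin <- pmax(1L, ceiling((ang + 180) / bin_width))
    H[, q] <- tabulate(bin, nb) / nfr
    cmean[q] <- atan2(mean(sin(ang * pi / 180)),
                      mean(cos(ang * pi / 180))) * 180 / pi
  }
  avg <- rowMeans(H)
  w <- max(1L, running_window); if (w %% 2L == 0L) w <- w + 1L
  # periodic moving average
  ext <- c(tail(avg, w %/% 2), avg, head(avg, w %/% 2))
  smooth <- as.numeric(stats::filter(ext, rep(1 / w, w),
                                     sides = 2))[(w %/% 2 + 1):(w %/% 2 + nb)]
  out <- data.frame(theta = mids)
  nms <- vapply(seq_along(quadruples), function(q) {
    nm <- quadruples[[q]]$name
    if (is.null(nm)) paste0("q", q) else nm
  }, character(1))
  for (q in seq_along(quadruples)) out[[paste0("freq_", nms[q])]] <- H[, q]
  out$freq_mean <- avg
  out$freq_smooth <- smooth
  structure(out, class = c("torsion_distribution", "data.frame"),
            circular_mean = stats::setNames(cmean, nms),
            labels = vapply(quadruples, `[[`, "", "label"))
}
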