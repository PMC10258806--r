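## Radial, angular and coordination-number statistics of hydration shells.

#' Radial distribution function with running coordination number
#'
#' Computes g(r) between a centre selection and a target selection,
#' averaged over frames, on half-open bins `[i*dr, (i+1)*dr)`.  For a
#' periodic trajectory the reference density is `rho = N_target / V`
#' (minimum-image distances; `r_max` must not exceed half the box).  For a
#' non-periodic system a reference `density` must be supplied for g(r) to
#' be meaningful; the running coordination number
#' `n(r) = integral 4 pi r'^2 rho g(r') dr'` is in either case accumulated
#' directly from the binned counts per centre per frame, so it is exact
#' regardless of the density convention.  Atoms occurring in both
#' selections are never paired with themselves.
#'
#' @param traj [trajectory()]
#' @param center,target selections (roles or indices, see
#'   [resolve_selection()])
#' @param r_max histogram range, angstrom
#' @param dr bin width, angstrom (default 0.05, resolving typical
#'   hydration-shell peak widths of ~0.6 angstrom)
#' @param density reference number density, atoms/angstrom^3 (required for
#'   non-periodic trajectories)
#' @return object of class `rdf`: data.frame-like with `r_lo`, `r_hi`, `r`
#'   (midpoints), `g`, `cn` (running coordination number at `r_hi`) and
#'   `counts` (raw pair counts per bin), plus attributes `density`,
#'   `n_frames`, `n_centers`
#' @export
compute_rdf <- function(traj, center, target, r_max, dr = 0.05,
                        density = NULL) {
  if (dr <= 0) stop("dr must be > 0")
  periodic <- !is.null(traj$box_length)
  if (periodic && r_max > traj$box_length / 2)
    stop("r_max = ", r_max, " exceeds half the box (",
         traj$box_length / 2, ")")
  ci <- resolve_selection(traj$topology, center)
  ti <- resolve_selection(traj$topology, target)
  nfr <- n_frames(traj)
  nbins <- ceiling(r_max / dr)
  counts <- numeric(nbins)
  box <- if (periodic) traj$box_length else -1
  for (f in seq_len(nfr)) {
    X <- frame_coords(traj, f)
    counts <- counts + pair_hist_frame(X[ci, , drop = FALSE],
                                       X[ti, , drop = FALSE],
                                       as.integer(ci), as.integer(ti),
                                       box, r_max, dr)
  }
  if (is.null(density)) {
    if (!periodic)
      stop("non-periodic trajectory: supply a reference density (atoms/A^3)")
    density <- length(ti) / traj$box_length^3
  }
  edges <- dr * (0:nbins)
  shell_vol <- 4 / 3 * pi * (edges[-1]^3 - edges[-(nbins + 1)]^3)
  norm <- nfr * length(ci)
  g <- counts / (norm * shell_vol * density)
  cn <- cumsum(counts) / norm
  out <- data.frame(r_lo = edges[-(nbins + 1)], r_hi = edges[-1],
                    r = (edges[-1] + edges[-(nbins + 1)]) / 2,
                    g = g, cn = cn, counts = counts)
  structure(out, class = c("rdf", "data.frame"), density = density,
            n_frames = nfr, n_centers = length(ci))
}

#' Average coordination number by integrating an RDF
#'
#' Linear interpolation of the running coordination number n(r) at `r_cut`
#' (n is defined at bin upper edges, with n(0) = 0), matching the
#' convention of integrating the pair correlation up to a shell minimum.
#'
#' @param rdf from [compute_rdf()]
#' @param r_cut cutoff radius, angstrom; must lie within the RDF grid
#' @return mean coordination number (scalar)
#' @export
integrate_coordination <- function(rdf, r_cut) {
  hi <- max(rdf$r_hi)
  if (r_cut < 0 || r_cut > hi)
    stop("r_cut = ", r_cut, " outside the RDF grid [0, ", hi, "]")
  approx(c(0, rdf$r_hi), c(0, rdf$cn), xout = r_cut)$y
}

#' Detect hydration-shell boundaries from an RDF
#'
#' Boundaries are local minima of the moving-average-smoothed g(r) between
#' successive peaks.  Where g(r) vanishes over a contiguous run between two
#' peaks the boundary is the run's midpoint and the minimum is flagged
#' `zero` — a vanishing first-shell minimum indicates no exchange between
#' the shells on the sampled timescale, while a nonzero minimum marks a
#' labile, exchanging shell.
#'
#' @param rdf from [compute_rdf()]
#' @param smoothing_window moving-average width, bins (odd; default 5)
#' @param n_shells number of boundaries required
#' @param min_depth a valley separates two peaks only if its smoothed g
#'   falls below `min_depth` times the lower of the two peak heights;
#'   shallower ripples (e.g. the statistical noise of a structureless
#'   fluid) are merged into one peak (default 0.7)
#' @param min_height a bin qualifies as a shell peak only if its smoothed
#'   g exceeds `min_height` times the median smoothed g (default 1.5): a
#'   physical coordination peak stands well above the typical level of
#'   the profile, while the noise ripples of a structureless fluid stay
#'   near it
#' @return object of class `shell_partition`: list with `boundaries`
#'   (angstrom, strictly increasing), `zero_minimum` (logical per
#'   boundary), `peaks` (peak positions, angstrom)
#' @export
detect_shell_boundaries <- function(rdf, smoothing_window = 5L,
                                    n_shells = 1L, min_depth = 0.7,
                                    min_height = 1.5) {
  g <- rdf$g
  r <- rdf$r
  if (!length(g)) stop("empty RDF")
  w <- max(1L, smoothing_window)
  if (w %% 2L == 0L) w <- w + 1L
  gs <- stats::filter(g, rep(1 / w, w), sides = 2)
  gs[is.na(gs)] <- g[is.na(gs)]
  gs <- as.numeric(gs)
  n <- length(gs)
  eps <- 1e-12
  thr <- min_height * stats::median(gs)
  is_peak <- vapply(seq_len(n), function(i) {
    gl <- if (i > 1) gs[i - 1] else -Inf
    gr <- if (i < n) gs[i + 1] else -Inf
    gs[i] > eps && gs[i] >= max(gl, thr) && gs[i] > gr
  }, logical(1))
  peaks <- which(is_peak)
  # collapse plateau peaks
  if (length(peaks) > 1) peaks <- peaks[c(TRUE, diff(peaks) > 1)]
  # merge peak pairs not separated by a sufficiently deep valley
  repeat {
    if (length(peaks) < 2) break
    merged <- FALSE
    for (s in seq_len(length(peaks) - 1L)) {
      seg <- (peaks[s] + 1L):(peaks[s + 1L] - 1L)
      valley <- if (length(seg)) min(gs[seg]) else Inf
      if (valley > min_depth * min(gs[peaks[s]], gs[peaks[s + 1L]])) {
        drop <- if (gs[peaks[s]] < gs[peaks[s + 1L]]) s else s + 1L
        peaks <- peaks[-drop]
        merged <- TRUE
        break
      }
    }
    if (!merged) break
  }
  # a trailing run of zero density after the last peak closes the last shell
  trailing <- length(peaks) >= 1L && peaks[length(peaks)] < n &&
    any(g[(peaks[length(peaks)] + 1L):n] <= 0) &&
    g[n] <= 0
  n_minima <- length(peaks) - 1L + as.integer(trailing)
  if (n_minima < n_shells)
    stop("found ", length(peaks), " peak(s) at r = ",
         paste(signif(r[peaks], 4), collapse = ", "), " giving ",
         n_minima, " usable minima; cannot define ", n_shells,
         " shell boundar", if (n_shells == 1) "y" else "ies")
  boundaries <- numeric(n_shells)
  zero_min <- logical(n_shells)
  for (s in seq_len(n_shells)) {
    if (s < length(peaks)) {
      seg <- (peaks[s] + 1L):(peaks[s + 1L] - 1L)
      zero_run <- seg[g[seg] <= 0]
      if (length(zero_run)) {
        boundaries[s] <- (r[min(zero_run)] + r[max(zero_run)]) / 2
        zero_min[s] <- TRUE
      } else {
        boundaries[s] <- r[seg[which.min(gs[seg])]]
      }
    } else {                       # trailing zero run closes the last shell
      seg <- (peaks[s] + 1L):n
      zero_run <- seg[g[seg] <= 0]
      boundaries[s] <- (r[min(zero_run)] + r[max(zero_run)]) / 2
      zero_min[s] <- TRUE
    }
  }
  structure(list(boundaries = boundaries, zero_minimum = zero_min,
                 peaks = r[peaks]),
            class = "shell_partition")
}

#' @export
print.shell_partition <- function(x, ...) {
  cat("<shell_partition> boundaries (A): ",
      paste(sprintf("%.3f%s", x$boundaries,
                    ifelse(x$zero_minimum, " [zero min]", "")),
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Angular distribution function of ligand-centre-ligand angles
#'
#' For every frame, all unordered pairs of ligand atoms within `r_cut` of
#' the centre contribute the angle they subtend at the centre.  For an
#' octahedral complex the distribution concentrates at 90 and 180 degrees
#' (12:3 of the 15 vertex pairs); a square pyramid gives 8:2.
#'
#' @param traj [trajectory()]
#' @param center centre selection (single atom per frame; typically
#'   `"metal"`)
#' @param ligands ligand selection, e.g. `c("ring_N", "water_O")`
#' @param r_cut coordination cutoff, angstrom
#' @param bin_width degrees (default 2)
#' @return object of class `adf`: data.frame with `theta_lo`, `theta_hi`,
#'   `theta`, `freq` (normalised over all registered angles); attribute
#'   `n_angles`
#' @export
compute_adf <- function(traj, center, ligands, r_cut, bin_width = 2) {
  if (r_cut <= 0) stop("r_cut must be > 0")
  ci <- resolve_selection(traj$topology, center)
  li <- resolve_selection(traj$topology, ligands)
  li <- setdiff(li, ci)
  nbins <- ceiling(180 / bin_width)
  counts <- numeric(nbins)
  n_angles <- 0L
  for (f in seq_len(n_frames(traj))) {
    X <- frame_coords(traj, f)
    cpos <- X[ci[1], ]
    v <- sweep(X[li, , drop = FALSE], 2, cpos)
    if (!is.null(traj$box_length))
      v <- v - traj$box_length * floor(v / traj$box_length + 0.5)
    d <- sqrt(rowSums(v^2))
    inshell <- which(d < r_cut)
    if (length(inshell) < 2) next
    u <- v[inshell, , drop = FALSE] / d[inshell]
    cosm <- tcrossprod(u)
    ang <- acos(pmin(1, pmax(-1, cosm[upper.tri(cosm)]))) * 180 / pi
    bin <- pmin(nbins, floor(ang / bin_width) + 1L)  # 180 lands in last bin
    tab <- tabulate(bin, nbins)
    counts <- counts + tab
    n_angles <- n_angles + length(ang)
  }
  if (n_angles == 0L)
    stop("no frame with >= 2 ligands within r_cut = ", r_cut)
  edges <- bin_width * (0:nbins)
  structure(data.frame(theta_lo = edges[-(nbins + 1)], theta_hi = edges[-1],
                       theta = (edges[-1] + edges[-(nbins + 1)]) / 2,
                       freq = counts / n_angles),
            class = c("adf", "data.frame"), n_angles = n_angles)
}

#' Coordination number distribution
#'
#' Per-frame integer count of target atoms within `r_cut` of the centre,
#' reported as an empirical probability distribution over frames.
#'
#' @inheritParams compute_adf
#' @param targets target selection
#' @return object of class `cnd`: data.frame with `cn`, `p`; attributes
#'   `mean` and `n_frames`
#' @export
compute_cnd <- function(traj, center, targets, r_cut) {
  if (r_cut <= 0) stop("r_cut must be > 0")
  nfr <- n_frames(traj)
  if (!nfr) stop("empty trajectory")
  ci <- resolve_selection(traj$topology, center)
  ti <- setdiff(resolve_selection(traj$topology, targets), ci)
  per_frame <- integer(nfr)
  for (f in seq_len(nfr)) {
    X <- frame_coords(traj, f)
    d <- min_image_distance(X[ci[1], ], X[ti, , drop = FALSE],
                            traj$box_length)
    per_frame[f] <- sum(d < r_cut)
  }
  cnd_from_counts(per_frame)
}

cnd_from_counts <- function(per_frame) {
  tab <- table(factor(per_frame, levels = 0:max(per_frame, 0)))
  structure(data.frame(cn = as.integer(names(tab)),
                       p = as.numeric(tab) / length(per_frame)),
            class = c("cnd", "data.frame"),
            mean = mean(per_frame), n_frames = length(per_frame))
}

#' Hydrogen-bond coordination of water hydrogens at the pyrrole nitrogens
#'
#' Per-frame count of `water_H` atoms within `h_bond_cutoff` of *any*
#' `ring_N`, as a distribution over frames.  A distance-only criterion is
#' used (default 2.5 angstrom); the concentration of the distribution at
#' zero diagnoses metal-repelled water hydrogens, i.e. suppressed N-H
#' hydrogen bonding after metal insertion.
#'
#' @param traj [trajectory()] whose topology has `ring_N` and `water_H`
#' @param h_bond_cutoff angstrom
#' @return object of class `cnd` (see [compute_cnd()])
#' @export
compute_nh_cnd <- function(traj, h_bond_cutoff = 2.5) {
  ni <- resolve_selection(traj$topology, "ring_N")
  hi <- resolve_selection(traj$topology, "water_H")
  nfr <- n_frames(traj)
  if (!nfr) stop("empty trajectory")
  per_frame <- integer(nfr)
  for (f in seq_len(nfr)) {
    X <- frame_coords(traj, f)
    near <- logical(length(hi))
    for (n1 in ni) {
      d <- min_image_distance(X[n1, ], X[hi, , drop = FALSE],
                              traj$box_length)
      near <- near | d < h_bond_cutoff
    }
    per_frame[f] <- sum(near)
  }
  cnd_from_counts(per_frame)
}
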