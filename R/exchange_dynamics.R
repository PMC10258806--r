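## Shell occupancy, direct-method mean residence times and exchange counts.
##
## The direct method counts ligand departures from a coordination shell
## that persist for more than a threshold t*: t* = 0 ps registers every
## boundary crossing, while t* = 0.5 ps (the average hydrogen-bond
## lifetime in water) registers only sustainable exchanges.  The mean
## residence time is tau = CN * t_sim / N_ex, and
## R_ex = N_ex(0.0) / N_ex(0.5) measures how many crossing attempts are
## needed per sustained exchange.

#' Per-ligand shell-occupancy time series
#'
#' Assigns each target atom, in each frame, the index of the radial shell
#' containing its minimum-image distance to the centre: shell 1 is the
#' innermost (r below the first boundary), shell `k+1` means beyond the
#' last of the `k` boundaries.  A distance exactly on a boundary belongs
#' to the inner shell (half-open `[lo, hi)` bins).
#'
#' @param traj [trajectory()]
#' @param center centre selection (single atom; typically `"metal"`)
#' @param target ligand selection (typically `"water_O"`)
#' @param partition [detect_shell_boundaries()] result, or numeric vector
#'   of boundary radii (angstrom)
#' @return object of class `occupancy_series`: integer matrix
#'   `n_frames x n_ligands` with attributes `dt`, `boundaries`,
#'   `ligand_atoms`
#' @export
shell_occupancy_series <- function(traj, center, target, partition) {
  b <- if (inherits(partition, "shell_partition")) partition$boundaries
       else as.numeric(partition)
  if (!length(b) || is.unsorted(b, strictly = TRUE))
    stop("partition boundaries must be strictly increasing")
  ci <- resolve_selection(traj$topology, center)
  ti <- setdiff(resolve_selection(traj$topology, target), ci)
  if (!length(ti)) stop("empty ligand selection")
  nfr <- n_frames(traj)
  ser <- matrix(NA_integer_, nfr, length(ti))
  for (f in seq_len(nfr)) {
    X <- frame_coords(traj, f)
    d <- min_image_distance(X[ci[1], ], X[ti, , drop = FALSE],
                            traj$box_length)
    # d < b[s] puts a boundary distance in the outer shell; findInterval
    # with left-open gives the half-open [lo, hi) shell convention
    ser[f, ] <- findInterval(d, b, left.open = TRUE) + 1L
  }
  structure(ser, class = "occupancy_series", dt = traj$dt, boundaries = b,
            ligand_atoms = ti)
}

#' Count shell departures persisting longer than t*
#'
#' A departure event is a maximal run of frames outside `shell_index`,
#' immediately preceded by occupancy of `shell_index`, lasting strictly
#' more than `floor(t_star/dt)` frames; a single continuous absence counts
#' once no matter how many frames it spans, and `t_star = 0` counts every
#' crossing.  Re-entry events with the same persistence rule are counted
#' symmetrically and reported in the `n_entries` attribute.
#'
#' @param series [shell_occupancy_series()] result
#' @param shell_index probed shell (1 = innermost)
#' @param t_star persistence threshold, ps
#' @param dt frame spacing, ps (default: taken from `series`)
#' @return integer N_ex with attribute `n_entries`
#' @export
count_exchanges <- function(series, shell_index, t_star = 0,
                            dt = attr(series, "dt")) {
  if (t_star < 0) stop("t_star must be >= 0")
  k_max <- max(series)
  if (shell_index < 1 || shell_index > k_max)
    stop("shell_index ", shell_index, " out of range [1, ", k_max, "]")
  need <- floor(t_star / dt)       # absence must span > `need` frames
  n_ex <- 0L; n_in <- 0L
  for (l in seq_len(ncol(series))) {
    r <- rle(series[, l] == shell_index)
    v <- r$values; len <- r$lengths
    for (j in seq_along(v)) {
      if (!v[j] && j > 1L && len[j] > need) n_ex <- n_ex + 1L   # departure
      if (v[j] && j > 1L && len[j] > need) n_in <- n_in + 1L    # entry
    }
  }
  structure(n_ex, n_entries = n_in)
}

#' Direct-method mean residence time
#'
#' tau = CN * t_sim / N_ex: the mean shell occupancy times the simulated
#' time, divided by the number of registered exchange events.  With no
#' events the residence time is unresolved by the simulation and a
#' sentinel (`NA` flagged `"no exchange observed (tau > t_sim)"`) is
#' returned rather than a number.
#'
#' @param CN mean occupancy of the probed shell (may be fractional)
#' @param t_sim analysed time span, ps
#' @param N_ex exchange count at the chosen t*
#' @return tau in ps, or the flagged `NA` sentinel
#' @export
mean_residence_time <- function(CN, t_sim, N_ex) {
  if (N_ex < 0 || t_sim <= 0 || CN < 0) stop("invalid residence-time inputs")
  if (N_ex == 0)
    return(structure(NA_real_, sentinel = "no exchange observed (tau > t_sim)"))
  CN * t_sim / N_ex
}

#' Attempted-to-sustained exchange ratio
#'
#' `R_ex = N_ex(0.0) / N_ex(0.5)` — how many boundary crossings occur per
#' sustained exchange — and its reciprocal, the sustainability
#' coefficient.
#'
#' @param N_ex_0 crossings at t* = 0 ps
#' @param N_ex_05 sustained exchanges at t* = 0.5 ps
#' @return list with `R_ex` and `sustainability`; `NA` sentinels when
#'   `N_ex_05 = 0`
#' @export
compute_rex <- function(N_ex_0, N_ex_05) {
  if (N_ex_05 == 0)
    return(list(R_ex = structure(NA_real_, sentinel = "no sustained exchange"),
                sustainability = 0))
  list(R_ex = N_ex_0 / N_ex_05, sustainability = N_ex_05 / N_ex_0)
}

#' Full residence-time statistics for one shell
#'
#' Bundles the direct-method quantities for the probed shell: mean
#' occupancy CN, exchange counts and mean residence times at each t*, and
#' R_ex/sustainability from the first two t* values (conventionally 0.0
#' and 0.5 ps).
#'
#' @param series [shell_occupancy_series()] result
#' @param shell_index probed shell (1 = innermost)
#' @param t_star persistence thresholds, ps
#' @return object of class `residence_stats`: list with `CN`, `t_sim`,
#'   `t_star`, `N_ex`, `tau`, `R_ex`, `sustainability`
#' @export
residence_stats <- function(series, shell_index, t_star = c(0, 0.5)) {
  dt <- attr(series, "dt")
  t_sim <- (nrow(series) - 1L) * dt
  CN <- mean(series == shell_index) * ncol(series)
  N_ex <- vapply(t_star, function(ts)
    as.integer(count_exchanges(series, shell_index, ts, dt)), integer(1))
  tau <- lapply(N_ex, function(n) mean_residence_time(CN, t_sim, n))
  rex <- if (length(t_star) >= 2) compute_rex(N_ex[1], N_ex[2])
         else list(R_ex = NA_real_, sustainability = NA_real_)
  structure(list(CN = CN, t_sim = t_sim, t_star = t_star, N_ex = N_ex,
                 tau = tau, R_ex = rex$R_ex,
                 sustainability = rex$sustainability),
            class = "residence_stats")
}

#' @export
print.residence_stats <- function(x, ...) {
  cat("<residence_stats> CN = ", signif(x$CN, 4), ", t_sim = ", x$t_sim,
      " ps\n", sep = "")
  for (i in seq_along(x$t_star)) {
    tv <- x$tau[[i]]
    cat(sprintf("  t* = %.2f ps: N_ex = %d, tau = %s\n", x$t_star[i],
                x$N_ex[i],
                if (is.na(tv)) attr(tv, "sentinel")
                else paste0(signif(tv, 4), " ps")))
  }
  cat("  R_ex = ", if (is.na(x$R_ex)) attr(x$R_ex, "sentinel")
      else signif(x$R_ex, 4),
      ", sustainability = ", signif(x$sustainability, 4), "\n", sep = "")
  invisible(x)
}

#' Centre-ligand distance series for exchange plots
#'
#' Minimum-image centre-target distance per frame per ligand, with the
#' shell boundaries attached for plotting horizontal guides.
#'
#' @inheritParams shell_occupancy_series
#' @param partition optional boundaries to annotate
#' @return data.frame with `frame`, `time` (ps), one column per ligand
#'   atom; attribute `boundaries`
#' @export
distance_series <- function(traj, center, target, partition = NULL) {
  ci <- resolve_selection(traj$topology, center)
  ti <- setdiff(resolve_selection(traj$topology, target), ci)
  if (!length(ti)) stop("empty ligand selection")
  nfr <- n_frames(traj)
  D <- matrix(NA_real_, nfr, length(ti))
  for (f in seq_len(nfr)) {
    X <- frame_coords(traj, f)
    D[f, ] <- min_image_distance(X[ci[1], ], X[ti, , drop = FALSE],
                                 traj$box_length)
  }
  out <- data.frame(frame = seq_len(nfr), time = (seq_len(nfr) - 1) * traj$dt)
  for (j in seq_along(ti)) out[[paste0("atom_", ti[j])]] <- D[, j]
  b <- if (inherits(partition, "shell_partition")) partition$boundaries
       else partition
  structure(out, boundaries = b)
}
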