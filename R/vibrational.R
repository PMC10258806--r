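## Velocity autocorrelation functions and vibrational power spectra.

#' Derive velocities by central finite differences
#'
#' `v_i = (x_{i+1} - x_{i-1}) / (2 dt)` with one-sided differences at the
#' endpoints.  For periodic trajectories the frame-to-frame displacements
#' are minimum-imaged first, so a particle crossing the box boundary has a
#' continuous velocity.  Harmonic motion of period T is attenuated by
#' `sinc(w dt)`; the error is below 1% for `dt <= T/40`.
#'
#' @param traj [trajectory()] with >= 3 frames
#' @return the trajectory with a `velocities` array (angstrom/ps)
#' @export
velocities_from_positions <- function(traj) {
  nfr <- n_frames(traj)
  if (nfr < 3) stop("need >= 3 frames for central differences")
  dt <- traj$dt
  dx <- traj$coords[-1, , , drop = FALSE] - traj$coords[-nfr, , , drop = FALSE]
  if (!is.null(traj$box_length))
    dx <- dx - traj$box_length * floor(dx / traj$box_length + 0.5)
  v <- array(0, dim(traj$coords))
  v[1, , ] <- dx[1, , ] / dt
  v[nfr, , ] <- dx[nfr - 1, , ] / dt
  v[2:(nfr - 1), , ] <- (dx[-1, , , drop = FALSE] +
                           dx[-(nfr - 1), , , drop = FALSE]) / (2 * dt)
  traj$velocities <- v
  traj
}

#' Velocity autocorrelation function
#'
#' `C(t) = < sum_j v_j(t_i) . v_j(t_i + t) >` averaged over `n_origins`
#' evenly spaced time origins `t_i` and the selected atoms, normalised so
#' `C(0) = 1`.  Hydrogens are conventionally excluded from solute spectra
#' (their motion is often constrained in the generating simulation);
#' select roles accordingly.
#'
#' @param traj [trajectory()]; velocities are derived from positions via
#'   [velocities_from_positions()] when absent
#' @param selection atoms to include (roles or indices); default: all
#'   non-hydrogen atoms
#' @param correlation_length maximum lag, ps (default 2.0)
#' @param n_origins number of time origins (default 5000)
#' @return object of class `vacf`: data.frame with `t` (ps) and `C`
#'   (normalised); attributes `n_origins`, `dt`, `C0_raw`
#' @export
compute_vacf <- function(traj, selection = NULL, correlation_length = 2.0,
                         n_origins = 5000L) {
  if (is.null(traj$velocities)) traj <- velocities_from_positions(traj)
  top <- traj$topology
  sel <- if (!is.null(selection)) resolve_selection(top, selection)
         else if (!is.null(top)) which(top$atoms$element != "H")
         else seq_len(n_atoms(traj))
  if (!length(sel)) stop("empty atom selection")
  dt <- traj$dt
  nfr <- n_frames(traj)
  n_lag <- floor(correlation_length / dt)
  max_origins <- nfr - n_lag
  if (max_origins < 1)
    stop("trajectory too short for correlation_length = ",
         correlation_length, " ps (needs > ", n_lag, " frames)")
  if (n_origins > max_origins)
    stop("too few frames for ", n_origins, " origins; maximum here is ",
         max_origins)
  origins <- unique(round(seq(1, max_origins, length.out = n_origins)))
  V <- traj$velocities[, sel, , drop = FALSE]
  dim(V) <- c(nfr, length(sel) * 3L)      # frame-major flattening
  C <- numeric(n_lag + 1L)
  for (lag in 0:n_lag)
    C[lag + 1L] <- mean(rowSums(V[origins, , drop = FALSE] *
                                  V[origins + lag, , drop = FALSE]))
  if (C[1] <= 0) stop("zero velocity variance in the selection")
  structure(data.frame(t = dt * (0:n_lag), C = C / C[1]),
            class = c("vacf", "data.frame"),
            n_origins = length(origins), dt = dt, C0_raw = C[1])
}

#' Vibrational power spectrum from a VACF
#'
#' Discrete cosine transform of the (windowed, zero-padded) normalised
#' VACF, reported against wavenumber in cm^-1:
#' `I(nu) = dt * [ C_w(0) + 2 sum_{t>0} C_w(t) cos(2 pi c nu t) ]`,
#' clipped at zero (the even-extension transform of a finite noisy record
#' can dip slightly negative).  Zero padding refines the plotted grid
#' only; the physical resolution is `1 / (c * correlation_length)` and is
#' reported as such.
#'
#' @param vacf from [compute_vacf()]
#' @param zero_padding_factor grid-refinement factor (default 4)
#' @param window `"hann"` (default), `"blackman"` or `"none"`
#' @param nu_max upper wavenumber bound of the report, cm^-1
#' @return object of class `power_spectrum`: data.frame with `nu` (cm^-1)
#'   and `intensity`; attributes `resolution` (cm^-1), `window`
#' @export
power_spectrum <- function(vacf, zero_padding_factor = 4, window = "hann",
                           nu_max = 4000) {
  C <- vacf$C
  n <- length(C)
  if (!n) stop("empty VACF")
  dt <- attr(vacf, "dt")
  w <- switch(window,
              none = rep(1, n),
              hann = 0.5 * (1 + cos(pi * (0:(n - 1)) / (n - 1))),
              blackman = {
                x <- (0:(n - 1)) / (n - 1)  # half window: lag 0 at peak
                0.42 + 0.5 * cos(pi * x) + 0.08 * cos(2 * pi * x)
              },
              stop("unknown window: ", window))
  Cw <- C * w
  npad <- max(2L, as.integer(zero_padding_factor)) * n
  padded <- c(Cw, numeric(npad - n))
  # one-sided cosine transform via FFT of the zero-padded record
  ft <- fft(padded)
  I_raw <- dt * (2 * Re(ft) - Cw[1])
  nu <- (0:(npad - 1)) / (npad * dt * C_LIGHT_CM_PS)
  keep <- nu <= nu_max & seq_along(nu) <= npad / 2
  structure(data.frame(nu = nu[keep], intensity = pmax(0, I_raw[keep])),
            class = c("power_spectrum", "data.frame"),
            resolution = 1 / (C_LIGHT_CM_PS * dt * (n - 1)),
            window = window, zero_padding_factor = zero_padding_factor)
}

#' Locate spectral peaks
#'
#' Local maxima of the intensity above a prominence threshold (fraction of
#' the global maximum).
#'
#' @param spec from [power_spectrum()]
#' @param min_prominence fraction of the maximum intensity (default 0.1)
#' @return data.frame with `nu` and `intensity`, strongest first
#' @export
spectrum_peaks <- function(spec, min_prominence = 0.1) {
  y <- spec$intensity
  n <- length(y)
  thr <- min_prominence * max(y)
  idx <- which(y > thr &
                 y >= c(-Inf, y[-n]) &
                 y > c(y[-1], -Inf))
  out <- data.frame(nu = spec$nu[idx], intensity = y[idx])
  out[order(-out$intensity), , drop = FALSE]
}
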