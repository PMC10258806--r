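## Synthetic trajectories with exact, controllable ground truth.
##
## These generators emulate the statistical structure of a hydrated
## metalloporphyrin — a metal centre with four in-plane pyrrole nitrogens,
## axial first-shell waters, layered hydration shells with stochastic
## exchange, and bulk water at liquid density — without any force field.
## Ground truth (shell occupancies, exchange event logs, oscillator
## frequencies, rigid-body motion) is exact by construction, so every
## analysis stage has a parameter-recovery test.

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has_old) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

# Uniform random proper rotation (quaternion method).
random_rotation_matrix <- function() {
  q <- rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

#' Specify radial hydration shells
#'
#' @param r_lo,r_hi inner/outer shell radii, angstrom; shells must be
#'   ordered and non-overlapping
#' @param occupancy integer water count per shell
#' @param jitter std-dev (angstrom) of radial placement noise about the
#'   shell midpoint
#' @return object of class `shell_spec`
#' @export
shell_spec <- function(r_lo, r_hi, occupancy = rep(0L, length(r_lo)),
                       jitter = 0.05) {
  stopifnot(length(r_lo) == length(r_hi), length(occupancy) == length(r_lo))
  if (any(r_hi <= r_lo)) stop("each shell needs r_hi > r_lo")
  if (any(occupancy < 0)) stop("occupancies must be >= 0")
  if (length(r_lo) > 1 && any(diff(r_lo) <= 0 | r_lo[-1] < r_hi[-length(r_hi)]))
    stop("shells must be ordered and non-overlapping")
  structure(list(r_lo = r_lo, r_hi = r_hi,
                 occupancy = as.integer(occupancy), jitter = jitter),
            class = "shell_spec")
}

#' Specify a shell-exchange process
#'
#' Each ligand performs a continuous-time Markov jump process between
#' adjacent shells: it leaves its current shell after an exponential dwell
#' with mean `1/rate`, moving to a uniformly chosen adjacent shell.
#'
#' @param rate per-ligand transition rate, events/ps
#' @param n_ligands number of exchanging waters
#' @param duration simulated time, ps
#' @param dt sampling interval, ps
#' @param seed RNG seed
#' @return object of class `exchange_spec`
#' @export
exchange_spec <- function(rate, n_ligands, duration, dt, seed = 1L) {
  if (rate < 0) stop("rate must be >= 0")
  if (duration < dt) stop("duration must be >= dt")
  structure(list(rate = rate, n_ligands = as.integer(n_ligands),
                 duration = duration, dt = dt, seed = seed),
            class = "exchange_spec")
}

#' Idealised planar metalloporphine scaffold
#'
#' Builds a D4h-symmetric porphine-like skeleton in the xy-plane: one metal
#' at the origin, four pyrrole nitrogens at `metal_N_distance` along the
#' +-x/+-y axes, eight alpha and eight beta carbons, four meso carbons and
#' twelve ring hydrogens (37 atoms).  Roles, polarity classes and the
#' torsion quadruples used by the flexibility analysis (the proper
#' N-N-N-N dihedral and the four improper metal-Ca-Ca-N torsions, one per
#' pyrrole) are pre-assigned.
#'
#' @param metal_N_distance metal-nitrogen bond length, angstrom
#' @param metal_element element symbol of the central ion
#' @return list of class `scaffold` with `topology` and `coords`
#'   (`n_atoms x 3` matrix, plane normal = +z)
#' @export
generate_porphyrin_scaffold <- function(metal_N_distance = 1.98,
                                        metal_element = "Co") {
  d <- metal_N_distance
  if (d <= 0) stop("metal_N_distance must be > 0")
  rot90 <- function(p, k) {        # rotate 2D point(s) by k*90 degrees
    th <- k * pi / 2
    cbind(p[, 1] * cos(th) - p[, 2] * sin(th),
          p[, 1] * sin(th) + p[, 2] * cos(th))
  }
  # local pyrrole geometry (x outward from the metal), angstrom offsets
  # chosen to mimic porphine bond lengths at d ~ 2.0
  N_loc  <- cbind(d, 0)
  CA_loc <- cbind(c(d + 0.75, d + 0.75), c(1.10, -1.10))
  CB_loc <- cbind(c(d + 2.10, d + 2.10), c(0.68, -0.68))
  HB_loc <- cbind(c(d + 3.00, d + 3.00), c(1.25, -1.25))
  meso_r <- d + 1.42
  CM_loc <- cbind(meso_r * cos(pi / 4), meso_r * sin(pi / 4))
  HM_loc <- cbind((meso_r + 1.08) * cos(pi / 4), (meso_r + 1.08) * sin(pi / 4))

  coords <- matrix(0, 0, 3)
  name <- character(); element <- character(); role <- character()
  add <- function(p2, el, nm, rl) {
    coords <<- rbind(coords, cbind(p2, 0))
    element <<- c(element, rep(el, nrow(p2)))
    name <<- c(name, nm); role <<- c(role, rep(rl, nrow(p2)))
  }
  add(matrix(0, 1, 2), metal_element, toupper(metal_element), "metal")
  for (k in 0:3) add(rot90(N_loc, k), "N", paste0("N", k + 1), "ring_N")
  for (k in 0:3) add(rot90(CA_loc, k), "C",
                     paste0("CA", 2 * k + 1:2), "ring_C_alpha")
  for (k in 0:3) add(rot90(CB_loc, k), "C",
                     paste0("CB", 2 * k + 1:2), "ring_C_beta")
  for (k in 0:3) add(rot90(CM_loc, k), "C", paste0("CM", k + 1), "ring_C_meso")
  for (k in 0:3) add(rot90(HB_loc, k), "H", paste0("HB", 2 * k + 1:2), "ring_H")
  for (k in 0:3) add(rot90(HM_loc, k), "H", paste0("HM", k + 1), "ring_H")

  atoms <- data.frame(element = element, name = name, role = role,
                      stringsAsFactors = FALSE)
  atoms$polarity_class <- ifelse(atoms$element %in% c("N", "O") |
                                   atoms$role == "metal",
                                 "hydrophilic", "hydrophobic")
  iN <- which(role == "ring_N"); iM <- which(role == "metal")
  torsions <- list(list(ids = iN, label = "proper", name = "N-N-N-N"))
  for (k in 0:3) {
    ica <- which(name %in% paste0("CA", 2 * k + 1:2))
    torsions[[length(torsions) + 1L]] <-
      list(ids = c(iM, ica[1], ica[2], iN[k + 1]), label = "improper",
           name = paste0("M-CA-CA-N", k + 1))
  }
  dimnames(coords) <- NULL
  top <- topology(atoms, torsions)
  validate_macrocycle(top)
  structure(list(topology = top, coords = coords), class = "scaffold")
}

# O-H 0.957 A, H-O-H 104.5 deg; orientation "random" or "away" (hydrogen
# bisector pointing away from `away_from`, emulating metal-repelled
# hydrogens), azimuth always randomised.
place_water_hydrogens <- function(O, orientation = "random", away_from = NULL) {
  roh <- 0.957; half <- 104.5 / 2 * pi / 180
  if (orientation == "away" && !is.null(away_from)) {
    bis <- O - away_from
    bis <- bis / sqrt(sum(bis^2))
  } else {
    bis <- rnorm(3); bis <- bis / sqrt(sum(bis^2))
  }
  # orthonormal frame around the bisector, random azimuth
  ref <- if (abs(bis[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- ref - sum(ref * bis) * bis; e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(bis[2] * e1[3] - bis[3] * e1[2],
          bis[3] * e1[1] - bis[1] * e1[3],
          bis[1] * e1[2] - bis[2] * e1[1])
  phi <- runif(1, 0, 2 * pi)
  u <- cos(phi) * e1 + sin(phi) * e2
  rbind(O + roh * (cos(half) * bis + sin(half) * u),
        O + roh * (cos(half) * bis - sin(half) * u))
}

#' Single-frame hydrated-scaffold snapshot with exact shell occupancies
#'
#' Places exactly `occupancy[s]` water oxygens in each radial shell around
#' the metal, then `n_bulk` waters uniformly in the box outside the
#' outermost shell, with a hard minimum O-O separation of `min_OO`.
#' First-shell waters are placed axially (along +-z, the scaffold plane
#' normal) when `axial = TRUE` and the occupancy is 1 or 2 — emulating the
#' square-pyramidal / octahedral coordination observed for hydrated
#' cobalt porphyrins; otherwise directions are drawn uniformly.
#'
#' @param scaffold from [generate_porphyrin_scaffold()]
#' @param shellspec [shell_spec()]
#' @param n_bulk bulk water count outside the last shell
#' @param box_length cubic box edge (required if `n_bulk > 0`); the
#'   scaffold is centred in the box
#' @param seed RNG seed
#' @param axial axial placement of 1-2 first-shell waters
#' @param orientation water hydrogen mode: `"away"` (from the metal) or
#'   `"random"`
#' @param min_OO minimum O-O separation, angstrom
#' @param max_tries placement retries per water before a packing error
#' @return one-frame [trajectory()]; waters carry roles
#'   `water_O`/`water_H`
#' @export
generate_shell_snapshot <- function(scaffold, shellspec, n_bulk = 0,
                                    box_length = NULL, seed = 1L,
                                    axial = TRUE,
                                    orientation = c("away", "random"),
                                    min_OO = 2.4, max_tries = 2000L) {
  orientation <- match.arg(orientation)
  k <- length(shellspec$r_lo)
  if (!is.null(box_length) && max(shellspec$r_hi) > box_length / 2)
    stop("shells must fit inside half the box")
  if (n_bulk > 0 && is.null(box_length))
    stop("bulk waters require a box_length")
  with_seed(seed, {
    centre <- if (is.null(box_length)) c(0, 0, 0) else rep(box_length / 2, 3)
    sc <- sweep(scaffold$coords, 2, centre, `+`)
    metal <- sc[which(scaffold$topology$atoms$role == "metal")[1], ]
    O <- matrix(0, 0, 3)
    place <- function(radial_fun, n, label) {
      placed <- 0L
      while (placed < n) {
        ok <- FALSE
        for (t in seq_len(max_tries)) {
          p <- radial_fun()
          if (nrow(O) == 0 || min(sqrt(rowSums(sweep(O, 2, p)^2))) >= min_OO) {
            O <<- rbind(O, p); ok <- TRUE; break
          }
        }
        if (!ok) stop("packing error: cannot place ", label,
                      " water without O-O overlap")
        placed <- placed + 1L
      }
    }
    for (s in seq_len(k)) {
      n_s <- shellspec$occupancy[s]
      if (n_s == 0) next
      mid <- (shellspec$r_lo[s] + shellspec$r_hi[s]) / 2
      ax_dirs <- rbind(c(0, 0, 1), c(0, 0, -1))
      i_s <- 0L
      rad <- function() {
        i_s <<- i_s + 1L
        u <- if (axial && s == 1L && n_s <= 2L) ax_dirs[i_s, ]
             else { v <- rnorm(3); v / sqrt(sum(v^2)) }
        r <- min(max(mid + rnorm(1, 0, shellspec$jitter),
                     shellspec$r_lo[s] + 1e-6), shellspec$r_hi[s] - 1e-6)
        metal + r * u
      }
      place(rad, n_s, paste0("shell-", s))
    }
    if (n_bulk > 0) {
      r_out <- max(shellspec$r_hi)
      bulk <- function() {
        repeat {
          p <- runif(3, 0, box_length)
          d <- p - metal
          d <- d - box_length * floor(d / box_length + 0.5)
          if (sqrt(sum(d^2)) > r_out) return(p)
        }
      }
      place(bulk, n_bulk, "bulk")
    }
    nw <- nrow(O)
    wat_coords <- matrix(0, 3 * nw, 3)
    for (i in seq_len(nw)) {
      wat_coords[3 * i - 2, ] <- O[i, ]
      wat_coords[3 * i - c(1, 0), ] <-
        place_water_hydrogens(O[i, ], orientation, metal)
    }
    a <- scaffold$topology$atoms
    nsc <- nrow(a)
    wa <- data.frame(element = rep(c("O", "H", "H"), nw),
                     name = paste0(rep(c("OW", "HW1", "HW2"), nw),
                                   rep(seq_len(nw), each = 3)),
                     role = rep(c("water_O", "water_H", "water_H"), nw),
                     polarity_class = rep("hydrophilic", 3 * nw),
                     stringsAsFactors = FALSE)
    atoms <- rbind(cbind(a[c("element", "name", "role", "polarity_class")]),
                   wa)
    top <- topology(atoms, scaffold$topology$torsions)
    wp <- rep(NA_integer_, nrow(atoms))
    if (nw > 0) {
      oidx <- nsc + 3 * seq_len(nw) - 2
      wp[oidx + 1] <- oidx; wp[oidx + 2] <- oidx
    }
    top$atoms$water_parent <- wp
    validate_macrocycle(top)
    coords <- array(0, c(1, nrow(atoms), 3))
    coords[1, , ] <- rbind(sc, wat_coords)
    trajectory(coords, dt = 1, box_length = box_length, topology = top)
  })
}

#' Shell-exchange trajectory with an exact event log
#'
#' Ligand waters (represented by their oxygens) hop between the shells of
#' `shellspec` as a continuous-time Markov jump process with per-ligand
#' leave rate `exchangespec$rate`; an interior shell's successor is drawn
#' uniformly from its neighbours.  The jump process is generated first, in
#' shell-index space, and only then embedded in 3D (each ligand keeps a
#' fixed random direction from the metal; its radius is the occupied
#' shell's midpoint plus clamped Gaussian jitter), so the true crossing
#' times, dwell times and per-frame shell indices are exact by
#' construction and independent of any geometry code.
#'
#' @param scaffold from [generate_porphyrin_scaffold()]
#' @param exchangespec [exchange_spec()]
#' @param shellspec [shell_spec()] with >= 2 shells
#' @param axial_pair give the first two ligands the axial directions
#'   (+z/-z, perpendicular to the macrocycle plane) instead of random
#'   ones, so that first-shell occupancy mimics axial coordination
#' @return list with `trajectory` (non-periodic), `events` (data.frame:
#'   `ligand`, `time` ps, `from`, `to` shell indices, `dwell` ps spent in
#'   `to` after the crossing, `censored`), `shell_index`
#'   (`n_frames x n_ligands` ground-truth matrix, shells numbered from 1
#'   innermost) and `ligand_atoms` (atom indices of the ligand oxygens)
#' @export
generate_exchange_trajectory <- function(scaffold, exchangespec, shellspec,
                                         axial_pair = FALSE) {
  k <- length(shellspec$r_lo)
  if (k < 2) stop("exchange generation needs >= 2 shells")
  es <- exchangespec
  nfr <- floor(es$duration / es$dt) + 1L
  tgrid <- (seq_len(nfr) - 1L) * es$dt
  with_seed(es$seed, {
    events <- list()
    shell_idx <- matrix(NA_integer_, nfr, es$n_ligands)
    radii <- matrix(NA_real_, nfr, es$n_ligands)
    mid <- (shellspec$r_lo + shellspec$r_hi) / 2
    dirs <- matrix(rnorm(3 * es$n_ligands), ncol = 3)
    dirs <- dirs / sqrt(rowSums(dirs^2))
    if (axial_pair && es$n_ligands >= 2)
      dirs[1:2, ] <- rbind(c(0, 0, 1), c(0, 0, -1))
    for (l in seq_len(es$n_ligands)) {
      s <- ((l - 1L) %% k) + 1L        # balanced initial shells
      t <- 0
      path_t <- 0; path_s <- s
      if (es$rate > 0) {
        repeat {
          t <- t + rexp(1, es$rate)
          if (t > es$duration) break
          s_new <- if (s == 1L) 2L else if (s == k) k - 1L
                   else s + sample(c(-1L, 1L), 1L)
          events[[length(events) + 1L]] <-
            data.frame(ligand = l, time = t, from = s, to = s_new)
          s <- s_new
          path_t <- c(path_t, t); path_s <- c(path_s, s)
        }
      }
      shell_idx[, l] <- path_s[findInterval(tgrid, path_t)]
      lo <- shellspec$r_lo[shell_idx[, l]]; hi <- shellspec$r_hi[shell_idx[, l]]
      radii[, l] <- pmin(pmax(mid[shell_idx[, l]] +
                                rnorm(nfr, 0, shellspec$jitter),
                              lo + 1e-6), hi - 1e-6)
    }
    events <- if (length(events)) do.call(rbind, events)
              else data.frame(ligand = integer(), time = numeric(),
                              from = integer(), to = integer())
    events <- events[order(events$time), , drop = FALSE]
    rownames(events) <- NULL
    # post-crossing dwell: time spent in `to` before that ligand's next jump
    events$dwell <- rep(NA_real_, nrow(events))
    events$censored <- rep(FALSE, nrow(events))
    if (nrow(events)) {
      for (l in unique(events$ligand)) {
        i <- which(events$ligand == l)
        tt <- events$time[i]
        events$dwell[i] <- c(diff(tt), es$duration - tt[length(tt)])
        events$censored[i[length(i)]] <- TRUE
      }
    }
    a <- scaffold$topology$atoms
    nsc <- nrow(a)
    wa <- data.frame(element = "O", name = paste0("OW", seq_len(es$n_ligands)),
                     role = "water_O", polarity_class = "hydrophilic",
                     stringsAsFactors = FALSE)
    top <- topology(rbind(a[c("element", "name", "role", "polarity_class")], wa),
                    scaffold$topology$torsions)
    validate_macrocycle(top)
    coords <- array(0, c(nfr, nsc + es$n_ligands, 3))
    for (i in seq_len(nfr)) coords[i, seq_len(nsc), ] <- scaffold$coords
    for (l in seq_len(es$n_ligands))
      for (c3 in 1:3)
        coords[, nsc + l, c3] <- radii[, l] * dirs[l, c3]
    list(trajectory = trajectory(coords, dt = es$dt, topology = top),
         events = events, shell_index = shell_idx,
         ligand_atoms = nsc + seq_len(es$n_ligands))
  })
}

#' Harmonic-oscillator trajectory with exact velocities
#'
#' One atom per entry of `freq`, oscillating along x with analytic
#' phase-space propagation (no integrator error): `x = A cos(w t + phi)`,
#' `v = -A w sin(w t + phi)` with `w = 2 pi c freq` and thermal amplitude
#' `A = sqrt(2 kB T / m) / w` (so the time-averaged kinetic energy matches
#' equipartition at temperature `T`).  A quadrature pair — two atoms at the
#' same frequency with phases 0 and -pi/2 — has an exactly cosine velocity
#' autocorrelation regardless of time origin.
#'
#' @param freq wavenumber(s), cm^-1 (one oscillator per entry)
#' @param mass amu (recycled)
#' @param temperature K; 0 gives an at-rest trajectory
#' @param dt sampling step, ps; must satisfy `dt < 1/(10 c max(freq))`
#' @param n_frames frames to generate
#' @param seed RNG seed (phases); ignored when `phases` given
#' @param phases optional explicit phases, radians
#' @return [trajectory()] with velocities
#' @export
generate_oscillator_trajectory <- function(freq, mass = 1, temperature = 298.15,
                                           dt = 1e-3, n_frames = 1000L,
                                           seed = 1L, phases = NULL) {
  n <- length(freq)
  mass <- rep_len(mass, n)
  nyq <- 1 / (10 * C_LIGHT_CM_PS * max(freq))
  if (dt >= nyq)
    stop("dt = ", dt, " ps undersamples the oscillation; Nyquist-safe ",
         "limit here is dt < ", signif(nyq, 3), " ps")
  ph <- if (!is.null(phases)) rep_len(phases, n)
        else with_seed(seed, runif(n, 0, 2 * pi))
  omega <- 2 * pi * C_LIGHT_CM_PS * freq            # rad/ps
  A <- if (temperature > 0)
    sqrt(2 * KB_AMU_A2_PS2 * temperature / mass) / omega else rep(0, n)
  tgrid <- (seq_len(n_frames) - 1L) * dt
  coords <- array(0, c(n_frames, n, 3))
  vel <- array(0, c(n_frames, n, 3))
  for (j in seq_len(n)) {
    coords[, j, 1] <- A[j] * cos(omega[j] * tgrid + ph[j])
    vel[, j, 1] <- -A[j] * omega[j] * sin(omega[j] * tgrid + ph[j])
  }
  top <- topology(data.frame(element = rep("X", n),
                             name = paste0("X", seq_len(n)),
                             role = "other", stringsAsFactors = FALSE))
  top$atoms$vdw_radius <- rep(1.5, n)
  trajectory(coords, dt = dt, velocities = vel, topology = top)
}

#' Rigid-body (optionally jittered) trajectory of a scaffold
#'
#' Every frame is a uniformly random proper rotation plus translation of
#' frame 1 (the scaffold as given); with `jitter_sd > 0`, isotropic
#' Gaussian displacements are added after the rigid motion.  The
#' jitter-free version is the null model for RMSF (zero after alignment);
#' the jittered version has closed-form expected RMSF `jitter_sd * sqrt(3)`.
#'
#' @param scaffold from [generate_porphyrin_scaffold()]
#' @param n_frames frames
#' @param seed RNG seed
#' @param jitter_sd per-component Gaussian displacement, angstrom
#' @param max_translation uniform translation half-range, angstrom
#' @return [trajectory()]
#' @export
generate_rigid_body_trajectory <- function(scaffold, n_frames, seed = 1L,
                                           jitter_sd = 0, max_translation = 3) {
  X0 <- scaffold$coords
  na <- nrow(X0)
  with_seed(seed, {
    coords <- array(0, c(n_frames, na, 3))
    coords[1, , ] <- X0
    for (i in seq(2, length.out = n_frames - 1L)) {
      R <- random_rotation_matrix()
      tr <- runif(3, -max_translation, max_translation)
      coords[i, , ] <- sweep(X0 %*% t(R), 2, tr, `+`)
    }
    if (jitter_sd > 0)
      coords <- coords + array(rnorm(length(coords), 0, jitter_sd), dim(coords))
    trajectory(coords, dt = 1, topology = scaffold$topology)
  })
}

#' Ideal-gas box: i.i.d. uniform positions every frame
#'
#' The null model for pair-correlation normalisation: g(r) = 1 at all r,
#' and the coordination integral to `r_c` is `(4/3) pi r_c^3 rho (n-1)/n`.
#'
#' @param n_atoms atoms per frame (>= 2)
#' @param box_length cubic box edge, angstrom
#' @param n_frames frames
#' @param seed RNG seed
#' @return periodic [trajectory()] (element `Ar`, role `other`)
#' @export
generate_ideal_gas_box <- function(n_atoms, box_length, n_frames, seed = 1L) {
  if (n_atoms < 2) stop("n_atoms must be >= 2")
  with_seed(seed, {
    coords <- array(runif(n_frames * n_atoms * 3, 0, box_length),
                    c(n_frames, n_atoms, 3))
    top <- topology(data.frame(element = rep("Ar", n_atoms),
                               name = paste0("AR", seq_len(n_atoms)),
                               role = "other", stringsAsFactors = FALSE))
    trajectory(coords, dt = 1, box_length = box_length, topology = top)
  })
}
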