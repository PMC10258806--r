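## One-command end-to-end hydration analysis with a machine-readable report.

.default_params <- function() list(
  r_max = NA_real_,          # default: box/2 (periodic) or 8 A
  dr = 0.05,                 # RDF bin, A
  n_shells = 1L,
  smoothing_window = 5L,
  adf_bin = 2,               # degrees
  h_bond_cutoff = 2.5,       # N...Hw distance criterion, A
  t_star = c(0, 0.5),        # ps
  correlation_length = 2.0,  # ps
  n_origins = 5000L,
  temperature = 298.15,      # K
  probe_radius = 1.4,        # A
  n_sphere_points = 960L,
  torsion_bin = 5,           # degrees
  ard_dr = 0.1, ard_dtheta = 2,
  sdf_spacing = 0.5, sdf_extent = 8,
  density = NA_real_         # reference density for non-periodic input
)

#' Validate and complete an analysis configuration
#'
#' Accepts a YAML file path or a list.  Recognised top-level keys:
#' `input_xyz`, `topology_pdb`, `dt` (ps), `box_length` (A), `seed`,
#' `output_dir`, and `params` (any of the per-analysis parameters: `r_max`,
#' `dr`, `n_shells`, `smoothing_window`, `adf_bin`, `h_bond_cutoff`,
#' `t_star`, `correlation_length`, `n_origins`, `temperature`,
#' `probe_radius`, `n_sphere_points`, `torsion_bin`, `ard_dr`,
#' `ard_dtheta`, `sdf_spacing`, `sdf_extent`, `density`).  Unknown keys are
#' an error, never silently ignored.  Missing parameters receive the
#' package defaults (0.05 A pair bins, t* of 0.0 and 0.5 ps, 2.0 ps
#' correlation length with 5000 origins, 298.15 K, 1.4 A probe).
#'
#' @param config path to a YAML file, or a list
#' @return validated config of class `analysis_config`
#' @export
validate_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a list or a YAML file path")
  top_keys <- c("input_xyz", "topology_pdb", "dt", "box_length", "seed",
                "output_dir", "params")
  unknown <- setdiff(names(config), top_keys)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  defaults <- .default_params()
  params <- config$params %||% list()
  unknown <- setdiff(names(params), names(defaults))
  if (length(unknown))
    stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
  params <- utils::modifyList(defaults, params)
  for (k in c("dr", "adf_bin", "h_bond_cutoff", "correlation_length",
              "temperature", "probe_radius", "torsion_bin", "ard_dr",
              "ard_dtheta", "sdf_spacing", "sdf_extent"))
    if (!is.na(params[[k]]) && params[[k]] <= 0)
      stop("parameter ", k, " must be positive (got ", params[[k]], ")")
  if (any(params$t_star < 0)) stop("t_star values must be >= 0")
  if (!is.null(config$input_xyz) && !file.exists(config$input_xyz))
    stop("input trajectory not found: ", config$input_xyz)
  if (!is.null(config$topology_pdb) && !file.exists(config$topology_pdb))
    stop("topology PDB not found: ", config$topology_pdb)
  config$params <- params
  config$dt <- config$dt %||% 1
  config$seed <- config$seed %||% 1L
  config$output_dir <- config$output_dir %||% "solvshell_out"
  structure(config, class = "analysis_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full hydration-analysis battery
#'
#' Executes, in order: metal-water RDF with coordination integration;
#' shell-boundary detection; ADF and coordination-number distributions;
#' N-Hw hydrogen-bond CND; solute alignment, RMSF and torsional
#' distributions; SDF and ARD maps; shell-occupancy series with
#' direct-method residence statistics; VACF and power spectrum; PMF; and
#' time-averaged SASA.  Every stage logs the parameters it used; each
#' output file is recorded in the manifest; a stage failure aborts with
#' the stage name (outputs written so far are kept).  When no shell
#' structure is detectable (e.g. an ideal gas), the report flags it and
#' the shell-dependent stages are skipped.
#'
#' @param config see [validate_config()]
#' @param traj optional in-memory [trajectory()] (overrides `input_xyz`)
#' @param quiet suppress progress messages
#' @return object of class `analysis_report`: list with `manifest`,
#'   `summary`, `flags`, `provenance`; also written as `report.json` in
#'   the output directory
#' @export
run_full_analysis <- function(config, traj = NULL, quiet = FALSE) {
  cfg <- validate_config(config)
  p <- cfg$params
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message("[solvshell] ", ...)
  manifest <- character()
  summary <- list()
  flags <- list()
  emit <- function(df, name) {
    path <- file.path(cfg$output_dir, name)
    utils::write.table(df, path, sep = "\t", row.names = FALSE,
                       quote = FALSE)
    manifest <<- c(manifest, path)
    path
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  if (is.null(traj)) {
    stage("input", {
      if (is.null(cfg$input_xyz)) stop("no trajectory given")
      traj <- read_xyz_trajectory(cfg$input_xyz, dt = cfg$dt,
                                  box_length = cfg$box_length)
      if (!is.null(cfg$topology_pdb)) {
        top <- assign_roles(read_pdb_topology(cfg$topology_pdb))
        if (nrow(top$atoms) != n_atoms(traj))
          stop("topology/trajectory atom count mismatch")
        traj$topology <- top
      }
    })
  }
  top <- traj$topology
  has_macro <- sum(top$atoms$role == "metal") == 1 &&
    sum(top$atoms$role == "ring_N") == 4
  has_water <- any(top$atoms$role == "water_O")
  r_max <- if (!is.na(p$r_max)) p$r_max
           else if (!is.null(traj$box_length)) traj$box_length / 2 else 8
  center <- if (has_macro) "metal" else seq_len(n_atoms(traj))
  target <- if (has_water) "water_O" else "other"

  say("rdf: r_max = ", r_max, " A, dr = ", p$dr, " A")
  rdf <- stage("rdf", compute_rdf(traj, center, target, r_max, p$dr,
                                  density = if (is.na(p$density)) NULL
                                            else p$density))
  emit(data.frame(r = rdf$r, g = rdf$g, n = rdf$cn), "rdf.tsv")

  part <- tryCatch(
    detect_shell_boundaries(rdf, p$smoothing_window, p$n_shells),
    error = function(e) NULL)
  if (is.null(part)) {
    flags$no_shell_structure <- TRUE
    say("shells: no shell structure detected")
  } else {
    summary$shell_boundaries <- part$boundaries
    summary$shell_minimum_zero <- part$zero_minimum
    summary$cn_first_shell <-
      integrate_coordination(rdf, part$boundaries[1])
    say("shells: boundaries at ",
        paste(signif(part$boundaries, 4), collapse = ", "), " A")
  }

  if (!is.null(part) && has_macro) {
    r_cut <- part$boundaries[1]
    say("adf/cnd: r_cut = ", signif(r_cut, 4), " A")
    adf <- stage("adf", compute_adf(traj, "metal", c("ring_N", "water_O"),
                                    r_cut, p$adf_bin))
    emit(adf, "adf.tsv")
    pk <- adf$theta[adf$freq > 0.25 * max(adf$freq)]
    summary$adf_peak_angles <- range(pk)
    cnd <- stage("cnd", compute_cnd(traj, "metal", c("ring_N", "water_O"),
                                    r_cut))
    emit(cnd, "cnd.tsv")
    summary$cn_distribution_mean <- attr(cnd, "mean")
  }

  if (has_macro && any(top$atoms$role == "water_H")) {
    nh <- stage("nh_cnd", compute_nh_cnd(traj, p$h_bond_cutoff))
    emit(nh, "nh_cnd.tsv")
    summary$nh_cnd_p0 <- nh$p[nh$cn == 0]
  }

  if (has_macro && n_frames(traj) > 1) {
    say("align/rmsf/torsions")
    ali <- stage("align", kabsch_align(traj))
    rmsf <- stage("rmsf", compute_rmsf(ali))
    emit(rmsf, "rmsf.tsv")
    summary$rmsf_mean <- mean(rmsf$rmsf)
    if (length(top$torsions)) {
      tor <- stage("torsions", torsion_distribution(ali,
                                                    bin_width = p$torsion_bin))
      emit(tor, "torsions.tsv")
      summary$torsion_circular_mean <- attr(tor, "circular_mean")
    }
    if (has_water) {
      ard <- stage("ard", compute_ard(ali, "water_O", r_max,
                                      p$ard_dr, p$ard_dtheta))
      ardf <- data.frame(
        r = rep((ard$r_edges[-1] + head(ard$r_edges, -1)) / 2,
                times = ncol(ard$density)),
        theta = rep((ard$theta_edges[-1] + head(ard$theta_edges, -1)) / 2,
                    each = nrow(ard$density)),
        density = as.vector(ard$density))
      emit(ardf, "ard.tsv")
      ext <- p$sdf_extent
      mi <- which(top$atoms$role == "metal")[1]
      m0 <- frame_coords(ali, 1L)[mi, ]
      sdf <- stage("sdf", compute_sdf(ali, "water_O", m0 - ext,
                                      p$sdf_spacing,
                                      rep(ceiling(2 * ext / p$sdf_spacing),
                                          3)))
      path <- file.path(cfg$output_dir, "sdf.dx")
      write_sdf_dx(sdf, path)
      manifest <- c(manifest, path)
    }
  }

  if (!is.null(part) && has_water && n_frames(traj) > 1) {
    say("occupancy/mrt: t* = ", paste(p$t_star, collapse = ", "), " ps")
    ser <- stage("occupancy", shell_occupancy_series(traj, center,
                                                     "water_O", part))
    rs <- stage("mrt", residence_stats(ser, 1L, p$t_star))
    summary$residence <- list(
      CN = rs$CN, t_sim = rs$t_sim, t_star = rs$t_star, N_ex = rs$N_ex,
      tau = vapply(rs$tau, function(x) as.numeric(x), numeric(1)),
      R_ex = as.numeric(rs$R_ex), sustainability = rs$sustainability)
    dser <- stage("distances", distance_series(traj, center, "water_O",
                                               part))
    emit(dser, "distances.tsv")
  }

  nlag_ok <- n_frames(traj) > floor(p$correlation_length / traj$dt) + 1
  if (n_frames(traj) >= 3 && nlag_ok) {
    say("vacf/spectrum: correlation length ", p$correlation_length,
        " ps, up to ", p$n_origins, " origins")
    max_orig <- n_frames(traj) - floor(p$correlation_length / traj$dt)
    vac <- stage("vacf", compute_vacf(traj,
                                      correlation_length =
                                        p$correlation_length,
                                      n_origins = min(p$n_origins,
                                                      max_orig)))
    spec <- stage("spectrum", power_spectrum(vac))
    emit(spec, "spectrum.tsv")
    pks <- spectrum_peaks(spec)
    summary$spectrum_peaks <- utils::head(pks$nu, 5)
  }

  say("pmf: T = ", p$temperature, " K")
  pmf <- stage("pmf", pmf_from_rdf(rdf, p$temperature, part))
  emit(pmf, "pmf.tsv")
  if (!is.null(attr(pmf, "wells")))
    summary$pmf_wells <- attr(pmf, "wells")

  say("sasa: probe ", p$probe_radius, " A, ", p$n_sphere_points, " points")
  sas <- stage("sasa", time_averaged_sasa(traj, top,
                                          stride = max(1L,
                                            n_frames(traj) %/% 20L),
                                          probe_radius = p$probe_radius,
                                          n_points = p$n_sphere_points))
  summary$sasa <- list(hydrophobic = sas$hydrophobic,
                       hydrophilic = sas$hydrophilic, total = sas$total)

  provenance <- list(
    package_version = as.character(utils::packageVersion("solvshell")),
    seed = cfg$seed,
    config_hash = sum(utf8ToInt(paste(deparse(unclass(cfg)[
      setdiff(names(cfg), "output_dir")]), collapse = ""))))
  report <- structure(list(manifest = manifest, summary = summary,
                           flags = flags, provenance = provenance),
                      class = "analysis_report")
  jsonlite::write_json(
    list(manifest = basename(manifest), summary = summary, flags = flags,
         provenance = provenance),
    file.path(cfg$output_dir, "report.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE, force = TRUE)
  report
}
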