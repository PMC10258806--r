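# solvshell

Hydration-shell structure and dynamics analysis for metal-centred
macrocycles (metalloporphyrins and related solutes) in explicit-water MD
trajectories.

## The problem

A metal ion chelated in a porphyrin ring is coordinatively unsaturated:
water binds axially, perpendicular to the ring plane, and whether one or
two axial waters bind — and how labile they are — distinguishes
square-pyramidal (5-fold) from octahedral (6-fold) hydration complexes
and stable from fragile ones.  Characterising this from an MD trajectory
requires a battery of estimators that is tedious to reimplement and easy
to get subtly wrong (bin conventions, minimum-image tie-breaks,
persistence counting, transform normalisation).  `solvshell` packages the
whole battery for R users, with every estimator backed by a
parameter-recovery test against synthetic trajectories whose ground truth
is exact by construction.

The core quantities:

* **g(r)** and the running coordination number
  `n(r) = ∫ 4πr'²ρ g(r') dr'`, with shell-boundary detection and the
  zero/nonzero first-minimum stability diagnostic;
* **ADF / CND** — ligand–metal–ligand angle distributions (octahedral
  complexes show ~90°/~180° peaks) and per-frame coordination-number
  distributions;
* **SDF / ARD** — 3D solvent density in the solute-fixed frame (Kabsch
  alignment) and the distance–angle map about the ring normal;
* **direct-method residence times** `τ = CN·t_sim/N_ex`, where `N_ex`
  counts shell departures persisting longer than t\* (0.0 and 0.5 ps by
  default), plus `R_ex = N_ex^0.0/N_ex^0.5`;
* **vibrational power spectra** — cosine transform of the velocity
  autocorrelation `C(t) = ⟨Σ_j v_j(t_i)·v_j(t_i+t)⟩`;
* **PMF** `w(r) = −RT ln g(r)`;
* **Shrake–Rupley SASA** with hydrophobic/hydrophilic decomposition;
* **RMSF** and proper/improper **torsional distributions** of the ring.

See the vignette (`vignettes/hydration-analysis.Rmd`) for the methods in
full, including every numerical convention.

## Worked example

```r
library(solvshell)

# An idealised cobalt-porphine scaffold with two axial waters
sc   <- generate_porphyrin_scaffold(1.98)
snap <- generate_shell_snapshot(sc, shell_spec(1.93, 2.67, 2L), seed = 7)

rdf <- compute_rdf(snap, "metal", "water_O", r_max = 6, dr = 0.05,
                   density = 0.033)
integrate_coordination(rdf, 2.67)
#> [1] 2
```

Two waters inside the 1.93–2.67 Å first-shell window: with the four
pyrrole nitrogens this is the octahedral, 6-coordinate complex.

```r
# 20 ligands hopping between two shells with exponential dwells (mean 0.5 ps)
ex  <- generate_exchange_trajectory(
  sc, exchange_spec(rate = 2, n_ligands = 20, duration = 50, dt = 0.01,
                    seed = 7),
  shell_spec(c(1.93, 2.67), c(2.67, 5.2), jitter = 0.08))
ser <- shell_occupancy_series(ex$trajectory, "metal", "water_O",
                              c(2.67, 5.2))
residence_stats(ser, 1)
#> <residence_stats> CN = 9.988, t_sim = 50 ps
#>   t* = 0.00 ps: N_ex = 966, tau = 0.517 ps
#>   t* = 0.50 ps: N_ex = 354, tau = 1.411 ps
#>   R_ex = 2.729, sustainability = 0.3665
```

The direct method recovers the true 0.5 ps dwell time at t\* = 0 within
sampling error; `R_ex ≈ 2.7` says nearly three crossing attempts occur
per exchange that persists beyond 0.5 ps.

```r
# Vibrational line recovery at the default spectral settings
osc  <- generate_oscillator_trajectory(c(1000, 1000), dt = 1e-3,
                                       n_frames = 7001,
                                       phases = c(0, -pi / 2))
vac  <- compute_vacf(osc, 1:2, correlation_length = 2.0, n_origins = 5000)
head(spectrum_peaks(power_spectrum(vac)), 1)
#>         nu intensity
#> 1 1000.192 0.9996575

compute_sasa(sc$coords, sc$topology)
#> <sasa> total 4.968 nm^2 (hydrophobic 4.702, hydrophilic 0.266);
#>        probe 1.40 A, 960 points
```

The 1000 cm⁻¹ oscillator is located well within one resolution element
(16.7 cm⁻¹ at a 2.0 ps correlation length), and the porphine surface is
overwhelmingly hydrophobic — the nitrogens and metal are buried in the
ring core, which is why metal insertion suppresses the ring's
hydrogen-bonding with water.

The one-command pipeline runs the full battery and writes tab-separated
curves, an OpenDX density grid and a JSON report:

```r
run_full_analysis(list(input_xyz = "traj.xyz", topology_pdb = "system.pdb",
                       dt = 0.002, box_length = 39.28,
                       output_dir = "out"))
```

A thin CLI wrapper lives at `inst/cli/solvshell`
(`solvshell run -c config.yml`, `solvshell synth ...`).

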