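#' System state
#'
#' Positions and velocities of every bead in a cubic periodic box. Positions
#' are in nm and wrapped into `[0, box_edge)^3` at output; all pair distances
#' use the minimum-image convention. Velocities are stored in internal units
#' (nm per internal time unit of 488.8821 fs; the natural unit of the
#' nm / kcal mol^-1 / amu system).
#'
#' @param positions N x 3 matrix (nm).
#' @param box_edge Cubic box edge (nm).
#' @param velocities N x 3 matrix, or `NULL` for zero velocities.
#' @param time_fs Elapsed simulation time (fs).
#' @return A `cooke_state` object.
#' @export
new_system_state <- function(positions, box_edge, velocities = NULL,
                             time_fs = 0) {
  positions <- as.matrix(positions)
  stopifnot(ncol(positions) == 3, box_edge > 0)
  if (is.null(velocities)) velocities <- matrix(0, nrow(positions), 3)
  st <- list(positions = wrap_positions(positions, box_edge),
             velocities = as.matrix(velocities),
             box_edge = box_edge, time_fs = time_fs)
  class(st) <- "cooke_state"
  st
}

wrap_positions <- function(pos, box) {
  pos - box * floor(pos / box)
}

#' @export
print.cooke_state <- function(x, ...) {
  cat(sprintf("Cooke state: %d beads, box edge %.3f nm, t = %.3g ns\n",
              nrow(x$positions), x$box_edge, x$time_fs / 1e6))
  invisible(x)
}

#' Engine configuration
#'
#' Langevin NVT settings. Production defaults: 10 fs time step, friction
#' 1 ps^-1, 310 K, uniform bead mass 100 amu (equilibrium NVT statistics are
#' mass-independent), neighbor-list skin 0.3 nm.
#'
#' @param timestep_fs Integration time step (fs).
#' @param friction_ps Langevin friction (ps^-1); 0 disables the thermostat
#'   (microcanonical velocity-Verlet limit).
#' @param temperature_K Thermostat temperature (K).
#' @param seed Integer seed; same seed gives a bit-identical trajectory.
#' @param skin_nm Verlet-list skin (nm); the pair list is rebuilt when any
#'   bead has moved more than `skin_nm / 2` since the last build.
#' @param snapshot_every Steps between stored snapshots.
#' @param mass_amu Uniform bead mass (amu).
#' @return An `engine_config` object.
#' @export
engine_config <- function(timestep_fs = 10, friction_ps = 1,
                          temperature_K = 310, seed = 1,
                          skin_nm = 0.3, snapshot_every = 1e5,
                          mass_amu = 100) {
  stopifnot(timestep_fs > 0, friction_ps >= 0, temperature_K > 0,
            skin_nm > 0, mass_amu > 0)
  cfg <- list(timestep_fs = timestep_fs, friction_ps = friction_ps,
              temperature_K = temperature_K, seed = as.integer(seed),
              skin_nm = skin_nm, snapshot_every = as.integer(snapshot_every),
              mass_amu = mass_amu)
  class(cfg) <- "engine_config"
  cfg
}

#' Draw Maxwell-Boltzmann velocities
#'
#' Each velocity component is Gaussian with variance `kT/m` (internal
#' units). Uses R's RNG; call `set.seed()` first for reproducibility.
#'
#' @param n Number of beads.
#' @param temperature_K Temperature (K).
#' @param mass_amu Bead mass (amu).
#' @return N x 3 matrix of velocities (internal units).
#' @export
maxwell_velocities <- function(n, temperature_K = 310, mass_amu = 100) {
  sd <- sqrt(.kB_kcal * temperature_K / mass_amu)
  matrix(stats::rnorm(3 * n, sd = sd), ncol = 3)
}

#' Kinetic temperature of a state
#'
#' From equipartition: \eqn{T = 2 KE / (3 N k_B)}.
#'
#' @param state `cooke_state`.
#' @param mass_amu Uniform bead mass (amu).
#' @return Temperature (K).
#' @export
kinetic_temperature <- function(state, mass_amu = 100) {
  ke <- 0.5 * mass_amu * sum(state$velocities^2)
  2 * ke / (3 * nrow(state$positions) * .kB_kcal)
}

#' Energy minimization
#'
#' Steepest descent with backtracking and a per-bead displacement cap;
#' intended to relax the residual overlaps of a freshly packed random
#' configuration before dynamics. The FENE divergence is replaced by a
#' linear continuation during minimization so arbitrarily bad input cannot
#' blow up; the returned energy is never above the input energy.
#'
#' @param state `cooke_state`.
#' @param topology `cooke_topology`.
#' @param params `cooke_ff`.
#' @param max_steps Step budget.
#' @param ftol Convergence threshold on the max per-bead force norm
#'   (kcal/mol/nm).
#' @param max_disp_nm Per-bead displacement cap per step (nm).
#' @return Minimized `cooke_state` with attributes `energy`, `steps`,
#'   `converged`.
#' @export
minimize <- function(state, topology, params = ff_params(),
                     max_steps = 5000, ftol = 1, max_disp_nm = 0.02) {
  ta <- topology_arrays(topology)
  res <- cpp_minimize(state$positions, state$box_edge,
                      ta$cls, ta$kind, ta$fene, ta$harm, ta$harm_r0,
                      ta$elas, ta$elas_r0, unclass(params),
                      as.integer(max_steps), ftol, max_disp_nm)
  if (!is.finite(res$energy))
    stop("minimize: diverged (non-finite energy)")
  out <- new_system_state(res$positions, state$box_edge,
                          velocities = state$velocities,
                          time_fs = state$time_fs)
  attr(out, "energy") <- res$energy
  attr(out, "steps") <- res$steps
  attr(out, "converged") <- res$converged
  out
}

#' Ramped-timestep equilibration
#'
#' Staged Langevin dynamics with the time step increased tenfold per stage,
#' by default 0.01, 0.1, 1, then 10 fs, each for `stage_steps` steps. The
#' tiny initial step lets residual bead overlaps left by minimization relax
#' without FENE overextension; the final stage hands over a state already
#' thermalized at the production time step.
#'
#' @param state Minimized `cooke_state`.
#' @param topology `cooke_topology`.
#' @param params `cooke_ff`.
#' @param seed Integer seed.
#' @param stage_dt_fs Time-step ladder (fs).
#' @param stage_steps Steps per stage.
#' @param config Base `engine_config` (friction, temperature, mass, skin).
#' @return Equilibrated `cooke_state`; attribute `stage_dt_fs` records the
#'   ladder.
#' @export
equilibrate <- function(state, topology, params = ff_params(), seed = 1,
                        stage_dt_fs = c(0.01, 0.1, 1, 10),
                        stage_steps = 1e4,
                        config = engine_config()) {
  st <- state
  if (all(st$velocities == 0)) {
    set.seed(seed)
    st$velocities <- maxwell_velocities(nrow(st$positions),
                                        config$temperature_K,
                                        config$mass_amu)
  }
  for (k in seq_along(stage_dt_fs)) {
    cfg <- config
    cfg$timestep_fs <- stage_dt_fs[k]
    cfg$seed <- as.integer(seed + 7919 * k)
    cfg$snapshot_every <- 0L
    tr <- tryCatch(
      run_langevin(st, topology, params, cfg, n_steps = stage_steps),
      error = function(e) stop(sprintf(
        "equilibrate: instability in stage %d (dt = %g fs): %s",
        k, stage_dt_fs[k], conditionMessage(e)), call. = FALSE)
    )
    st <- tr$final_state
  }
  attr(st, "stage_dt_fs") <- stage_dt_fs
  st
}

#' Langevin NVT dynamics
#'
#' Integrates the underdamped Langevin equation with a BAOAB splitting
#' (velocity Verlet plus an exact Ornstein-Uhlenbeck velocity kick each
#' step). With `friction_ps = 0` the scheme reduces exactly to velocity
#' Verlet and conserves energy (the integrator-correctness oracle).
#' Trajectories are bit-reproducible for a given seed on the
#' single-threaded reference path.
#'
#' @param state Equilibrated `cooke_state`.
#' @param topology `cooke_topology`.
#' @param params `cooke_ff`.
#' @param config `engine_config`.
#' @param n_steps Number of integration steps.
#' @return A `cooke_trajectory`: list with `frames` (list of `cooke_state`
#'   snapshots), `times_fs`, `potential_energy`, `kinetic_energy`
#'   (kcal/mol, one entry per snapshot), and `final_state`.
#' @export
run_langevin <- function(state, topology, params = ff_params(),
                         config = engine_config(), n_steps) {
  ta <- topology_arrays(topology)
  res <- cpp_run_langevin(state$positions, state$velocities, state$box_edge,
                          ta$cls, ta$kind, ta$fene, ta$harm, ta$harm_r0,
                          ta$elas, ta$elas_r0, unclass(params),
                          config$mass_amu, config$timestep_fs,
                          config$friction_ps, config$temperature_K,
                          as.numeric(n_steps), as.integer(config$snapshot_every),
                          as.numeric(config$seed),
                          thermostat = config$friction_ps > 0,
                          skin = config$skin_nm)
  t0 <- state$time_fs
  dt <- config$timestep_fs
  frames <- lapply(seq_along(res$frames), function(k) {
    new_system_state(res$frames[[k]], state$box_edge,
                     time_fs = t0 + res$snap_step[k] * dt)
  })
  final_state <- new_system_state(res$positions, state$box_edge,
                                  velocities = res$velocities,
                                  time_fs = t0 + n_steps * dt)
  traj <- list(frames = frames,
               times_fs = t0 + res$snap_step * dt,
               potential_energy = res$snap_pe,
               kinetic_energy = res$snap_ke,
               final_state = final_state,
               box_edge = state$box_edge)
  class(traj) <- "cooke_trajectory"
  traj
}

#' @export
print.cooke_trajectory <- function(x, ...) {
  cat(sprintf("Cooke trajectory: %d snapshots, %d beads, %.3g ns\n",
              length(x$frames), nrow(x$final_state$positions),
              (x$final_state$time_fs) / 1e6))
  invisible(x)
}

#' Candidate neighbor pairs
#'
#' Cell-list enumeration of all bead pairs within `cutoff + skin` under the
#' minimum-image convention: a superset of the interacting pairs, suitable
#' for Verlet-list reuse until any bead moves more than `skin/2`. Falls back
#' to an all-pairs sweep (with a warning) when the box is too small for a
#' 3 x 3 x 3 cell decomposition.
#'
#' @param state `cooke_state`.
#' @param cutoff Interaction cutoff (nm).
#' @param skin Extra margin (nm).
#' @return Two-column integer matrix of 1-based bead index pairs (i < j).
#' @export
neighbor_list <- function(state, cutoff, skin = 0) {
  rlist <- cutoff + skin
  if (floor(state$box_edge / rlist) < 3)
    warning("neighbor_list: box too small for cell decomposition; ",
            "using all-pairs sweep")
  cpp_neighbor_pairs(state$positions, state$box_edge, rlist, brute = FALSE)
}
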