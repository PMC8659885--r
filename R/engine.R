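# System assembly and the R-facing surface of the event-driven engine.

#' Assemble a simulation-ready system
#'
#' Bundles a structure with its pair-potential table, hydrogen-bond wells,
#' bonded constraints and any additional restraints.  Donor-acceptor H...O
#' pairs that are handled by the hydrogen-bond machinery are removed from the
#' generic nonbonded table (they keep the same inner hard wall there), so a
#' system built with `w_hb = 0` is identical to one with the hydrogen-bond
#' machinery absent.
#'
#' @param structure a `pacsab_structure` (topology + coordinates)
#' @param params a `pacsab_params`
#' @param box_L periodic box side in Angstrom (0 = open boundaries)
#' @param restraints optional extra constraint data.frame from
#'   [make_restraints()]
#' @param pair_table optional pre-built [build_pair_table()] result
#' @param hbonds optional pre-built [hbond_wells()] result
#' @return a `pacsab_system`
#' @export
build_system <- function(structure, params = ff_params(), box_L = 0,
                         restraints = NULL, pair_table = NULL, hbonds = NULL) {
  topology <- structure$topology
  if (is.null(pair_table)) pair_table <- build_pair_table(topology, params)
  if (is.null(hbonds)) hbonds <- hbond_wells(topology, params)
  if (nrow(hbonds)) {
    N <- nrow(topology$atoms)
    hk <- pmin(hbonds$h, hbonds$o) * (N + 1) + pmax(hbonds$h, hbonds$o)
    pk <- pmin(pair_table$pairs$i, pair_table$pairs$j) * (N + 1) +
      pmax(pair_table$pairs$i, pair_table$pairs$j)
    pair_table$pairs <- pair_table$pairs[!(pk %in% hk), , drop = FALSE]
  }
  bonds <- topology$constraints
  if (!is.null(restraints) && nrow(restraints)) bonds <- rbind(bonds, restraints)
  structure(list(topology = topology, xyz = structure$xyz, box_L = box_L,
                 params = params, pair_table = pair_table, hbonds = hbonds,
                 bonds = bonds),
            class = "pacsab_system")
}

#' @export
print.pacsab_system <- function(x, ...) {
  cat("pacsab_system:", nrow(x$topology$atoms), "particles,",
      nrow(x$pair_table$pairs), "nonbonded pairs,",
      nrow(x$bonds), "distance-range constraints,",
      nrow(x$hbonds), "hydrogen-bond wells,",
      if (x$box_L > 0) paste0("box L = ", format(x$box_L), " A")
      else "open boundaries", "\n")
  invisible(x)
}

#' Maxwell-Boltzmann velocities
#'
#' @param masses particle masses (amu)
#' @param kT temperature (energy units)
#' @param seed RNG seed
#' @param remove_com remove the center-of-mass momentum
#' @return n x 3 velocity matrix (reduced units)
#' @export
maxwell_velocities <- function(masses, kT, seed = NULL, remove_com = TRUE) {
  if (!is.null(seed)) set.seed(seed)
  n <- length(masses)
  v <- matrix(rnorm(3 * n), n, 3) * sqrt(kT / masses)
  if (remove_com && n > 1L)
    v <- sweep(v, 2, colSums(v * masses) / sum(masses))
  v
}

# outermost interaction distance of the system (for the resync interval)
max_cutoff <- function(system) {
  r <- vapply(system$pair_table$potentials, function(p) max(p$radii), 0)
  max(c(r, system$hbonds$r_max, 0))
}

#' Run event-driven discrete molecular dynamics
#'
#' Propagates the system to `t_end` (reduced time units: Angstrom *
#' sqrt(amu / energy unit)) with exact event-by-event dynamics: ballistic
#' motion between events; momentum- and energy-conserving impulses at step
#' discontinuities, bond-range walls and hydrogen-bond well edges; an
#' Andersen-style thermostat that resamples one particle's velocity from the
#' Maxwell-Boltzmann distribution as a Poisson process (`ghost_rate` per
#' particle per time unit; 0 gives microcanonical dynamics).  Identical
#' inputs and seed give bit-identical trajectories, independent of the
#' snapshot interval.
#'
#' @param system a `pacsab_system`
#' @param t_end end time (reduced units)
#' @param snapshot_interval time between stored frames
#' @param ghost_rate thermostat collision rate per particle per time unit
#' @param seed integer seed (drives initial velocities and the thermostat)
#' @param vel optional explicit initial velocities (n x 3); otherwise sampled
#'   from Maxwell-Boltzmann at `kT`
#' @param kT temperature; defaults to the force-field `kT`
#' @param max_events stop after this many events
#' @param log_events keep a per-event log (time, kind, i, j, shell)
#' @return a `pacsab_trajectory`: `frames` (n x 3 x n_frames), `times`,
#'   final state, per-snapshot energy/momentum diagnostics and event counts
#' @export
run_dmd <- function(system, t_end, snapshot_interval = t_end / 100,
                    ghost_rate = 0.1, seed = 1, vel = NULL, kT = NULL,
                    max_events = Inf, log_events = FALSE) {
  stopifnot(inherits(system, "pacsab_system"), t_end > 0)
  at <- system$topology$atoms
  if (is.null(kT)) kT <- system$params$kT
  if (is.null(vel)) vel <- maxwell_velocities(at$mass, kT, seed = seed)
  pt <- system$pair_table
  bonds <- system$bonds
  hb <- system$hbonds

  resync_dt <- 0
  if (system$box_L > 0) {
    margin <- system$box_L / 2 - max_cutoff(system)
    if (margin <= 0)
      stop("box side must exceed twice the largest interaction cutoff")
    vref <- 8 * sqrt(max(kT, 1e-6) / min(at$mass))
    resync_dt <- max(margin / (2 * vref), 1e-3)
  }

  res <- dmd_run_cpp(system$xyz, vel, at$mass, system$box_L,
                     lapply(pt$potentials, `[[`, "radii"),
                     lapply(pt$potentials, `[[`, "energies"),
                     pt$pairs$i, pt$pairs$j, pt$pairs$pot,
                     bonds$i, bonds$j, bonds$dmin, bonds$dmax,
                     hb$h, hb$o, hb$n, hb$r_min, hb$r_max, hb$depth,
                     hb$gate_min, hb$gate_max,
                     t_end, snapshot_interval, ghost_rate, kT,
                     as.integer(seed), resync_dt,
                     if (is.finite(max_events)) max_events else 1e18,
                     log_events, 1000000L)
  nf <- res$n_frames
  traj <- list(frames = res$frames[, , seq_len(nf), drop = FALSE],
               times = res$times[seq_len(nf)],
               system = system,
               x_final = res$x_final, v_final = res$v_final,
               t_final = res$t_final,
               n_events = res$n_events, event_counts = res$event_counts,
               energy = res$energy[seq_len(nf)],
               kinetic = res$kinetic[seq_len(nf)],
               momentum = res$momentum[seq_len(nf), , drop = FALSE],
               epot_final_tracked = res$epot_final_tracked,
               epot_final_recomputed = res$epot_final_recomputed,
               event_log = res$event_log,
               seed = seed, kT = kT, ghost_rate = ghost_rate)
  class(traj) <- "pacsab_trajectory"
  traj
}

#' @export
print.pacsab_trajectory <- function(x, ...) {
  cat("pacsab_trajectory:", dim(x$frames)[3], "frames,",
      format(x$n_events, big.mark = ","), "events, t =",
      format(x$t_final, digits = 6), "\n")
  invisible(x)
}

#' Extract one frame of a trajectory
#' @param traj a `pacsab_trajectory`
#' @param k frame index
#' @return n x 3 coordinate matrix
#' @export
frame_xyz <- function(traj, k) traj$frames[, , k]

#' Total energy of a configuration
#'
#' Kinetic energy plus the sum of current shell energies over all interacting
#' pairs (hydrogen-bond wells counted when the H...O distance is inside the
#' well and the N...O gate is open); configurations inside a forbidden region
#' report `Inf`.
#'
#' @param system a `pacsab_system`
#' @param xyz coordinates (defaults to the system's)
#' @param vel velocities (defaults to zero: potential energy only)
#' @return energy (reduced units)
#' @export
total_energy <- function(system, xyz = system$xyz, vel = NULL) {
  at <- system$topology$atoms
  if (is.null(vel)) vel <- matrix(0, nrow(at), 3)
  pt <- system$pair_table
  bonds <- system$bonds
  hb <- system$hbonds
  dmd_energy_cpp(xyz, vel, at$mass, system$box_L,
                 lapply(pt$potentials, `[[`, "radii"),
                 lapply(pt$potentials, `[[`, "energies"),
                 pt$pairs$i, pt$pairs$j, pt$pairs$pot,
                 bonds$i, bonds$j, bonds$dmin, bonds$dmax,
                 hb$h, hb$o, hb$n, hb$r_min, hb$r_max, hb$depth,
                 hb$gate_min, hb$gate_max)
}

#' Predict the next step-potential crossing for an isolated pair
#'
#' Earliest positive root of `|r_ij + v_ij t| = d` over the discontinuity
#' radii reachable from the current shell (minimum image when `box_L > 0`).
#'
#' @param xi,xj,vi,vj positions and velocities (length-3)
#' @param radii discontinuity radii of the pair's step potential
#' @param box_L periodic box side (0 = open)
#' @return list with `time` (`Inf` if no discontinuity is ever reached),
#'   `radius_index`, `outward`, and the current `shell`
#' @export
predict_pair_event <- function(xi, xj, vi, vj, radii, box_L = 0) {
  dmd_predict_pair_cpp(as.numeric(xi), as.numeric(xj),
                       as.numeric(vi), as.numeric(vj),
                       as.numeric(radii), box_L)
}

#' Resolve a pair event: reflect or refract at a potential step
#'
#' Given two particles exactly at an event radius and the energy step `dU`
#' (target shell minus current shell; `Inf` for a hard wall), applies the
#' momentum-conserving impulse along the line of centers: refraction
#' `v_r' = sign(v_r) sqrt(v_r^2 - 2 dU / mu)` when the radial kinetic energy
#' exceeds the step, reflection `v_r' = -v_r` otherwise.
#'
#' @param xi,xj,vi,vj positions and velocities (length-3)
#' @param mi,mj masses
#' @param dU energy step (target minus current shell)
#' @param box_L periodic box side (0 = open)
#' @return list with updated `vi`, `vj` and logical `crossed`
#' @export
execute_collision <- function(xi, xj, vi, vj, mi, mj, dU, box_L = 0) {
  dmd_collide_cpp(as.numeric(xi), as.numeric(xj),
                  as.numeric(vi), as.numeric(vj), mi, mj, dU, box_L)
}
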