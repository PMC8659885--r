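# Experiment drivers: concentration-box arithmetic, replica initialization,
# restrained complex relaxation and force-field parameter scans.

AVOGADRO <- 6.02214076e23

#' Box side for a target molar concentration
#'
#' Side length of the cubic periodic box holding `n_molecules` at the given
#' concentration: `L = (n / (C N_A))^(1/3)`.  Two molecules at 30 uM need a
#' 48 nm box; at 100 uM, 32 nm.
#'
#' @param n_molecules number of molecules in the box
#' @param concentration molar concentration (mol/L)
#' @return box side in nm
#' @export
box_for_concentration <- function(n_molecules, concentration) {
  if (n_molecules <= 0 || concentration <= 0)
    stop("n_molecules and concentration must be positive")
  # molecules per nm^3 = concentration * N_A / 1e24
  (n_molecules / (concentration * AVOGADRO * 1e-24))^(1 / 3)
}

#' Molar concentration of a box
#' @param n_molecules number of molecules
#' @param box_L box side in nm
#' @return concentration in mol/L
#' @export
concentration_for_box <- function(n_molecules, box_L) {
  n_molecules / (box_L^3 * AVOGADRO * 1e-24)
}

#' Water count an explicit-solvent box of this size would need
#'
#' Reporting helper for solvent-cost context: `L^3 * rho_w` with
#' `rho_w = 33.37` molecules/nm^3 (0.997 g/cm^3).  A 48 nm box corresponds
#' to about 4 million water molecules.
#'
#' @param box_L box side in nm
#' @return water-molecule count
#' @export
estimate_water_count <- function(box_L) {
  if (box_L <= 0) stop("box_L must be positive")
  box_L^3 * 33.37
}

#' Place molecule copies in a box with random poses
#'
#' Each molecule is rotated by a uniform random rotation and placed at a
#' random center, re-drawing until every inter-molecule minimum distance is
#' at least `separation_min` (so "far apart" starts are literally
#' non-interacting).  Deterministic under `seed`.
#'
#' @param molecules list of `pacsab_structure` objects (distinct chain labels)
#' @param box_L box side in Angstrom
#' @param seed RNG seed
#' @param separation_min minimum inter-molecule distance (Angstrom)
#' @param max_tries retry budget per molecule
#' @return a `pacsab_structure` with the merged topology and coordinates
#' @export
place_replicas <- function(molecules, box_L, seed = 1, separation_min = 20,
                           max_tries = 200L) {
  stopifnot(length(molecules) >= 1L)
  set.seed(seed)
  placed <- list()
  topo <- NULL
  coords <- NULL
  for (m in molecules) {
    xyz <- m$xyz
    com <- colMeans(xyz)
    x0 <- sweep(xyz, 2, com)
    diam <- 2 * sqrt(max(rowSums(x0^2)))
    if (diam >= box_L / 2)
      stop("molecule too large for the box (diameter ", format(diam),
           " A vs box ", format(box_L), " A)")
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      R <- random_rotation()
      center <- runif(3, 0, box_L)
      cand <- sweep(x0 %*% t(R), 2, center, "+")
      ok <- all(vapply(placed, function(p)
        min(cross_distances(cand, p, box_L)) >= separation_min, TRUE))
      if (ok) break
    }
    if (!ok)
      stop("could not place molecule with separation >= ", separation_min,
           " A after ", max_tries, " tries")
    placed[[length(placed) + 1L]] <- cand
    topo <- if (is.null(topo)) m$topology else merge_topologies(topo, m$topology)
    coords <- rbind(coords, cand)
  }
  structure(list(topology = topo, xyz = coords), class = "pacsab_structure")
}

#' Relax a complex under all-CA restraints
#'
#' Runs a short simulation with relax-mode restraints between all CA pairs of
#' the complex (both chains), letting the side-chain beads settle after the
#' atomistic-to-coarse-grained remapping, and emits equally spaced snapshots
#' to be used as starting points for stability runs.
#'
#' @param complex_structure a `pacsab_structure` with at least two chains
#' @param params force-field parameters
#' @param n_snapshots number of snapshots to emit
#' @param t_relax relaxation time (reduced units)
#' @param seed RNG seed
#' @param box_L box side (Angstrom; 0 = open)
#' @param ghost_rate thermostat rate
#' @return list with `snapshots` (list of coordinate matrices), `trajectory`,
#'   and the `restraints` used
#' @export
relax_complex <- function(complex_structure, params = ff_params(),
                          n_snapshots = 8L, t_relax = 20, seed = 1,
                          box_L = 0, ghost_rate = 0.2) {
  topo <- complex_structure$topology
  if (length(unique(topo$atoms$chain)) < 2L)
    stop("relax_complex needs a complex of at least two chains")
  restr <- make_restraints(complex_structure$xyz, topo, NULL, mode = "relax")
  sys <- build_system(complex_structure, params, box_L = box_L,
                      restraints = restr)
  traj <- run_dmd(sys, t_end = t_relax,
                  snapshot_interval = t_relax / n_snapshots,
                  ghost_rate = ghost_rate, seed = seed)
  nf <- dim(traj$frames)[3]
  pick <- round(seq(nf / n_snapshots, nf, length.out = n_snapshots))
  snaps <- lapply(pick, function(k) frame_xyz(traj, k))
  # contract check: every restrained CA-CA distance inside its range
  for (k in seq_along(snaps)) {
    d <- sqrt(rowSums((snaps[[k]][restr$i, ] - snaps[[k]][restr$j, ])^2))
    bad <- d < restr$dmin - 1e-6 | d > restr$dmax + 1e-6
    if (any(bad))
      stop("internal error: ", sum(bad),
           " restraints violated in snapshot ", k)
  }
  list(snapshots = snaps, trajectory = traj, restraints = restr)
}

#' Replica plan
#'
#' @param n_replicas number of replicas
#' @param seeds distinct integer seeds (defaults to `1:n_replicas`)
#' @param t_end simulation length per replica (reduced units)
#' @param initial_mode how replicas start
#' @param preset force-field preset label
#' @return a `pacsab_plan` list
#' @export
replica_plan <- function(n_replicas, seeds = seq_len(n_replicas), t_end,
                         initial_mode = c("extended_far_apart",
                                          "native_complex_relaxed",
                                          "non_native_bound",
                                          "folded_far_apart"),
                         preset = "original") {
  initial_mode <- match.arg(initial_mode)
  stopifnot(n_replicas >= 1L, length(seeds) == n_replicas,
            !anyDuplicated(seeds))
  structure(list(n_replicas = n_replicas, seeds = as.integer(seeds),
                 t_end = t_end, initial_mode = initial_mode, preset = preset),
            class = "pacsab_plan")
}

#' Scan a force-field parameter against an observable
#'
#' For each value, runs `plan$n_replicas` replica simulations built by
#' `build` (a function of the parameter value) and aggregates the observable
#' per replica.  The same seeds are used for every value (common random
#' numbers for variance reduction).  A failing observable flags the row but
#' the scan continues.
#'
#' @param values parameter values (e.g. multipliers on the vdW weight)
#' @param plan a [replica_plan()]
#' @param observable function(trajectory) -> scalar
#' @param build function(value, seed) -> `pacsab_system` for one replica
#' @param snapshot_interval passed to [run_dmd()]
#' @param ghost_rate thermostat rate
#' @return data.frame with one row per value: `value`, `mean`, `sd`, `n_ok`,
#'   `failed`
#' @export
scan_parameter <- function(values, plan, observable, build,
                           snapshot_interval = plan$t_end / 50,
                           ghost_rate = 0.1) {
  stopifnot(length(values) >= 1L)
  rows <- lapply(values, function(v) {
    obs <- vapply(plan$seeds, function(s) {
      tryCatch({
        sys <- build(v, s)
        tr <- run_dmd(sys, t_end = plan$t_end,
                      snapshot_interval = snapshot_interval,
                      ghost_rate = ghost_rate, seed = s)
        as.numeric(observable(tr))
      }, error = function(e) NA_real_)
    }, 0)
    ok <- !is.na(obs)
    data.frame(value = v, mean = mean(obs[ok]),
               sd = if (sum(ok) > 1L) sd(obs[ok]) else 0,
               n_ok = sum(ok), failed = any(!ok))
  })
  do.call(rbind, rows)
}
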