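# Synthetic-structure and toy-system generators: extended chains, ideal
# alpha-helices, two-particle square-well systems with analytic references,
# and a small aggregating homopolymer pair.  Everything here is deterministic
# so the rest of the package is testable without external downloads.

# side-chain bead directions from the local backbone frame: the bisector of
# the N-CA / C-CA directions pushed out of the backbone plane
sidechain_direction <- function(N, CA, C) {
  b1 <- unitv(CA - N); b2 <- unitv(CA - C)
  bis <- unitv(b1 + b2)
  nrm <- unitv(cross3(b1, b2))
  unitv(bis + 0.9 * nrm)
}

place_sidechains <- function(topology, bb, map = read_sidechain_map()) {
  at <- topology$atoms
  xyz <- matrix(NA_real_, nrow(at), 3)
  for (r in seq_along(bb)) {
    res <- bb[[r]]
    for (k in names(res))
      xyz[at$resno == r & at$kind == k, ] <- res[[k]]
    beads <- map[[at$resid[at$resno == r][1]]]
    if (length(beads)) {
      u <- sidechain_direction(res$N, res$CA, res$C)
      pos <- res$CA
      for (b in beads) {
        pos <- pos + b$link * u
        xyz[at$resno == r & at$kind == b$name, ] <- pos
      }
    }
  }
  xyz
}

build_conformer <- function(sequence, phi, psi, chain_id = "A",
                            params = ff_params(), map = read_sidechain_map(),
                            geom = load_peptide_geometry()) {
  topology <- build_topology(sequence, chain_id, map = map, params = params,
                             geom = geom)
  resid3 <- seq_to_resid(sequence)
  bb <- build_backbone(resid3, phi, psi, geom)
  xyz <- place_sidechains(topology, bb, map)
  structure(list(topology = topology, xyz = xyz),
            class = "pacsab_structure")
}

#' Extended-chain conformer
#'
#' Backbone built at phi = psi = 180 degrees with ideal bond geometry;
#' side-chain beads placed along ideal directions from the local backbone
#' frame.  Deterministic.
#'
#' @param sequence one-letter amino-acid string
#' @param chain_id chain label
#' @param params force-field parameters (masses/radii tables)
#' @return a `pacsab_structure` (list with `topology` and `xyz`)
#' @export
extended_chain <- function(sequence, chain_id = "A", params = ff_params()) {
  geom <- load_peptide_geometry()
  n <- nchar(sequence)
  ex <- geom$conformations$extended
  build_conformer(sequence, rep(ex$phi, n), rep(ex$psi, n), chain_id, params,
                  geom = geom)
}

#' Ideal alpha-helix conformer
#'
#' Residues of `segment` are built at phi = -57, psi = -47 degrees (rise of
#' about 1.5 Angstrom per residue along the helix axis); the remainder of the
#' chain is extended.
#'
#' @param sequence one-letter amino-acid string
#' @param segment `NULL` for the whole chain, or `c(from, to)` (1-based,
#'   inclusive)
#' @param chain_id chain label
#' @param params force-field parameters
#' @return a `pacsab_structure`
#' @export
ideal_helix <- function(sequence, segment = NULL, chain_id = "A",
                        params = ff_params()) {
  geom <- load_peptide_geometry()
  n <- nchar(sequence)
  if (is.null(segment)) segment <- c(1L, n)
  if (segment[1] < 1L || segment[2] > n || segment[1] > segment[2])
    stop("segment ", segment[1], "-", segment[2],
         " outside the 1-", n, " sequence range")
  hx <- geom$conformations$helix; ex <- geom$conformations$extended
  phi <- rep(ex$phi, n); psi <- rep(ex$psi, n)
  idx <- segment[1]:segment[2]
  phi[idx] <- hx$phi; psi[idx] <- hx$psi
  build_conformer(sequence, phi, psi, chain_id, params, geom = geom)
}

#' Two-particle square-well toy system
#'
#' Two free particles with a hard core at `sigma` and a well of depth
#' `-depth` out to `lambda`, with the analytic references the engine can be
#' validated against: the closed-form bound-orbit period and the two-state
#' equilibrium bound fraction
#' `p = Vw e^(eps/kT) / (Vw e^(eps/kT) + V - Vb)` with
#' `Vw = (4 pi / 3)(lambda^3 - sigma^3)` and `Vb = (4 pi / 3) lambda^3`.
#'
#' @param sigma hard-core distance (Angstrom)
#' @param lambda_range outer well radius (> sigma)
#' @param depth well depth (energy units, > 0)
#' @param masses the two particle masses
#' @param box_L periodic box side (0 for open boundaries)
#' @return a `pacsab_toy_pair` list: `system` (ready for [run_dmd()]),
#'   `bound_fraction(kT)`, `orbit_period(x, v)` and a canonical bound
#'   initial condition `x0`, `v0` with its `period`
#' @export
square_well_pair <- function(sigma, lambda_range, depth, masses = c(1, 1),
                             box_L = 0) {
  stopifnot(lambda_range > sigma, sigma > 0, depth > 0)
  atoms <- data.frame(index = 1:2, kind = "P", resno = c(1L, 1L),
                      resid = "XXX", chain = c("A", "B"),
                      mass = masses, radius = sigma / 2, type = "toy",
                      stringsAsFactors = FALSE)
  topology <- structure(list(atoms = atoms,
                             constraints = data.frame(i = integer(), j = integer(),
                                                      dmin = numeric(), dmax = numeric(),
                                                      role = character()),
                             sequence = c(A = "X", B = "X")),
                        class = "pacsab_topology")
  pot <- step_potential(c(sigma, lambda_range), c(Inf, -depth, 0))
  pair_table <- structure(list(potentials = list(pot),
                               pairs = data.frame(i = 1L, j = 2L, pot = 1L,
                                                  local = FALSE)),
                          class = "pacsab_pair_table")
  mu <- prod(masses) / sum(masses)

  bound_fraction <- function(kT) {
    V <- box_L^3
    if (V <= 0) stop("bound fraction needs a periodic box")
    Vw <- 4 * pi / 3 * (lambda_range^3 - sigma^3)
    Vb <- 4 * pi / 3 * lambda_range^3
    Vw * exp(depth / kT) / (Vw * exp(depth / kT) + V - Vb)
  }

  # closed-form radial period of a bound orbit from relative state (x, v):
  # free-flight chords between the outer wall (and the core when the impact
  # parameter is below sigma)
  orbit_period <- function(x, v) {
    L <- vnorm(cross3(x, v))          # specific angular momentum magnitude
    sp <- vnorm(v)
    b <- L / sp                       # impact parameter of the chord
    if (b >= sigma) 2 * sqrt(lambda_range^2 - b^2) / sp
    else 2 * (sqrt(lambda_range^2 - b^2) - sqrt(sigma^2 - b^2)) / sp
  }

  # canonical bound initial condition: relative separation between the walls,
  # slow oblique approach (energy below the escape threshold)
  r0 <- (sigma + lambda_range) / 2
  vrel_speed <- sqrt(depth / mu)      # KE_rel = depth / 2 < depth: bound
  x0 <- rbind(c(-r0 / 2, 0, 0), c(r0 / 2, 0, 0))
  vdir <- unitv(c(0.6, 0.8, 0))
  v0 <- rbind(-vrel_speed * vdir * mu / masses[1],
              vrel_speed * vdir * mu / masses[2])
  if (box_L > 0) x0 <- x0 + box_L / 2

  system <- list(topology = topology, xyz = x0, box_L = box_L,
                 params = ff_params(), pair_table = pair_table,
                 hbonds = hbond_wells(topology, ff_params(w_hb = 0)),
                 bonds = topology$constraints)
  class(system) <- "pacsab_system"
  structure(list(system = system, sigma = sigma, lambda = lambda_range,
                 depth = depth, mu = mu,
                 bound_fraction = bound_fraction,
                 orbit_period = orbit_period,
                 x0 = x0, v0 = v0,
                 period = orbit_period(x0[2, ] - x0[1, ], v0[2, ] - v0[1, ])),
            class = "pacsab_toy_pair")
}

#' Aggregating homopolymer pair
#'
#' A desk-scale stand-in for two-peptide aggregation runs: two identical
#' leucine homopolymers in a periodic box, with the side-chain well depth set
#' directly by `stickiness` (energy units; 0 gives a purely repulsive,
#' non-aggregating reference) and the desolvation channel switched off so
#' that `stickiness` is the only attraction knob besides hydrogen bonding.
#'
#' @param n_residues chain length (>= 5)
#' @param stickiness side-chain well-depth scale (energy units)
#' @param box_L periodic box side (Angstrom)
#' @param w_hb hydrogen-bond weight (0 unplugs hydrogen bonding)
#' @param preset parametrization preset for the remaining knobs
#' @return a `pacsab_toy_aggregation` list: `molecule` (single-chain
#'   extended conformer), `params`, `box_L`
#' @export
aggregation_toy <- function(n_residues = 7L, stickiness = 0.4, box_L = 54,
                            w_hb = 1, preset = "original") {
  stopifnot(n_residues >= 5L)
  tables <- load_param_tables()
  tables$vdw$eps0 <- stickiness
  tables$solvation$s0 <- 0
  params <- ff_params(preset, w_hb = w_hb, tables = tables)
  seqn <- paste(rep("L", n_residues), collapse = "")
  molecule <- extended_chain(seqn, chain_id = "A", params = params)
  structure(list(molecule = molecule, params = params, box_L = box_L,
                 n_residues = n_residues, stickiness = stickiness,
                 sequence = seqn),
            class = "pacsab_toy_aggregation")
}

#' Assemble one replica of the aggregation toy
#'
#' Places two copies of the toy chain in the periodic box with a random pose
#' (deterministic under `seed`) and a minimum separation of 12 Angstrom
#' (beyond every interaction cutoff).  With `helix_restraint = TRUE` both
#' chains start as ideal helices and their central segment (residues 2 to
#' n-1) carries helix-mode restraints, mimicking a helix-stabilizing ligand;
#' otherwise the chains start extended and unrestrained.
#'
#' @param toy an [aggregation_toy()] object
#' @param seed placement seed
#' @param helix_restraint restrain the central segment to the helix
#' @return a `pacsab_system` ready for [run_dmd()]
#' @export
aggregation_replica_system <- function(toy, seed, helix_restraint = FALSE) {
  mol <- if (helix_restraint)
    ideal_helix(toy$sequence, params = toy$params)
  else toy$molecule
  molB <- set_chain(mol, "B")
  st <- place_replicas(list(mol, molB), toy$box_L, seed = seed,
                       separation_min = 12)
  restr <- NULL
  if (helix_restraint) {
    seg <- c(2L, toy$n_residues - 1L)
    segs <- list(list(chain = "A", from = seg[1], to = seg[2]),
                 list(chain = "B", from = seg[1], to = seg[2]))
    restr <- make_restraints(st$xyz, st$topology, segs, mode = "helix")
  }
  build_system(st, toy$params, box_L = toy$box_L, restraints = restr)
}
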