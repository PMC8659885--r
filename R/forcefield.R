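# Discretized pairwise force field: a van der Waals channel and an
# implicit-solvation (desolvation) channel combined with two weights,
#     V(r) = w_vdw * V_vdw(r) + w_solv * V_solv(r),
# so that hydrophobicity increases with w_vdw and decreases with w_solv;
# plus gated backbone hydrogen-bond wells and structure-based restraints.

the_params_cache <- new.env(parent = emptyenv())

load_param_tables <- function(path = system.file("extdata", "default_params.yaml",
                                                 package = "pacsab")) {
  key <- path
  if (is.null(the_params_cache[[key]]))
    the_params_cache[[key]] <- yaml::read_yaml(path)
  the_params_cache[[key]]
}

#' Force-field parameters
#'
#' Assembles the tunable force-field parameters from a named preset plus
#' optional overrides.  The shipped presets are `original` (neutral
#' reference), `new` (extra hydrophobicity for sequence-local pairs, which
#' favors local hydrogen bonds and helix structure) and `enhanced_hb`
#' (additionally raises the hydrogen-bond energy and the vdW weight by 5%).
#' All weights are relative multipliers on the base tables.
#'
#' @param preset preset name or `NULL` for `original`
#' @param w_vdw,w_solv,w_hb,local_scale,local_window,kT optional overrides:
#'   vdW weight, solvation weight, hydrogen-bond weight (0 unplugs hydrogen
#'   bonding), sequence-local hydrophobicity multiplier (>= 1), maximum
#'   sequence separation counted as local, thermostat temperature (energy
#'   units)
#' @param tables base parameter tables (per-kind masses/radii, shell scheme,
#'   hydropathy scale); defaults to the file shipped with the package
#' @return a `pacsab_params` list
#' @export
ff_params <- function(preset = "original", w_vdw = NULL, w_solv = NULL,
                      w_hb = NULL, local_scale = NULL, local_window = NULL,
                      kT = NULL, tables = load_param_tables()) {
  if (is.null(preset)) preset <- "original"
  if (!preset %in% names(tables$presets))
    stop("unknown preset '", preset, "'; available: ",
         paste(names(tables$presets), collapse = ", "))
  p <- tables$presets[[preset]]
  ov <- list(w_vdw = w_vdw, w_solv = w_solv, w_hb = w_hb,
             local_scale = local_scale, local_window = local_window, kT = kT)
  for (nm in names(ov)) if (!is.null(ov[[nm]])) p[[nm]] <- ov[[nm]]
  for (nm in c("w_vdw", "w_solv", "w_hb"))
    if (!is.finite(p[[nm]]) || p[[nm]] < 0)
      stop(nm, " must be finite and non-negative")
  if (p$local_scale < 1) stop("local_scale must be >= 1")
  if (p$local_window < 0) stop("local_window must be >= 0")
  if (p$kT <= 0) stop("kT must be positive")
  structure(c(p, list(preset = preset,
                      kinds = tables$kinds, sidechain = tables$sidechain,
                      vdw = tables$vdw, solvation = tables$solvation,
                      hbond = tables$hbond, hydropathy = tables$hydropathy)),
            class = "pacsab_params")
}

#' Construct a step potential
#'
#' A piecewise-constant pair potential: `radii` are the strictly increasing
#' discontinuity distances and `energies` the shell energies, with
#' `energies[1]` applying below `radii[1]` (it may be `Inf`, a hard core) and
#' the last entry, beyond the outermost radius, required to be zero.
#'
#' @param radii strictly increasing distances (Angstrom)
#' @param energies shell energies, `length(radii) + 1` values
#' @return a `pacsab_step` list
#' @export
step_potential <- function(radii, energies) {
  radii <- as.numeric(radii); energies <- as.numeric(energies)
  if (length(radii) < 1L) stop("need at least one radius")
  if (any(diff(radii) <= 0)) stop("radii must be strictly increasing")
  if (length(energies) != length(radii) + 1L)
    stop("need length(energies) == length(radii) + 1")
  if (energies[length(energies)] != 0)
    stop("the outermost shell energy must be zero (no interaction beyond cutoff)")
  if (any(!is.finite(energies[-1L])))
    stop("only the innermost shell may be infinite")
  structure(list(radii = radii, energies = energies), class = "pacsab_step")
}

#' Evaluate a step potential at given distances
#' @param pot a `pacsab_step`
#' @param r distances
#' @return shell energies at `r`
#' @export
step_energy <- function(pot, r) {
  pot$energies[findInterval(r, pot$radii) + 1L]
}

#' Discretize a continuous pair potential onto shells
#'
#' Each shell energy is the uniform-in-r average of the continuous potential
#' over the shell; the innermost shell (below the first radius) becomes a
#' hard core if the average does not exist, and the outermost shell is forced
#' to zero.
#'
#' @param continuous a function of distance
#' @param radii_scheme strictly increasing shell boundaries (Angstrom)
#' @return a `pacsab_step`
#' @export
discretize <- function(continuous, radii_scheme) {
  radii <- as.numeric(radii_scheme)
  if (any(diff(radii) <= 0)) stop("radii_scheme must be strictly increasing")
  lo <- c(0, radii[-length(radii)])
  hi <- radii
  e <- vapply(seq_along(radii), function(k) {
    val <- tryCatch(
      integrate(function(r) vapply(r, continuous, 0), lo[k], hi[k],
                rel.tol = 1e-10, abs.tol = 1e-12)$value / (hi[k] - lo[k]),
      error = function(e) Inf)
    if (!is.finite(val)) Inf else val
  }, 0)
  step_potential(radii, c(e, 0))
}

#' Resample a step potential onto a finer grid
#'
#' The new grid must contain every old discontinuity (the representation is
#' then exact).
#'
#' @param pot a `pacsab_step`
#' @param grid strictly increasing radii including all of `pot$radii`
#' @return a `pacsab_step` on `grid`
#' @export
resample_step <- function(pot, grid) {
  grid <- sort(unique(as.numeric(grid)))
  if (!all(pot$radii %in% grid))
    stop("grid must contain every discontinuity of the potential")
  mids <- c(grid[1] / 2, (grid[-length(grid)] + grid[-1]) / 2, grid[length(grid)] + 1)
  step_potential(grid, step_energy(pot, mids))
}

#' Combine vdW and solvation channels with their weights
#'
#' Shell-wise `w_vdw * e_vdw + w_solv * e_solv`; hard cores propagate as
#' `Inf`.  Both potentials must live on the same radii grid (use
#' `resample = TRUE` to resample onto the union grid first).
#'
#' @param v_vdw,v_solv `pacsab_step` objects
#' @param params a `pacsab_params` (uses `w_vdw`, `w_solv`)
#' @param resample resample onto the union grid if the grids differ
#' @return combined `pacsab_step`
#' @export
combine_potentials <- function(v_vdw, v_solv, params, resample = FALSE) {
  if (!identical(v_vdw$radii, v_solv$radii)) {
    if (!resample)
      stop("potentials live on different radii grids; set resample = TRUE")
    grid <- sort(unique(c(v_vdw$radii, v_solv$radii)))
    v_vdw <- resample_step(v_vdw, grid)
    v_solv <- resample_step(v_solv, grid)
  }
  e <- params$w_vdw * v_vdw$energies + params$w_solv * v_solv$energies
  e[!is.finite(v_vdw$energies) | !is.finite(v_solv$energies)] <- Inf
  if (params$w_vdw == 0 && params$w_solv == 0) {
    e <- ifelse(is.finite(v_vdw$energies) & is.finite(v_solv$energies), 0, Inf)
  }
  step_potential(v_vdw$radii, e)
}

hydropathy_unit <- function(params, resid3) {
  kd <- unlist(params$hydropathy[resid3])
  0.2 + 0.8 * (kd + 4.5) / 9
}

# continuous channel generators (shared by build_pair_table and tests)
lj_potential <- function(eps, sigma) {
  function(r) 4 * eps * ((sigma / r)^12 - (sigma / r)^6)
}
solv_potential <- function(s, sigma, decay) {
  function(r) ifelse(r < sigma, s, s * exp(-(r - sigma) / (decay * sigma)))
}

#' Build the pair-potential table for a topology
#'
#' Assigns every non-excluded particle pair a step potential.  Side-chain
#' bead pairs receive the full two-channel potential (vdW well depth from the
#' hydropathy of both residues, desolvation penalty for hydrophilic pairs);
#' all other pairs interact by excluded volume only.  Pairs whose residues
#' are within `local_window` positions on the same chain have their
#' attractive shell energies multiplied by `local_scale`.  Pairs at bond-graph
#' distance <= 2 (1-2 and 1-3) and pairs already carrying a distance-range
#' constraint are excluded from the nonbonded table, as are 1-4 pairs (the
#' standard nonbonded exclusion set; backbone 1-4 geometry is governed by the
#' dihedral-range constraints instead).
#'
#' @param topology a `pacsab_topology`
#' @param params a `pacsab_params`
#' @param base_tables optional externally supplied step-potential tables: a
#'   named list `type_a|type_b` -> `list(vdw = pacsab_step, solv =
#'   pacsab_step)`, used verbatim for those type pairs
#' @return a `pacsab_pair_table`: `potentials` (list of `pacsab_step`) and
#'   `pairs` (data.frame i, j, pot, local)
#' @export
build_pair_table <- function(topology, params, base_tables = NULL) {
  at <- topology$atoms
  N <- nrow(at)
  con <- topology$constraints

  # exclusions: bond-graph distance <= 2 plus every constrained pair
  adj <- vector("list", N)
  cov <- con[con$role == "covalent", ]
  for (k in seq_len(nrow(cov))) {
    adj[[cov$i[k]]] <- c(adj[[cov$i[k]]], cov$j[k])
    adj[[cov$j[k]]] <- c(adj[[cov$j[k]]], cov$i[k])
  }
  key <- function(i, j) pmin(i, j) * (N + 1) + pmax(i, j)
  ekeys <- key(con$i, con$j)
  # bond-graph distance <= 3 (standard 1-2/1-3/1-4 nonbonded exclusions)
  for (c0 in seq_len(N)) {
    d1 <- adj[[c0]]
    d2 <- unique(unlist(adj[d1]))
    d3 <- unique(unlist(adj[d2]))
    reach <- setdiff(unique(c(d1, d2, d3)), c0)
    if (length(reach)) ekeys <- c(ekeys, key(c0, reach))
  }
  ekeys <- unique(ekeys)

  is_sc <- grepl("^SC", at$kind)
  h_unit <- ifelse(is_sc, hydropathy_unit(params, at$resid), NA_real_)

  i <- rep.int(seq_len(N - 1L), (N - 1L):1L)
  j <- sequence((N - 1L):1L, from = 2:N)
  keep <- !(key(i, j) %in% ekeys)
  i <- i[keep]; j <- j[keep]

  local <- at$chain[i] == at$chain[j] &
    abs(at$resno[i] - at$resno[j]) <= params$local_window &
    is_sc[i] & is_sc[j]

  pot_key <- ifelse(is_sc[i] & is_sc[j],
                    paste(pmin(at$type[i], at$type[j]),
                          pmax(at$type[i], at$type[j]),
                          ifelse(local, "L", "G"), sep = "|"),
                    paste0("hc|", format(at$radius[i] + at$radius[j], digits = 10)))

  ukeys <- unique(pot_key)
  potentials <- vector("list", length(ukeys))
  names(potentials) <- ukeys
  scheme <- as.numeric(params$vdw$shell_scheme)
  first <- match(ukeys, pot_key)
  for (u in seq_along(ukeys)) {
    a <- i[first[u]]; b <- j[first[u]]
    if (is_sc[a] && is_sc[b]) {
      sigma <- at$radius[a] + at$radius[b]
      tkey <- paste(pmin(at$type[a], at$type[b]), pmax(at$type[a], at$type[b]),
                    sep = "|")
      if (!is.null(base_tables)) {
        if (is.null(base_tables[[tkey]]))
          stop("base_tables has no entry for type pair ", tkey)
        ch <- base_tables[[tkey]]
      } else {
        eps <- params$vdw$eps0 * sqrt(h_unit[a] * h_unit[b])
        s <- params$solvation$s0 * (2 - h_unit[a] - h_unit[b])
        grid <- scheme * sigma
        vdw <- discretize(lj_potential(eps, sigma), grid)
        vdw$energies[1] <- Inf
        slv <- discretize(solv_potential(s, sigma, params$solvation$decay), grid)
        slv$energies[1] <- Inf
        ch <- list(vdw = vdw, solv = slv)
      }
      pot <- combine_potentials(ch$vdw, ch$solv, params, resample = TRUE)
      if (local[first[u]] && params$local_scale != 1) {
        neg <- is.finite(pot$energies) & pot$energies < 0
        pot$energies[neg] <- pot$energies[neg] * params$local_scale
      }
      potentials[[u]] <- pot
    } else {
      # excluded-volume-only pairs: contact distance softened by 0.8 so that
      # ideal backbone geometry never sits inside a core
      core <- 0.8 * (at$radius[a] + at$radius[b])
      potentials[[u]] <- step_potential(core, c(Inf, 0))
    }
  }
  structure(list(potentials = unname(potentials),
                 pairs = data.frame(i = i, j = j,
                                    pot = match(pot_key, ukeys),
                                    local = local)),
            class = "pacsab_pair_table")
}

#' @export
print.pacsab_pair_table <- function(x, ...) {
  cat("pacsab_pair_table:", nrow(x$pairs), "interacting pairs,",
      length(x$potentials), "distinct step potentials\n")
  invisible(x)
}

#' Enumerate gated backbone hydrogen-bond wells
#'
#' For every donor (amide H of residue i; proline contributes none) and
#' acceptor (carbonyl O of residue j) with sequence separation |i - j| >= 2
#' or on different chains, an attractive well of depth `w_hb * eps_hb`
#' between H and O over the well range, active only while the auxiliary
#' N(i)-O(j) distance lies inside its linearity gate.  Bonds are saturating:
#' the engine forms at most one bond per donor and per acceptor, so
#' internally satisfied partners (as in a helix) are unavailable for
#' intermolecular bonding.  `w_hb = 0` unplugs hydrogen bonding and returns
#' an empty set.
#'
#' @param topology a `pacsab_topology`
#' @param params a `pacsab_params`
#' @return data.frame with columns h, o, n (particle indices), r_min, r_max,
#'   depth, gate_min, gate_max
#' @export
hbond_wells <- function(topology, params) {
  hbp <- params$hbond
  empty <- data.frame(h = integer(), o = integer(), n = integer(),
                      r_min = numeric(), r_max = numeric(), depth = numeric(),
                      gate_min = numeric(), gate_max = numeric())
  if (params$w_hb == 0) return(empty)
  at <- topology$atoms
  don <- at[at$kind == "H", c("index", "resno", "chain")]
  acc <- at[at$kind == "O", c("index", "resno", "chain")]
  if (nrow(don) == 0L || nrow(acc) == 0L) return(empty)
  g <- expand.grid(d = seq_len(nrow(don)), a = seq_len(nrow(acc)))
  ok <- don$chain[g$d] != acc$chain[g$a] |
    abs(don$resno[g$d] - acc$resno[g$a]) >= 2L
  g <- g[ok, , drop = FALSE]
  nidx <- vapply(seq_len(nrow(g)), function(u)
    atom_index(at[at$chain == don$chain[g$d[u]], ], don$resno[g$d[u]], "N"), 0L)
  data.frame(h = don$index[g$d], o = acc$index[g$a], n = nidx,
             r_min = hbp$r_min, r_max = hbp$r_max,
             depth = params$w_hb * hbp$eps,
             gate_min = hbp$gate_min, gate_max = hbp$gate_max)
}

# ideal alpha-helix CA-CA distances for offsets 2, 3, 4 (backbone only,
# sequence independent)
helix_ca_distances <- function(geom = load_peptide_geometry()) {
  hx <- geom$conformations$helix
  bb <- build_backbone(rep("ALA", 7L), rep(hx$phi, 7L), rep(hx$psi, 7L), geom)
  ca <- t(vapply(bb, `[[`, numeric(3), "CA"))
  c(d2 = vnorm(ca[3, ] - ca[1, ]),
    d3 = vnorm(ca[4, ] - ca[1, ]),
    d4 = vnorm(ca[5, ] - ca[1, ]))
}

#' Structure-based distance restraints
#'
#' Modes `native`, `freeze` and `relax` generate, for every CA pair in the
#' selection, a range `[d (1 - dR), d (1 + dR)]` around the current distance
#' (dR = 0.05); mode `helix` generates, for every (i, i+2), (i, i+3),
#' (i, i+4) CA pair inside each selected segment, ranges around the ideal
#' alpha-helix distances (dR = 0.08).  Residue ranges are 1-based inclusive.
#'
#' @param coordinates particle coordinate matrix aligned with the topology
#' @param topology a `pacsab_topology`
#' @param selection `NULL` for all residues of all chains, or a list of
#'   `list(chain =, from =, to =)` segments
#' @param mode one of `"native"`, `"freeze"`, `"relax"`, `"helix"`
#' @param delta optional override of the relative half-width
#' @return constraint data.frame (i, j, dmin, dmax, role)
#' @export
make_restraints <- function(coordinates, topology, selection = NULL,
                            mode = c("native", "freeze", "relax", "helix"),
                            delta = NULL) {
  mode <- match.arg(mode)
  at <- topology$atoms
  if (is.null(selection)) {
    selection <- lapply(unique(at$chain), function(ch)
      list(chain = ch, from = min(at$resno[at$chain == ch]),
           to = max(at$resno[at$chain == ch])))
  }
  if (!is.null(selection$chain)) selection <- list(selection)
  for (seg in selection) {
    sel <- at$chain == seg$chain
    if (!any(sel)) stop("chain ", seg$chain, " not found")
    if (seg$from < min(at$resno[sel]) || seg$to > max(at$resno[sel]) ||
        seg$from > seg$to)
      stop("selection ", seg$from, "-", seg$to, " outside chain ", seg$chain)
  }
  role <- switch(mode, native = "native_restraint", relax = "native_restraint",
                 freeze = "freeze", helix = "helix_restraint")
  dR <- if (!is.null(delta)) delta else if (mode == "helix") 0.08 else 0.05

  if (mode == "helix") {
    dh <- helix_ca_distances()
    out <- list()
    for (seg in selection) {
      res <- seg$from:seg$to
      ca <- vapply(res, function(r)
        atom_index(at[at$chain == seg$chain, ], r, "CA"), 0L)
      for (off in 2:4) {
        if (length(res) <= off) next
        d0 <- dh[[paste0("d", off)]]
        ii <- seq_len(length(res) - off)
        out[[length(out) + 1L]] <- data.frame(
          i = ca[ii], j = ca[ii + off],
          dmin = d0 * (1 - dR), dmax = d0 * (1 + dR), role = role)
      }
    }
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    return(res)
  }

  ca_idx <- unlist(lapply(selection, function(seg) {
    vapply(seg$from:seg$to, function(r)
      atom_index(at[at$chain == seg$chain, ], r, "CA"), 0L)
  }))
  if (length(ca_idx) < 2L) stop("selection contains fewer than two residues")
  pr <- utils::combn(ca_idx, 2L)
  d <- sqrt(colSums((t(coordinates[pr[1, ], , drop = FALSE]) -
                     t(coordinates[pr[2, ], , drop = FALSE]))^2))
  data.frame(i = pr[1, ], j = pr[2, ], dmin = d * (1 - dR),
             dmax = d * (1 + dR), role = role)
}
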