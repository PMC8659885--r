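# Trajectory observables: association state, monomer fraction, contact maps,
# radius of gyration, helicity, RMSD, dissociation curves, leader clustering.

mic_delta <- function(d, box_L) {
  if (box_L > 0) d - box_L * round(d / box_L) else d
}

# all minimum-image distances between two coordinate sets (na x nb matrix)
cross_distances <- function(xa, xb, box_L = 0) {
  dx <- mic_delta(outer(xa[, 1], xb[, 1], "-"), box_L)
  dy <- mic_delta(outer(xa[, 2], xb[, 2], "-"), box_L)
  dz <- mic_delta(outer(xa[, 3], xb[, 3], "-"), box_L)
  sqrt(dx * dx + dy * dy + dz * dz)
}

#' Minimum inter-chain distance in a frame
#'
#' Minimum over all inter-chain particle pairs of the minimum-image distance.
#'
#' @param xyz frame coordinates (n x 3)
#' @param topology matching `pacsab_topology`
#' @param chain_a,chain_b chain labels
#' @param box_L periodic box side (0 = open)
#' @return distance in Angstrom
#' @export
min_interchain_distance <- function(xyz, topology, chain_a, chain_b,
                                    box_L = 0) {
  at <- topology$atoms
  ia <- at$index[at$chain == chain_a]
  ib <- at$index[at$chain == chain_b]
  if (!length(ia)) stop("chain ", chain_a, " not found")
  if (!length(ib)) stop("chain ", chain_b, " not found")
  min(cross_distances(xyz[ia, , drop = FALSE], xyz[ib, , drop = FALSE], box_L))
}

as_traj_list <- function(trajectories) {
  if (inherits(trajectories, "pacsab_trajectory")) list(trajectories)
  else trajectories
}

traj_min_dist_series <- function(traj, cutoff = NULL) {
  sys <- traj$system
  ch <- unique(sys$topology$atoms$chain)
  if (length(ch) != 2L)
    stop("association observables need exactly two chains; found ",
         length(ch))
  vapply(seq_len(dim(traj$frames)[3]), function(k)
    min_interchain_distance(frame_xyz(traj, k), sys$topology, ch[1], ch[2],
                            sys$box_L), 0)
}

#' Monomer percentage over time, pooled across replicas
#'
#' A frame's two molecules are counted as a dimer when the minimum
#' inter-chain distance is below `cutoff`, otherwise both are monomers.
#' Frames are pooled into time bins across replicas; empty bins are reported
#' as missing, not as zero.
#'
#' @param trajectories a `pacsab_trajectory` or list of them (matching chains)
#' @param cutoff association cutoff on the minimum inter-chain distance
#'   (Angstrom)
#' @param n_bins number of equal time bins over the common time span
#' @param burn_in fraction of each trajectory discarded before pooling
#' @return data.frame with `time` (bin center), `monomer_pct`, `n_frames`
#' @export
monomer_fraction <- function(trajectories, cutoff = 8, n_bins = 20,
                             burn_in = 0) {
  trajs <- as_traj_list(trajectories)
  recs <- lapply(trajs, function(tr) {
    md <- traj_min_dist_series(tr)
    keep <- tr$times >= burn_in * max(tr$times)
    data.frame(time = tr$times[keep], mono = (md >= cutoff)[keep])
  })
  all <- do.call(rbind, recs)
  breaks <- seq(min(all$time), max(all$time), length.out = n_bins + 1L)
  bin <- findInterval(all$time, breaks, rightmost.closed = TRUE)
  out <- data.frame(time = (breaks[-1] + breaks[-length(breaks)]) / 2,
                    monomer_pct = NA_real_, n_frames = 0L)
  for (b in seq_len(n_bins)) {
    sel <- bin == b
    out$n_frames[b] <- sum(sel)
    if (any(sel)) out$monomer_pct[b] <- 100 * mean(all$mono[sel])
  }
  out
}

#' Stationary monomer percentage
#'
#' Pooled monomer percentage over the stationary part of the trajectories
#' (after discarding the `burn_in` fraction).
#'
#' @inheritParams monomer_fraction
#' @return scalar percentage in [0, 100]
#' @export
stationary_monomer_pct <- function(trajectories, cutoff = 8, burn_in = 0.25) {
  trajs <- as_traj_list(trajectories)
  vals <- unlist(lapply(trajs, function(tr) {
    md <- traj_min_dist_series(tr)
    (md >= cutoff)[tr$times >= burn_in * max(tr$times)]
  }))
  100 * mean(vals)
}

#' Intermolecular residue contact map
#'
#' Entry (p, q) is the fraction of pooled frames in which any particle of
#' residue p of the first chain lies within `cutoff` of any particle of
#' residue q of the second chain (minimum image).
#'
#' @param trajectories a `pacsab_trajectory` or list of them (two chains)
#' @param cutoff contact cutoff (Angstrom)
#' @return a `pacsab_contact_map`: `matrix` (frequencies in [0, 1]), `chains`,
#'   `n_frames`
#' @export
contact_map <- function(trajectories, cutoff = 6.5) {
  trajs <- as_traj_list(trajectories)
  sys <- trajs[[1]]$system
  at <- sys$topology$atoms
  ch <- unique(at$chain)
  if (length(ch) != 2L) stop("contact maps need exactly two chains")
  ia <- at$index[at$chain == ch[1]]; ra <- at$resno[at$chain == ch[1]]
  ib <- at$index[at$chain == ch[2]]; rb <- at$resno[at$chain == ch[2]]
  na <- max(ra); nb <- max(rb)
  acc <- matrix(0, na, nb)
  nf <- 0L
  for (tr in trajs) {
    for (k in seq_len(dim(tr$frames)[3])) {
      xyz <- frame_xyz(tr, k)
      d <- cross_distances(xyz[ia, , drop = FALSE], xyz[ib, , drop = FALSE],
                           sys$box_L)
      hit <- d < cutoff
      if (any(hit)) {
        resmat <- matrix(0, na, nb)
        w <- which(hit, arr.ind = TRUE)
        resmat[cbind(ra[w[, 1]], rb[w[, 2]])] <- 1
        acc <- acc + resmat
      }
      nf <- nf + 1L
    }
  }
  structure(list(matrix = acc / nf, chains = ch, n_frames = nf,
                 cutoff = cutoff),
            class = "pacsab_contact_map")
}

#' @export
print.pacsab_contact_map <- function(x, ...) {
  cat("pacsab_contact_map:", nrow(x$matrix), "x", ncol(x$matrix),
      "residues,", x$n_frames, "frames, max frequency",
      format(max(x$matrix), digits = 3), "\n")
  invisible(x)
}

#' Interface-region mask for a contact map
#'
#' Logical matrix marking the rows/columns of annotated binding-interface
#' segments (1-based inclusive residue ranges), e.g. the beta-sheet face of
#' ubiquitin: residues 4-12, 42-51 and 62-71.
#'
#' @param map a `pacsab_contact_map`
#' @param regions_a,regions_b list of `c(from, to)` ranges per chain (the
#'   second defaults to the first)
#' @return logical matrix, `TRUE` where both residues fall in a region
#' @export
interface_mask <- function(map, regions_a, regions_b = regions_a) {
  inreg <- function(n, regions) {
    m <- rep(FALSE, n)
    for (rg in regions) m[rg[1]:rg[2]] <- TRUE
    m
  }
  outer(inreg(nrow(map$matrix), regions_a), inreg(ncol(map$matrix), regions_b),
        "&")
}

#' Radius of gyration of a chain
#'
#' Mass-weighted radius of gyration over the chain's particles.
#'
#' @param xyz frame coordinates (n x 3)
#' @param topology matching topology
#' @param chain chain label (`NULL`: all particles)
#' @return radius of gyration in nm
#' @export
radius_of_gyration <- function(xyz, topology, chain = NULL) {
  at <- topology$atoms
  sel <- if (is.null(chain)) at$index else at$index[at$chain == chain]
  if (!length(sel)) stop("chain ", chain, " not found")
  m <- at$mass[match(sel, at$index)]
  x <- xyz[sel, , drop = FALSE]
  com <- colSums(x * m) / sum(m)
  rg2 <- sum(m * rowSums(sweep(x, 2, com)^2)) / sum(m)
  sqrt(rg2) / 10
}

hb_geometry_ok <- function(xyz, iH, iO, iN, r_max = 2.6, gate_max = 3.6,
                           box_L = 0) {
  dho <- sqrt(sum(mic_delta(xyz[iH, ] - xyz[iO, ], box_L)^2))
  dno <- sqrt(sum(mic_delta(xyz[iN, ] - xyz[iO, ], box_L)^2))
  dho < r_max && dno < gate_max
}

#' Helical fraction from backbone hydrogen-bond geometry
#'
#' Residue i is helical when the (i, i+4) backbone hydrogen bond
#' (H(i+4)...O(i) < 2.6 Angstrom and N(i+4)...O(i) < 3.6 Angstrom) is formed
#' for i or for i-4; helicity is the helical-residue fraction of the chain.
#'
#' @param xyz frame coordinates
#' @param topology matching topology
#' @param chain chain label (`NULL`: first chain)
#' @param box_L periodic box side
#' @return fraction in [0, 1]
#' @export
helicity <- function(xyz, topology, chain = NULL, box_L = 0) {
  at <- topology$atoms
  if (is.null(chain)) chain <- at$chain[1]
  ach <- at[at$chain == chain, ]
  n <- max(ach$resno)
  if (n < 5L) stop("helicity needs a chain of at least 5 residues")
  bond <- rep(FALSE, n)   # bond[i]: O(i) ... H(i+4) formed
  for (i in seq_len(n - 4L)) {
    iO <- atom_index(ach, i, "O")
    iH <- atom_index(ach, i + 4L, "H")
    iN <- atom_index(ach, i + 4L, "N")
    if (is.na(iH)) next                      # proline: no donor
    bond[i] <- hb_geometry_ok(xyz, iH, iO, iN, box_L = box_L)
  }
  helical <- vapply(seq_len(n), function(i)
    (i <= n - 4L && bond[i]) || (i > 4L && bond[i - 4L]), TRUE)
  mean(helical)
}

#' Helical fraction from backbone dihedrals
#'
#' Alternative criterion: residue i is helical when phi(i) lies in
#' [-100, -30] degrees and psi(i) in [-80, -5] degrees (terminal residues,
#' with only one defined dihedral, use that one).
#'
#' @inheritParams helicity
#' @return fraction in [0, 1]
#' @export
helicity_dihedral <- function(xyz, topology, chain = NULL) {
  at <- topology$atoms
  if (is.null(chain)) chain <- at$chain[1]
  ach <- at[at$chain == chain, ]
  n <- max(ach$resno)
  gx <- function(r, k) xyz[atom_index(ach, r, k), ]
  phi_ok <- rep(NA, n); psi_ok <- rep(NA, n)
  for (i in seq_len(n)) {
    if (i > 1L) {
      phi <- dihedral_deg(gx(i - 1L, "C"), gx(i, "N"), gx(i, "CA"), gx(i, "C"))
      phi_ok[i] <- phi >= -100 && phi <= -30
    }
    if (i < n) {
      psi <- dihedral_deg(gx(i, "N"), gx(i, "CA"), gx(i, "C"), gx(i + 1L, "N"))
      psi_ok[i] <- psi >= -80 && psi <= -5
    }
  }
  hel <- vapply(seq_len(n), function(i) {
    ok <- c(phi_ok[i], psi_ok[i])
    ok <- ok[!is.na(ok)]
    length(ok) > 0L && all(ok)
  }, TRUE)
  mean(hel)
}

#' Optimal-superposition RMSD
#'
#' Least-squares rigid superposition (proper rotation only, Kabsch) computed
#' on `align_sel`, RMSD reported over `measure_sel`.
#'
#' @param xyz frame coordinates (n x 3)
#' @param ref reference coordinates (same layout)
#' @param align_sel particle indices used for the superposition (>= 3,
#'   non-collinear)
#' @param measure_sel particle indices the RMSD is computed over (defaults to
#'   `align_sel`)
#' @return RMSD in Angstrom
#' @export
rmsd <- function(xyz, ref, align_sel, measure_sel = align_sel) {
  if (length(align_sel) < 3L)
    stop("need at least 3 alignment particles")
  A <- ref[align_sel, , drop = FALSE]
  B <- xyz[align_sel, , drop = FALSE]
  ca <- colMeans(A); cb <- colMeans(B)
  A0 <- sweep(A, 2, ca); B0 <- sweep(B, 2, cb)
  sv <- svd(crossprod(B0, A0))
  if (sv$d[2] < 1e-8 * max(sv$d[1], 1))
    stop("degenerate (collinear) alignment set")
  d <- sign(det(sv$u %*% t(sv$v)))
  R <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  M <- sweep(xyz[measure_sel, , drop = FALSE], 2, cb) %*% R
  Mref <- sweep(ref[measure_sel, , drop = FALSE], 2, ca)
  sqrt(mean(rowSums((M - Mref)^2)))
}

#' Dissociation percentage over time
#'
#' Each replica must start bound (minimum inter-chain distance below
#' `cutoff`); at each snapshot time the dissociated percentage is the
#' fraction of replicas whose current frame has minimum inter-chain distance
#' at or above `cutoff`.  Re-binding counts: no monotone smoothing.
#'
#' @param replicas list of `pacsab_trajectory` (two chains, common snapshot
#'   times)
#' @param cutoff association cutoff (Angstrom)
#' @return data.frame with `time` and `dissociated_pct`
#' @export
dissociation_fraction <- function(replicas, cutoff = 8) {
  replicas <- as_traj_list(replicas)
  series <- list()
  for (k in seq_along(replicas)) {
    md <- traj_min_dist_series(replicas[[k]])
    if (md[1] >= cutoff) {
      warning("replica ", k, " does not start bound; excluded")
      next
    }
    series[[length(series) + 1L]] <-
      data.frame(time = replicas[[k]]$times, diss = md >= cutoff)
  }
  if (!length(series)) stop("no replica starts bound")
  nt <- min(vapply(series, nrow, 0L))
  diss <- rowMeans(vapply(series, function(s) s$diss[seq_len(nt)],
                          logical(nt)))
  data.frame(time = series[[1]]$time[seq_len(nt)],
             dissociated_pct = 100 * diss)
}

#' Leader clustering of trajectory frames
#'
#' Frames are visited in order; a frame joins the first cluster whose center
#' is within `rmsd_cutoff` (RMSD aligned and measured on the given
#' selections), otherwise it founds a new cluster.  Centers are recomputed
#' once at the end as the member frame minimizing the mean intra-cluster
#' RMSD; populations are reported in descending order.
#'
#' @param frames list of coordinate matrices, or an n x 3 x F array
#' @param align_sel,measure_sel particle index selections passed to [rmsd()]
#' @param rmsd_cutoff cluster radius (Angstrom)
#' @return a `pacsab_clusters`: `assignments` (frame -> cluster id, relabelled
#'   by descending population), `populations`, `central_frame`
#' @export
cluster_frames <- function(frames, align_sel, measure_sel = align_sel,
                           rmsd_cutoff = 5) {
  if (is.array(frames) && length(dim(frames)) == 3L)
    frames <- lapply(seq_len(dim(frames)[3]), function(k) frames[, , k])
  nf <- length(frames)
  stopifnot(nf >= 1L)
  centers <- integer()
  assign <- integer(nf)
  for (k in seq_len(nf)) {
    placed <- FALSE
    for (c0 in seq_along(centers)) {
      if (rmsd(frames[[k]], frames[[centers[c0]]], align_sel,
               measure_sel) <= rmsd_cutoff) {
        assign[k] <- c0; placed <- TRUE; break
      }
    }
    if (!placed) {
      centers <- c(centers, k)
      assign[k] <- length(centers)
    }
  }
  # recompute centers as medoid frames
  central <- integer(length(centers))
  for (c0 in seq_along(centers)) {
    members <- which(assign == c0)
    if (length(members) == 1L) { central[c0] <- members; next }
    meanr <- vapply(members, function(k)
      mean(vapply(members, function(l)
        if (l == k) 0 else rmsd(frames[[l]], frames[[k]], align_sel,
                                measure_sel), 0)), 0)
    central[c0] <- members[which.min(meanr)]
  }
  pop <- tabulate(assign, nbins = length(centers)) / nf
  ord <- order(pop, decreasing = TRUE)
  relabel <- match(seq_along(centers), ord)
  structure(list(assignments = relabel[assign],
                 populations = pop[ord],
                 central_frame = central[ord]),
            class = "pacsab_clusters")
}

#' @export
print.pacsab_clusters <- function(x, ...) {
  cat("pacsab_clusters:", length(x$populations), "clusters; populations:",
      paste(format(100 * x$populations, digits = 3), collapse = "%, "),
      "%\n")
  invisible(x)
}
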