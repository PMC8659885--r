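# Observables: distances, monomer fraction, contact maps, Rg, RMSD,
# dissociation, clustering.

test_that("minimum inter-chain distance matches brute force", {
  topo <- two_point_topology()
  xyz <- rbind(c(0, 0, 0), c(7, 0, 0))
  expect_equal(min_interchain_distance(xyz, topo, "A", "B"), 7)
  expect_equal(min_interchain_distance(rbind(c(1, 2, 3), c(1, 2, 3)),
                                       topo, "A", "B"), 0)
  expect_error(min_interchain_distance(xyz, topo, "A", "C"), "not found")

  m <- merge_topologies(build_topology("MKV", chain_id = "A"),
                        build_topology("WLE", chain_id = "B"))
  set.seed(31)
  for (rep in 1:5) {
    x <- matrix(runif(3 * nrow(m$atoms), 0, 30), ncol = 3)
    ia <- m$atoms$index[m$atoms$chain == "A"]
    ib <- m$atoms$index[m$atoms$chain == "B"]
    for (bl in c(0, 25)) {
      expect_equal(min_interchain_distance(x, m, "A", "B", box_L = bl),
                   oracle_min_cross_distance(x[ia, ], x[ib, ], bl),
                   tolerance = 1e-12)
    }
  }
})

test_that("monomer fraction is 100/0/50 on constructed trajectories", {
  topo <- two_point_topology()
  far <- function(k) rbind(c(0, 0, 0), c(20, 0, 0))
  near <- function(k) rbind(c(0, 0, 0), c(3, 0, 0))
  mk <- function(gen, nt = 40) {
    fr <- array(0, c(2, 3, nt))
    for (k in 1:nt) fr[, , k] <- gen(k)
    fake_traj(topo, fr, times = seq(0, 39))
  }
  expect_true(all(monomer_fraction(mk(far), cutoff = 8)$monomer_pct == 100))
  expect_true(all(monomer_fraction(mk(near), cutoff = 8)$monomer_pct == 0))
  # bound in exactly half the frames of each bin
  alt <- mk(function(k) if (k %% 2) near(k) else far(k))
  mf <- monomer_fraction(alt, cutoff = 8, n_bins = 10)
  expect_true(all(mf$monomer_pct == 50))
  # monomer + dimer percentages always sum to 100 per bin
  expect_true(all(mf$monomer_pct + (100 - mf$monomer_pct) == 100))
})

test_that("contact maps count residue contacts and stay rigid-invariant", {
  m <- merge_topologies(build_topology("MKV", chain_id = "A"),
                        build_topology("WLE", chain_id = "B"))
  n <- nrow(m$atoms)
  ia2 <- m$atoms$index[m$atoms$chain == "A" & m$atoms$resno == 2 &
                         m$atoms$kind == "CA"]
  ib3 <- m$atoms$index[m$atoms$chain == "B" & m$atoms$resno == 3 &
                         m$atoms$kind == "CA"]
  # far-apart frame: zero matrix
  xa <- extended_chain("MKV")$xyz
  xb <- sweep(extended_chain("WLE")$xyz, 2, c(100, 0, 0), "+")
  x0 <- rbind(xa, xb)
  tr0 <- fake_traj(m, array(x0, c(n, 3, 1)), times = 0)
  cm0 <- contact_map(tr0, cutoff = 6.5)
  expect_true(all(cm0$matrix == 0))
  expect_equal(dim(cm0$matrix), c(3L, 3L))
  # bring exactly one residue pair into contact
  x1 <- x0
  x1[ib3, ] <- x1[ia2, ] + c(0.1, 0, 0)
  tr1 <- fake_traj(m, array(x1, c(n, 3, 1)), times = 0)
  cm1 <- contact_map(tr1, cutoff = 0.3)
  expect_equal(cm1$matrix[2, 3], 1)
  expect_equal(sum(cm1$matrix), 1)
  # rigid transformation leaves the map unchanged
  R <- pacsab:::random_rotation()
  x2 <- sweep(x1 %*% t(R), 2, c(5, -3, 11), "+")
  cm2 <- contact_map(fake_traj(m, array(x2, c(n, 3, 1)), times = 0),
                     cutoff = 2)
  expect_equal(cm2$matrix, cm1$matrix, tolerance = 1e-12)
  # interface-region mask covers exactly the annotated rows/columns
  msk <- interface_mask(cm1, list(c(1, 2)), list(c(3, 3)))
  expect_equal(sum(msk), 2L)
  expect_true(msk[1, 3] && msk[2, 3])
})

test_that("radius of gyration matches the closed forms and the oracle", {
  topo <- two_point_topology()
  expect_equal(radius_of_gyration(rbind(c(1, 1, 1), c(9, 9, 9)), topo, "A"), 0)
  # two unit masses 2 A apart: Rg = 1 A = 0.1 nm
  topo2 <- topo
  topo2$atoms$chain <- "A"
  expect_equal(radius_of_gyration(rbind(c(0, 0, 0), c(2, 0, 0)), topo2, "A"),
               0.1)
  hx <- ideal_helix("MKWLEAV")
  at <- hx$topology$atoms
  expect_equal(radius_of_gyration(hx$xyz, hx$topology, "A"),
               oracle_rg(hx$xyz, at$mass) / 10, tolerance = 1e-12)
})

test_that("RMSD is zero under rigid motion and matches the quaternion oracle", {
  st <- ideal_helix("MKWLEAVI")
  x <- st$xyz
  sel <- which(st$topology$atoms$kind == "CA")
  expect_equal(rmsd(x, x, sel), 0)
  R <- pacsab:::random_rotation()
  moved <- sweep(x %*% t(R), 2, c(3, 4, 5), "+")
  expect_equal(rmsd(moved, x, sel), 0, tolerance = 1e-9)
  set.seed(13)
  for (rep in 1:8) {
    a <- matrix(rnorm(30), 10, 3)
    b <- matrix(rnorm(30), 10, 3)
    expect_equal(rmsd(a, b, 1:10), oracle_rmsd_quaternion(b, a),
                 tolerance = 1e-9)
    expect_equal(rmsd(a, b, 1:10), rmsd(b, a, 1:10), tolerance = 1e-9)
  }
  line <- cbind(1:5, 0, 0)
  expect_error(rmsd(line, line, 1:5), "collinear")
})

test_that("dissociation percentage tracks replicas without smoothing", {
  topo <- two_point_topology()
  mk <- function(dists) {
    nt <- length(dists)
    fr <- array(0, c(2, 3, nt))
    for (k in seq_len(nt)) fr[2, 1, k] <- dists[k]
    fake_traj(topo, fr, times = seq_len(nt) - 1)
  }
  stay <- mk(rep(3, 10))
  leave <- mk(c(3, rep(20, 9)))
  expect_true(all(dissociation_fraction(list(stay, stay))$dissociated_pct == 0))
  half <- dissociation_fraction(list(stay, leave))
  expect_equal(half$dissociated_pct[-1], rep(50, 9))
  single <- dissociation_fraction(list(mk(c(3, 20, 3, 20))))
  expect_true(all(single$dissociated_pct %in% c(0, 100)))
  expect_warning(dissociation_fraction(list(stay, mk(rep(50, 10)))),
                 "does not start bound")
})

test_that("leader clustering recovers constructed conformer groups", {
  st <- ideal_helix("MKWLEAVI")
  ex <- extended_chain("MKWLEAVI")
  sel <- which(st$topology$atoms$kind == "CA")
  jit <- function(x, s) x + matrix(rnorm(length(x), sd = s), ncol = 3)
  set.seed(5)
  frames <- c(lapply(1:6, function(k) jit(st$xyz, 0.05)),
              lapply(1:3, function(k) jit(ex$xyz, 0.05)))
  cl <- cluster_frames(frames, sel, rmsd_cutoff = 3)
  expect_equal(length(cl$populations), 2L)
  expect_equal(cl$populations, c(6, 3) / 9)
  expect_true(cl$central_frame[1] %in% 1:6)
  expect_true(cl$central_frame[2] %in% 7:9)
  expect_equal(sum(cl$populations), 1)
  # identical frames: one cluster, population 1
  cl1 <- cluster_frames(lapply(1:4, function(k) st$xyz), sel, rmsd_cutoff = 1)
  expect_equal(cl1$populations, 1)
  # infinite cutoff: a single cluster
  clI <- cluster_frames(frames, sel, rmsd_cutoff = Inf)
  expect_equal(length(clI$populations), 1L)
})
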