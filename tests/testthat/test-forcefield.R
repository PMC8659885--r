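# Step potentials, channel combination, pair table, hydrogen bonds,
# restraints.

test_that("discretize averages shells and zeroes the cutoff", {
  p <- discretize(function(r) 2.5, 5)
  expect_equal(p$energies, c(2.5, 0))
  p0 <- discretize(function(r) 0, c(2, 4, 6))
  expect_equal(p0$energies, rep(0, 4))
  expect_error(discretize(function(r) 1, c(5, 4)), "increasing")
})

test_that("discretized Lennard-Jones matches an independent quadrature oracle", {
  eps <- 1; sigma <- 4
  lj <- function(r) 4 * eps * ((sigma / r)^12 - (sigma / r)^6)
  radii <- c(4.0, 4.5, 5.2, 6.5, 8.0)
  p <- discretize(lj, radii)
  for (k in 2:5) {
    ora <- oracle_shell_average(lj, radii[k - 1], radii[k])
    expect_equal(p$energies[k], ora, tolerance = 1e-9)
  }
  expect_identical(p$energies[6], 0)
})

test_that("channel combination is shell-wise linear with Inf propagation", {
  a <- step_potential(c(3, 5), c(Inf, -1.0, 0))
  b <- step_potential(c(3, 5), c(Inf, +0.4, 0))
  p11 <- combine_potentials(a, b, ff_params(w_vdw = 1, w_solv = 1))
  expect_equal(p11$energies, c(Inf, -0.6, 0))
  p00 <- combine_potentials(a, b, ff_params(w_vdw = 0, w_solv = 0))
  expect_equal(p00$energies, c(Inf, 0, 0))
  p21 <- combine_potentials(a, b, ff_params(w_vdw = 2, w_solv = 1))
  expect_equal(p21$energies[2] - p11$energies[2], -1.0)  # doubling w_vdw
  # mismatched grids reject unless resampled
  c2 <- step_potential(c(3, 4, 5), c(Inf, -1, -0.5, 0))
  expect_error(combine_potentials(a, c2, ff_params()), "grid")
  pr <- combine_potentials(a, c2, ff_params(), resample = TRUE)
  expect_equal(pr$radii, c(3, 4, 5))
  expect_equal(pr$energies, c(Inf, -2, -1.5, 0))
})

test_that("increasing the vdW weight never weakens attractive shells", {
  topo <- build_topology("LWIV")
  for (w in c(0.5, 1, 2)) {
    p1 <- build_pair_table(topo, ff_params(w_vdw = w))
    p2 <- build_pair_table(topo, ff_params(w_vdw = w * 1.3))
    for (k in seq_along(p1$potentials)) {
      e1 <- p1$potentials[[k]]$energies
      e2 <- p2$potentials[[k]]$energies
      att <- is.finite(e1) & e1 < 0
      expect_true(all(e2[att] <= e1[att] + 1e-12))
    }
  }
})

test_that("the pair table is symmetric and respects locality", {
  topo <- build_topology("KWLE")
  params <- ff_params("new")    # local_scale 1.5
  tab <- build_pair_table(topo, params)
  at <- topo$atoms
  pr <- tab$pairs
  # one potential per unordered (type, type, locality) class
  keyed <- paste(pmin(at$type[pr$i], at$type[pr$j]),
                 pmax(at$type[pr$i], at$type[pr$j]), pr$local)
  expect_true(all(tapply(pr$pot, keyed, function(z) length(unique(z))) == 1L))

  # neutral scaling: local and non-local identical when local_scale = 1
  tab1 <- build_pair_table(topo, ff_params("original"))
  pr1 <- tab1$pairs
  sc <- grepl("^SC", at$kind)
  same_type <- which(sc[pr1$i] & sc[pr1$j])
  for (k in same_type) {
    tk <- paste(pmin(at$type[pr1$i[k]], at$type[pr1$j[k]]),
                pmax(at$type[pr1$i[k]], at$type[pr1$j[k]]))
    mates <- which(vapply(seq_len(nrow(pr1)), function(u)
      paste(pmin(at$type[pr1$i[u]], at$type[pr1$j[u]]),
            pmax(at$type[pr1$i[u]], at$type[pr1$j[u]])) == tk, TRUE))
    expect_equal(length(unique(pr1$pot[mates])), 1L)
  }

  # local scaling multiplies attractive shells by local_scale
  lw <- which(pr$local)[1]
  gw <- which(!pr$local & sc[pr$i] & sc[pr$j] &
                at$type[pr$i] == at$type[pr$i[lw]] &
                at$type[pr$j] == at$type[pr$j[lw]])
  if (length(gw)) {
    el <- tab$potentials[[pr$pot[lw]]]$energies
    eg <- tab$potentials[[pr$pot[gw[1]]]]$energies
    att <- is.finite(eg) & eg < 0
    expect_equal(el[att], 1.5 * eg[att], tolerance = 1e-12)
  }
})

test_that("pairs on different chains never receive local scaling", {
  a <- build_topology("LL", chain_id = "A")
  b <- build_topology("LL", chain_id = "B")
  m <- merge_topologies(a, b)
  tab <- build_pair_table(m, ff_params("new"))
  at <- m$atoms
  pr <- tab$pairs
  inter <- at$chain[pr$i] != at$chain[pr$j]
  expect_true(any(inter))
  expect_true(all(!pr$local[inter]))
})

test_that("hydrogen-bond wells enumerate eligible donor-acceptor pairs", {
  topo <- build_topology("AAAAA")
  hb <- hbond_wells(topo, ff_params())
  # brute force: donors 1..5 (all have H), acceptors 1..5, |i-j| >= 2
  brute <- sum(abs(outer(1:5, 1:5, "-")) >= 2L)
  expect_equal(nrow(hb), brute)
  expect_true(all(abs(topo$atoms$resno[hb$h] - topo$atoms$resno[hb$o]) >= 2L))

  # proline contributes no donor
  hbP <- hbond_wells(build_topology("APAAA"), ff_params())
  expect_equal(nrow(hbP), sum(abs(outer(c(1, 3:5), 1:5, "-")) >= 2L))

  # w_hb = 0 unplugs hydrogen bonding
  expect_equal(nrow(hbond_wells(topo, ff_params(w_hb = 0))), 0L)

  # different chains are always eligible
  m <- merge_topologies(build_topology("AA", chain_id = "A"),
                        build_topology("AA", chain_id = "B"))
  hb2 <- hbond_wells(m, ff_params())
  ch <- m$atoms$chain
  inter <- ch[hb2$h] != ch[hb2$o]
  expect_equal(sum(inter), 2L * 2L * 2L)  # 2 donors x 2 acceptors, both ways
})

test_that("ideal helix geometry sits inside the hydrogen-bond well", {
  hx <- ideal_helix("AAAAAAAAAA")
  topo <- hx$topology
  hb <- hbond_wells(topo, ff_params())
  at <- topo$atoms
  i4 <- abs(at$resno[hb$h] - at$resno[hb$o]) == 4L &
    at$resno[hb$h] > at$resno[hb$o]
  d <- sqrt(rowSums((hx$xyz[hb$h[i4], ] - hx$xyz[hb$o[i4], ])^2))
  g <- sqrt(rowSums((hx$xyz[hb$n[i4], ] - hx$xyz[hb$o[i4], ])^2))
  expect_true(all(d > hb$r_min[i4] & d < hb$r_max[i4]))
  expect_true(all(g > hb$gate_min[i4] & g < hb$gate_max[i4]))
})

test_that("restraint generation has the exact pair counts of each mode", {
  st <- extended_chain("ACDEFGHIKL")
  n <- 10L
  fr <- make_restraints(st$xyz, st$topology, NULL, mode = "freeze")
  expect_equal(nrow(fr), n * (n - 1L) / 2L)
  expect_true(all(fr$role == "freeze"))
  d <- sqrt(rowSums((st$xyz[fr$i, ] - st$xyz[fr$j, ])^2))
  expect_true(all(d > fr$dmin & d < fr$dmax))

  hr <- make_restraints(st$xyz, st$topology,
                        list(chain = "A", from = 3, to = 8), mode = "helix")
  # 14-residue-window analogue: offsets 2, 3, 4 inside a 6-residue segment
  expect_equal(nrow(hr), (6L - 2L) + (6L - 3L) + (6L - 4L))
  ca <- st$topology$atoms$index[st$topology$atoms$kind == "CA"][3:8]
  expect_true(all(hr$i %in% ca & hr$j %in% ca))
  expect_error(make_restraints(st$xyz, st$topology,
                               list(chain = "A", from = 5, to = 11), "helix"),
               "outside")
})
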