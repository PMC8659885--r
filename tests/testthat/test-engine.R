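# Event-driven engine: event prediction, event resolution, thermostat,
# conservation laws, determinism.

test_that("pair-event prediction handles head-on and miss geometries", {
  # head-on: |r| = 10, closing speed 2, next radius 6 -> t = 2
  ev <- predict_pair_event(c(0, 0, 0), c(10, 0, 0), c(0, 0, 0),
                           c(-2, 0, 0), radii = 6)
  expect_equal(ev$time, 2.0, tolerance = 1e-12)
  expect_false(ev$outward)

  # perpendicular motion with impact parameter beyond the outermost radius
  ev2 <- predict_pair_event(c(0, 0, 0), c(10, 8, 0), c(0, 0, 0),
                            c(0, 1, 0), radii = 6)
  expect_identical(ev2$time, Inf)
})

test_that("predicted crossing times match a fine-step integration oracle", {
  set.seed(42)
  radii <- c(2, 3.5, 5, 8)
  for (rep in 1:25) {
    r <- runif(3, -6, 6)
    if (sqrt(sum(r^2)) < 2.2) r <- r * 3
    v <- runif(3, -1, 1)
    ev <- predict_pair_event(c(0, 0, 0), r, c(0, 0, 0), v, radii)
    ora <- oracle_first_crossing(r, v, radii)
    if (is.finite(ora$time)) {
      expect_equal(ev$time, ora$time, tolerance = 1e-8)
    } else {
      expect_identical(ev$time, Inf)
    }
  }
})

test_that("event resolution conserves momentum and handles steps exactly", {
  # equal masses, head-on hard-core bounce: velocities exchange
  out <- execute_collision(c(0, 0, 0), c(2, 0, 0), c(1, 0, 0), c(-1, 0, 0),
                           1, 1, Inf)
  expect_equal(out$vi, c(-1, 0, 0))
  expect_equal(out$vj, c(1, 0, 0))

  # zero step: velocities unchanged, marked as crossed
  out0 <- execute_collision(c(0, 0, 0), c(2, 0, 0), c(0.3, 0.1, 0),
                            c(-0.2, 0, 0.4), 1.5, 2.5, 0)
  expect_true(out0$crossed)
  expect_equal(out0$vi, c(0.3, 0.1, 0))
  expect_equal(out0$vj, c(-0.2, 0, 0.4))

  # capture into a well of depth 1 with mu = 1, radial speed 1:
  # v_r' = sqrt(3), radial kinetic-energy gain exactly 1
  out1 <- execute_collision(c(0, 0, 0), c(2, 0, 0), c(0.5, 0, 0),
                            c(-0.5, 0, 0), 2, 2, -1)
  vr_new <- out1$vj[1] - out1$vi[1]
  expect_equal(abs(vr_new), sqrt(3), tolerance = 1e-12)
  expect_true(out1$crossed)
  # momentum conserved exactly
  expect_equal(2 * out1$vi + 2 * out1$vj, c(0, 0, 0))

  # insufficient energy reflects instead of crossing
  outr <- execute_collision(c(0, 0, 0), c(2, 0, 0), c(0.5, 0, 0),
                            c(-0.5, 0, 0), 2, 2, 5)
  expect_false(outr$crossed)
  expect_equal(outr$vi, c(-0.5, 0, 0))
})

test_that("free flight is ballistic and total_energy is purely kinetic", {
  tp <- square_well_pair(1, 2, 1e-9, box_L = 0)
  tp$system$pair_table$pairs <- tp$system$pair_table$pairs[0, ]
  v0 <- rbind(c(0.3, -0.2, 0.1), c(-0.1, 0.4, 0.2))
  tr <- run_dmd(tp$system, 10, snapshot_interval = 1, ghost_rate = 0,
                seed = 1, vel = v0)
  for (k in seq_along(tr$times)) {
    expect_equal(frame_xyz(tr, k), tp$system$xyz + tr$times[k] * v0,
                 tolerance = 1e-12)
  }
  expect_equal(total_energy(tp$system, vel = v0),
               0.5 * sum(v0^2), tolerance = 1e-12)
})

test_that("total_energy matches a brute-force R evaluation on random states", {
  set.seed(7)
  st <- extended_chain("MKVLW")
  sys <- build_system(st, ff_params())
  for (rep in 1:5) {
    xyz <- st$xyz + matrix(rnorm(length(st$xyz), sd = 0.05), ncol = 3)
    e <- total_energy(sys, xyz = xyz)
    # brute force over the package's own tables, but independent arithmetic
    eb <- 0
    pt <- sys$pair_table
    for (k in seq_len(nrow(pt$pairs))) {
      p <- pt$potentials[[pt$pairs$pot[k]]]
      d <- sqrt(sum((xyz[pt$pairs$i[k], ] - xyz[pt$pairs$j[k], ])^2))
      eb <- eb + p$energies[sum(d > p$radii) + 1L]
    }
    hb <- sys$hbonds
    busy <- rep(FALSE, nrow(xyz))    # saturating bonds, greedy row order
    for (k in seq_len(nrow(hb))) {
      if (busy[hb$h[k]] || busy[hb$o[k]]) next
      d <- sqrt(sum((xyz[hb$h[k], ] - xyz[hb$o[k], ])^2))
      g <- sqrt(sum((xyz[hb$n[k], ] - xyz[hb$o[k], ])^2))
      if (d < hb$r_max[k] && g >= hb$gate_min[k] && g <= hb$gate_max[k]) {
        eb <- eb - hb$depth[k]
        busy[hb$h[k]] <- TRUE
        busy[hb$o[k]] <- TRUE
      }
    }
    for (k in seq_len(nrow(sys$bonds))) {
      d <- sqrt(sum((xyz[sys$bonds$i[k], ] - xyz[sys$bonds$j[k], ])^2))
      if (d < sys$bonds$dmin[k] - 1e-7 || d > sys$bonds$dmax[k] + 1e-7)
        eb <- eb + Inf
    }
    expect_equal(e, eb, tolerance = 1e-12)
  }
})

test_that("a parked pair inside a well reports kinetic minus depth", {
  tp <- square_well_pair(2, 4, 0.5, box_L = 0)
  v <- rbind(c(0.1, 0, 0), c(0, 0.2, 0))
  expect_equal(total_energy(tp$system, vel = v),
               0.5 * (0.01 + 0.04) - 0.5, tolerance = 1e-12)
})

test_that("microcanonical runs conserve energy and momentum", {
  st <- ideal_helix("ACDEFGHIKLMN")
  sys <- build_system(st, ff_params())
  tr <- run_dmd(sys, 40, snapshot_interval = 4, ghost_rate = 0, seed = 5,
                max_events = 5e4)
  drift <- max(abs(tr$energy - tr$energy[1])) / abs(tr$energy[1])
  expect_lt(drift, 1e-10)
  pdrift <- max(abs(sweep(tr$momentum, 2, tr$momentum[1, ])))
  expect_lt(pdrift, 1e-12)
  expect_equal(tr$epot_final_tracked, tr$epot_final_recomputed,
               tolerance = 1e-9)
  expect_equal(unname(tr$event_counts["ghost"]), 0)
})

test_that("the thermostat equilibrates kinetic energy to (3/2) kT", {
  tp <- square_well_pair(3, 5, 1e-9, masses = c(1, 1), box_L = 50)
  tp$system$pair_table$pairs <- tp$system$pair_table$pairs[0, ]
  tr <- run_dmd(tp$system, 20000, snapshot_interval = 2, ghost_rate = 0.5,
                seed = 4, kT = 1.3)
  ke <- mean(tr$kinetic[-(1:100)]) / 2
  expect_equal(ke, 1.5 * 1.3, tolerance = 0.02 * 3)  # ~2% statistical
})

test_that("trajectories are bit-identical under seed, independent of snapshots", {
  st <- extended_chain("MKVL")
  sys <- build_system(st, ff_params())
  a <- run_dmd(sys, 10, snapshot_interval = 1, ghost_rate = 0.3, seed = 9)
  b <- run_dmd(sys, 10, snapshot_interval = 1, ghost_rate = 0.3, seed = 9)
  expect_identical(a$frames, b$frames)
  expect_identical(a$x_final, b$x_final)
  # coarser snapshots do not perturb the trajectory
  c2 <- run_dmd(sys, 10, snapshot_interval = 2, ghost_rate = 0.3, seed = 9)
  expect_identical(c2$frames[, , 2], a$frames[, , 3])
  expect_identical(c2$x_final, a$x_final)
  # different seed diverges
  d <- run_dmd(sys, 10, snapshot_interval = 1, ghost_rate = 0.3, seed = 10)
  expect_false(identical(d$x_final, a$x_final))
})

test_that("hydrogen-bond machinery is inert when unplugged", {
  hx <- ideal_helix("AAAAAAAA")
  sys0 <- build_system(hx, ff_params(w_hb = 0))
  expect_equal(nrow(sys0$hbonds), 0L)
  tr <- run_dmd(sys0, 5, snapshot_interval = 1, ghost_rate = 0, seed = 2)
  expect_equal(unname(tr$event_counts["hbond"]), 0)
})

test_that("overlapping starts are rejected with the pair named", {
  tp <- square_well_pair(3, 5, 1)
  tp$system$xyz <- rbind(c(0, 0, 0), c(1, 0, 0))   # inside the hard core
  expect_error(run_dmd(tp$system, 1, snapshot_interval = 1, seed = 1),
               "forbidden core")
})

test_that("two-body square-well dynamics reproduces the analytic orbit period", {
  tp <- square_well_pair(3, 5, 1, masses = c(2, 3), box_L = 0)
  tr <- run_dmd(tp$system, 100, snapshot_interval = 100, ghost_rate = 0,
                seed = 1, vel = tp$v0, log_events = TRUE)
  tev <- tr$event_log$time
  gaps <- diff(tev)
  # all radial periods equal the closed form to 1e-10
  expect_true(all(abs(gaps - tp$period) < 1e-10))
  # and the closed form agrees with brute-force integration
  r0 <- tp$x0[2, ] - tp$x0[1, ]
  v0 <- tp$v0[2, ] - tp$v0[1, ]
  ora <- oracle_first_crossing(r0, v0, c(tp$sigma, tp$lambda), t_max = 20)
  expect_equal(tev[1], ora$time, tolerance = 1e-8)
})
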