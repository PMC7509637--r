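ff <- default_forcefield()

nve_config <- function(duration, sample = duration, box = 6)
  run_config(box_length = box, duration = duration,
             analysis_window = duration, sample_interval = sample,
             time_scale = 1, ghost_rate = 0)

test_that("velocity initialisation is Maxwell-Boltzmann with zero momentum", {
  n <- 10000L
  pos <- matrix(runif(3 * n, 0, 100), n, 3)
  sys <- make_bead_system(pos, matrix(0, n, 3), rep(50, n),
                          rep("V", n), 100)
  sys <- init_velocities(sys, 300, seed = 4)
  p <- colSums(sys$vel * sys$mass)
  expect_lt(max(abs(p)), 1e-12)
  ke_per_dof <- sum(0.5 * sys$mass * rowSums(sys$vel^2)) / (3 * n)
  kT2 <- 0.0019872041 * 300 / 2
  expect_lt(abs(ke_per_dof - kT2) / kT2, 0.02)
  sys2 <- init_velocities(sys, 300, seed = 4)
  expect_identical(sys$vel, sys2$vel)
})

test_that("pair event times match ballistic closed forms", {
  # head-on hard-core bounce of sidechain beads: t = (d - sigma)/v
  sys <- make_bead_system(rbind(c(1, 1, 1), c(2.5, 1, 1)),
                          rbind(c(0.2, 0, 0), c(0, 0, 0)),
                          c(43, 43), c("A", "A"), 8)
  # A-A well entry first at (1.5-0.65)/0.2, then core at (1.5-0.34)/0.2
  cfg <- nve_config(10, sample = 10, box = 8)
  ev <- next_event(sys, ff, cfg)
  expect_equal(ev$time, (1.5 - 0.65) / 0.2, tolerance = 1e-9)
  expect_equal(ev$kind, "well entry")
  sys2 <- advance(sys, ev, ff, cfg)
  ev2 <- next_event(sys2, ff, cfg)
  expect_equal(ev2$kind, "hardcore bounce")
  # speed increased by the well capture, so arrival is earlier than
  # the bare ballistic estimate
  expect_lt(ev2$time, (1.5 - 0.34) / 0.2)

  # receding beads outside all wells: only the sample tick remains
  sys3 <- make_bead_system(rbind(c(1, 1, 1), c(2.5, 1, 1)),
                           rbind(c(-0.1, 0, 0), c(0.1, 0, 0)),
                           c(43, 43), c("A", "A"), 20)
  cfg3 <- run_config(box_length = 20, duration = 4, analysis_window = 4,
                     sample_interval = 2, time_scale = 1, ghost_rate = 0)
  ev3 <- next_event(sys3, ff, cfg3)
  expect_equal(ev3$kind, "sample")
  expect_equal(ev3$time, 2)

  # thermostat ghosts are scheduled events too
  cfg4 <- run_config(box_length = 20, duration = 50, analysis_window = 50,
                     sample_interval = 50, time_scale = 1, ghost_rate = 2)
  ev4 <- next_event(sys3, ff, cfg4, seed = 5)
  expect_equal(ev4$kind, "thermostat ghost")
})

test_that("three-body event time is the minimum of pairwise closed forms", {
  # brute force: compute all pairwise first-boundary times directly
  pos <- rbind(c(1, 1, 1), c(3.2, 1, 1), c(1, 2.8, 1))
  vel <- rbind(c(0.15, 0.02, 0), c(-0.1, 0, 0), c(0, -0.12, 0))
  sys <- make_bead_system(pos, vel, c(43, 57, 43), c("V", "I", "L"), 12)
  cfg <- nve_config(50, sample = 50, box = 12)
  pair_first <- function(i, j) {
    d <- pos[j, ] - pos[i, ]; w <- vel[j, ] - vel[i, ]
    out <- Inf
    for (R in c(0.34, 0.65)) {
      a <- sum(w^2); b <- 2 * sum(d * w); cc <- sum(d^2) - R^2
      disc <- b^2 - 4 * a * cc
      if (disc >= 0) {
        roots <- (-b + c(-1, 1) * sqrt(disc)) / (2 * a)
        roots <- roots[roots > 1e-12]
        if (length(roots)) out <- min(out, min(roots))
      }
    }
    out
  }
  expected <- min(pair_first(1, 2), pair_first(1, 3), pair_first(2, 3))
  ev <- next_event(sys, ff, cfg)
  expect_equal(ev$time, expected, tolerance = 1e-9)
})

test_that("collision rules conserve momentum and exchange energy exactly", {
  # equal masses, head-on core collision -> velocities exchanged
  sys <- make_bead_system(rbind(c(1, 1, 1), c(1.4, 1, 1)),
                          rbind(c(0.2, 0, 0), c(0, 0, 0)),
                          c(43, 43), c("V", "V"), 8)
  cfg <- nve_config(10, sample = 10, box = 8)
  ev <- next_event(sys, ff, cfg)   # already inside the well: core bounce
  expect_equal(ev$kind, "hardcore bounce")
  sys2 <- advance(sys, ev, ff, cfg)
  expect_equal(sys2$vel[1, ], c(0, 0, 0), tolerance = 1e-12)
  expect_equal(sys2$vel[2, ], c(0.2, 0, 0), tolerance = 1e-12)

  # well capture: radial speed sqrt(v^2 + 4 eps / m) for equal masses
  eps <- sc_depth("V", "V")
  sys <- make_bead_system(rbind(c(1, 1, 1), c(2, 1, 1)),
                          rbind(c(0.05, 0, 0), c(0, 0, 0)),
                          c(43, 43), c("V", "V"), 8)
  ev <- next_event(sys, ff, cfg)
  sys2 <- advance(sys, ev, ff, cfg)
  vr <- sys2$vel[2, 1] - sys2$vel[1, 1]
  expect_equal(abs(vr), sqrt(0.05^2 + 4 * eps / 43), tolerance = 1e-12)
  e0 <- total_energy(sys, ff)$total
  expect_equal(total_energy(sys2, ff)$total, e0, tolerance = 1e-12)

  # escape attempt with insufficient radial energy: reflection
  vr_small <- 0.5 * sqrt(4 * eps / 43)
  sys <- make_bead_system(rbind(c(1, 1, 1), c(1.64, 1, 1)),
                          rbind(c(-vr_small, 0.03, 0), c(0, 0, 0)),
                          c(43, 43), c("V", "V"), 8)
  ev <- next_event(sys, ff, cfg)
  expect_equal(ev$kind, "well exit attempt")
  sys2 <- advance(sys, ev, ff, cfg)
  # tangential relative velocity unchanged, radial reversed
  expect_equal(sys2$vel[1, 2] + sys2$vel[2, 2], 0.03, tolerance = 1e-12)
  d <- sys2$pos[2, ] - sys2$pos[1, ]
  vrad <- sum((sys2$vel[2, ] - sys2$vel[1, ]) * d) / sqrt(sum(d^2))
  expect_lt(vrad, 0)
})

test_that("stale events are refused", {
  sys <- make_bead_system(rbind(c(1, 1, 1), c(2.5, 1, 1)),
                          rbind(c(0.2, 0, 0), c(0, 0, 0)),
                          c(43, 43), c("A", "A"), 8)
  cfg <- nve_config(10, sample = 10, box = 8)
  ev <- next_event(sys, ff, cfg)
  fake <- ev; fake$time <- ev$time + 1
  expect_error(advance(sys, fake, ff, cfg), "stale")
})

test_that("NVE runs conserve energy and momentum; statics never move", {
  frags <- gen_fragment_set(1)
  chains <- with_seed_local(3, {
    out <- list(); acc <- NULL
    for (i in 1:6) {
      p <- crossbeta:::place_chain_random(frags[[1]], 6, acc, chain_id = i)
      acc <- rbind(acc, p$pos); out[[i]] <- p
    }
    out
  })
  sys <- build_system(chains, 6)
  sys <- init_velocities(sys, 300, 11)
  p0 <- colSums(sys$vel * sys$mass)
  cfg <- nve_config(200, sample = 5)
  tr <- run_dmd(sys, ff, cfg, seed = 5)
  expect_gt(tr$n_events, 1e5)
  drift <- max(abs(tr$energies - tr$energies[1])) / abs(tr$energies[1])
  expect_lt(drift, 1e-8)
  p1 <- colSums(tr$final$vel * sys$mass)
  expect_lt(max(abs(p1 - p0)), 1e-10)
  expect_equal(tr$n_inconsistent, 0)
  # bit-for-bit determinism given the seed
  tr2 <- run_dmd(sys, ff, cfg, seed = 5)
  expect_identical(tr$final$pos, tr2$final$pos)
  expect_identical(tr$energies, tr2$energies)

  # frozen chains never move but still scatter and conserve energy
  chains[[6]]$mobile <- FALSE
  syss <- build_system(chains, 6)
  syss <- init_velocities(syss, 300, 11)
  cfgs <- nve_config(50, sample = 5)
  trs <- run_dmd(syss, ff, cfgs, seed = 5)
  static_idx <- which(!syss$mobile)
  expect_identical(trs$final$pos[static_idx, ], syss$pos[static_idx, ])
  drifts <- max(abs(trs$energies - trs$energies[1])) / abs(trs$energies[1])
  expect_lt(drifts, 1e-8)
})

test_that("trajectories match a brute-force small-timestep integrator", {
  # two beads through well entry, core bounce and escape
  sys <- make_bead_system(rbind(c(2, 2, 2), c(3.2, 2.05, 2)),
                          rbind(c(0.12, 0, 0), c(-0.08, 0.01, 0)),
                          c(43, 57), c("V", "I"), 8)
  cfg <- nve_config(10, sample = 0.5, box = 8)
  tr <- run_dmd(sys, ff, cfg, seed = 1)
  or <- oracle_integrate(sys, ff, 10, dt = 2e-4, sample_dt = 0.5)
  for (k in seq_along(tr$frames))
    expect_lt(max(abs(tr$frames[[k]] - or$frames[[k]])), 1e-4)

  # three beads including a bonded dimer
  sys3 <- make_bead_system(rbind(c(2, 2, 2), c(2.26, 2, 2), c(3.4, 2.1, 2)),
                           rbind(c(0.1, 0.02, 0), c(0.05, -0.03, 0),
                                 c(-0.09, 0, 0.01)),
                           c(56, 43, 57), c("BB", "V", "I"), 8)
  sys3 <- add_bond(sys3, 1, 2, 0.24, 0.28)
  tr3 <- run_dmd(sys3, ff, cfg, seed = 1)
  or3 <- oracle_integrate(sys3, ff, 10, dt = 2e-4, sample_dt = 0.5)
  for (k in seq_along(tr3$frames))
    expect_lt(max(abs(tr3$frames[[k]] - or3$frames[[k]])), 1e-4)
})

test_that("the ghost thermostat imposes kT/2 per degree of freedom", {
  n <- 24L
  pos <- as.matrix(expand.grid(x = 1:3, y = 1:4, z = 1:2)) * 1.4
  sys <- make_bead_system(pos, matrix(0, n, 3), rep(60, n),
                          rep("A", n), 6)
  sys <- init_velocities(sys, 300, 2)
  cfg <- run_config(box_length = 6, duration = 2500, analysis_window = 2000,
                    sample_interval = 2, time_scale = 1, ghost_rate = 0.3)
  tr <- run_dmd(sys, ff, cfg, seed = 9, record_frames = FALSE)
  # drop the first fifth as equilibration
  keep <- tr$kinetic[-seq_len(length(tr$kinetic) %/% 5)]
  ke_dof <- mean(keep) / (3 * n)
  kT2 <- 0.0019872041 * 300 / 2
  expect_lt(abs(ke_dof - kT2) / kT2, 0.02)
})

test_that("square-well dimer occupancy matches the two-state Boltzmann ratio", {
  eps <- sc_depth("V", "V")
  box <- 3
  sys <- make_bead_system(rbind(c(1, 1, 1), c(1.8, 1, 1)),
                          matrix(0, 2, 3), c(43, 43), c("V", "V"), box)
  sys <- init_velocities(sys, 300, 42)
  cfg <- run_config(box_length = box, duration = 40000,
                    analysis_window = 40000, sample_interval = 4,
                    time_scale = 1, ghost_rate = 0.2)
  tr <- run_dmd(sys, ff, cfg, seed = 7)
  r <- vapply(tr$frames, function(f) {
    d <- f[2, ] - f[1, ]
    d <- d - box * round(d / box)
    sqrt(sum(d^2))
  }, numeric(1))
  bound <- r < 0.65
  beta <- 1 / (0.0019872041 * 300)
  vw <- 4 * pi / 3 * (0.65^3 - 0.34^3)
  vu <- box^3 - 4 * pi / 3 * 0.65^3
  p_theory <- vw * exp(beta * eps) / (vw * exp(beta * eps) + vu)
  blocks <- split(bound, cut(seq_along(bound), 25))
  bm <- vapply(blocks, mean, numeric(1))
  se <- sd(bm) / sqrt(length(bm))
  expect_lt(abs(mean(bound) - p_theory), 3 * se)
})

test_that("hydrogen bonds form only between aligned backbones", {
  # two parallel extended tripeptides poised just outside the hb well;
  # NVE: captures and escapes must conserve total energy exactly
  a <- build_peptide(sequence_record("a", "GGG"), "extended",
                     origin = c(1, 1, 1))
  b <- build_peptide(sequence_record("b", "GGG"), "extended",
                     origin = c(1, 1, 1.60))
  sys <- build_system(list(a, b), 8)
  sys$vel[4:6, 3] <- -0.05   # drive chain b toward chain a
  cfg <- nve_config(8, sample = 0.25, box = 8)
  tr <- run_dmd(sys, ff, cfg, seed = 1)
  drift <- max(abs(tr$energies - tr$energies[1]))
  expect_lt(drift, 1e-10 * max(1, abs(tr$energies[1])))

  # at 300 K (kT << eps_hb) thermostatted chains stay zipped
  sysT <- init_velocities(sys, 300, 3)
  cfgT <- run_config(box_length = 8, duration = 60, analysis_window = 30,
                     sample_interval = 2, time_scale = 1, ghost_rate = 0.1)
  trT <- run_dmd(sysT, ff, cfgT, seed = 2)
  expect_gt(nrow(trT$final$hb_pairs), 0)

  # perpendicular chains fail the alignment criterion: no bonds form
  bperp <- build_peptide(sequence_record("b", "GGG"), "extended",
                         origin = c(1.38, 0.62, 1.6), axis = c(0, 1, 0),
                         side = c(1, 0, 0))
  sys2 <- build_system(list(a, bperp), 8)
  sys2$vel[4:6, 3] <- -0.05
  tr2 <- run_dmd(sys2, ff, cfg, seed = 1)
  expect_equal(nrow(tr2$final$hb_pairs), 0L)
})

test_that("total energy sums kinetic and step terms", {
  # a single moving bead: E = m v^2 / 2
  sys <- make_bead_system(matrix(c(1, 1, 1), 1, 3),
                          matrix(c(0.3, 0, 0), 1, 3), 50, "V", 8)
  e <- total_energy(sys, ff)
  expect_equal(e$total, 0.5 * 50 * 0.3^2)
  expect_equal(e$potential, 0)

  # a resting dimer inside its well: E = -depth
  sys2 <- make_bead_system(rbind(c(1, 1, 1), c(1.5, 1, 1)),
                           matrix(0, 2, 3), c(43, 43), c("V", "V"), 8)
  e2 <- total_energy(sys2, ff)
  expect_equal(e2$total, -sc_depth("V", "V"))
})
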