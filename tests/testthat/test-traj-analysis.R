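ff <- default_forcefield()

test_that("residue contacts apply the minimum-image cutoff rule", {
  sys <- make_bead_system(rbind(c(1, 1, 1), c(1.5, 1, 1)), matrix(0, 2, 3),
                          c(43, 43), c("V", "V"), 10)
  ct <- residue_contacts(sys, cutoff = 0.65)
  expect_equal(nrow(ct), 1L)
  sys$pos[2, 1] <- 1.70
  expect_equal(nrow(residue_contacts(sys, cutoff = 0.65)), 0L)
  # periodic image: 9.8 nm apart in a 10 nm box is 0.2 nm
  sys$pos[2, 1] <- 1 + 9.8
  expect_equal(nrow(residue_contacts(sys, cutoff = 0.65)), 1L)
  expect_error(residue_contacts(sys, cutoff = 0), "positive")
  # the configured default cutoff is the conventional 0.65 nm
  expect_equal(run_config()$contact_cutoff, 0.65)
  # same-chain pairs are never intermolecular contacts
  sys$chain <- c(1L, 1L); sys$resid <- c(1L, 5L)
  sys$pos[2, 1] <- 1.5
  expect_equal(nrow(residue_contacts(sys, cutoff = 0.65)), 0L)
})

test_that("binding frequency averages frames within replicates first", {
  sysA <- make_bead_system(rbind(c(1, 1, 1), c(1.4, 1, 1)), matrix(0, 2, 3),
                           c(43, 43), c("V", "V"), 10)
  near <- sysA$pos
  far <- near; far[2, 1] <- 5
  bound_all <- make_traj(sysA, list(near, near, near, near))
  unbound_all <- make_traj(sysA, list(far, far, far, far))
  expect_equal(binding_frequency(list(bound_all)), 1)
  expect_equal(binding_frequency(list(unbound_all)), 0)
  # replicate A always bound, replicate B never: two-level average = 0.5
  expect_equal(binding_frequency(list(bound_all, unbound_all)), 0.5)
  # and NOT frame-pooled averaging when replicates have unequal lengths
  bound_short <- make_traj(sysA, list(near))
  expect_equal(binding_frequency(list(bound_short, unbound_all)), 0.5)
})

test_that("single-linkage clusters equal brute-force connected components", {
  # chain of contacts A-B, B-C -> one cluster
  pos <- rbind(c(1, 1, 1), c(1.5, 1, 1), c(2.0, 1, 1), c(5, 5, 5))
  sys <- make_bead_system(pos, matrix(0, 4, 3), rep(43, 4),
                          rep("V", 4), 10)
  cl <- single_linkage_clusters(sys, cutoff = 0.65)
  expect_equal(sort(vapply(cl, length, integer(1))), c(1L, 3L))
  expect_true(list(c(1L, 2L, 3L)) %in% cl)

  # no contacts -> all singletons
  sys2 <- make_bead_system(cbind(seq(1, 17, by = 4), 1, 1),
                           matrix(0, 5, 3), rep(43, 5), rep("V", 5), 20)
  expect_length(single_linkage_clusters(sys2, cutoff = 0.65), 5L)

  # 100 random 20-peptide geometries vs transitive-closure oracle
  for (trial in 1:100) {
    p <- with_seed_local(trial, matrix(runif(60, 0, 4), 20, 3))
    sysr <- make_bead_system(p, matrix(0, 20, 3), rep(43, 20),
                             rep("V", 20), 12)
    got <- single_linkage_clusters(sysr, cutoff = 0.65)
    # oracle: boolean adjacency closure
    adj <- as.matrix(dist(p)) < 0.65
    reach <- adj | diag(20)
    for (k in 1:20) reach <- reach | (reach %*% reach > 0)
    oracle <- unique(apply(reach, 1, function(r) sort(which(r)),
                           simplify = FALSE))
    oracle <- lapply(oracle, function(v) as.integer(unname(v)))
    expect_setequal(lapply(got, as.integer), oracle)
    # partition property: each peptide in exactly one cluster
    expect_equal(sort(unlist(got)), 1:20)
  }
})

test_that("mass-weighted size is sum(n^2)/sum(n), bounded by extremes", {
  expect_equal(mass_weighted_size(rep(1, 10)), 1)
  expect_equal(mass_weighted_size(10), 10)
  expect_equal(mass_weighted_size(c(4, 3, 2, 1)), 3)
  expect_error(mass_weighted_size(integer(0)), "empty")
  # always >= number-weighted mean; equal only for equal sizes
  for (s in 1:20) {
    sizes <- with_seed_local(s, sample(1:6, 5, replace = TRUE))
    expect_gte(mass_weighted_size(sizes), mean(sizes))
  }
  expect_equal(mass_weighted_size(c(3, 3, 3)), 3)
})

test_that("beta content flags hydrogen-bonded extended strands", {
  a <- build_peptide(sequence_record("a", "VIVIVI"), "extended",
                     origin = c(1, 1, 1))
  b <- build_peptide(sequence_record("b", "VIVIVI"), "extended",
                     origin = c(1, 1, 1.5), chain_id = 2)
  sys <- build_system(list(a, b), 10)
  bc <- beta_content(sys, ff = ff)
  interior <- bc$flags$resid %in% 2:5
  expect_true(all(bc$flags$strand[interior]))

  # an isolated coil has no partners: zero beta content
  coil <- build_peptide(sequence_record("c", "VIVIVI"), "coil", seed = 2)
  sysc <- build_system(list(coil), 10)
  expect_equal(beta_content(sysc, ff = ff)$fraction, 0)

  # the ideal nanofibril is almost entirely strand (interior residues)
  fib <- build_nanofibril(sequence_record("s", "VIVIVIVIVI"),
                          center = c(5, 5, 5))
  sysf <- build_system(fib, 12)
  bcf <- beta_content(sysf, ff = ff)
  interior <- bcf$flags$resid %in% 2:9
  expect_gt(mean(bcf$flags$strand[interior]), 0.9)
})

test_that("distance distributions are normalised with prominent peaks", {
  # constant offset -> a single occupied bin, one peak
  sys <- make_bead_system(rbind(c(1, 1, 1), c(4, 1, 1)), matrix(0, 2, 3),
                          c(43, 43), c("V", "V"), 20)
  frames <- replicate(20, sys$pos, simplify = FALSE)
  traj <- make_traj(sys, frames)
  cd <- com_distance_distribution(traj, 1L, 2L)
  expect_equal(sum(cd$probability), 1, tolerance = 1e-9)
  expect_length(cd$peaks, 1L)
  expect_lt(abs(cd$peaks[1] - 3), 0.2)
  expect_error(com_distance_distribution(traj, 1L, 1L), "disjoint")
  expect_error(distance_distribution(1:5, bin_width = 0), "positive")

  # three well-separated mixture components -> three detected peaks
  d <- with_seed_local(8, c(rnorm(400, 2, 0.15), rnorm(400, 5, 0.15),
                            rnorm(400, 8, 0.15)))
  dd <- distance_distribution(d, bin_width = 0.2, prominence = 0.05)
  expect_length(dd$peaks, 3L)
  expect_equal(sort(dd$peaks), c(2, 5, 8), tolerance = 0.15)
})

test_that("binding modes split end, lateral and unbound geometries", {
  rec <- sequence_record("s", "VIVIVIVIVI")
  fib <- build_nanofibril(rec, n_chains = 10, center = c(6, 6, 6))
  probe <- build_peptide(sequence_record("m", "VV"), "extended",
                         chain_id = 11L)
  place_probe <- function(where) {
    cen <- crossbeta:::strand_bb_centroids(fib)
    proj <- cen %*% fib$axis
    target <- switch(where,
      end = cen[which.max(proj), ] + c(0, 0, 0.5),
      mid = cen[which(abs(proj - median(proj)) ==
                      min(abs(proj - median(proj))))[1], ] + c(0, 1.1, 0),
      away = c(1, 1, 1))
    p <- probe
    p$pos <- sweep(p$pos, 2, target - colMeans(p$pos), `+`)
    p
  }
  for (case in list(c("end", "end"), c("mid", "lateral"),
                    c("away", "unbound"))) {
    sys <- build_system(c(fib$chains, list(place_probe(case[1]))), 12,
                        check = FALSE)
    mode <- classify_binding_mode(sys, sys$pos, fib, 11L)
    expect_equal(mode, case[2], label = case[1])
  }
})

test_that("per-residue fibril binding probabilities match a recount oracle", {
  rec <- sequence_record("s", "VIVI")
  fib <- build_nanofibril(rec, n_chains = 4, center = c(4, 4, 4))
  mono <- build_peptide(sequence_record("m", "VV"), "extended",
                        chain_id = 5L)
  frames <- lapply(1:12, function(k) {
    sys0 <- build_system(c(fib$chains, list(mono)), 8, check = FALSE)
    pos <- sys0$pos
    mbeads <- which(sys0$chain == 5)
    shift <- with_seed_local(k, runif(3, 0, 8))
    pos[mbeads, ] <- sweep(pos[mbeads, , drop = FALSE], 2, shift, `+`)
    pos
  })
  sys <- build_system(c(fib$chains, list(mono)), 8, check = FALSE)
  traj <- make_traj(sys, frames)
  got <- per_residue_fibril_binding(traj, 5L, 1:4)
  # oracle: recount contact frames residue by residue
  for (row in seq_len(nrow(got))) {
    cnt <- 0
    for (f in frames) {
      ct <- residue_contacts(sys, f, 0.65)
      hit <- (ct$chain_a == got$chain[row] & ct$res_a == got$resid[row] &
                ct$chain_b == 5) |
             (ct$chain_b == got$chain[row] & ct$res_b == got$resid[row] &
                ct$chain_a == 5)
      cnt <- cnt + any(hit)
    }
    expect_equal(got$probability[row], cnt / length(frames))
  }
  # monomer far away in every frame -> all zeros
  far <- lapply(frames, function(f) {
    f[sys$chain == 5, ] <- rep(c(0.2, 0.2, 0.2), each = sum(sys$chain == 5))
    f
  })
  g0 <- per_residue_fibril_binding(make_traj(sys, far), 5L, 1:4)
  expect_true(all(g0$probability == 0))
})

test_that("contact maps report per-residue-pair frequencies in [0,1]", {
  a <- build_peptide(sequence_record("a", "VIV"), "extended",
                     origin = c(1, 1, 1))
  b <- build_peptide(sequence_record("b", "VIV"), "extended",
                     origin = c(1, 1, 1.5), chain_id = 2)
  sys <- build_system(list(a, b), 10)
  near <- sys$pos
  far <- near; far[sys$chain == 2, 3] <- 8
  traj <- make_traj(sys, list(near, near, far, far))
  cm <- contact_map(traj, 1L, 2L)
  expect_true(all(cm >= 0 & cm <= 1))
  expect_equal(max(cm), 0.5)   # in contact half the frames
  expect_equal(cm["1", "1"], 0.5)
})
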