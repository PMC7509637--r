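tiny_cfg <- function(...) run_config(sample_interval = 1, time_scale = 1,
                                     ...)

test_that("fragment windows tile the sequence with a trailing anchor", {
  r20 <- sequence_record("P", strrep("A", 20))
  frags <- fragment_sequence(r20)
  expect_equal(vapply(frags, `[[`, "", "id"), c("P1-10", "P6-15", "P11-20"))
  expect_equal(vapply(frags, `[[`, 1L, "start_index"), c(1L, 6L, 11L))

  expect_length(fragment_sequence(sequence_record("Q", strrep("A", 10))), 1L)
  expect_error(fragment_sequence(sequence_record("S", "ACDEF")), "shorter")

  # a 250-residue protein: the canonical hotspot windows appear
  r250 <- sequence_record("FapC", strrep("QANV", 63) |> substr(1, 250))
  ids <- vapply(fragment_sequence(r250), `[[`, "", "id")
  expect_true(all(c("FapC41-50", "FapC91-100", "FapC131-140") %in% ids))
  # a 23-mer gets a trailing window anchored at the C-terminus
  ids23 <- vapply(fragment_sequence(sequence_record("R", strrep("A", 23))),
                  `[[`, "", "id")
  expect_equal(tail(ids23, 1), "R14-23")
})

test_that("hotspot scan returns one row per fragment, reproducibly", {
  frags <- gen_fragment_set(1)[1:2]
  cfg <- tiny_cfg(box_length = 6, duration = 10, analysis_window = 5,
                  n_replicates = 2)
  res <- hotspot_scan(frags, sequence_record("t", "VIVID"), cfg, seed = 1)
  expect_equal(nrow(res$table), 2L)
  expect_equal(res$table$fragment_id, c("AMY10", "POL10"))
  expect_true(all(res$table$binding_frequency >= 0 &
                  res$table$binding_frequency <= 1))
  expect_equal(res$table$start, c(1L, 1L))
  res2 <- hotspot_scan(frags, sequence_record("t", "VIVID"), cfg, seed = 1)
  expect_identical(res$table, res2$table)

  # a full sequence is fragmented automatically: rows = fragment count
  seq20 <- sequence_record("P", "VIVIVIVIVIDEKNQDEKNQ")
  res3 <- hotspot_scan(seq20, sequence_record("t", "VIVID"), cfg, seed = 1)
  expect_equal(nrow(res3$table), 3L)

  expect_error(hotspot_scan(frags, abeta42(),
                            tiny_cfg(n_replicates = 1)), "2 replicates")
})

test_that("aggregation obeys peptide-count defaults and repulsive limit", {
  frags <- gen_fragment_set(1)
  # 10-mers default to 10 copies, the 25-mer to 7
  res10 <- aggregation_sim(frags[[1]],
                           config = tiny_cfg(box_length = 12, duration = 2,
                                             analysis_window = 1), seed = 1)
  expect_equal(res10$n_peptides, 10L)
  res25 <- aggregation_sim(frags[[3]],
                           config = tiny_cfg(box_length = 10, duration = 2,
                                             analysis_window = 1), seed = 1)
  expect_equal(res25$n_peptides, 7L)

  # purely repulsive force field: no attraction, no clusters
  ff0 <- default_forcefield(epsilon_hp = 0, epsilon_hb = 0)
  res <- aggregation_sim(frags[[1]], n_peptides = 5,
                         config = tiny_cfg(box_length = 12, duration = 30,
                                           analysis_window = 25),
                         ff = ff0, seed = 2)
  expect_true(all(res$mass_weighted == 1))
  expect_true(all(res$mass_weighted >= 1 &
                  res$mass_weighted <= res$n_peptides))
})

test_that("cross-seeding keeps the fibril static and counts all runs", {
  frags <- gen_fragment_set(1)
  cfg <- tiny_cfg(box_length = 10.5, duration = 20, analysis_window = 10,
                  n_replicates = 2)
  res <- cross_seed_sim(frags[[1]], sequence_record("m", "VIVIDKVIVI"),
                        config = cfg, seed = 3)
  expect_equal(nrow(res$runs), 2L)
  expect_equal(sum(res$mode_counts), 2)
  expect_s3_class(res$com_distribution, "com_distribution")
  expect_true(all(res$residue_binding$probability >= 0 &
                  res$residue_binding$probability <= 1))
  res2 <- cross_seed_sim(frags[[1]], sequence_record("m", "VIVIDKVIVI"),
                         config = cfg, seed = 3)
  expect_identical(res$runs, res2$runs)
})

test_that("fibril beads are identical in the first and last frame", {
  frags <- gen_fragment_set(1)
  cfg <- tiny_cfg(box_length = 10.5, duration = 15, analysis_window = 10)
  centre <- rep(10.5 / 2, 3)
  fibril <- build_nanofibril(frags[[1]], center = centre, box_length = 10.5)
  fib_pos <- do.call(rbind, lapply(fibril$chains, `[[`, "pos"))
  mono <- with_seed_local(5, crossbeta:::place_chain_random(
    sequence_record("m", "VIVID"), 10.5, existing_pos = fib_pos,
    chain_id = 35L, min_gap = 1.5, max_try = 500L))
  sys <- build_system(c(fibril$chains, list(mono)), 10.5)
  sys$hb_pairs <- nanofibril_hb_pairs(fibril, sys, 1:34)
  sys <- init_velocities(sys, 300, 5)
  tr <- run_dmd(sys, default_forcefield(), cfg, seed = 5)
  fib_beads <- which(sys$chain <= 34)
  expect_identical(tr$frames[[1]][fib_beads, ],
                   tr$frames[[length(tr$frames)]][fib_beads, ])
})
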