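test_that("peptides are built with two beads per residue (one for Gly)", {
  p <- build_peptide(sequence_record("x", "AAAA"))
  expect_equal(nrow(p$pos), 8L)
  bb <- p$pos[p$kind == "bb", ]
  # extended backbone spans 3 x 0.38 nm collinearly
  expect_equal(sqrt(sum((bb[4, ] - bb[1, ])^2)), 3 * 0.38, tolerance = 1e-12)
  expect_equal(nrow(build_peptide(sequence_record("g", "G"))$pos), 1L)
  # bond geometry sits inside the wells
  expect_true(all(abs(sqrt(rowSums((bb[-1, ] - bb[-4, ])^2)) - 0.38) < 1e-12))

  c1 <- build_peptide(sequence_record("c", "VIVID"), "coil", seed = 9)
  c2 <- build_peptide(sequence_record("c", "VIVID"), "coil", seed = 9)
  expect_identical(c1$pos, c2$pos)
  c3 <- build_peptide(sequence_record("c", "VIVID"), "coil", seed = 10)
  expect_false(isTRUE(all.equal(c1$pos, c3$pos)))
})

test_that("random placements never violate hard cores", {
  rec <- sequence_record("x", "QWERTYHIK")
  worst <- Inf
  for (s in 1:300) {
    p <- build_peptide(rec, "coil", seed = s)
    n <- nrow(p$pos)
    for (i in seq_len(n - 1)) {
      j <- (i + 1):n
      excl <- abs(p$res_index[j] - p$res_index[i]) <= 1
      d <- sqrt(rowSums(sweep(p$pos[j, , drop = FALSE], 2, p$pos[i, ])^2))
      if (any(!excl)) worst <- min(worst, d[!excl])
    }
  }
  expect_gte(worst, 0.34)
})

test_that("force-field wells deepen monotonically with pair hydropathy", {
  ff <- default_forcefield()
  depth <- function(a, b) -pair_potential(ff, a, b, 0.5)
  expect_gt(depth("V", "V"), depth("D", "D"))
  # full monotonicity across ranked single-residue pairs
  h <- sort(kyte_doolittle())
  dd <- vapply(names(h), function(a) depth(a, a), numeric(1))
  expect_true(all(diff(dd) >= -1e-12))
  # tables: breakpoints increasing, finite range
  for (key in names(ff$tables)) {
    expect_true(all(diff(ff$tables[[key]]$breaks) > 0), label = key)
  }
  expect_equal(pair_potential(ff, "V", "V", 0.66), 0)
  expect_identical(pair_potential(ff, "V", "V", 0.1), Inf)
  # explicit depth normalisation: V-V on the Kyte-Doolittle map
  expect_equal(depth("V", "V"), 1.2 * (4.2 + 4.5) / 9)
  expect_equal(depth("R", "R"), 0) # max(0, .) clamp for hydrophilic pairs
})

test_that("force-field CSV roundtrip preserves tables and rules", {
  ff <- default_forcefield(epsilon_hp = 1.37)
  f <- tempfile(fileext = ".csv")
  write_forcefield(ff, f)
  back <- read_forcefield(f)
  expect_equal(back$hb$epsilon, ff$hb$epsilon)
  expect_equal(back$tables[["V:I"]], ff$tables[["V:I"]])
  expect_equal(back$tables[["BB:BB"]]$breaks, ff$tables[["BB:BB"]]$breaks)
})

test_that("nanofibril builder realises the requested cross-beta geometry", {
  rec <- sequence_record("seed", "VIVIVIVIVI")
  fib <- build_nanofibril(rec)
  expect_length(fib$chains, 34L)
  expect_equal(fib$strands_per_sheet, 17L)
  expect_false(any(vapply(fib$chains, `[[`, logical(1), "mobile")))
  g <- measure_fibril_geometry(fib)
  expect_equal(unname(g["interstrand"]), 4.7, tolerance = 1e-9)
  expect_equal(unname(g["intersheet"]), 9.6, tolerance = 1e-9)

  # measurement inverts construction for non-default spacings
  fib2 <- build_nanofibril(rec, n_chains = 6, interstrand = 5.0,
                           intersheet = 10.2)
  g2 <- measure_fibril_geometry(fib2)
  expect_equal(unname(g2["interstrand"]), 5.0, tolerance = 1e-9)
  expect_equal(unname(g2["intersheet"]), 10.2, tolerance = 1e-9)

  # 2 chains: one strand per sheet -> axial gap measurement impossible
  expect_error(measure_fibril_geometry(build_nanofibril(rec, n_chains = 2)),
               "two strands")
  expect_error(build_nanofibril(rec, n_chains = 7), "even")
  expect_error(build_nanofibril(sequence_record("long", strrep("A", 16))),
               "<= 15")
  expect_error(build_nanofibril(rec, n_chains = 34, box_length = 6),
               "exceeds the box")
})

test_that("fibril hydrogen-bond saturation leaves only terminal strands open", {
  rec <- sequence_record("seed", "VIVIVIVIVI")
  fib <- build_nanofibril(rec, n_chains = 8)
  sys <- build_system(fib, box_length = 10.5)
  hbp <- nanofibril_hb_pairs(fib, sys)
  # per sheet: (strands - 1) x residues bonds
  expect_equal(nrow(hbp), 2 * 3 * 10)
  counts <- table(c(hbp[, 1], hbp[, 2]) + 1L)
  per_chain <- tapply(as.integer(counts), sys$chain[as.integer(names(counts))],
                      sum)
  term <- terminal_strands_for_tests(fib)
  expect_true(all(per_chain[as.character(term)] == 10))
  expect_true(all(per_chain[setdiff(names(per_chain),
                                    as.character(term))] == 20))
})
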