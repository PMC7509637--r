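# The three simulation campaigns: fragment hotspot scanning against a target
# monomer, multi-peptide self-assembly, and cross-seeding of a free monomer
# by a static preformed nanofibril. Each campaign is reproducible
# bit-for-bit given (config, seed); per-replicate seeds are derived from the
# campaign seed by fixed offsets.

#' Divide a sequence into overlapping fragments
#'
#' Fragments of `window` residues starting every `step` residues; when the
#' arithmetic progression does not reach the C-terminus, a final window
#' anchored at `length - window + 1` is appended so no residue is dropped.
#' Fragment ids carry absolute residue ranges (via the record's
#' `start_index`), e.g. `FapC41-50`.
#'
#' @param record a [sequence_record()].
#' @param window fragment length in residues (default 10).
#' @param step offset between fragment starts (default 5, i.e. five
#'   overlapping residues for 10-mers).
#' @return A list of [sequence_record()] fragments.
#' @examples
#' frags <- fragment_sequence(sequence_record("P", strrep("A", 20)))
#' sapply(frags, `[[`, "id")
#' @export
fragment_sequence <- function(record, window = 10L, step = 5L) {
  L <- seq_length(record)
  if (L < window)
    stop("sequence shorter (", L, ") than the fragment window (", window, ")")
  starts <- seq(1L, L - window + 1L, by = step)
  if (tail(starts, 1L) + window - 1L < L) starts <- c(starts, L - window + 1L)
  lapply(starts, function(s) {
    abs_start <- record$start_index + s - 1L
    abs_end <- abs_start + window - 1L
    sequence_record(sprintf("%s%d-%d", record$id, abs_start, abs_end),
                    substr(record$residues, s, s + window - 1L),
                    start_index = abs_start)
  })
}

# random rotation matrix (uniform over SO(3), via a random quaternion)
random_rotation <- function() {
  q <- rnorm(4)
  q <- q / sqrt(sum(q^2))
  a <- q[1]; b <- q[2]; c <- q[3]; d <- q[4]
  matrix(c(a^2 + b^2 - c^2 - d^2, 2 * (b * c - a * d), 2 * (b * d + a * c),
           2 * (b * c + a * d), a^2 - b^2 + c^2 - d^2, 2 * (c * d - a * b),
           2 * (b * d - a * c), 2 * (c * d + a * b),
           a^2 - b^2 - c^2 + d^2), 3, 3)
}

# place a coil-built peptide at a random position/orientation such that all
# beads keep min_gap from existing beads (minimum image); bounded retries
place_chain_random <- function(record, box, existing_pos = NULL,
                               chain_id = 1L, min_gap = 0.36,
                               max_try = 200L,
                               conformation = c("coil", "extended")) {
  conformation <- match.arg(conformation)
  for (try in seq_len(max_try)) {
    p <- build_peptide(record, conformation,
                       seed = floor(runif(1) * 2^31),
                       chain_id = chain_id)
    rot <- random_rotation()
    pos <- p$pos %*% rot
    pos <- sweep(pos, 2, runif(3) * box, `+`)
    ok <- TRUE
    if (!is.null(existing_pos) && nrow(existing_pos)) {
      for (i in seq_len(nrow(pos))) {
        d <- sweep(existing_pos, 2, pos[i, ], `-`)
        d <- d - box * round(d / box)
        if (min(rowSums(d^2)) < min_gap^2) { ok <- FALSE; break }
      }
    }
    if (ok) { p$pos <- pos; return(p) }
  }
  stop("failed to place chain '", record$id, "' after ", max_try,
       " attempts; box too crowded")
}

# assemble, thermalise and run one simulation; returns the trajectory
run_campaign_sim <- function(chains, ff, config, seed,
                             record_frames = TRUE) {
  sys <- build_system(chains, config$box_length)
  sys <- init_velocities(sys, config$temperature, seed)
  run_dmd(sys, ff, config, seed = seed, record_frames = record_frames)
}

#' Fragment hotspot scan against a target monomer
#'
#' For every fragment of `full_seq` (or every record of a supplied fragment
#' list), runs `config$n_replicates` independent two-molecule binding
#' simulations -- one fragment copy plus one free target monomer at random
#' positions, orientations and velocities -- and summarises, over the
#' trailing analysis window, the binding frequency (frames-then-replicates
#' averaging), the mean beta fraction, and the fragment-vs-target contact
#' frequency map.
#'
#' @param full_seq a [sequence_record()] to fragment, or a list of
#'   fragment records used as-is.
#' @param target the target monomer record (e.g. [abeta42()]).
#' @param config a [run_config()]; the classic protocol is an 8 nm box,
#'   200 ns runs with the last 150 ns analysed, 20 replicates.
#' @param ff a `forcefield`.
#' @param seed campaign seed; replicate r of fragment f runs with seed
#'   `seed + 7919*r + 104729*f`.
#' @return A `hotspot_scan_result`: `table` (one row per fragment:
#'   `fragment_id`, `start`, `end`, `binding_frequency`, `beta_fraction`),
#'   `contact_maps` (per fragment, averaged over replicates) and
#'   `bound_fractions` (per fragment, per replicate).
#' @export
hotspot_scan <- function(full_seq, target, config = run_config(),
                         ff = default_forcefield(),
                         seed = config$rng_seed) {
  validate_config(config)
  if (config$n_replicates < 2L)
    stop("hotspot scan needs at least 2 replicates")
  fragments <- if (inherits(full_seq, "sequence_record"))
    fragment_sequence(full_seq) else full_seq
  rows <- list(); maps <- list(); bfs <- list()
  for (f in seq_along(fragments)) {
    frag <- fragments[[f]]
    bf <- numeric(config$n_replicates)
    beta <- numeric(config$n_replicates)
    cmap <- NULL
    for (r in seq_len(config$n_replicates)) {
      rs <- seed + 7919L * r + 104729L * f
      chains <- with_seed(rs, {
        c1 <- place_chain_random(frag, config$box_length, chain_id = 1L,
                                 conformation = "extended")
        c2 <- place_chain_random(target, config$box_length,
                                 existing_pos = c1$pos, chain_id = 2L,
                                 conformation = "extended")
        list(c1, c2)
      })
      traj <- run_campaign_sim(chains, ff, config, rs)
      bf[r] <- bound_fraction(traj, 1L, 2L)
      idx <- analysis_frames(traj)
      beta[r] <- mean(vapply(idx, function(k)
        beta_content(traj$system, traj$frames[[k]], ff)$fraction,
        numeric(1)))
      cm <- contact_map(traj, 1L, 2L)
      cmap <- if (is.null(cmap)) cm else cmap + cm
    }
    rows[[f]] <- data.frame(
      fragment_id = frag$id, start = frag$start_index,
      end = frag$start_index + seq_length(frag) - 1L,
      binding_frequency = mean(bf), beta_fraction = mean(beta))
    maps[[frag$id]] <- cmap / config$n_replicates
    bfs[[frag$id]] <- bf
  }
  structure(list(table = do.call(rbind, rows), contact_maps = maps,
                 bound_fractions = bfs, config = config, seed = seed),
            class = "hotspot_scan_result")
}

#' @export
print.hotspot_scan_result <- function(x, ...) {
  cat("<hotspot_scan_result>\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Multi-peptide self-assembly simulation
#'
#' Places `n_peptides` copies of a fragment at random non-overlapping
#' positions and orientations and follows their aggregation, reporting
#' single-linkage cluster statistics and beta content over the trailing
#' analysis window. The classic protocol uses 10 copies of each 10-mer (7
#' for a 25-mer) in a 12 nm box for 350 ns with the last 100 ns analysed;
#' the default `n_peptides` follows that rule (7 when the fragment has 20+
#' residues, else 10).
#'
#' @param fragment a [sequence_record()].
#' @param n_peptides number of copies.
#' @param config a [run_config()].
#' @param ff a `forcefield`.
#' @param seed simulation seed.
#' @param record_frames keep frames (needed for downstream analysis).
#' @return An `aggregation_result`: `times`, `mass_weighted` (time series),
#'   `beta_fraction` (time series), `final_mass_weighted`,
#'   `mass_weighted_mean`, `beta_mean`, `final` snapshot, `trajectory`.
#' @export
aggregation_sim <- function(fragment,
                            n_peptides = if (seq_length(fragment) >= 20L)
                              7L else 10L,
                            config = run_config(box_length = 12,
                                                duration = 350,
                                                analysis_window = 100,
                                                n_replicates = 10),
                            ff = default_forcefield(),
                            seed = config$rng_seed,
                            record_frames = TRUE) {
  validate_config(config)
  if (n_peptides < 2L) stop("need at least 2 peptides")
  chains <- with_seed(seed, {
    out <- list()
    pos_acc <- NULL
    for (i in seq_len(n_peptides)) {
      p <- place_chain_random(fragment, config$box_length,
                              existing_pos = pos_acc, chain_id = i)
      pos_acc <- rbind(pos_acc, p$pos)
      out[[i]] <- p
    }
    out
  })
  traj <- run_campaign_sim(chains, ff, config, seed)
  idx <- analysis_frames(traj)
  cs <- cluster_stats(traj)
  beta <- vapply(idx, function(k)
    beta_content(traj$system, traj$frames[[k]], ff)$fraction, numeric(1))
  structure(list(
    times = traj$times[idx],
    mass_weighted = cs$mass_weighted,
    beta_fraction = beta,
    final_mass_weighted = tail(cs$mass_weighted, 1L),
    mass_weighted_mean = cs$mass_weighted_mean,
    beta_mean = mean(beta),
    final = traj$final, trajectory = traj,
    n_peptides = n_peptides, config = config, seed = seed),
    class = "aggregation_result")
}

#' @export
print.aggregation_result <- function(x, ...) {
  cat(sprintf(paste0("<aggregation_result> %d peptides; mass-weighted size ",
                     "%.3g (final %.3g); beta fraction %.3g\n"),
              x$n_peptides, x$mass_weighted_mean, x$final_mass_weighted,
              x$beta_mean))
  invisible(x)
}

#' Cross-seeding simulation campaign
#'
#' Builds the static double-layer nanofibril of `fibril_seq` (34 strands by
#' default) at the box centre and runs `config$n_replicates` independent
#' simulations in which a free target monomer, initially placed at a uniform
#' random position at least 1.5 nm from any fibril bead, diffuses and
#' interacts with the frozen template. The classic protocol is a 10.5 nm
#' box, 450 ns runs with the last 50 ns analysed, 10 replicates. Reports
#' per-run binding and final binding mode (end/lateral/intermediate/
#' unbound), the pooled monomer-fibril centre-of-mass distance distribution,
#' and per-residue fibril binding probabilities.
#'
#' @param fibril_seq the fibril-forming fragment record (<= 15 residues).
#' @param target the free monomer record.
#' @param config a [run_config()].
#' @param ff a `forcefield`.
#' @param seed campaign seed; run r uses seed `seed + 7919*r`.
#' @param n_chains fibril strand count (even; default 34).
#' @param min_gap minimum initial monomer-fibril bead distance (nm).
#' @return A `cross_seed_result`: `runs` data frame (`run`, `seed`, `bound`,
#'   `mode`), `mode_counts`, `n_bound`, `com_distribution`,
#'   `residue_binding`, plus the `fibril` used.
#' @export
cross_seed_sim <- function(fibril_seq, target,
                           config = run_config(box_length = 10.5,
                                               duration = 900,
                                               analysis_window = 50,
                                               n_replicates = 10),
                           ff = default_forcefield(),
                           seed = config$rng_seed, n_chains = 34L,
                           min_gap = 1.5) {
  validate_config(config)
  centre <- rep(config$box_length / 2, 3)
  fibril <- build_nanofibril(fibril_seq, n_chains = n_chains,
                             center = centre,
                             box_length = config$box_length)
  fib_pos <- do.call(rbind, lapply(fibril$chains, `[[`, "pos"))
  n_fib <- length(fibril$chains)
  monomer_chain <- n_fib + 1L
  runs <- list(); com_d <- list(); res_bind <- NULL
  for (r in seq_len(config$n_replicates)) {
    rs <- seed + 7919L * r
    chains <- with_seed(rs, {
      mono <- place_chain_random(target, config$box_length,
                                 existing_pos = fib_pos,
                                 chain_id = monomer_chain,
                                 min_gap = min_gap, max_try = 500L,
                                 conformation = "extended")
      c(fibril$chains, list(mono))
    })
    sys <- build_system(chains, config$box_length)
    # saturate the fibril's internal donors/acceptors: only terminal-strand
    # backbones remain available to the monomer
    sys$hb_pairs <- nanofibril_hb_pairs(fibril, sys, seq_len(n_fib))
    sys <- init_velocities(sys, config$temperature, rs)
    traj <- run_dmd(sys, ff, config, seed = rs)
    idx <- analysis_frames(traj)
    bound <- bound_fraction(traj, monomer_chain, seq_len(n_fib)) > 0
    mode <- classify_binding_mode(traj$system,
                                  traj$frames[[length(traj$frames)]],
                                  fibril, monomer_chain, seq_len(n_fib),
                                  cutoff = config$contact_cutoff)
    com_d[[r]] <- vapply(idx, function(k) {
      dv <- group_com(traj$system, traj$frames[[k]], monomer_chain) -
        group_com(traj$system, traj$frames[[k]], seq_len(n_fib))
      dv <- dv - config$box_length * round(dv / config$box_length)
      sqrt(sum(dv^2))
    }, numeric(1))
    rb <- per_residue_fibril_binding(traj, monomer_chain, seq_len(n_fib),
                                     cutoff = config$contact_cutoff)
    res_bind <- if (is.null(res_bind)) rb else {
      rb2 <- res_bind
      rb2$probability <- rb2$probability + rb$probability
      rb2
    }
    runs[[r]] <- data.frame(run = r, seed = rs, bound = bound, mode = mode)
  }
  res_bind$probability <- res_bind$probability / config$n_replicates
  runs <- do.call(rbind, runs)
  modes <- factor(runs$mode,
                  levels = c("end", "lateral", "intermediate", "unbound"))
  structure(list(
    runs = runs, mode_counts = table(modes), n_bound = sum(runs$bound),
    com_distribution = distance_distribution(unlist(com_d)),
    residue_binding = res_bind, fibril = fibril,
    config = config, seed = seed), class = "cross_seed_result")
}

#' @export
print.cross_seed_result <- function(x, ...) {
  cat(sprintf("<cross_seed_result> %d/%d runs bound; modes: %s\n",
              x$n_bound, nrow(x$runs),
              paste(names(x$mode_counts), as.integer(x$mode_counts),
                    sep = "=", collapse = " ")))
  invisible(x)
}
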