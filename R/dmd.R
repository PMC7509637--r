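# R-side interface to the event-driven engine: system assembly, velocity
# initialisation, full runs, single-event stepping and energy accounting.
# Units: length nm, energy kcal/mol, mass amu; the derived reduced time unit
# corresponds to ~0.49 ps, and run_config$time_scale maps the configured
# "protocol ns" onto reduced time.

#' Assemble peptides into a simulation system
#'
#' Merges coarse-grained chains (see [build_peptide()], [build_nanofibril()])
#' into a single periodic-box system for the DMD engine, building the bond
#' table (backbone-backbone wells \[0.36, 0.40\] nm, backbone-sidechain
#' \[0.24, 0.28\] nm) and validating that no non-bonded beads overlap their
#' hard cores.
#'
#' @param chains a list of `cg_peptide` objects, a single one, or a
#'   `nanofibril` (whose chains are all static); mixed lists are allowed.
#' @param box_length cubic box edge (nm).
#' @param check logical; verify hard-core constraints at assembly.
#' @return A `dmd_system` holding bead coordinates, velocities, masses,
#'   classes, chain/residue topology, bonds and the (initially empty)
#'   hydrogen-bond state.
#' @export
build_system <- function(chains, box_length, check = TRUE) {
  if (inherits(chains, "cg_peptide")) chains <- list(chains)
  if (inherits(chains, "nanofibril")) chains <- chains$chains
  chains <- unlist(lapply(chains, function(ch) {
    if (inherits(ch, "nanofibril")) ch$chains else list(ch)
  }), recursive = FALSE)
  pos <- do.call(rbind, lapply(chains, `[[`, "pos"))
  vel <- do.call(rbind, lapply(chains, `[[`, "vel"))
  mass <- unlist(lapply(chains, `[[`, "mass"))
  kind <- unlist(lapply(chains, `[[`, "kind"))
  resid <- unlist(lapply(chains, `[[`, "res_index"))
  nb <- vapply(chains, function(ch) nrow(ch$pos), integer(1))
  chain <- rep(seq_along(chains), nb)
  mobile <- rep(vapply(chains, `[[`, logical(1), "mobile"), nb)
  res_letter <- unlist(lapply(chains, function(ch)
    strsplit(ch$residues, "")[[1]][ch$res_index]))
  clazz <- ifelse(kind == "bb", 0L, match(res_letter, .canonical_aa))

  # bonds and backbone neighbour maps (0-based for the engine)
  bonds <- NULL
  bbprev <- rep(-1L, nrow(pos)); bbnext <- rep(-1L, nrow(pos))
  offset <- 0L
  for (ci in seq_along(chains)) {
    ch <- chains[[ci]]
    nres <- max(ch$res_index)
    bb_idx <- offset + which(ch$kind == "bb")  # 1-based global, by residue
    for (r in seq_len(nres)) {
      beads <- offset + which(ch$res_index == r)
      bb <- beads[ch$kind[beads - offset] == "bb"]
      sc <- beads[ch$kind[beads - offset] == "sc"]
      if (length(sc))
        bonds <- rbind(bonds, c(bb, sc, .bond_sc))
      if (r < nres) {
        bb2 <- offset + which(ch$res_index == r + 1 &
                              ch$kind == "bb")
        bonds <- rbind(bonds, c(bb, bb2, .bond_bb))
        bbnext[bb] <- bb2 - 1L
        bbprev[bb2] <- bb - 1L
      }
    }
    offset <- offset + nrow(ch$pos)
  }
  if (is.null(bonds)) bonds <- matrix(numeric(0), 0, 4)
  chain_info <- data.frame(
    chain_id = seq_along(chains),
    residues = vapply(chains, `[[`, character(1), "residues"),
    start_index = vapply(chains, `[[`, integer(1), "start_index"),
    mobile = vapply(chains, `[[`, logical(1), "mobile"))
  sys <- structure(list(
    pos = unname(pos), vel = unname(vel), mass = unname(mass),
    mobile = mobile, clazz = as.integer(clazz), chain = as.integer(chain),
    resid = as.integer(resid), res_letter = res_letter, kind = kind,
    bbprev = bbprev, bbnext = bbnext,
    bonds = matrix(as.integer(bonds[, 1:2, drop = FALSE] - 1L), ncol = 2),
    bond_rmin = as.numeric(bonds[, 3]), bond_rmax = as.numeric(bonds[, 4]),
    hb_pairs = matrix(integer(0), 0, 2),
    box_length = box_length, time = 0,
    chain_info = chain_info,
    labels = paste0(kind, chain, ".", resid)), class = "dmd_system")
  if (check) check_system(sys)
  sys
}

#' @export
print.dmd_system <- function(x, ...) {
  cat(sprintf(paste0("<dmd_system> %d beads, %d chains (%d mobile), ",
                     "box %.3g nm, t = %.4g\n"),
              nrow(x$pos), nrow(x$chain_info), sum(x$chain_info$mobile),
              x$box_length, x$time))
  invisible(x)
}

# hard-core / bond-well validation (assembly-time invariant)
check_system <- function(sys, tol = 1e-7) {
  n <- nrow(sys$pos)
  excl <- function(i, j)
    sys$chain[i] == sys$chain[j] & abs(sys$resid[i] - sys$resid[j]) <= 1
  # pairwise distances under minimum image, vectorised per bead
  L <- sys$box_length
  for (i in seq_len(n - 1)) {
    j <- (i + 1):n
    d <- sweep(sys$pos[j, , drop = FALSE], 2, sys$pos[i, ], `-`)
    d <- d - L * round(d / L)
    r <- sqrt(rowSums(d^2))
    bad <- r < 2 * .hardcore_radius - tol & !excl(i, j)
    if (any(bad))
      stop("hard-core overlap between bead ", i, " and bead ",
           j[which(bad)[1]], " (r = ", signif(r[which(bad)[1]], 3), " nm)")
  }
  invisible(sys)
}

# compile a forcefield into the flat table layout the engine consumes
compile_forcefield <- function(ff) {
  classes <- ff$classes
  ncl <- length(classes)
  breaks <- vector("list", ncl * ncl)
  energies <- vector("list", ncl * ncl)
  for (a in seq_len(ncl)) for (b in seq_len(ncl)) {
    key1 <- paste(classes[a], classes[b], sep = ":")
    key2 <- paste(classes[b], classes[a], sep = ":")
    tab <- ff$tables[[key1]]
    if (is.null(tab)) tab <- ff$tables[[key2]]
    if (is.null(tab)) stop("no table for pair ", key1)
    idx <- (a - 1) * ncl + (b - 1) + 1
    breaks[[idx]] <- as.numeric(tab$breaks)
    energies[[idx]] <- as.numeric(tab$energies)
  }
  list(n_class = ncl, breaks = breaks, energies = energies,
       hb_rmin = ff$hb$rmin, hb_rmax = ff$hb$rmax, hb_eps = ff$hb$epsilon,
       hb_align_deg = ff$hb$align_deg,
       hb_max_per_bead = as.integer(ff$hb$max_per_bead),
       hb_min_seq_sep = as.integer(ff$hb$min_seq_sep))
}

# fields the C++ layer needs, in its expected types
prep_sys <- function(sys) {
  list(pos = sys$pos, vel = sys$vel, mass = sys$mass, mobile = sys$mobile,
       clazz = sys$clazz, chain = sys$chain, resid = sys$resid,
       bbprev = as.integer(sys$bbprev), bbnext = as.integer(sys$bbnext),
       bonds = sys$bonds, bond_rmin = sys$bond_rmin,
       bond_rmax = sys$bond_rmax, hb_pairs = sys$hb_pairs,
       box_length = sys$box_length, time = sys$time)
}

#' Draw Maxwell-Boltzmann velocities
#'
#' Assigns velocities to all mobile beads from the Maxwell-Boltzmann
#' distribution at the given temperature and removes the net momentum of the
#' mobile subsystem (static beads keep zero velocity).
#'
#' @param sys a `dmd_system`.
#' @param temperature target temperature (K).
#' @param seed integer RNG seed; the draw is a pure function of it.
#' @return The system with velocities set.
#' @export
init_velocities <- function(sys, temperature, seed) {
  stopifnot(all(sys$mass > 0))
  mob <- which(sys$mobile)
  if (!length(mob)) return(sys)
  sd_i <- sqrt(.kB * temperature / sys$mass[mob])
  v <- with_seed(seed, matrix(rnorm(3 * length(mob)), ncol = 3) * sd_i)
  p_tot <- colSums(v * sys$mass[mob])
  v <- sweep(v, 2, p_tot / sum(sys$mass[mob]), `-`)
  sys$vel[mob, ] <- v
  sys
}

run_opts <- function(sys, config, seed, record_frames = TRUE) {
  list(seed = as.numeric(seed),
       temperature = config$temperature,
       ghost_rate = config$ghost_rate,
       sample_dt = config$sample_interval * config$time_scale,
       t_end = sys$time + config$duration * config$time_scale,
       skin = 0.3,
       max_events_per_sample = 5e7,
       record_frames = record_frames)
}

#' Run an event-driven DMD simulation
#'
#' Propagates the system exactly between potential discontinuities until
#' `config$duration` (protocol ns, mapped to reduced time by
#' `config$time_scale`), sampling frames and total energy every
#' `config$sample_interval`. With `config$ghost_rate > 0`, Andersen-style
#' ghost collisions redraw single-bead velocities at that per-bead rate,
#' imposing a canonical ensemble at `config$temperature`; with rate 0 the
#' dynamics are NVE and conserve energy to near machine precision.
#'
#' @param sys a `dmd_system` with initialised velocities
#'   (see [init_velocities()]).
#' @param ff a `forcefield`.
#' @param config a [run_config()].
#' @param seed engine RNG seed (thermostat schedule and bead picks);
#'   defaults to `config$rng_seed`.
#' @param record_frames set `FALSE` to keep only energies (fast checks).
#' @return A `dmd_trajectory`: `times` (ns), `times_reduced`, `frames`
#'   (list of beads-x-3 matrices), `energies`, `kinetic`, `n_events`
#'   (pair/bond events processed), `final` state, plus the originating
#'   `system` and `config`.
#' @export
run_dmd <- function(sys, ff, config, seed = config$rng_seed,
                    record_frames = TRUE) {
  validate_config(config)
  opts <- run_opts(sys, config, seed, record_frames)
  res <- dmd_run_cpp(prep_sys(sys), compile_forcefield(ff), opts)
  structure(list(
    times = unlist(res$times) / config$time_scale,
    times_reduced = unlist(res$times),
    frames = res$frames,
    energies = unlist(res$energies),
    kinetic = unlist(res$kinetic),
    n_events = res$n_events,
    n_ghost = res$n_ghost,
    n_inconsistent = res$n_inconsistent,
    final = res$state,
    system = sys, config = config, seed = seed,
    labels = sys$labels), class = "dmd_trajectory")
}

#' @export
print.dmd_trajectory <- function(x, ...) {
  cat(sprintf(paste0("<dmd_trajectory> %d frames over %.4g ns ",
                     "(%.4g reduced), %s events\n"),
              length(x$times), max(x$times), max(x$times_reduced),
              format(x$n_events, big.mark = ",")))
  invisible(x)
}

# frames of the trailing analysis window
analysis_frames <- function(traj, config = traj$config) {
  t0 <- max(traj$times) - config$analysis_window
  which(traj$times > t0 + 1e-9)
}

#' Find the next event of a system
#'
#' Returns the globally earliest pending event: the first pair-potential
#' discontinuity crossing (solved from relative ballistic motion under
#' minimum image), bond-wall collision, scheduled thermostat ghost or the
#' next sample tick.
#'
#' @param sys a `dmd_system`.
#' @param ff a `forcefield`.
#' @param config a [run_config()]; supplies the thermostat rate, sampling
#'   interval and time scale.
#' @param seed engine RNG seed (fixes the ghost schedule).
#' @return A list with `time` (reduced units), `i`, `j` (1-based bead ids,
#'   `NA` for non-pair events) and `kind` (one of `"hardcore bounce"`,
#'   `"well entry"`, `"well exit attempt"`, `"bond boundary"`,
#'   `"thermostat ghost"`, `"sample"`).
#' @export
next_event <- function(sys, ff, config, seed = config$rng_seed) {
  opts <- run_opts(sys, config, seed)
  opts$t_end <- sys$time + 100 * opts$sample_dt
  res <- dmd_step_cpp(prep_sys(sys), compile_forcefield(ff), opts, 0L)
  next_tick <- (floor(sys$time / opts$sample_dt + 1e-9) + 1) * opts$sample_dt
  if (!length(res$event_time) || res$event_time[1] > next_tick)
    return(list(time = next_tick, i = NA_integer_, j = NA_integer_,
                kind = "sample"))
  t <- res$event_time[1]
  i <- res$event_i[1]; j <- res$event_j[1]
  code <- res$event_code[1]
  if (code == 100)
    return(list(time = t, i = NA_integer_, j = NA_integer_,
                kind = "thermostat ghost"))
  kind <- if (code == 7) "bond boundary" else classify_pair_event(sys, ff, t,
                                                                  i + 1L,
                                                                  j + 1L)
  list(time = t, i = i + 1L, j = j + 1L, kind = kind)
}

# label a pair event from geometry at its event time
classify_pair_event <- function(sys, ff, t, i, j) {
  L <- sys$box_length
  xi <- sys$pos[i, ] + sys$vel[i, ] * (t - sys$time)
  xj <- sys$pos[j, ] + sys$vel[j, ] * (t - sys$time)
  d <- xj - xi; d <- d - L * round(d / L)
  r <- sqrt(sum(d^2))
  vr <- sum((sys$vel[j, ] - sys$vel[i, ]) * d) / r
  core <- ff$hardcore[sys$clazz[i] + 1] + ff$hardcore[sys$clazz[j] + 1]
  if (abs(r - core) < 1e-6) "hardcore bounce"
  else if (vr < 0) "well entry"
  else "well exit attempt"
}

#' Process the earliest pending event
#'
#' Advances the system to the given event and applies the corresponding
#' velocity update: elastic reflection at hard cores and bond walls,
#' radial speed-up/slow-down at well boundaries conserving momentum and
#' total (kinetic + step) energy, reflection when the radial kinetic energy
#' cannot pay a step, Maxwell-Boltzmann redraw at thermostat ghosts.
#'
#' @param sys a `dmd_system`.
#' @param event the event to process, as returned by [next_event()] with the
#'   same seed; an error is raised if it is not the earliest pending event.
#' @param ff a `forcefield`.
#' @param config a [run_config()].
#' @param seed engine RNG seed (must match the [next_event()] call).
#' @return The updated `dmd_system` (positions, velocities, hydrogen-bond
#'   state, time).
#' @export
advance <- function(sys, event, ff, config, seed = config$rng_seed) {
  current <- next_event(sys, ff, config, seed)
  same <- isTRUE(all.equal(current$time, event$time, tolerance = 1e-7)) &&
    identical(current$kind, event$kind) &&
    ((is.na(current$i) && is.na(event$i)) ||
       isTRUE(current$i == event$i && current$j == event$j))
  if (!same)
    stop("stale event: an earlier event exists (next is ", current$kind,
         " at t = ", signif(current$time, 6), ")")
  if (identical(event$kind, "sample")) {
    dt <- event$time - sys$time
    mob <- sys$mobile
    sys$pos[mob, ] <- sys$pos[mob, ] + sys$vel[mob, ] * dt
    sys$time <- event$time
    return(sys)
  }
  opts <- run_opts(sys, config, seed)
  opts$t_end <- sys$time + 100 * opts$sample_dt
  res <- dmd_step_cpp(prep_sys(sys), compile_forcefield(ff), opts, 1L)
  st <- res$state
  sys$pos <- st$pos
  sys$vel <- st$vel
  sys$hb_pairs <- st$hb_pairs
  sys$time <- st$time
  sys
}

#' Total energy of a system state
#'
#' Kinetic energy of the mobile beads plus the sum of step-potential
#' energies at the current pair separations (including -epsilon_hb per
#' formed hydrogen bond). The internal energy of fully static chains is
#' constant and excluded.
#'
#' @param sys a `dmd_system`.
#' @param ff a `forcefield`.
#' @return A list with `total`, `kinetic`, `potential` (kcal/mol).
#' @export
total_energy <- function(sys, ff) {
  dmd_energy_cpp(prep_sys(sys), compile_forcefield(ff))
}
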