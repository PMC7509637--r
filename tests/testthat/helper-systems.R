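# Hand-built minimal systems and trajectories for engine and analysis tests.

# run code under a fixed seed without disturbing the session RNG state
with_seed_local <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  code
}

# free beads (no bonds), one chain per bead; letters give the bead class
# ("BB" for a backbone-class bead, else a residue's sidechain class)
make_bead_system <- function(pos, vel, mass, letters, box) {
  n <- nrow(pos)
  clazz <- ifelse(letters == "BB", 0L,
                  match(letters, names(kyte_doolittle())))
  structure(list(
    pos = pos, vel = vel, mass = mass, mobile = rep(TRUE, n),
    clazz = as.integer(clazz), chain = seq_len(n), resid = rep(1L, n),
    res_letter = ifelse(letters == "BB", "G", letters),
    kind = ifelse(letters == "BB", "bb", "sc"),
    bbprev = rep(-1L, n), bbnext = rep(-1L, n),
    bonds = matrix(integer(0), 0, 2), bond_rmin = numeric(0),
    bond_rmax = numeric(0), hb_pairs = matrix(integer(0), 0, 2),
    box_length = box, time = 0,
    chain_info = data.frame(chain_id = seq_len(n),
                            residues = ifelse(letters == "BB", "G", letters),
                            start_index = 1L, mobile = TRUE),
    labels = paste0("b", seq_len(n))), class = "dmd_system")
}

# add a bond (1-based bead ids) to a hand-built system
add_bond <- function(sys, i, j, rmin, rmax) {
  sys$bonds <- rbind(sys$bonds, as.integer(c(i - 1L, j - 1L)))
  sys$bond_rmin <- c(sys$bond_rmin, rmin)
  sys$bond_rmax <- c(sys$bond_rmax, rmax)
  # bonded beads must not be treated as separate interacting chains
  sys$chain[j] <- sys$chain[i]
  sys$resid[j] <- sys$resid[i] + 1L
  sys
}

# minimal trajectory wrapper around explicit frames for analysis tests
make_traj <- function(sys, frames, times = seq_along(frames) - 1,
                      analysis_window = length(frames)) {
  cfg <- run_config(duration = max(times) + 1,
                    analysis_window = analysis_window, time_scale = 1)
  structure(list(times = times, times_reduced = times, frames = frames,
                 energies = numeric(length(frames)),
                 n_events = 0, system = sys, config = cfg, seed = 1L,
                 labels = sys$labels), class = "dmd_trajectory")
}

terminal_strands_for_tests <- function(fibril)
  crossbeta:::terminal_strands(fibril, seq_along(fibril$chains))

# default-forcefield sidechain well depth for a residue pair
sc_depth <- function(a, b, eps = 1.2) {
  h <- kyte_doolittle()
  eps * max(0, (h[[a]] + h[[b]]) / 2 + 4.5) / 9
}
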