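# Two-bead-per-residue geometry constants (nm). Backbone-backbone bonds live
# in a hard-walled well [0.36, 0.40]; backbone-sidechain in [0.24, 0.28];
# equilibrium placements use the midpoints 0.38 and 0.26.
.bond_bb <- c(0.36, 0.40)
.bond_sc <- c(0.24, 0.28)
.bb_spacing <- 0.38
.sc_offset <- 0.26
.hardcore_radius <- 0.17   # all bead classes; non-bonded contact at 0.34 nm
.sc_well_outer <- 0.65     # outer radius of sidechain attraction wells (nm)

#' Build a coarse-grained peptide
#'
#' Represents a peptide with two beads per residue -- a backbone bead (56 amu)
#' and a sidechain bead carrying the residue's remaining mass; glycine has a
#' backbone bead only. `"extended"` places backbone beads collinearly at
#' 0.38 nm spacing with sidechains alternating to either side (the geometry
#' of a beta-strand); `"coil"` grows a self-avoiding random walk with the
#' same bond geometry.
#'
#' @param record a [sequence_record()].
#' @param conformation `"extended"` or `"coil"`.
#' @param origin position of the first backbone bead (nm).
#' @param axis unit vector along the backbone (extended conformation).
#' @param side unit vector (perpendicular to `axis`) for sidechain placement.
#' @param seed RNG seed for the coil walk (required for `"coil"`).
#' @param chain_id integer chain label.
#' @param mobile logical; `FALSE` marks every bead static (used for the
#'   preformed nanofibril, whose beads scatter mobile beads but never move).
#' @return A `cg_peptide`: list with `chain_id`, `residues`, `start_index`,
#'   `pos` (beads x 3, nm), `vel`, `mass` (amu), `kind` (`"bb"`/`"sc"`),
#'   `res_index` (1-based within the chain), `mobile`.
#' @examples
#' p <- build_peptide(sequence_record("x", "AAAA"))
#' nrow(p$pos) # 8 beads: 4 backbone + 4 sidechain
#' @export
build_peptide <- function(record, conformation = c("extended", "coil"),
                          origin = c(0, 0, 0), axis = c(1, 0, 0),
                          side = c(0, 1, 0), seed = NULL, chain_id = 1L,
                          mobile = TRUE) {
  conformation <- match.arg(conformation)
  chars <- strsplit(record$residues, "")[[1]]
  n <- length(chars)
  axis <- axis / sqrt(sum(axis^2))
  side <- side - sum(side * axis) * axis
  if (sqrt(sum(side^2)) < 1e-9) stop("side vector parallel to axis")
  side <- side / sqrt(sum(side^2))

  if (conformation == "extended") {
    bb <- t(sapply(seq_len(n) - 1, function(i) origin + i * .bb_spacing * axis))
    sc_dir <- rep(c(1, -1), length.out = n)
    sc <- bb + outer(sc_dir * .sc_offset, side)
  } else {
    if (is.null(seed)) stop("coil conformation needs a seed")
    walk <- with_seed(seed, coil_walk(n))
    bb <- sweep(walk$bb, 2, origin, `+`)
    sc <- sweep(walk$sc, 2, origin, `+`)
  }

  pos <- matrix(0, 0, 3)
  kind <- character(0); res_index <- integer(0)
  for (i in seq_len(n)) {
    pos <- rbind(pos, bb[i, ])
    kind <- c(kind, "bb"); res_index <- c(res_index, i)
    if (chars[i] != "G") {
      pos <- rbind(pos, sc[i, ])
      kind <- c(kind, "sc"); res_index <- c(res_index, i)
    }
  }
  mass <- ifelse(kind == "bb",
                 ifelse(chars[res_index] == "G", .bb_mass + 1, .bb_mass),
                 .sc_mass[chars[res_index]])
  structure(list(chain_id = as.integer(chain_id), residues = record$residues,
                 start_index = record$start_index, pos = unname(pos),
                 vel = matrix(0, nrow(pos), 3), mass = unname(mass),
                 kind = kind, res_index = res_index, mobile = mobile),
            class = "cg_peptide")
}

# self-avoiding random walk for a coil conformation, centred on bead 1
coil_walk <- function(n, max_try = 2000L) {
  bb <- matrix(0, n, 3)
  for (i in seq_len(n)[-1]) {
    placed <- FALSE
    for (try in seq_len(max_try)) {
      u <- rnorm(3); u <- u / sqrt(sum(u^2))
      cand <- bb[i - 1, ] + .bb_spacing * u
      prev <- seq_len(i - 2)
      ok <- TRUE
      if (length(prev)) {
        d2 <- rowSums(sweep(bb[prev, , drop = FALSE], 2, cand, `-`)^2)
        ok <- all(d2 > 0.36^2)
      }
      if (ok) { bb[i, ] <- cand; placed <- TRUE; break }
    }
    if (!placed) stop("coil walk failed to avoid overlaps")
  }
  sc <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    placed <- FALSE
    for (try in seq_len(max_try)) {
      u <- rnorm(3); u <- u / sqrt(sum(u^2))
      cand <- bb[i, ] + .sc_offset * u
      others <- setdiff(seq_len(n), c(i - 1, i, i + 1))
      ok <- TRUE
      if (length(others)) {
        d2 <- rowSums(sweep(bb[others, , drop = FALSE], 2, cand, `-`)^2)
        ok <- all(d2 > 0.34^2)
      }
      if (ok && i > 2) {
        done <- seq_len(i - 2)
        d2 <- rowSums(sweep(sc[done, , drop = FALSE], 2, cand, `-`)^2)
        ok <- all(d2 > 0.34^2)
      }
      if (ok) { sc[i, ] <- cand; placed <- TRUE; break }
    }
    if (!placed) stop("coil walk failed to place sidechain")
  }
  list(bb = bb, sc = sc)
}

#' Default stepwise force field
#'
#' The pair potential model driving the event-driven dynamics:
#' \itemize{
#'   \item hard cores of radius 0.17 nm on every bead (non-bonded contact
#'     distance 0.34 nm);
#'   \item a single attractive square well between sidechain beads reaching
#'     to 0.65 nm whose depth scales with the Kyte-Doolittle hydropathy of
#'     the residue pair, `depth = epsilon_hp * max(0, (h_i+h_j)/2 + 4.5)/9`
#'     (so the scale's \[-4.5, 4.5\] maps onto \[0, epsilon_hp\]);
#'   \item directional backbone-backbone hydrogen bonds: a square well
#'     \[0.44, 0.56\] nm of depth `epsilon_hb`, formed only when the local
#'     chain tangents of the two residues are aligned within 30 degrees
#'     (parallel or antiparallel) and each backbone bead holds fewer than
#'     two bonds;
#'   \item bonds as infinite square wells (backbone-backbone
#'     \[0.36, 0.40\] nm, backbone-sidechain \[0.24, 0.28\] nm).
#' }
#' `epsilon_hp` defaults to 1.2 kcal/mol and `epsilon_hb` to 1.4x that,
#' chosen once so that at 300 K hydrophobic 10-mers aggregate into
#' beta-sheet-bonded clusters while polar/charged controls remain mostly
#' monomeric.
#'
#' @param epsilon_hp sidechain well-depth unit (kcal/mol).
#' @param epsilon_hb hydrogen-bond well depth (kcal/mol).
#' @return A `forcefield`: list with `classes`, `hardcore` (named radii,
#'   nm), `tables` (per class pair: `breaks` nm and shell `energies`
#'   kcal/mol, zero beyond the last break), `hb` rules and `hydropathy`.
#' @examples
#' ff <- default_forcefield()
#' ff$tables[["V:V"]]
#' @export
default_forcefield <- function(epsilon_hp = 1.2, epsilon_hb = 1.4 * epsilon_hp) {
  aa <- .canonical_aa
  h <- kyte_doolittle()
  classes <- c("BB", aa)
  hardcore <- setNames(rep(.hardcore_radius, length(classes)), classes)
  core <- 2 * .hardcore_radius
  tables <- list()
  # 210 unordered sidechain pair classes
  for (i in seq_along(aa)) for (j in i:length(aa)) {
    depth <- epsilon_hp * max(0, (h[aa[i]] + h[aa[j]]) / 2 + 4.5) / 9
    tables[[paste(aa[i], aa[j], sep = ":")]] <-
      list(breaks = c(core, .sc_well_outer), energies = -depth)
  }
  tables[["BB:BB"]] <- list(breaks = core, energies = numeric(0))
  for (a in aa) tables[[paste("BB", a, sep = ":")]] <-
    list(breaks = core, energies = numeric(0))
  structure(list(
    classes = classes, hardcore = hardcore, tables = tables,
    hb = list(rmin = 0.44, rmax = 0.56, epsilon = epsilon_hb,
              align_deg = 30, max_per_bead = 2L, min_seq_sep = 3L),
    epsilon_hp = epsilon_hp, hydropathy = h), class = "forcefield")
}

#' Look up the pair potential at a distance
#'
#' @param ff a [default_forcefield()].
#' @param class_a,class_b bead classes (one-letter residue code for
#'   sidechains, `"BB"` for backbone).
#' @param r distance (nm), may be a vector.
#' @return Energy in kcal/mol (`Inf` inside the hard core, 0 beyond range).
#' @export
pair_potential <- function(ff, class_a, class_b, r) {
  key <- paste(sort(c(class_a, class_b)), collapse = ":")
  if (is.null(ff$tables[[key]]))
    key <- paste(c(class_a, class_b), collapse = ":")
  tab <- ff$tables[[key]]
  if (is.null(tab)) stop("no table for pair ", class_a, ":", class_b)
  vapply(r, function(ri) {
    if (ri < tab$breaks[1]) return(Inf)
    shell <- findInterval(ri, tab$breaks)
    if (shell >= length(tab$breaks)) 0 else tab$energies[shell]
  }, numeric(1))
}

#' Export / import a force field as CSV
#'
#' Long-format table with one row per shell boundary
#' (`class_a, class_b, r_nm, energy_kcal`) plus `param` rows for the scalar
#' hydrogen-bond and hard-core settings, so a force field can be audited or
#' edited outside R and read back losslessly.
#'
#' @param ff a `forcefield`.
#' @param path CSV path.
#' @return `path` invisibly (write) or a `forcefield` (read).
#' @export
write_forcefield <- function(ff, path) {
  rows <- list()
  for (key in names(ff$tables)) {
    cl <- strsplit(key, ":")[[1]]
    tab <- ff$tables[[key]]
    en <- c(tab$energies, 0)
    for (s in seq_along(tab$breaks))
      rows[[length(rows) + 1L]] <- data.frame(
        class_a = cl[1], class_b = cl[2], r_nm = tab$breaks[s],
        energy_kcal = en[s])
  }
  pars <- c(hb_rmin = ff$hb$rmin, hb_rmax = ff$hb$rmax,
            hb_epsilon = ff$hb$epsilon, hb_align_deg = ff$hb$align_deg,
            hb_max_per_bead = ff$hb$max_per_bead,
            hb_min_seq_sep = ff$hb$min_seq_sep,
            epsilon_hp = ff$epsilon_hp,
            hardcore_radius = unname(ff$hardcore[1]))
  for (k in names(pars))
    rows[[length(rows) + 1L]] <- data.frame(
      class_a = "param", class_b = k, r_nm = NA_real_, energy_kcal = pars[[k]])
  write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_forcefield
#' @export
read_forcefield <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  pars <- df[df$class_a == "param", ]
  p <- setNames(pars$energy_kcal, pars$class_b)
  ff <- default_forcefield(epsilon_hp = p[["epsilon_hp"]])
  ff$hb <- list(rmin = p[["hb_rmin"]], rmax = p[["hb_rmax"]],
                epsilon = p[["hb_epsilon"]],
                align_deg = p[["hb_align_deg"]],
                max_per_bead = as.integer(p[["hb_max_per_bead"]]),
                min_seq_sep = as.integer(p[["hb_min_seq_sep"]]))
  ff$hardcore[] <- p[["hardcore_radius"]]
  tab <- df[df$class_a != "param", ]
  tables <- list()
  for (key in unique(paste(tab$class_a, tab$class_b, sep = ":"))) {
    cl <- strsplit(key, ":")[[1]]
    sub <- tab[tab$class_a == cl[1] & tab$class_b == cl[2], ]
    sub <- sub[order(sub$r_nm), ]
    tables[[key]] <- list(breaks = sub$r_nm,
                          energies = head(sub$energy_kcal, -1))
  }
  ff$tables <- tables
  ff
}

#' Build an ideal double-layer cross-beta nanofibril
#'
#' Constructs a preformed seed fibril: two parallel in-register beta-sheets
#' of `n_chains/2` extended strands each. Strands run perpendicular to the
#' fibril axis; adjacent strands within a sheet are offset along the axis by
#' the interstrand (hydrogen-bonding) spacing and the two sheets are offset
#' laterally by the intersheet (sidechain-packing) spacing. Defaults are the
#' canonical cross-beta spacings seen in fibre diffraction: 4.7 A meridional
#' (interstrand) and 9.6 A equatorial (intersheet). All chains are static
#' (`mobile = FALSE`), matching a seeding simulation in which the fibril
#' template is frozen while the monomer diffuses.
#'
#' @param record a [sequence_record()] of length <= 15 (short zipper-forming
#'   fragment).
#' @param n_chains even total strand count (default 34, i.e. 17 per sheet).
#' @param interstrand axial strand spacing within a sheet, in Angstrom.
#' @param intersheet lateral sheet-sheet spacing, in Angstrom.
#' @param center fibril centre (nm).
#' @param box_length optional box edge (nm); if given, an error is raised
#'   when the fibril (plus interaction range) does not fit.
#' @return A `nanofibril`: list of `cg_peptide` chains plus geometry
#'   metadata (`axis`, `n_sheets`, `strands_per_sheet`, `sheet` assignment,
#'   spacings as constructed).
#' @examples
#' fib <- build_nanofibril(sequence_record("seed", "VIVIVIVIVI"))
#' measure_fibril_geometry(fib)
#' @export
build_nanofibril <- function(record, n_chains = 34L, interstrand = 4.7,
                             intersheet = 9.6, center = c(0, 0, 0),
                             box_length = NULL) {
  n_chains <- as.integer(n_chains)
  if (n_chains %% 2L != 0L) stop("n_chains must be even (two equal sheets)")
  if (n_chains < 2L) stop("need at least 2 chains")
  L <- seq_length(record)
  if (L > 15L) stop("fibril-forming fragment must be <= 15 residues")
  d_strand <- interstrand / 10  # A -> nm
  d_sheet <- intersheet / 10
  nps <- n_chains %/% 2L
  axis <- c(0, 0, 1)
  strand_dir <- c(1, 0, 0)
  side <- c(0, 1, 0)
  axial <- (seq_len(nps) - 1) * d_strand
  axial <- axial - mean(axial)
  x0 <- -(L - 1) * .bb_spacing / 2
  chains <- list()
  sheet <- integer(0)
  for (s in 1:2) {
    y <- (if (s == 1) -1 else 1) * d_sheet / 2
    for (k in seq_len(nps)) {
      chains[[length(chains) + 1L]] <- build_peptide(
        record, "extended",
        origin = center + c(x0, y, axial[k]),
        axis = strand_dir, side = side * (if (s == 1) 1 else -1),
        chain_id = length(chains) + 1L, mobile = FALSE)
      sheet <- c(sheet, s)
    }
  }
  extent <- (nps - 1) * d_strand + 2 * .hardcore_radius
  if (!is.null(box_length) && extent > box_length)
    stop("fibril axial extent (", round(extent, 2),
         " nm) exceeds the box (", box_length, " nm)")
  structure(list(chains = chains, sheet = sheet, axis = axis,
                 n_sheets = 2L, strands_per_sheet = nps,
                 interstrand = interstrand, intersheet = intersheet,
                 record = record, center = center),
            class = "nanofibril")
}

#' @export
print.nanofibril <- function(x, ...) {
  cat(sprintf(paste0("<nanofibril> %d strands (%d per sheet x %d sheets) of ",
                     "%s; interstrand %.2f A, intersheet %.2f A\n"),
              length(x$chains), x$strands_per_sheet, x$n_sheets,
              x$record$id, x$interstrand, x$intersheet))
  invisible(x)
}

#' Internal hydrogen bonds of a built nanofibril
#'
#' Enumerates the backbone hydrogen bonds holding each sheet together:
#' residue i of strand k paired with residue i of the axially adjacent
#' strand k+1 (in-register). Registering these in a system's initial
#' hydrogen-bond state saturates the interior strands' donor/acceptor
#' capacity, so a diffusing monomer can only form backbone hydrogen bonds
#' with the terminal strands -- the fibril's seeding-competent ends.
#'
#' @param fibril a `nanofibril`.
#' @param sys the `dmd_system` the fibril chains were assembled into.
#' @param chains system chain ids of the fibril strands, in build order.
#' @return An integer matrix of 0-based bead-index pairs, suitable for
#'   `sys$hb_pairs`.
#' @export
nanofibril_hb_pairs <- function(fibril, sys,
                                chains = seq_along(fibril$chains)) {
  cen <- strand_bb_centroids(fibril)
  proj <- as.numeric(cen %*% fibril$axis)
  pairs <- NULL
  for (s in unique(fibril$sheet)) {
    idx <- which(fibril$sheet == s)
    idx <- idx[order(proj[idx])]
    for (k in seq_len(length(idx) - 1L)) {
      ca <- chains[idx[k]]; cb <- chains[idx[k + 1L]]
      for (r in seq_len(seq_length(fibril$record))) {
        ba <- which(sys$chain == ca & sys$resid == r & sys$kind == "bb")
        bb <- which(sys$chain == cb & sys$resid == r & sys$kind == "bb")
        pairs <- rbind(pairs, c(ba - 1L, bb - 1L))
      }
    }
  }
  matrix(as.integer(pairs), ncol = 2)
}

strand_bb_centroids <- function(fibril) {
  t(vapply(fibril$chains, function(ch)
    colMeans(ch$pos[ch$kind == "bb", , drop = FALSE]), numeric(3)))
}

#' Measure cross-beta spacings from built fibril coordinates
#'
#' Recovers the two diffraction-visible repeat distances from the bead
#' coordinates of a [build_nanofibril()] model: the interstrand spacing as
#' the mean axial distance between backbone centroids of adjacent strands
#' within a sheet (meridional, ~4.7 A), and the intersheet spacing as the
#' mean lateral distance between axially paired strand centroids across the
#' two sheets (equatorial, ~9.6 A).
#'
#' @param fibril a `nanofibril`.
#' @return Named numeric vector `c(interstrand, intersheet)` in Angstrom.
#' @export
measure_fibril_geometry <- function(fibril) {
  cen <- strand_bb_centroids(fibril)
  axis <- fibril$axis
  proj <- cen %*% axis
  inter_strand <- numeric(0)
  for (s in unique(fibril$sheet)) {
    idx <- which(fibril$sheet == s)
    if (length(idx) < 2L)
      stop("need at least two strands per sheet to measure spacings")
    z <- sort(proj[idx])
    inter_strand <- c(inter_strand, diff(z))
  }
  sheets <- unique(fibril$sheet)
  if (length(sheets) < 2L) stop("intersheet spacing needs two sheets")
  a_idx <- which(fibril$sheet == sheets[1])
  b_idx <- which(fibril$sheet == sheets[2])
  a_idx <- a_idx[order(proj[a_idx])]
  b_idx <- b_idx[order(proj[b_idx])]
  m <- min(length(a_idx), length(b_idx))
  lateral <- vapply(seq_len(m), function(k) {
    d <- cen[b_idx[k], ] - cen[a_idx[k], ]
    d <- d - sum(d * axis) * axis
    sqrt(sum(d^2))
  }, numeric(1))
  c(interstrand = mean(inter_strand) * 10, intersheet = mean(lateral) * 10)
}
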