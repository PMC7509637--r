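# Trajectory-derived statistics: residue contacts, binding frequencies,
# contact maps, single-linkage clusters, beta content, centre-of-mass
# distance distributions and fibril binding-mode classification. All
# statistics over a trajectory are computed on the trailing analysis window
# configured in its run_config.

#' Intermolecular residue contacts in a frame
#'
#' Two residues of different chains are in contact when any pair of their
#' beads lies within the cutoff under the minimum-image convention. The
#' default cutoff (0.65 nm) is the conventional heavy-atom contact distance
#' for protein interaction analysis.
#'
#' @param sys a `dmd_system` (supplies chain/residue topology and the box).
#' @param pos beads-by-3 coordinate matrix (defaults to the system's own).
#' @param cutoff contact distance (nm).
#' @return A data frame with columns `chain_a`, `res_a`, `chain_b`, `res_b`
#'   (chain ids and within-chain residue indices, `chain_a < chain_b`).
#' @export
residue_contacts <- function(sys, pos = sys$pos, cutoff = 0.65) {
  if (cutoff <= 0) stop("cutoff must be positive")
  m <- residue_contacts_cpp(pos, sys$chain, sys$resid, cutoff,
                            sys$box_length)
  data.frame(chain_a = m[, 1], res_a = m[, 2], chain_b = m[, 3],
             res_b = m[, 4])
}

# contacts between two chain groups in one frame (rows of residue_contacts)
contacts_between <- function(ct, chains_a, chains_b) {
  sel <- (ct$chain_a %in% chains_a & ct$chain_b %in% chains_b) |
         (ct$chain_a %in% chains_b & ct$chain_b %in% chains_a)
  ct[sel, , drop = FALSE]
}

#' Fraction of frames bound, per trajectory
#'
#' Fraction of analysis-window frames in which at least one intermolecular
#' residue contact exists between the two chain groups.
#'
#' @param traj a `dmd_trajectory`.
#' @param chains_a,chains_b chain-id vectors (defaults: first chain vs all
#'   others).
#' @param cutoff contact cutoff (nm); defaults to the trajectory's
#'   configured `contact_cutoff`.
#' @return A single fraction in \[0, 1\].
#' @export
bound_fraction <- function(traj, chains_a = 1L,
                           chains_b = setdiff(unique(traj$system$chain),
                                              chains_a),
                           cutoff = traj$config$contact_cutoff) {
  idx <- analysis_frames(traj)
  if (!length(idx)) stop("empty analysis window")
  bound <- vapply(idx, function(k) {
    ct <- residue_contacts(traj$system, traj$frames[[k]], cutoff)
    nrow(contacts_between(ct, chains_a, chains_b)) > 0
  }, logical(1))
  mean(bound)
}

#' Binding frequency across replicate simulations
#'
#' The bound-state frequency of a binding campaign: within each replicate
#' the fraction of analysis-window frames with at least one intermolecular
#' residue contact between the chain groups, then the unweighted mean of
#' the per-replicate fractions.
#'
#' @param trajs a list of `dmd_trajectory` replicates (or a numeric vector
#'   of precomputed per-replicate bound fractions).
#' @param ... passed to [bound_fraction()] (`chains_a`, `chains_b`,
#'   `cutoff`).
#' @return A fraction in \[0, 1\].
#' @export
binding_frequency <- function(trajs, ...) {
  if (is.numeric(trajs)) {
    stopifnot(all(trajs >= 0 & trajs <= 1))
    return(mean(trajs))
  }
  if (inherits(trajs, "dmd_trajectory")) trajs <- list(trajs)
  mean(vapply(trajs, bound_fraction, numeric(1), ...))
}

#' Residue-pair contact frequency map
#'
#' For each residue pair (one residue from each chain group), the fraction
#' of analysis-window frames in which the pair is in contact.
#'
#' @param traj a `dmd_trajectory`.
#' @param chains_a,chains_b chain-id vectors; rows of the map are residues
#'   of `chains_a`, columns of `chains_b`. When a group spans several
#'   chains, per-chain residues are pooled by residue index.
#' @param cutoff contact cutoff (nm).
#' @return A matrix of frequencies in \[0, 1\] with residue indices as
#'   dimnames.
#' @export
contact_map <- function(traj, chains_a = 1L,
                        chains_b = setdiff(unique(traj$system$chain),
                                           chains_a),
                        cutoff = traj$config$contact_cutoff) {
  sys <- traj$system
  res_a <- sort(unique(sys$resid[sys$chain %in% chains_a]))
  res_b <- sort(unique(sys$resid[sys$chain %in% chains_b]))
  mat <- matrix(0, length(res_a), length(res_b),
                dimnames = list(res_a, res_b))
  idx <- analysis_frames(traj)
  for (k in idx) {
    ct <- residue_contacts(sys, traj$frames[[k]], cutoff)
    ct <- contacts_between(ct, chains_a, chains_b)
    if (!nrow(ct)) next
    swap <- !(ct$chain_a %in% chains_a)
    ra <- ifelse(swap, ct$res_b, ct$res_a)
    rb <- ifelse(swap, ct$res_a, ct$res_b)
    seen <- unique(cbind(match(ra, res_a), match(rb, res_b)))
    mat[seen] <- mat[seen] + 1
  }
  mat / max(length(idx), 1L)
}

#' Single-linkage peptide clusters in a frame
#'
#' Peptides belong to one aggregated cluster when they are interconnected
#' via single linkages: the connected components of the graph whose edges
#' join chains sharing at least one intermolecular residue contact.
#'
#' @param sys a `dmd_system`.
#' @param pos frame coordinates (defaults to the system's own).
#' @param cutoff contact cutoff (nm).
#' @param chains chain ids to cluster (default: all chains).
#' @return A list of integer vectors, each one cluster of chain ids; the
#'   union is a partition of `chains`.
#' @export
single_linkage_clusters <- function(sys, pos = sys$pos, cutoff = 0.65,
                                    chains = unique(sys$chain)) {
  ct <- residue_contacts(sys, pos, cutoff)
  ct <- ct[ct$chain_a %in% chains & ct$chain_b %in% chains, ]
  edges <- unique(ct[, c("chain_a", "chain_b")])
  graph_components(edges, chains)
}

# connected components of a chain-level contact graph (igraph backend)
graph_components <- function(edges, vertices) {
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(edges[[1]]),
               to = as.character(edges[[2]])),
    directed = FALSE,
    vertices = data.frame(name = as.character(vertices)))
  comp <- igraph::components(g)
  unname(lapply(split(names(comp$membership), comp$membership),
                function(v) sort(as.integer(v))))
}

#' Mass-weighted mean cluster size
#'
#' For cluster sizes \eqn{n_i}, the mass-weighted average
#' \eqn{\sum n_i^2 / \sum n_i} -- the mean cluster size experienced by a
#' randomly chosen peptide. Always at least the number-weighted mean.
#'
#' @param sizes integer vector of cluster sizes (or a list of clusters).
#' @return The mass-weighted mean size, in peptides.
#' @examples
#' mass_weighted_size(c(4, 3, 2, 1)) # 3
#' @export
mass_weighted_size <- function(sizes) {
  if (is.list(sizes)) sizes <- lengths(sizes)
  if (!length(sizes)) stop("empty cluster set")
  sum(sizes^2) / sum(sizes)
}

#' Per-frame cluster statistics over the analysis window
#'
#' @param traj a `dmd_trajectory`.
#' @param cutoff contact cutoff (nm).
#' @param chains chains to include.
#' @return A `cluster_stats`: per-frame size multisets, time series of
#'   mass-weighted sizes, and the window means (`mass_weighted_mean`,
#'   `number_weighted_mean`).
#' @export
cluster_stats <- function(traj, cutoff = traj$config$contact_cutoff,
                          chains = unique(traj$system$chain)) {
  idx <- analysis_frames(traj)
  sizes <- lapply(idx, function(k)
    lengths(single_linkage_clusters(traj$system, traj$frames[[k]], cutoff,
                                    chains)))
  mw <- vapply(sizes, mass_weighted_size, numeric(1))
  nw <- vapply(sizes, mean, numeric(1))
  structure(list(times = traj$times[idx], sizes = sizes,
                 mass_weighted = mw,
                 mass_weighted_mean = mean(mw),
                 number_weighted_mean = mean(nw)), class = "cluster_stats")
}

#' @export
print.cluster_stats <- function(x, ...) {
  cat(sprintf(paste0("<cluster_stats> %d frames; mass-weighted mean %.3g, ",
                     "number-weighted mean %.3g peptides\n"),
              length(x$sizes), x$mass_weighted_mean, x$number_weighted_mean))
  invisible(x)
}

# chain tangent at a backbone bead (frame geometry), NULL if undefined
frame_tangent <- function(sys, pos, bead) {
  p <- sys$bbprev[bead]; n <- sys$bbnext[bead]
  if (p < 0 && n < 0) return(NULL)
  a <- if (p >= 0) pos[p + 1L, ] else pos[bead, ]
  b <- if (n >= 0) pos[n + 1L, ] else pos[bead, ]
  d <- b - a
  d <- d - sys$box_length * round(d / sys$box_length)
  nn <- sqrt(sum(d^2))
  if (nn < 1e-12) return(NULL)
  d / nn
}

#' Beta-strand content of a frame
#'
#' A coarse-grained secondary-structure assignment in the spirit of DSSP's
#' hydrogen-bond criterion: a residue is flagged `strand` when its backbone
#' bead has at least one geometrically satisfied backbone hydrogen bond
#' (partner backbone bead within the \[0.44, 0.56\] nm well, local chain
#' tangents within 30 degrees of parallel or antiparallel, sequence
#' separation >= 3 within a chain) and its local segment is extended (the
#' backbone i-1 to i+1 virtual distance exceeds 0.70 nm). Terminal residues
#' and chains shorter than 3 residues cannot be tested for extension and are
#' flagged on the hydrogen-bond criterion alone.
#'
#' @param sys a `dmd_system`.
#' @param pos frame coordinates.
#' @param ff a `forcefield` (hydrogen-bond geometry rules).
#' @param chains chains to assess (default all).
#' @return A list with `flags` (data frame `chain`, `resid`, `strand`) and
#'   `fraction` (flagged residues / total residues).
#' @export
beta_content <- function(sys, pos = sys$pos, ff = default_forcefield(),
                         chains = unique(sys$chain)) {
  L <- sys$box_length
  bb <- which(sys$kind == "bb" & sys$chain %in% chains)
  all_bb <- which(sys$kind == "bb")
  tangents <- lapply(seq_len(nrow(pos)), function(i) NULL)
  for (i in all_bb) tangents[[i]] <- frame_tangent(sys, pos, i)
  cosmin <- cos(ff$hb$align_deg * pi / 180)
  flags <- logical(length(bb))
  for (q in seq_along(bb)) {
    i <- bb[q]
    partners <- all_bb[all_bb != i]
    partners <- partners[sys$chain[partners] != sys$chain[i] |
                         abs(sys$resid[partners] - sys$resid[i]) >=
                           ff$hb$min_seq_sep]
    if (!length(partners)) next
    d <- sweep(pos[partners, , drop = FALSE], 2, pos[i, ], `-`)
    d <- d - L * round(d / L)
    r <- sqrt(rowSums(d^2))
    inwell <- partners[r >= ff$hb$rmin & r <= ff$hb$rmax]
    hbond <- FALSE
    ti <- tangents[[i]]
    for (j in inwell) {
      tj <- tangents[[j]]
      if (is.null(ti) || is.null(tj)) next
      if (abs(sum(ti * tj)) >= cosmin) { hbond <- TRUE; break }
    }
    if (!hbond) next
    # extension test where both chain neighbours exist
    p <- sys$bbprev[i]; nx <- sys$bbnext[i]
    if (p >= 0 && nx >= 0) {
      dv <- pos[nx + 1L, ] - pos[p + 1L, ]
      dv <- dv - L * round(dv / L)
      flags[q] <- sqrt(sum(dv^2)) > 0.70
    } else flags[q] <- TRUE
  }
  list(flags = data.frame(chain = sys$chain[bb], resid = sys$resid[bb],
                          strand = flags),
       fraction = mean(flags))
}

#' Histogram and peaks of a distance sample
#'
#' Normalised histogram (probabilities summing to one) with local maxima
#' filtered by topographic prominence.
#'
#' @param distances numeric sample (nm).
#' @param bin_width histogram bin width (nm).
#' @param prominence minimum peak prominence as a fraction of the highest
#'   bin probability.
#' @return A `com_distribution`: `distances`, `breaks`, `mids`,
#'   `probability`, `peaks` (bin centres of the accepted maxima).
#' @export
distance_distribution <- function(distances, bin_width = 0.2,
                                  prominence = 0.05) {
  if (bin_width <= 0) stop("bin_width must be positive")
  if (!length(distances)) stop("no distances supplied")
  breaks <- seq(0, max(distances) + bin_width, by = bin_width)
  h <- graphics::hist(distances, breaks = breaks, plot = FALSE)
  p <- h$counts / sum(h$counts)
  peaks <- find_peaks(p, prominence * max(p))
  structure(list(distances = distances, breaks = breaks, mids = h$mids,
                 probability = p, peaks = h$mids[peaks]),
            class = "com_distribution")
}

# indices of local maxima with topographic prominence >= minprom
find_peaks <- function(p, minprom) {
  n <- length(p)
  if (n < 3) return(integer(0))
  out <- integer(0)
  for (k in 2:(n - 1)) {
    if (!(p[k] > p[k - 1] && p[k] >= p[k + 1])) next
    # walk outwards to the nearest higher bin on each side
    left <- p[seq_len(k - 1)]
    higher_l <- which(left > p[k])
    sad_l <- if (length(higher_l)) min(left[(max(higher_l) + 1):(k - 1)])
             else min(left)
    right <- p[(k + 1):n]
    higher_r <- which(right > p[k])
    sad_r <- if (length(higher_r)) min(right[seq_len(min(higher_r) - 1)])
             else min(right)
    prom <- p[k] - max(sad_l, sad_r)
    if (prom >= minprom) out <- c(out, k)
  }
  out
}

#' @export
print.com_distribution <- function(x, ...) {
  cat(sprintf("<com_distribution> %d samples, %d bins, peaks at %s nm\n",
              length(x$distances), length(x$mids),
              paste(signif(x$peaks, 3), collapse = ", ")))
  invisible(x)
}

# mass-weighted centre of mass of a chain group in a frame
group_com <- function(sys, pos, chains) {
  sel <- sys$chain %in% chains
  w <- sys$mass[sel]
  colSums(pos[sel, , drop = FALSE] * w) / sum(w)
}

#' Centre-of-mass distance distribution between two groups
#'
#' Per analysis-window frame, the minimum-image distance between the
#' mass-weighted centres of the two chain groups, histogrammed with peak
#' detection ([distance_distribution()]).
#'
#' @param trajs a `dmd_trajectory` or list of replicates (pooled).
#' @param chains_a,chains_b disjoint chain-id groups.
#' @param bin_width histogram bin width (nm).
#' @param prominence peak prominence threshold (fraction of max).
#' @return A `com_distribution`.
#' @export
com_distance_distribution <- function(trajs, chains_a, chains_b,
                                      bin_width = 0.2, prominence = 0.05) {
  if (inherits(trajs, "dmd_trajectory")) trajs <- list(trajs)
  if (!length(chains_a) || !length(chains_b) ||
      length(intersect(chains_a, chains_b)))
    stop("chain groups must be non-empty and disjoint")
  d <- unlist(lapply(trajs, function(traj) {
    sys <- traj$system
    vapply(analysis_frames(traj), function(k) {
      dv <- group_com(sys, traj$frames[[k]], chains_b) -
        group_com(sys, traj$frames[[k]], chains_a)
      dv <- dv - sys$box_length * round(dv / sys$box_length)
      sqrt(sum(dv^2))
    }, numeric(1))
  }))
  distance_distribution(d, bin_width, prominence)
}

# chain ids of the terminal strand pairs (both fibril ends, both sheets)
terminal_strands <- function(fibril, fibril_chains) {
  cen <- strand_bb_centroids(fibril)
  proj <- as.numeric(cen %*% fibril$axis)
  term <- integer(0)
  for (s in unique(fibril$sheet)) {
    idx <- which(fibril$sheet == s)
    term <- c(term, idx[which.min(proj[idx])], idx[which.max(proj[idx])])
  }
  fibril_chains[term]
}

#' Classify how a monomer binds a nanofibril
#'
#' From the final (or any) frame: `"unbound"` with no monomer-fibril residue
#' contact; `"end"` when at least 60% of the monomer's fibril contacts are
#' with a terminal strand pair (the outermost strand of each sheet at either
#' fibril end); `"lateral"` when at least 60% are with non-terminal strands;
#' `"intermediate"` otherwise.
#'
#' @param sys the assembled `dmd_system` (fibril chains first).
#' @param pos frame coordinates.
#' @param fibril the `nanofibril` used to build the system.
#' @param monomer_chain chain id of the free monomer.
#' @param fibril_chains chain ids of the fibril strands, in build order.
#' @param cutoff contact cutoff (nm).
#' @param threshold majority fraction defining end/lateral (default 0.6).
#' @return One of `"end"`, `"lateral"`, `"intermediate"`, `"unbound"`.
#' @export
classify_binding_mode <- function(sys, pos, fibril, monomer_chain,
                                  fibril_chains = seq_along(fibril$chains),
                                  cutoff = 0.65, threshold = 0.6) {
  ct <- residue_contacts(sys, pos, cutoff)
  ct <- contacts_between(ct, monomer_chain, fibril_chains)
  if (!nrow(ct)) return("unbound")
  strand <- ifelse(ct$chain_a %in% fibril_chains, ct$chain_a, ct$chain_b)
  term <- terminal_strands(fibril, fibril_chains)
  frac_end <- mean(strand %in% term)
  if (frac_end >= threshold) "end"
  else if (1 - frac_end >= threshold) "lateral"
  else "intermediate"
}

#' Per-residue fibril binding probability
#'
#' For each residue of the fibril, the fraction of analysis-window frames in
#' which it has at least one contact with the free monomer -- the quantity
#' painted onto the fibril surface in binding-site maps.
#'
#' @param trajs a `dmd_trajectory` or list of replicates (pooled by frame).
#' @param monomer_chain chain id of the free monomer.
#' @param fibril_chains chain ids of the fibril strands.
#' @param cutoff contact cutoff (nm).
#' @return A data frame `chain`, `resid`, `probability`.
#' @export
per_residue_fibril_binding <- function(trajs, monomer_chain, fibril_chains,
                                       cutoff = 0.65) {
  if (inherits(trajs, "dmd_trajectory")) trajs <- list(trajs)
  sys <- trajs[[1]]$system
  sel <- sys$chain %in% fibril_chains & sys$kind == "bb"
  key_all <- paste(sys$chain[sel], sys$resid[sel])
  counts <- setNames(numeric(length(key_all)), key_all)
  nframes <- 0L
  for (traj in trajs) {
    idx <- analysis_frames(traj)
    nframes <- nframes + length(idx)
    for (k in idx) {
      ct <- residue_contacts(traj$system, traj$frames[[k]], cutoff)
      ct <- contacts_between(ct, monomer_chain, fibril_chains)
      if (!nrow(ct)) next
      fib_side_chain <- ifelse(ct$chain_a %in% fibril_chains, ct$chain_a,
                               ct$chain_b)
      fib_side_res <- ifelse(ct$chain_a %in% fibril_chains, ct$res_a,
                             ct$res_b)
      hits <- unique(paste(fib_side_chain, fib_side_res))
      counts[hits] <- counts[hits] + 1
    }
  }
  if (nframes == 0L) stop("no analysis frames")
  data.frame(chain = sys$chain[sel], resid = sys$resid[sel],
             probability = unname(counts / nframes))
}
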