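# Independent brute-force oracle for the event-driven engine: a
# small-timestep integrator of the same stepwise potentials that detects
# boundary crossings by stepping and bisection rather than solving event
# times in closed form. Supports free beads of sidechain classes plus
# hard-walled bonds (no hydrogen bonds, no thermostat).

# sorted boundary radii and shell energies for a pair of class letters
oracle_pair_table <- function(ff, la, lb) {
  key1 <- paste(la, lb, sep = ":"); key2 <- paste(lb, la, sep = ":")
  tab <- ff$tables[[key1]]
  if (is.null(tab)) tab <- ff$tables[[key2]]
  list(breaks = tab$breaks, energies = c(tab$energies, 0))
}

oracle_shell <- function(r, breaks) findInterval(r, breaks)

# impulse on a pair crossing/reflecting at a boundary; returns new velocities
oracle_collide <- function(vi, vj, mi, mj, nvec, dU_pass) {
  vr <- sum((vj - vi) * nvec)
  mu <- mi * mj / (mi + mj)
  if (is.finite(dU_pass) && vr^2 > 2 * dU_pass / mu) {
    vr_new <- sign(vr) * sqrt(vr^2 - 2 * dU_pass / mu)
  } else {
    vr_new <- -vr
  }
  dp <- mu * (vr_new - vr)
  list(vi = vi - dp / mi * nvec, vj = vj + dp / mj * nvec)
}

# integrate to t_end; returns sampled positions (list) and final state
oracle_integrate <- function(sys, ff, t_end, dt = 2e-4, sample_dt = 0.5) {
  pos <- sys$pos; vel <- sys$vel; m <- sys$mass; L <- sys$box_length
  n <- nrow(pos)
  letters <- ifelse(sys$kind == "bb", "BB", sys$res_letter)
  pairs <- list()
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    bnd <- which(sys$bonds[, 1] == i - 1L & sys$bonds[, 2] == j - 1L |
                 sys$bonds[, 1] == j - 1L & sys$bonds[, 2] == i - 1L)
    if (length(bnd)) {
      pairs[[length(pairs) + 1L]] <- list(
        i = i, j = j, bonded = TRUE,
        breaks = c(sys$bond_rmin[bnd[1]], sys$bond_rmax[bnd[1]]),
        energies = c(0, 0))
    } else if (!(sys$chain[i] == sys$chain[j] &&
                 abs(sys$resid[i] - sys$resid[j]) <= 1)) {
      tab <- oracle_pair_table(ff, letters[i], letters[j])
      pairs[[length(pairs) + 1L]] <- list(
        i = i, j = j, bonded = FALSE, breaks = tab$breaks,
        energies = tab$energies)
    }
  }
  mim <- function(d) d - L * round(d / L)
  pdist <- function(p, pr) {
    d <- mim(p[pr$j, ] - p[pr$i, ])
    sqrt(sum(d^2))
  }
  shells <- vapply(pairs, function(pr) oracle_shell(pdist(pos, pr),
                                                    pr$breaks), numeric(1))
  t <- 0
  samples <- list(); stimes <- numeric(0)
  next_sample <- 0
  while (t < t_end - 1e-12) {
    if (t >= next_sample - 1e-12) {
      samples[[length(samples) + 1L]] <- pos
      stimes <- c(stimes, t)
      next_sample <- next_sample + sample_dt
    }
    h <- min(dt, t_end - t, next_sample - t)
    new_pos <- pos + vel * h
    # find the earliest boundary crossing within this step, if any
    hit <- NULL
    for (pidx in seq_along(pairs)) {
      pr <- pairs[[pidx]]
      r_new <- pdist(new_pos, pr)
      s_new <- oracle_shell(r_new, pr$breaks)
      if (s_new == shells[pidx]) next
      # bisect the first crossing time of the nearest boundary
      bdry <- if (s_new > shells[pidx]) pr$breaks[shells[pidx] + 1L]
              else pr$breaks[shells[pidx]]
      lo <- 0; hi <- h
      for (it in 1:60) {
        mid <- (lo + hi) / 2
        rm <- pdist(pos + vel * mid, pr)
        inside <- oracle_shell(rm, pr$breaks) == shells[pidx]
        if (inside) lo <- mid else hi <- mid
      }
      if (is.null(hit) || lo < hit$tcross)
        hit <- list(pidx = pidx, tcross = lo, bdry = bdry,
                    outward = s_new > shells[pidx])
    }
    if (is.null(hit)) {
      pos <- new_pos; t <- t + h
      next
    }
    pr <- pairs[[hit$pidx]]
    pos <- pos + vel * hit$tcross
    t <- t + hit$tcross
    d <- mim(pos[pr$j, ] - pos[pr$i, ])
    nvec <- d / sqrt(sum(d^2))
    sh <- shells[hit$pidx]
    # energy the pair must pay (Inf at hard walls)
    if (pr$bonded) {
      dU <- Inf
    } else if (hit$outward) {
      dU <- pr$energies[sh + 1L] - pr$energies[sh]
    } else {
      dU <- if (sh == 1L) Inf else pr$energies[sh - 1L] - pr$energies[sh]
    }
    upd <- oracle_collide(vel[pr$i, ], vel[pr$j, ], m[pr$i], m[pr$j],
                          nvec, dU)
    vel[pr$i, ] <- upd$vi; vel[pr$j, ] <- upd$vj
    # re-evaluate the shell after the collision with a tiny probe step
    probe <- pos + vel * 1e-9
    shells[hit$pidx] <- oracle_shell(pdist(probe, pr), pr$breaks)
  }
  samples[[length(samples) + 1L]] <- pos
  stimes <- c(stimes, t)
  list(times = stimes, frames = samples, pos = pos, vel = vel)
}
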