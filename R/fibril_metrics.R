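#' Estimate the helical pitch of a fibril height trace
#'
#' The pitch (axial repeat of the helical twist) is taken as the lag of the
#' first significant off-origin maximum of the mean-removed autocorrelation
#' of the height profile along arclength, refined to sub-sample resolution by
#' parabolic interpolation through the peak and its two neighbours. The
#' estimate is invariant to adding a constant height offset and to shifting
#' the arclength origin.
#'
#' @param trace a `fibril_trace` (see [gen_fibril_trace()]) or a list with
#'   uniformly sampled `arclength` (nm) and `height` (nm).
#' @param min_peak minimum autocorrelation a peak must reach to count as
#'   significant (default 0.2, well above the \eqn{O(1/\sqrt{n})}
#'   fluctuations of an aperiodic trace).
#' @return Pitch in nm.
#' @examples
#' tr <- gen_fibril_trace(pitch = 23, mean_height = 7, height_amp = 1.5,
#'                        length = 200)
#' estimate_pitch(tr)
#' @export
estimate_pitch <- function(trace, min_peak = 0.2) {
  s <- trace$arclength
  h <- trace$height
  n <- length(h)
  if (n < 50L) stop("trace too short (< 50 samples)")
  ds <- diff(s)
  if (any(ds <= 0)) stop("arclength must be strictly increasing")
  if (diff(range(ds)) > 1e-6 * mean(ds))
    stop("trace must be uniformly sampled along arclength")
  ds <- mean(ds)
  x <- h - mean(h)
  if (sd(x) < 1e-12)
    stop("no periodicity: trace is flat")
  maxlag <- floor(0.8 * n)
  ac <- as.numeric(stats::acf(x, lag.max = maxlag, plot = FALSE,
                              demean = FALSE)$acf)
  # first local maximum after the origin that clears the significance floor
  thr <- max(min_peak, 3 / sqrt(n))
  peak <- NA_integer_
  for (i in 2:(length(ac) - 1)) {
    if (ac[i] > ac[i - 1] && ac[i] >= ac[i + 1] && ac[i] >= thr) {
      peak <- i
      break
    }
  }
  if (is.na(peak))
    stop("no periodicity: no significant off-origin autocorrelation maximum")
  # parabolic refinement through (peak-1, peak, peak+1); lags are 0-based
  y1 <- ac[peak - 1]; y2 <- ac[peak]; y3 <- ac[peak + 1]
  denom <- y1 - 2 * y2 + y3
  delta <- if (abs(denom) > 1e-15) 0.5 * (y1 - y3) / denom else 0
  (peak - 1 + delta) * ds
}

#' Population statistics of fibril height and pitch
#'
#' Computes, per fibril, the mean height along the contour and (where the
#' trace is periodic) the pitch via [estimate_pitch()]; then summarises the
#' population as mean and sample standard deviation (n-1 denominator) of the
#' per-fibril values.
#'
#' @param traces a list of `fibril_trace` objects (a single trace is
#'   accepted).
#' @param estimate_pitches logical; set `FALSE` to skip pitch estimation.
#' @return A `fibril_stats`: list with `n_fibrils`, `height_mean`,
#'   `height_sd`, `pitch_mean`, `pitch_sd`, `n_periodic` and the per-fibril
#'   vectors `heights`, `pitches`.
#' @export
height_stats <- function(traces, estimate_pitches = TRUE) {
  if (inherits(traces, "fibril_trace")) traces <- list(traces)
  if (!length(traces)) stop("need at least one trace")
  heights <- vapply(traces, function(tr) mean(tr$height), numeric(1))
  pitches <- rep(NA_real_, length(traces))
  if (estimate_pitches)
    pitches <- vapply(traces, function(tr)
      tryCatch(estimate_pitch(tr), error = function(e) NA_real_), numeric(1))
  ok <- !is.na(pitches)
  structure(list(
    n_fibrils = length(traces),
    height_mean = mean(heights),
    height_sd = if (length(heights) > 1L) sd(heights) else 0,
    pitch_mean = if (any(ok)) mean(pitches[ok]) else NA_real_,
    pitch_sd = if (sum(ok) > 1L) sd(pitches[ok]) else if (any(ok)) 0
               else NA_real_,
    n_periodic = sum(ok),
    heights = heights, pitches = pitches), class = "fibril_stats")
}

#' @export
print.fibril_stats <- function(x, ...) {
  cat(sprintf("<fibril_stats> n=%d height %.3g +/- %.3g nm",
              x$n_fibrils, x$height_mean, x$height_sd))
  if (!is.na(x$pitch_mean))
    cat(sprintf("; pitch %.3g +/- %.3g nm (%d periodic)",
                x$pitch_mean, x$pitch_sd, x$n_periodic))
  cat("\n")
  invisible(x)
}

# Welch's unequal-variance t statistic from summary statistics
welch_stat <- function(m1, s1, n1, m2, s2, n2) {
  se2 <- s1^2 / n1 + s2^2 / n2
  t <- (m2 - m1) / sqrt(se2)
  df <- se2^2 / ((s1^2 / n1)^2 / (n1 - 1) + (s2^2 / n2)^2 / (n2 - 1))
  p <- 2 * pt(-abs(t), df)
  list(statistic = t, df = df, p_value = p)
}

#' Compare two fibril populations
#'
#' Percent difference of population means (of `b` relative to `a`) and
#' Welch's unequal-variance two-sample statistic, for both height and pitch.
#' Mirrors the morphometric comparison of native versus cross-seeded fibril
#' populations (e.g. a 5.1 nm versus 7.0 nm mean height is a +37% rise).
#'
#' @param a,b `fibril_stats` objects (see [height_stats()]) with
#'   `n_fibrils >= 2`.
#' @return A `fibril_comparison`: list with `height_percent_change`,
#'   `height_test` (Welch statistic, df, p), and where both populations have
#'   pitch estimates `pitch_percent_change`, `pitch_test`.
#' @export
compare_populations <- function(a, b) {
  for (x in list(a, b))
    if (!inherits(x, "fibril_stats") || x$n_fibrils < 2L)
      stop("both populations must be fibril_stats with n >= 2")
  out <- list(
    height_percent_change = 100 * (b$height_mean - a$height_mean) /
      a$height_mean,
    height_test = welch_stat(a$height_mean, a$height_sd, a$n_fibrils,
                             b$height_mean, b$height_sd, b$n_fibrils),
    pitch_percent_change = NA_real_, pitch_test = NULL)
  if (a$n_periodic >= 2L && b$n_periodic >= 2L) {
    out$pitch_percent_change <- 100 * (b$pitch_mean - a$pitch_mean) /
      a$pitch_mean
    out$pitch_test <- welch_stat(a$pitch_mean, a$pitch_sd, a$n_periodic,
                                 b$pitch_mean, b$pitch_sd, b$n_periodic)
  }
  structure(out, class = "fibril_comparison")
}

#' @export
print.fibril_comparison <- function(x, ...) {
  cat(sprintf("<fibril_comparison> height change %+.3g%% (Welch t=%.3g)",
              x$height_percent_change, x$height_test$statistic))
  if (!is.na(x$pitch_percent_change))
    cat(sprintf("; pitch change %+.3g%% (Welch t=%.3g)",
                x$pitch_percent_change, x$pitch_test$statistic))
  cat("\n")
  invisible(x)
}
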