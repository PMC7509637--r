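#' Fit the sigmoidal ThT fibrillization model
#'
#' Fits the four-parameter sigmoid
#' \deqn{y(t) = y_0 + \frac{y_{max} - y_0}{1 + e^{-(t - t_{1/2})k}}}
#' to a thioflavin-T time course by Levenberg-Marquardt least squares
#' ([minpack.lm::nlsLM]), and derives the nucleation lag time by the
#' standard tangent construction `lag = t_half - 2/k`. Initial values come
#' from the data: `y0` from the minimum, `ymax` from the maximum, `t_half`
#' from the half-range crossing and `k` from the maximum slope. Negative lag
#' values (lag phase abolished by seeding) are reported as-is.
#'
#' @param curve a `tht_curve` (see [gen_tht_curve()]), or a data frame with
#'   columns `times`/`time_h` and `fluorescence`. Replicates may be fitted
#'   jointly by stacking their points.
#' @return A `kinetic_fit`: list with `y0`, `ymax`, `t_half`, `k`, `lag`,
#'   `se` (named parameter standard errors), `converged`, `residual_sd`.
#' @examples
#' cv <- gen_tht_curve(0, 1, t_half = 5, k = 0.8, noise_sd = 0)
#' fit_sigmoid(cv)
#' @export
fit_sigmoid <- function(curve) {
  if (is.data.frame(curve)) {
    tcol <- intersect(c("times", "time_h", "time"), names(curve))[1]
    if (is.na(tcol)) stop("no time column found")
    curve <- list(times = curve[[tcol]], fluorescence = curve$fluorescence)
  }
  t <- as.numeric(curve$times)
  y <- as.numeric(curve$fluorescence)
  ord <- order(t)
  t <- t[ord]; y <- y[ord]
  if (length(t) < 8L) stop("need at least 8 points to fit the sigmoid")
  rng <- diff(range(y))
  # noise scale from lag-1 differences; a curve whose total range is not
  # well above it carries no resolvable transition
  noise <- stats::mad(diff(y)) / sqrt(2)
  if (rng <= 0 || (noise > 0 && rng < 5 * noise))
    stop("degenerate fit: fluorescence range (", signif(rng, 3),
         ") is less than 5x the noise estimate (", signif(noise, 3), ")")

  y0_i <- min(y); ymax_i <- max(y)
  half <- (y0_i + ymax_i) / 2
  t_half_i <- t[which.min(abs(y - half))]
  slope <- max(diff(y) / diff(t))
  # max slope of the sigmoid is (ymax-y0)*k/4
  k_i <- max(4 * slope / rng, 1e-3)

  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ y0 + (ymax - y0) / (1 + exp(-(t - t_half) * k)),
      start = list(y0 = y0_i, ymax = ymax_i, t_half = t_half_i, k = k_i),
      lower = c(y0 = -Inf, ymax = -Inf, t_half = 0, k = 1e-8),
      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) stop("sigmoid fit failed: ", conditionMessage(e)))
  cf <- coef(fit)
  if (cf[["k"]] <= 0 || cf[["ymax"]] <= cf[["y0"]])
    stop("sigmoid fit did not converge to a rising curve")
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, 4))
  structure(list(
    y0 = unname(cf[["y0"]]), ymax = unname(cf[["ymax"]]),
    t_half = unname(cf[["t_half"]]), k = unname(cf[["k"]]),
    lag = lag_time(cf[["t_half"]], cf[["k"]]),
    se = se, converged = TRUE,
    residual_sd = sd(stats::resid(fit))), class = "kinetic_fit")
}

#' @export
print.kinetic_fit <- function(x, ...) {
  cat(sprintf(paste0("<kinetic_fit> y0=%.4g ymax=%.4g t1/2=%.4g h ",
                     "k=%.4g 1/h lag=%.4g h\n"),
              x$y0, x$ymax, x$t_half, x$k, x$lag))
  invisible(x)
}

#' Lag time from half-time and rate constant
#'
#' The nucleation lag of a sigmoidal fibrillization curve by the tangent
#' construction at the midpoint: `lag = t_half - 2/k`. May be negative when
#' seeding abolishes the lag phase; it is reported unclamped.
#'
#' @param t_half half-completion time (h).
#' @param k apparent rate constant (1/h), positive.
#' @return Lag time in hours.
#' @examples
#' lag_time(10, 0.5) # 6 h
#' @export
lag_time <- function(t_half, k) {
  if (any(k <= 0)) stop("rate constant k must be positive")
  t_half - 2 / k
}

#' Compare seeded and unseeded fibrillization kinetics
#'
#' Summarises the seeding effect between two converged [fit_sigmoid()] fits:
#' fold change of the rate constant (`k_seeded / k_control`), percent
#' reduction of the half-time
#' (`100 * (t_half_control - t_half_seeded) / t_half_control`) and the
#' absolute lag-time change (`lag_seeded - lag_control`, h).
#'
#' @param control,seeded `kinetic_fit` objects.
#' @return A `seeding_comparison`: list with `k_fold_change`,
#'   `t_half_percent_change`, `lag_change`.
#' @examples
#' ctl <- fit_sigmoid(gen_tht_curve(0, 1, 10, 0.7))
#' sed <- fit_sigmoid(gen_tht_curve(0, 1, 1.4, 1.6, times = seq(0, 50, 0.25)))
#' compare_seeding(ctl, sed)
#' @export
compare_seeding <- function(control, seeded) {
  for (f in list(control, seeded)) {
    if (!inherits(f, "kinetic_fit")) stop("inputs must be kinetic_fit objects")
    if (!isTRUE(f$converged)) stop("cannot compare non-converged fits")
  }
  structure(list(
    k_fold_change = seeded$k / control$k,
    t_half_percent_change = 100 * (control$t_half - seeded$t_half) /
      control$t_half,
    lag_change = seeded$lag - control$lag), class = "seeding_comparison")
}

#' @export
print.seeding_comparison <- function(x, ...) {
  cat(sprintf(paste0("<seeding_comparison> k fold-change %.3g; t1/2 change ",
                     "%.3g%%; lag change %.3g h\n"),
              x$k_fold_change, x$t_half_percent_change, x$lag_change))
  invisible(x)
}
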