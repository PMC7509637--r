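#' Synthetic fragment set with known aggregation character
#'
#' Generates a small labelled set of peptide fragments standing in for the
#' overlapping 10-mers of a functional-amyloid protein whose sequence is not
#' distributed with the package: a strongly amyloidogenic 10-mer (alternating
#' Val/Ile, mean Kyte-Doolittle hydropathy > 1.5), a polar/charged control
#' 10-mer (mean hydropathy < -1.5) and a mixed-character 25-mer resembling the
#' longer low-complexity repeats of such proteins. Real sequences can be
#' supplied through [read_fasta()] instead.
#'
#' @param seed integer RNG seed. The set is a fixed design, so any seed
#'   returns the same sequences; the argument exists so that callers can
#'   treat all generators uniformly as pure functions of their seed.
#' @return A list of three [sequence_record()]s with unique ids
#'   (`AMY10`, `POL10`, `MIX25`).
#' @examples
#' frags <- gen_fragment_set(1)
#' sapply(frags, function(f) mean(kyte_doolittle(f$residues)))
#' @export
gen_fragment_set <- function(seed = 1L) {
  force(seed)
  list(
    sequence_record("AMY10", "VIVIVIVIVI"),
    sequence_record("POL10", "DEKNQDEKNQ"),
    sequence_record("MIX25", "QSGNAVLQSGNTSAQVGNDNSAQTV")
  )
}

#' Generate a noisy sigmoidal ThT fluorescence curve
#'
#' Simulates a thioflavin-T fibrillization time course from the standard
#' sigmoidal model
#' \deqn{y(t) = y_0 + \frac{y_{max} - y_0}{1 + e^{-(t - t_{1/2})k}}}
#' plus i.i.d. Gaussian noise, i.e. the generative inverse of the model
#' fitted by [fit_sigmoid()].
#'
#' @param y0,ymax baseline and plateau fluorescence (a.u.), `ymax > y0`.
#' @param t_half half-completion time (h).
#' @param k apparent rate constant (1/h), must be positive.
#' @param noise_sd standard deviation of the additive Gaussian noise (a.u.).
#' @param times sampling times in hours (default hourly over 50 h, the span
#'   of a typical plate-reader assay); must be strictly increasing with at
#'   least 8 points.
#' @param seed integer RNG seed.
#' @param replicate_id integer tag carried through to the output.
#' @return A `tht_curve`: list with `times`, `fluorescence`, `replicate_id`.
#' @examples
#' gen_tht_curve(0, 1, t_half = 5, k = 0.8, noise_sd = 0, seed = 1)
#' @export
gen_tht_curve <- function(y0, ymax, t_half, k, noise_sd = 0,
                          times = seq(0, 50, by = 1), seed = 1L,
                          replicate_id = 1L) {
  if (k <= 0) stop("rate constant k must be positive")
  if (t_half <= 0) stop("t_half must be positive")
  if (ymax <= y0) stop("ymax must exceed y0")
  if (length(times) < 8L) stop("need at least 8 time points")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  y <- y0 + (ymax - y0) / (1 + exp(-(times - t_half) * k))
  if (noise_sd > 0)
    y <- y + with_seed(seed, rnorm(length(times), 0, noise_sd))
  structure(list(times = times, fluorescence = y,
                 replicate_id = as.integer(replicate_id)),
            class = "tht_curve")
}

#' @export
print.tht_curve <- function(x, ...) {
  cat(sprintf("<tht_curve> %d points over [%g, %g] h, replicate %d\n",
              length(x$times), min(x$times), max(x$times), x$replicate_id))
  invisible(x)
}

#' Generate a helically twisted fibril height trace
#'
#' Emulates the 1-D height profile traced along the contour of a twisted
#' amyloid fibril in AFM: a cosine modulation of known pitch around a mean
#' height, plus Gaussian tracing noise,
#' `height(s) = mean_height + height_amp * cos(2*pi*s/pitch) + noise`.
#' The known ground truth is carried in the `true_pitch` / `true_height`
#' fields so that estimators such as [estimate_pitch()] can be validated.
#'
#' @param pitch helical repeat distance (nm), positive.
#' @param mean_height mean fibril height (nm).
#' @param height_amp amplitude of the height modulation (nm).
#' @param noise_sd standard deviation of additive Gaussian noise (nm).
#' @param length contour length (nm); must cover at least 4 pitch periods
#'   for downstream periodicity estimation to be meaningful.
#' @param ds arclength sampling step (nm).
#' @param seed integer RNG seed.
#' @param fibril_id integer tag.
#' @return A `fibril_trace`: list with `arclength`, `height`, `true_pitch`,
#'   `true_height`, `fibril_id`.
#' @examples
#' tr <- gen_fibril_trace(pitch = 23, mean_height = 7, height_amp = 1.5,
#'                        noise_sd = 0, length = 200, seed = 1)
#' @export
gen_fibril_trace <- function(pitch, mean_height, height_amp, noise_sd = 0,
                             length = 8 * pitch, ds = 0.5, seed = 1L,
                             fibril_id = 1L) {
  if (pitch <= 0) stop("pitch must be positive")
  if (length < 4 * pitch)
    stop("contour length (", length, " nm) must cover at least 4 pitch ",
         "periods (", 4 * pitch, " nm) for the periodicity to be estimable")
  s <- seq(0, length, by = ds)
  if (base::length(s) < 50L) s <- seq(0, length, length.out = 50L)
  h <- mean_height + height_amp * cos(2 * pi * s / pitch)
  if (noise_sd > 0)
    h <- h + with_seed(seed, rnorm(base::length(s), 0, noise_sd))
  h <- pmax(h, 0)
  structure(list(arclength = s, height = h, true_pitch = pitch,
                 true_height = mean_height, fibril_id = as.integer(fibril_id)),
            class = "fibril_trace")
}

#' @export
print.fibril_trace <- function(x, ...) {
  cat(sprintf(
    "<fibril_trace> %d points over %g nm (true pitch %s nm, height %s nm)\n",
    length(x$arclength), max(x$arclength),
    format(x$true_pitch), format(x$true_height)))
  invisible(x)
}
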