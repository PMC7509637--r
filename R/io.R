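#' Sequence records
#'
#' A `sequence_record` is a plain list with fields `id`, `residues`
#' (upper-case one-letter codes) and `start_index` (1-based number of the
#' first residue, so a fragment labelled 41-50 has `start_index = 41` and 10
#' residues). Residue ranges are always 1-based and inclusive.
#'
#' @param id character label.
#' @param residues one-letter amino-acid string (canonical 20 codes).
#' @param start_index 1-based index of the first residue (default 1).
#' @return An object of class `sequence_record`.
#' @examples
#' sequence_record("frag", "VIVIVIVIVI", start_index = 41)
#' @export
sequence_record <- function(id, residues, start_index = 1L) {
  stopifnot(is.character(id), length(id) == 1L)
  residues <- toupper(as.character(residues))
  if (!nzchar(residues)) stop("residues must be non-empty")
  chars <- strsplit(residues, "")[[1]]
  bad <- setdiff(unique(chars), .canonical_aa)
  if (length(bad))
    stop("non-canonical residue code(s): ", paste(bad, collapse = ", "))
  start_index <- as.integer(start_index)
  if (is.na(start_index) || start_index < 1L)
    stop("start_index must be >= 1")
  structure(list(id = id, residues = residues, start_index = start_index),
            class = "sequence_record")
}

#' @export
print.sequence_record <- function(x, ...) {
  n <- nchar(x$residues)
  cat(sprintf("<sequence_record> %s [%d-%d] %s\n", x$id, x$start_index,
              x$start_index + n - 1L, x$residues))
  invisible(x)
}

seq_length <- function(record) nchar(record$residues)

#' Read protein sequences from a FASTA file
#'
#' Headers may carry an optional `start=N` token (whitespace-separated) giving
#' the 1-based residue number of the first residue; otherwise numbering starts
#' at 1. Residues are upper-cased and validated against the 20 canonical
#' one-letter codes.
#'
#' @param path path to a FASTA file.
#' @return A list of [sequence_record()] objects, in file order.
#' @seealso [write_fasta()]
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- seqinr::read.fasta(path, seqtype = "AA", as.string = TRUE,
                            whole.header = TRUE)
  out <- lapply(raw, function(s) {
    header <- attr(s, "Annot")
    header <- sub("^>", "", header)
    tokens <- strsplit(trimws(header), "\\s+")[[1]]
    if (!length(tokens) || !nzchar(tokens[1]))
      stop("malformed FASTA header: ", header)
    start <- 1L
    hit <- grep("^start=", tokens, value = TRUE)
    if (length(hit)) {
      start <- suppressWarnings(as.integer(sub("^start=", "", hit[1])))
      if (is.na(start)) stop("malformed start= token in header: ", header)
    }
    sequence_record(tokens[1], as.character(s), start_index = start)
  })
  names(out) <- vapply(out, `[[`, character(1), "id")
  out
}

#' Write sequence records to a FASTA file
#'
#' The inverse of [read_fasta()]: `start_index` is stored as a `start=N`
#' header token when it differs from 1.
#'
#' @param records a list of [sequence_record()] objects (or a single one).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  if (inherits(records, "sequence_record")) records <- list(records)
  lines <- unlist(lapply(records, function(r) {
    header <- if (r$start_index != 1L)
      sprintf(">%s start=%d", r$id, r$start_index) else paste0(">", r$id)
    c(header, r$residues)
  }))
  writeLines(lines, path)
  invisible(path)
}

# valid run-configuration keys and their defaults.  Times are in
# "protocol ns"; time_scale converts them to reduced time units
# (length nm, energy kcal/mol, mass amu).  ghost_rate is the per-bead
# thermostat collision rate per reduced time unit (0 = NVE).
.config_defaults <- list(
  box_length      = 8,
  duration        = 200,
  analysis_window = 150,
  temperature     = 300,
  n_replicates    = 20,
  sample_interval = 1,
  contact_cutoff  = 0.65,
  rng_seed        = 1,
  time_scale      = 3,
  ghost_rate      = 0.004
)

#' Run configuration
#'
#' Holds the protocol constants of a simulation campaign: cubic box edge (nm),
#' run duration and trailing analysis window (protocol ns),
#' temperature (K), replicate count, frame sampling interval (ns), residue
#' contact cutoff (nm), the RNG seed, the reduced-time units per
#' protocol ns (`time_scale`), and the thermostat ghost-collision
#' rate per bead per reduced time unit (`ghost_rate`, 0 disables the
#' thermostat).
#'
#' @param ... named overrides of the defaults (see Details).
#' @details Defaults mirror the fragment-scanning protocol: 8 nm box, 200 ns
#'   duration with the final 150 ns analysed, 300 K, 20 replicates and a
#'   0.65 nm contact cutoff. Unknown keys are an error; the returned object
#'   always satisfies the invariants (`analysis_window <= duration`, positive
#'   lengths/times, `n_replicates >= 1`).
#' @return An object of class `run_config` (a named list).
#' @examples
#' run_config(box_length = 12, duration = 350, analysis_window = 100)
#' @export
run_config <- function(...) {
  over <- list(...)
  if (length(over) && (is.null(names(over)) || any(!nzchar(names(over)))))
    stop("all config entries must be named")
  unknown <- setdiff(names(over), names(.config_defaults))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         "; valid keys are: ", paste(names(.config_defaults), collapse = ", "))
  cfg <- .config_defaults
  cfg[names(over)] <- lapply(over, as.numeric)
  cfg$n_replicates <- as.integer(cfg$n_replicates)
  cfg$rng_seed <- as.integer(cfg$rng_seed)
  validate_config(cfg)
  structure(cfg, class = "run_config")
}

validate_config <- function(cfg) {
  pos <- c("box_length", "duration", "analysis_window", "temperature",
           "sample_interval", "contact_cutoff", "time_scale")
  for (k in pos)
    if (!is.finite(cfg[[k]]) || cfg[[k]] <= 0)
      stop("config field '", k, "' must be a positive number")
  if (cfg$ghost_rate < 0) stop("ghost_rate must be >= 0")
  if (cfg$analysis_window > cfg$duration)
    stop("analysis_window (", cfg$analysis_window,
         ") must not exceed duration (", cfg$duration, ")")
  if (cfg$n_replicates < 1L) stop("n_replicates must be >= 1")
  invisible(cfg)
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config>\n")
  for (k in names(x)) cat(sprintf("  %-16s %s\n", k, format(x[[k]])))
  invisible(x)
}

#' Load a run configuration from a key=value text file
#'
#' The file holds one `key = value` pair per line; blank lines and lines
#' starting with `#` are ignored. Missing keys take the documented defaults
#' of [run_config()]; unknown keys are an error listing the valid keys.
#'
#' @param path path to the configuration file.
#' @return A [run_config()] object.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- list()
  for (ln in lines) {
    if (!grepl("=", ln, fixed = TRUE))
      stop("malformed config line (expected key=value): ", ln)
    parts <- strsplit(ln, "=", fixed = TRUE)[[1]]
    key <- trimws(parts[1])
    val <- suppressWarnings(as.numeric(trimws(paste(parts[-1], collapse = "="))))
    if (is.na(val)) stop("non-numeric value for config key '", key, "'")
    kv[[key]] <- val
  }
  do.call(run_config, kv)
}

#' Write a trajectory in multi-frame XYZ-dialect text
#'
#' Each frame is a block: a line with the bead count, a comment line
#' `frame <k> time <t>`, then one `label x y z` line per bead with
#' coordinates in nm printed to 6 decimals. [read_trajectory()] reproduces
#' positions to 1e-6 nm.
#'
#' @param traj a `dmd_trajectory` (see [run_dmd()]) or any list with fields
#'   `frames` (list of n-by-3 matrices), `times` and optionally `labels`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  frames <- traj$frames
  if (is.null(frames) || length(frames) < 1L)
    stop("trajectory must contain at least one frame")
  n <- nrow(frames[[1]])
  labels <- traj$labels
  if (is.null(labels)) labels <- rep("X", n)
  times <- traj$times
  if (is.null(times)) times <- seq_along(frames) - 1
  con <- file(path, "w")
  on.exit(close(con))
  for (k in seq_along(frames)) {
    fr <- frames[[k]]
    if (any(!is.finite(fr)))
      stop("non-finite coordinate in frame ", k)
    writeLines(as.character(n), con)
    writeLines(sprintf("frame %d time %.9g", k, times[k]), con)
    writeLines(sprintf("%s %.6f %.6f %.6f", labels, fr[, 1], fr[, 2],
                       fr[, 3]), con)
  }
  invisible(path)
}

#' Read a trajectory written by [write_trajectory()]
#'
#' @param path path to an XYZ-dialect trajectory file.
#' @return A list with `frames` (list of n-by-3 matrices), `times` and
#'   `labels`.
#' @export
read_trajectory <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  frames <- list()
  times <- numeric()
  labels <- NULL
  i <- 1L
  while (i <= length(lines)) {
    n <- as.integer(lines[i])
    if (is.na(n)) stop("malformed frame header at line ", i)
    comment <- lines[i + 1L]
    t <- as.numeric(sub(".*time ", "", comment))
    body <- lines[(i + 2L):(i + 1L + n)]
    parts <- strsplit(body, "\\s+")
    lab <- vapply(parts, `[[`, "", 1L)
    xyz <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
    frames[[length(frames) + 1L]] <- xyz
    times <- c(times, t)
    if (is.null(labels)) labels <- lab
    i <- i + 2L + n
  }
  list(frames = frames, times = times, labels = labels)
}

#' The amyloid-beta 42 peptide
#'
#' Returns the canonical human Abeta42 sequence
#' (DAEFRHDSGYEVHHQKLVFFAEDVGSNKGAIIGLMVGGVVIA) as a [sequence_record()].
#' This is the aggregation-prone 42-residue cleavage product of APP whose
#' fibrillization the cross-seeding pipelines probe; the same record ships
#' as a FASTA fixture under `extdata/abeta42.fasta`.
#'
#' @return A [sequence_record()] of length 42.
#' @export
abeta42 <- function() {
  sequence_record("Abeta42", "DAEFRHDSGYEVHHQKLVFFAEDVGSNKGAIIGLMVGGVVIA")
}
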