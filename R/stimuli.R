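#' Odor stimulus constructor
#'
#' @param activation Numeric vector of OSN activations in `[0, 1]`.
#' @param label One of `"familiar"`, `"novel"`, `"blank"`.
#' @param concentration Concentration scaling already applied, in `(0, 1]`.
#' @return A list of class `odor_stimulus`.
#' @export
odor_stimulus <- function(activation, label = "blank", concentration = 1) {
  if (any(activation < 0) || any(activation > 1))
    stop("activation values must lie in [0, 1]")
  structure(list(activation = activation, label = label,
                 concentration = concentration),
            class = "odor_stimulus")
}

#' @export
print.odor_stimulus <- function(x, ...) {
  cat(sprintf("odor_stimulus '%s': %d/%d OSNs active, peak %.3g, concentration %.3g\n",
              x$label, sum(x$activation > 0), length(x$activation),
              max(x$activation), x$concentration))
  invisible(x)
}

#' A blank (no-odor) stimulus
#' @param n_osn Number of olfactory sensory neurons.
#' @return An [odor_stimulus()] with zero activation everywhere.
#' @export
blank_odor <- function(n_osn = 100) {
  odor_stimulus(numeric(n_osn), label = "blank")
}

# Gaussian amplitude profile over a contiguous block of `len` OSN columns
# starting at `start`, peak-normalized to 1 at full concentration.
gaussian_block <- function(n_osn, start, len) {
  act <- numeric(n_osn)
  idx <- start:(start + len - 1)
  centre <- start + (len - 1) / 2
  sigma <- len / 4
  act[idx] <- exp(-((idx - centre)^2) / (2 * sigma^2))
  act / max(act)
}

#' Generate a familiar/novel odor pair
#'
#' Each odor activates 20-25% of the OSNs with a Gaussian amplitude profile
#' across a contiguous block of OSN columns (maximal activity 1.0 at full
#' concentration), and the two active sets share a small controlled overlap.
#'
#' @param n_osn Number of OSNs.
#' @param active_fraction Target fraction of OSNs activated per odor; drawn
#'   uniformly from the interval (default 0.20-0.25).
#' @param overlap_fraction Fraction of an odor's active set shared with the
#'   other odor (default 0.05).
#' @param seed Integer seed; the same seed reproduces the identical pair.
#' @return A list with components `familiar` and `novel`, both
#'   [odor_stimulus()] objects.
#' @export
make_odor_pair <- function(n_osn = 100, active_fraction = c(0.20, 0.25),
                           overlap_fraction = 0.05, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (overlap_fraction < 0 || overlap_fraction >= 1)
    stop("overlap_fraction must lie in [0, 1)")
  n_active <- round(n_osn * stats::runif(2, active_fraction[1], active_fraction[2]))
  n_shared <- round(overlap_fraction * mean(n_active))
  span <- sum(n_active) - n_shared
  if (span > n_osn)
    stop("active fractions and overlap incompatible with n_osn")
  # place the two blocks so they share exactly n_shared columns
  start1 <- max(1, floor((n_osn - span) / 2))
  start2 <- start1 + n_active[1] - n_shared
  fam <- gaussian_block(n_osn, start1, n_active[1])
  nov <- gaussian_block(n_osn, start2, n_active[2])
  list(familiar = odor_stimulus(fam, "familiar"),
       novel = odor_stimulus(nov, "novel"))
}

#' Scale an odor to a lower concentration
#'
#' Multiplies the activation vector elementwise by `ratio` (the concentration
#' expressed as a ratio of the concentration used for learning); the active
#' set is unchanged.
#'
#' @param odor An [odor_stimulus()].
#' @param ratio Concentration ratio in `(0, 1]`.
#' @return The scaled [odor_stimulus()].
#' @export
scale_concentration <- function(odor, ratio) {
  if (!is.numeric(ratio) || ratio <= 0) stop("concentration ratio must be positive")
  odor$activation <- odor$activation * ratio
  odor$concentration <- odor$concentration * ratio
  odor
}

#' Respiration envelope
#'
#' Half-wave-rectified sinusoid at the sniff frequency, peak 1; OSNs are
#' driven periodically by simulated breathing.
#'
#' @param t Time, ms. Vectorised.
#' @param frequency_hz Respiration frequency, Hz.
#' @return Envelope values in `[0, 1]`.
#' @export
respiration_envelope <- function(t, frequency_hz = 8) {
  pmax(0, sin(2 * pi * frequency_hz * t / 1000))
}

#' Sniff-cycle boundaries within an interval
#'
#' @param duration Interval length, ms.
#' @param frequency_hz Respiration frequency, Hz.
#' @param t_start Absolute start time of the interval, ms (the clock runs
#'   from t = 0, with cycle boundaries at multiples of the period).
#' @return Boundary times in `(t_start, t_start + duration]`, ms.
#' @export
sniff_boundaries <- function(duration, frequency_hz = 8, t_start = 0) {
  period <- 1000 / frequency_hz
  k <- seq(floor(t_start / period) + 1, floor((t_start + duration) / period))
  b <- k * period
  b[b > t_start & b <= t_start + duration]
}

#' Per-OSN sensory drive at a time point
#'
#' `baseline + activation * envelope(t)`, in units of the peak drive; the
#' engine multiplies by the configured OSN gain (mV). The baseline term
#' provides the spontaneous drive that sustains baseline network activity.
#'
#' @param odor An [odor_stimulus()].
#' @param t Time, ms (scalar).
#' @param frequency_hz Respiration frequency, Hz.
#' @param baseline Constant spontaneous drive (fraction of peak).
#' @return Drive vector, one value per OSN.
#' @export
osn_drive <- function(odor, t, frequency_hz = 8, baseline = 0) {
  if (baseline < 0) stop("baseline must be non-negative")
  baseline + odor$activation * respiration_envelope(t, frequency_hz)
}

#' Write / read an odor as two-column text
#'
#' @param odor An [odor_stimulus()].
#' @param file Path to a tab-separated file with columns `osn`, `activation`.
#' @return `write_odor` returns the path invisibly; `read_odor` the
#'   reconstructed [odor_stimulus()] (label from a comment header line).
#' @export
write_odor <- function(odor, file) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(sprintf("# label=%s concentration=%g", odor$label,
                     odor$concentration), con)
  utils::write.table(
    data.frame(osn = seq_along(odor$activation), activation = odor$activation),
    con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' @rdname write_odor
#' @export
read_odor <- function(file) {
  header <- readLines(file, n = 1)
  label <- sub(".*label=(\\S+).*", "\\1", header)
  conc <- as.numeric(sub(".*concentration=(\\S+).*", "\\1", header))
  df <- utils::read.table(file, header = TRUE, sep = "\t", comment.char = "#")
  odor_stimulus(df$activation, label = label, concentration = conc)
}
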