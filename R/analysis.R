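#' Per-neuron pyramidal firing rates over a record
#'
#' Mean firing rate of every pyramidal cell (all cells, not only those
#' activated by the odor) over the analysis window, as a population vector
#' in spikes/s.
#'
#' @param record A [run_simulation()] record.
#' @param pop Population to count (default `"Pyr"`).
#' @return Numeric vector of rates, one per cell, spikes/s.
#' @export
population_rates <- function(record, pop = "Pyr") {
  n <- record$network$pops[[pop]]$n
  sp <- record$spikes[record$spikes$pop == pop, ]
  counts <- tabulate(sp$id, nbins = n)
  counts / record$duration * 1000
}

#' Euclidean distance between population rate vectors
#'
#' Odor representations are compared as N-dimensional vectors of mean firing
#' rates (N = number of neurons); the distance is the ordinary Euclidean
#' norm of their difference, in spikes/s. For pre/post-learning comparisons
#' the distances are conventionally normalized by the mean pre-learning
#' distance of the same comparison (divide by that value).
#'
#' @param a,b Rate vectors of equal length, spikes/s.
#' @return Euclidean distance, spikes/s.
#' @export
population_distance <- function(a, b) {
  if (length(a) != length(b)) stop("population vectors differ in dimension")
  sqrt(sum((a - b)^2))
}

#' Power spectrum of a simulated LFP trace
#'
#' Mean-subtracted, Hann-windowed Welch estimate: the trace is cut into
#' overlapping segments, each segment is centered, windowed and transformed,
#' and the one-sided periodograms are averaged. Traces shorter than 2 s are
#' analyzed as a single segment. Power is peak-normalized (1.0 at the highest
#' peak); the raw estimate is retained for absolute comparisons.
#'
#' @param lfp LFP trace, mV, sampled every `dt` ms.
#' @param dt Sampling step, ms.
#' @param segment_ms Segment length, ms; default 500 ms (the full trace when
#'   shorter than 2 s), giving 2 Hz resolution.
#' @param overlap Segment overlap fraction (default 0.5).
#' @param window `"hann"` (default) or `"rect"`.
#' @return A list of class `power_spectrum` with `freq` (Hz), `power`
#'   (normalized to the maximum), `raw` (mV^2/Hz) and `df` (bin width, Hz).
#' @export
lfp_spectrum <- function(lfp, dt = 1, segment_ms = NULL, overlap = 0.5,
                         window = c("hann", "rect")) {
  window <- match.arg(window)
  total_ms <- length(lfp) * dt
  if (total_ms < 500) stop("trace shorter than one 500 ms analysis window")
  if (is.null(segment_ms)) segment_ms <- if (total_ms < 2000) total_ms else 500
  L <- round(segment_ms / dt)
  if (L > length(lfp)) stop("segment longer than the trace")
  fs <- 1000 / dt
  w <- if (window == "hann")
    0.5 - 0.5 * cos(2 * pi * seq_len(L) / (L + 1)) else rep(1, L)
  hop <- max(1, round(L * (1 - overlap)))
  starts <- seq(1, length(lfp) - L + 1, by = hop)
  nf <- floor(L / 2)
  acc <- numeric(nf + 1)
  for (s in starts) {
    x <- lfp[s:(s + L - 1)]
    x <- (x - mean(x)) * w
    X <- stats::fft(x)[seq_len(nf + 1)]
    P <- Mod(X)^2 / (fs * sum(w^2))
    scale <- rep(2, nf + 1)
    scale[1] <- 1
    if (L %% 2 == 0) scale[nf + 1] <- 1
    acc <- acc + P * scale
  }
  raw <- acc / length(starts)
  freq <- (0:nf) * fs / L
  structure(list(freq = freq, power = raw / max(raw), raw = raw,
                 df = fs / L, segments = length(starts)),
            class = "power_spectrum")
}

#' @export
print.power_spectrum <- function(x, ...) {
  cat(sprintf("power_spectrum: %g-%g Hz, df = %g Hz, %d segment(s); peak at %g Hz\n",
              min(x$freq), max(x$freq), x$df, x$segments, spectrum_peak(x)))
  invisible(x)
}

#' @export
plot.power_spectrum <- function(x, xlim = c(0, 60), ...) {
  graphics::plot(x$freq, x$power, type = "l", xlim = xlim,
                 xlab = "frequency (Hz)", ylab = "normalized power", ...)
  invisible(x)
}

#' Frequency of the global spectral peak
#' @param spectrum A [lfp_spectrum()] result.
#' @param fmin Ignore frequencies below this (Hz); excludes any residual DC.
#' @return Peak frequency, Hz.
#' @export
spectrum_peak <- function(spectrum, fmin = 2) {
  keep <- spectrum$freq >= fmin
  spectrum$freq[keep][which.max(spectrum$power[keep])]
}

#' Mean normalized power in a frequency band
#'
#' The beta band is 12-30 Hz; power is averaged after peak normalization
#' (1.0 at the highest peak, the ~8 Hz respiration-locked theta peak in
#' odor-driven runs).
#'
#' @param spectrum A [lfp_spectrum()] result.
#' @param lo,hi Band edges, Hz (inclusive).
#' @return Mean normalized power over the band.
#' @export
band_power <- function(spectrum, lo = 12, hi = 30) {
  keep <- spectrum$freq >= lo & spectrum$freq <= hi
  if (!any(keep)) stop("band contains no frequency bins")
  mean(spectrum$power[keep])
}

#' Largest local maximum of the spectrum within a band
#'
#' Finds interior local maxima of the full spectrum and returns the frequency
#' of the most powerful one inside `[lo, hi]`; falls back to the band
#' maximum if no interior local maximum lies in the band.
#'
#' @inheritParams band_power
#' @return Frequency, Hz.
#' @export
band_local_max <- function(spectrum, lo = 12, hi = 30) {
  p <- spectrum$power
  f <- spectrum$freq
  i <- 2:(length(p) - 1)
  locmax <- i[p[i] >= p[i - 1] & p[i] >= p[i + 1]]
  locmax <- locmax[f[locmax] >= lo & f[locmax] <= hi]
  if (!length(locmax)) {
    keep <- which(f >= lo & f <= hi)
    return(f[keep][which.max(p[keep])])
  }
  f[locmax[which.max(p[locmax])]]
}

#' Instantaneous-frequency adaptation curve
#'
#' For each cell under constant suprathreshold drive, the instantaneous
#' firing frequency (1000/ISI in Hz) of the first `n_intervals` inter-spike
#' intervals, indexed by interval number. Cells with too few spikes are
#' flagged and excluded.
#'
#' @param spike_times A list of numeric spike-time vectors (ms), one per cell.
#' @param n_intervals Number of leading intervals to keep (default 8).
#' @return A data.frame with columns `cell`, `interval`, `frequency` (Hz);
#'   cells excluded for having fewer than `n_intervals + 1` spikes are listed
#'   in `attr(, "excluded")`.
#' @export
adaptation_curve <- function(spike_times, n_intervals = 8) {
  rows <- list()
  excluded <- integer(0)
  for (ci in seq_along(spike_times)) {
    st <- sort(spike_times[[ci]])
    if (length(st) < n_intervals + 1) {
      excluded <- c(excluded, ci)
      next
    }
    isi <- diff(st)[seq_len(n_intervals)]
    rows[[length(rows) + 1L]] <- data.frame(
      cell = ci, interval = seq_len(n_intervals), frequency = 1000 / isi)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(cell = integer(0), interval = integer(0),
               frequency = numeric(0))
  attr(out, "excluded") <- excluded
  out
}

#' Pearson correlation between interval number and instantaneous frequency
#' @param curve An [adaptation_curve()] data.frame.
#' @return The `stats::cor.test` result (Pearson) pooled across cells.
#' @export
adaptation_correlation <- function(curve) {
  stats::cor.test(curve$interval, curve$frequency, method = "pearson")
}

# one isolated pyramidal cell population under a constant current-like drive:
# the single-cell reduction of the network model (membrane + adaptation +
# Bernoulli output), used for the cellular-level characterizations
simulate_pyr_cells <- function(n_cells, drive_mv, duration, dt = 1,
                               oxt_level = "low", jitter_fraction = 0.10,
                               config = aon_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  spec <- config$populations$Pyr
  spec$n <- n_cells
  pop <- jitter_population(spec, jitter_fraction)
  sh <- oxt_shift_mv(oxt_level)
  thmax <- pop$theta_max - sh[["theta_max"]]
  thmin <- pmin(pop$theta_min - sh[["theta_min"]], thmax - 2)
  ad <- config$adaptation
  tau_ca <- uniform_jitter(ad$tau_ca, jitter_fraction, n_cells)
  u <- numeric(n_cells)
  ca <- numeric(n_cells)
  n_steps <- round(duration / dt)
  buf <- vector("list", n_steps)
  v_trace <- matrix(NA_real_, n_steps, n_cells)
  for (k in seq_len(n_steps)) {
    v <- pop$v_rest + u
    drive <- drive_mv + ad$a_ahc * ca * (ad$e_ahp - v)
    ca <- ca * exp(-dt / tau_ca)
    u <- u + dt / pop$tau * (drive - u)
    v <- pop$v_rest + u
    v_trace[k, ] <- v
    prob <- pmin(1, pmax(0, (v - thmin) / (thmax - thmin)))
    sp <- stats::runif(n_cells) < prob
    ca[sp] <- ca[sp] + ad$ca_increment
    u[sp] <- 0
    if (any(sp)) buf[[k]] <- which(sp)
  }
  times <- dt * (seq_len(n_steps) - 1)
  spikes <- lapply(seq_len(n_cells), function(ci)
    times[vapply(buf, function(b) !is.null(b) && ci %in% b, TRUE)])
  list(spike_times = spikes, v = v_trace, times = times)
}

#' Spike-rate adaptation experiment on simulated pyramidal cells
#'
#' Runs `n_cells` independently jittered pyramidal cells under a constant
#' suprathreshold drive and returns the pooled adaptation curve of the first
#' `n_intervals` action-potential intervals, from which the interval-number
#' vs frequency correlation is computed. The default drive is calibrated so
#' the cells fire in the tens-of-Hz range and show the characteristic 30-50%
#' instantaneous-rate drop across the first eight action potentials.
#'
#' @param n_cells Number of cells (default 10).
#' @param drive_mv Constant drive above rest, mV.
#' @param duration Simulated time, ms.
#' @param oxt_level OXT condition (default `"low"`, i.e. unshifted
#'   thresholds).
#' @param seed Integer seed.
#' @param n_intervals Intervals per cell (default 8).
#' @return A list with `curve` (the [adaptation_curve()] data.frame) and
#'   `correlation` (the pooled Pearson test).
#' @export
pyr_adaptation_experiment <- function(n_cells = 10, drive_mv = 14,
                                      duration = 3000, oxt_level = "low",
                                      seed = NULL, n_intervals = 8) {
  sim <- simulate_pyr_cells(n_cells, drive_mv, duration,
                            oxt_level = oxt_level, seed = seed)
  curve <- adaptation_curve(sim$spike_times, n_intervals)
  list(curve = curve, correlation = adaptation_correlation(curve))
}

#' Rheobase modulation curve under the three OXT conditions
#'
#' Monte-Carlo probability that a pyramidal cell emits at least one action
#' potential during a 100 ms constant-drive step, per input amplitude and
#' OXT level, estimated over repeated simulations.
#'
#' @param amplitudes Drive amplitudes above rest, mV.
#' @param oxt_levels OXT conditions to test.
#' @param n_repeats Repeats per (amplitude, level) (default 10).
#' @param duration Step duration, ms (default 100).
#' @param seed Integer seed.
#' @return A data.frame with columns `amplitude`, `oxt_level`, `p_spike`.
#' @export
rheobase_curve <- function(amplitudes, oxt_levels = c("low", "medium", "high"),
                           n_repeats = 10, duration = 100, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  grid <- expand.grid(amplitude = amplitudes, oxt_level = oxt_levels,
                      stringsAsFactors = FALSE)
  grid$p_spike <- vapply(seq_len(nrow(grid)), function(i) {
    hits <- vapply(seq_len(n_repeats), function(r) {
      sim <- simulate_pyr_cells(1, grid$amplitude[i], duration,
                                oxt_level = grid$oxt_level[i])
      length(sim$spike_times[[1]]) > 0
    }, TRUE)
    mean(hits)
  }, 0)
  grid
}

#' Cumulative pyramidal spike count over time
#'
#' Running total of all pyramidal spikes in a record, evaluated on a regular
#' time grid; familiar/novel accumulation curves are compared pointwise
#' across runs.
#'
#' @param record A [run_simulation()] record (or a spikes data.frame).
#' @param grid_ms Evaluation grid spacing, ms (default 1000).
#' @return A data.frame of class `accumulation_curve` with columns `t` (ms,
#'   relative to the record start) and `count`.
#' @export
accumulate_spikes <- function(record, grid_ms = 1000) {
  sp <- if (is.data.frame(record)) record else
    record$spikes[record$spikes$pop == "Pyr", ]
  t0 <- if (is.data.frame(record)) 0 else record$t_start
  dur <- if (is.data.frame(record)) max(c(sp$t, 0)) else record$duration
  grid <- seq_len(floor(dur / grid_ms)) * grid_ms
  counts <- vapply(grid, function(g) sum(sp$t - t0 < g), 0)
  structure(data.frame(t = grid, count = counts),
            class = c("accumulation_curve", "data.frame"))
}

#' Paired pre/post firing-rate test
#'
#' Two-sided paired t-test on per-instantiation mean rates, the test used for
#' all pre/post odor-response contrasts (alpha 0.01 to account for multiple
#' comparisons). Degenerate inputs (zero-variance differences) are flagged
#' rather than tested.
#'
#' @param pre,post Paired samples (one value per instantiation).
#' @param alpha_level Significance level (default 0.01).
#' @return A list with `statistic`, `p_value`, `significant`, `degenerate`,
#'   and `mean_difference` (post minus pre).
#' @export
paired_rate_test <- function(pre, post, alpha_level = 0.01) {
  if (length(pre) != length(post)) stop("pre and post must be paired")
  if (length(pre) < 2) stop("need at least two pairs")
  d <- post - pre
  if (stats::sd(d) == 0) {
    return(list(statistic = NA_real_,
                p_value = if (all(d == 0)) 1 else NA_real_,
                significant = FALSE, degenerate = TRUE,
                mean_difference = mean(d)))
  }
  tt <- stats::t.test(post, pre, paired = TRUE)
  list(statistic = unname(tt$statistic), p_value = tt$p.value,
       significant = tt$p.value < alpha_level, degenerate = FALSE,
       mean_difference = mean(d))
}
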