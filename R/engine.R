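#' Simulation settings
#'
#' @param dt Integration step, ms (all reported experiments use 1 ms
#'   forward-Euler steps).
#' @param duration Simulated time, ms; must be a multiple of `dt`.
#' @param oxt_level OXT condition applied to the pyramidal population:
#'   `"low"`, `"medium"` or `"high"`.
#' @param plasticity Apply sniff-cycle Hebbian updates to Pyr->Pyr weights?
#' @param alpha Potentiation rate per (spike x spike); the default is
#'   calibrated so 5 s of familiar-odor exposure under medium OXT produces a
#'   clear post-learning rate increase without runaway firing (learning rate
#'   and learning time trade off against each other).
#' @param weight_cap Maximum Pyr->Pyr weight after potentiation.
#' @param record_v Record per-step pyramidal membrane voltages (matrix)?
#' @param record_weights Snapshot the Pyr->Pyr weight matrix at every sniff
#'   boundary?
#' @return A list of class `sim_settings`.
#' @export
sim_settings <- function(dt = 1, duration = 500, oxt_level = "medium",
                         plasticity = FALSE, alpha = 3.5e-4,
                         weight_cap = 0.0075, record_v = FALSE,
                         record_weights = FALSE) {
  if (dt <= 0) stop("dt must be positive")
  if (abs(duration / dt - round(duration / dt)) > 1e-9)
    stop("duration must be a multiple of dt")
  if (alpha < 0) stop("alpha must be non-negative")
  structure(list(dt = dt, duration = duration,
                 oxt_level = match.arg(oxt_level, c("low", "medium", "high")),
                 plasticity = plasticity, alpha = alpha,
                 weight_cap = weight_cap, record_v = record_v,
                 record_weights = record_weights),
            class = "sim_settings")
}

#' Sniff-cycle Hebbian update of the Pyr->Pyr weight matrix
#'
#' Between sniff cycles, every existing pyramidal-pyramidal synapse is
#' potentiated by \eqn{\Delta w_{ij} = \alpha \, x_i \, x_j}, the product of
#' the total spike counts of the post- and presynaptic cell over the
#' preceding sniff cycle, clipped at `weight_cap`. Non-connections stay zero.
#'
#' @param W Weight matrix (`n_post x n_pre`).
#' @param counts Per-cell spike counts over the cycle (`>= 0`).
#' @param alpha Potentiation rate (`>= 0`).
#' @param weight_cap Maximum weight.
#' @param mask 0/1 connection mask; defaults to `W > 0` (adequate only
#'   before any weight has been driven to zero, so pass the mask explicitly
#'   in engine code).
#' @return The updated weight matrix.
#' @export
hebbian_update <- function(W, counts, alpha, weight_cap, mask = NULL) {
  if (alpha < 0) stop("alpha must be non-negative")
  if (any(counts < 0)) stop("spike counts must be non-negative")
  if (is.null(mask)) mask <- (W > 0) * 1
  pmin(W + alpha * (counts %o% counts) * mask, weight_cap)
}

# initialize the integration state for a network (all cells at rest)
sim_state_init <- function(network) {
  n <- vapply(network$pops, `[[`, 1L, "n")
  syn <- lapply(network$synapses, function(s)
    list(A = numeric(n[[s$post]]), B = numeric(n[[s$post]])))
  list(u = list(OSN = numeric(n[["OSN"]]), PG = numeric(n[["PG"]]),
                ET = numeric(n[["ET"]]), MC_apical = numeric(n[["MC"]]),
                MC_soma = numeric(n[["MC"]]), GC = numeric(n[["GC"]]),
                Pyr = numeric(n[["Pyr"]])),
       ca = numeric(n[["Pyr"]]),
       syn = syn,
       cycle_counts = numeric(n[["Pyr"]]),
       t = 0)
}

#' Run a time-stepped network simulation
#'
#' Forward-Euler integration of the whole circuit at `dt` resolution. Each
#' step computes all synaptic drives from the active conductance kernels,
#' adds the calcium-dependent adaptation drive to the pyramidal cells,
#' updates all membranes, draws Bernoulli spikes from the output function,
#' resets spikers to rest for the start of the next step, and logs spikes and
#' the local field potential (LFP, the mean subthreshold pyramidal
#' potential). At each sniff-cycle boundary, if plasticity is on, the
#' Pyr->Pyr weights receive the Hebbian update from the spike counts of the
#' completed cycle.
#'
#' The integration state (membrane potentials, conductances, calcium, sniff
#' phase) can be carried across calls via `state`, so that multi-phase
#' protocols run on a persistent network; the (possibly plasticity-updated)
#' network is returned in the record.
#'
#' @param network An [build_network()] result.
#' @param odor An [odor_stimulus()] driving the OSNs.
#' @param settings A [sim_settings()] object.
#' @param state Integration state from a previous call, or `NULL` to start
#'   from rest at `t = 0`.
#' @return A list of class `sim_record` with elements `spikes` (data.frame
#'   `t`, `pop`, `id`), `lfp` (mV, one value per step), `times` (step start
#'   times, ms), `sniff_boundaries`, `cycle_counts` (per-cycle Pyr spike
#'   counts, one row per completed cycle), `network` (with updated weights),
#'   `state`, `odor_label`, `oxt_level`, `dt`, and optionally `v_pyr` and
#'   `weight_snapshots`.
#' @export
run_simulation <- function(network, odor, settings = sim_settings(),
                           state = NULL) {
  stopifnot(inherits(network, "aon_network"))
  if (!inherits(odor, "odor_stimulus")) stop("odor must be an odor_stimulus")
  cfg <- network$config
  dt <- settings$dt
  n_steps <- as.integer(round(settings$duration / dt))
  if (is.null(state)) state <- sim_state_init(network)
  t0 <- state$t
  period <- 1000 / cfg$respiration_hz

  pops <- network$pops
  sh <- oxt_shift_mv(settings$oxt_level)
  thmin <- lapply(pops, `[[`, "theta_min")
  thmax <- lapply(pops, `[[`, "theta_max")
  thmax$Pyr <- thmax$Pyr - sh[["theta_max"]]
  thmin$Pyr <- pmin(thmin$Pyr - sh[["theta_min"]], thmax$Pyr - 2)
  vrest <- vapply(pops, `[[`, 0, "v_rest")
  tau <- lapply(pops, `[[`, "tau")

  # flatten the synapse classes into parallel vectors/lists for the hot loop;
  # compartments are integer-indexed: 1 OSN, 2 PG, 3 ET, 4 MC apical,
  # 5 MC soma, 6 GC, 7 Pyr
  pop_names <- c("OSN", "PG", "ET", "MC", "GC", "Pyr")
  comp_keys <- c("OSN", "PG", "ET", "MC_apical", "MC_soma", "GC", "Pyr")
  pop_comp <- c(OSN = 1L, PG = 2L, ET = 3L, MC = 5L, GC = 6L, Pyr = 7L)
  K <- length(network$synapses)
  Wl <- vector("list", K)
  d1 <- d2 <- knorm <- eabs <- numeric(K)
  pre_j <- post_ci <- integer(K)
  for (i in seq_len(K)) {
    s <- network$synapses[[i]]
    Wl[[i]] <- s$W
    d1[i] <- exp(-dt / s$tau1)
    d2[i] <- exp(-dt / s$tau2)
    knorm[i] <- 1 / kernel_peak_value(s$tau1, s$tau2)
    eabs[i] <- s$e_abs
    pre_j[i] <- match(s$pre, pop_names)
    post_ci[i] <- if (s$post == "MC") {
      if (s$post_compartment == "apical") 4L else 5L
    } else unname(pop_comp[s$post])
  }
  plastic_i <- which(vapply(network$synapses, `[[`, TRUE, "plastic"))
  ad <- network$adaptation
  ca_decay <- exp(-dt / ad$tau_ca)
  ca_inc <- ad$ca_increment
  a_ahc <- ad$a_ahc
  e_ahp <- ad$e_ahp

  vrest_c <- unname(vrest[c("OSN", "PG", "ET", "MC", "MC", "GC", "Pyr")])
  tau_j <- lapply(pop_names, function(p) tau[[p]])
  invw_j <- lapply(pop_names, function(p) 1 / (thmax[[p]] - thmin[[p]]))
  thmin_j <- lapply(pop_names, function(p) thmin[[p]])
  n_j <- vapply(pop_names, function(p) pops[[p]]$n, 0L)

  u <- unname(state$u[comp_keys])
  ca <- state$ca
  As <- lapply(state$syn, `[[`, "A")
  Bs <- lapply(state$syn, `[[`, "B")
  cyc <- state$cycle_counts

  spike_buf <- lapply(pop_names, function(p) vector("list", n_steps))
  lfp <- numeric(n_steps)
  times <- t0 + dt * (seq_len(n_steps) - 1)
  v_pyr <- if (settings$record_v)
    matrix(NA_real_, n_steps, pops$Pyr$n) else NULL
  boundaries <- sniff_boundaries(settings$duration, cfg$respiration_hz, t0)
  cycle_rows <- list()
  wsnap <- list()
  act <- odor$activation
  gain <- cfg$osn_gain
  base <- cfg$osn_baseline
  ccpl <- cfg$mc_coupling
  wfreq <- 2 * pi * cfg$respiration_hz / 1000
  plast_on <- settings$plasticity && settings$alpha > 0
  n_pyr <- pops$Pyr$n
  spiked <- vector("list", 6)
  dtau <- lapply(tau_j, function(x) dt / x)

  for (k in seq_len(n_steps)) {
    t_now <- t0 + dt * (k - 1)

    # external drives per compartment; OSN drive from odor x respiration
    env <- sin(wfreq * t_now)
    if (env < 0) env <- 0
    drv <- list(gain * (base + act * env), 0, 0, 0, 0, 0, 0)

    # conductance decay and synaptic drives (kernel superposition kept as
    # two exponential state variables per class)
    for (i in seq_len(K)) {
      A <- As[[i]] * d2[i]
      B <- Bs[[i]] * d1[i]
      As[[i]] <- A
      Bs[[i]] <- B
      ci <- post_ci[i]
      drv[[ci]] <- drv[[ci]] +
        (knorm[i] * (A - B)) * (eabs[i] - vrest_c[ci] - u[[ci]])
    }
    # adaptation drive (Pyr), from the calcium entering the step
    drv[[7]] <- drv[[7]] + a_ahc * ca * (e_ahp - vrest_c[7] - u[[7]])
    ca <- ca * ca_decay

    # Euler update; mitral apical/soma electrotonic coupling uses
    # pre-update values
    ua_old <- u[[4]]
    us_old <- u[[5]]
    u[[1]] <- u[[1]] + dtau[[1]] * (drv[[1]] - u[[1]])
    u[[2]] <- u[[2]] + dtau[[2]] * (drv[[2]] - u[[2]])
    u[[3]] <- u[[3]] + dtau[[3]] * (drv[[3]] - u[[3]])
    u[[6]] <- u[[6]] + dtau[[5]] * (drv[[6]] - u[[6]])
    u[[7]] <- u[[7]] + dtau[[6]] * (drv[[7]] - u[[7]])
    u[[4]] <- ua_old + dtau[[4]] * (drv[[4]] - ua_old) +
      (dt * ccpl) * (us_old - ua_old)
    u[[5]] <- us_old + dtau[[4]] * (drv[[5]] - us_old) +
      (dt * ccpl) * (ua_old - us_old)

    # LFP: mean subthreshold Pyr potential, logged before any reset
    lfp[k] <- vrest_c[7] + sum(u[[7]]) / n_pyr
    if (!is.null(v_pyr)) v_pyr[k, ] <- vrest_c[7] + u[[7]]

    # Bernoulli spikes from the piecewise-linear output function (no
    # clamping needed: the uniform draw lies in [0,1])
    for (j in 1:6) {
      ci <- pop_comp[j]
      prob <- (vrest_c[ci] + u[[ci]] - thmin_j[[j]]) * invw_j[[j]]
      sp <- stats::runif(n_j[j]) < prob
      spiked[[j]] <- sp
      if (any(sp)) spike_buf[[j]][[k]] <- which(sp)
    }

    # propagate spikes into conductance states (kernel is 0 at t = 0)
    for (i in seq_len(K)) {
      pre_sp <- spiked[[pre_j[i]]]
      if (any(pre_sp)) {
        inj <- as.vector(Wl[[i]] %*% pre_sp)
        As[[i]] <- As[[i]] + inj
        Bs[[i]] <- Bs[[i]] + inj
      }
    }

    sp_pyr <- spiked[[6]]
    ca[sp_pyr] <- ca[sp_pyr] + ca_inc
    cyc <- cyc + sp_pyr

    # reset spikers to rest for the start of the next step (soma only
    # for MC)
    u[[1]][spiked[[1]]] <- 0
    u[[2]][spiked[[2]]] <- 0
    u[[3]][spiked[[3]]] <- 0
    u[[5]][spiked[[4]]] <- 0
    u[[6]][spiked[[5]]] <- 0
    u[[7]][sp_pyr] <- 0

    # sniff-cycle boundary: Hebbian update from the completed cycle
    if (floor((t_now + dt) / period + 1e-9) > floor(t_now / period + 1e-9)) {
      cycle_rows[[length(cycle_rows) + 1L]] <- cyc
      if (plast_on) {
        for (i in plastic_i) {
          network$synapses[[i]]$W <- hebbian_update(
            network$synapses[[i]]$W, cyc, settings$alpha,
            settings$weight_cap, network$synapses[[i]]$mask)
          Wl[[i]] <- network$synapses[[i]]$W
        }
      }
      if (settings$record_weights)
        wsnap[[length(wsnap) + 1L]] <- network$synapses[[plastic_i[1]]]$W
      cyc <- cyc * 0
    }
    if (k %% 250L == 0L && !all(is.finite(u[[7]])))
      stop("simulation diverged: non-finite membrane potential at t = ", t_now)
  }
  names(spike_buf) <- pop_names

  spikes <- do.call(rbind, lapply(pop_names, function(p) {
    ks <- which(!vapply(spike_buf[[p]], is.null, TRUE))
    if (!length(ks)) return(NULL)
    ids <- spike_buf[[p]][ks]
    data.frame(t = rep(times[ks], lengths(ids)), pop = p,
               id = unlist(ids, use.names = FALSE))
  }))
  if (is.null(spikes))
    spikes <- data.frame(t = numeric(0), pop = character(0), id = integer(0))

  state$u <- stats::setNames(u, comp_keys)
  state$ca <- ca
  state$syn <- stats::setNames(
    lapply(seq_len(K), function(i) list(A = As[[i]], B = Bs[[i]])),
    names(network$synapses))
  state$cycle_counts <- cyc
  state$t <- t0 + n_steps * dt

  structure(list(spikes = spikes, lfp = lfp, times = times, dt = dt,
                 t_start = t0, duration = settings$duration,
                 sniff_boundaries = boundaries,
                 cycle_counts = if (length(cycle_rows))
                   do.call(rbind, cycle_rows) else
                   matrix(0, 0, pops$Pyr$n),
                 network = network, state = state,
                 odor_label = odor$label, oxt_level = settings$oxt_level,
                 v_pyr = v_pyr,
                 weight_snapshots = if (settings$record_weights) wsnap else NULL),
            class = "sim_record")
}

#' @export
print.sim_record <- function(x, ...) {
  counts <- table(factor(x$spikes$pop,
                         levels = c("OSN", "PG", "ET", "MC", "GC", "Pyr")))
  cat(sprintf("sim_record: odor '%s', %g ms from t = %g ms, OXT %s\n",
              x$odor_label, x$duration, x$t_start, x$oxt_level))
  cat("  spikes:", paste(names(counts), as.integer(counts), sep = "=",
                         collapse = " "), "\n")
  cat(sprintf("  LFP: %d samples, mean %.2f mV\n", length(x$lfp), mean(x$lfp)))
  invisible(x)
}

#' Raster and LFP plot of a simulation record
#' @param x A `sim_record`.
#' @param pops Populations to include in the raster.
#' @param ... Unused.
#' @return `x`, invisibly.
#' @export
plot.sim_record <- function(x, pops = c("OSN", "MC", "GC", "Pyr"), ...) {
  op <- graphics::par(mfrow = c(length(pops) + 1, 1), mar = c(2, 4, 1, 1))
  on.exit(graphics::par(op))
  for (p in pops) {
    sp <- x$spikes[x$spikes$pop == p, ]
    graphics::plot(sp$t, sp$id, pch = ".", xlim = range(x$times),
                   xlab = "", ylab = p)
  }
  graphics::plot(x$times, x$lfp, type = "l", xlab = "time (ms)",
                 ylab = "LFP (mV)")
  invisible(x)
}

#' Mean subthreshold pyramidal potential (the simulated LFP)
#'
#' The LFP is defined as the average membrane potential of the pyramidal
#' population at each step, excluding action potentials (voltages are the
#' pre-reset subthreshold values), emulating a low-pass electrode recording.
#'
#' @param v_pyr Matrix of pyramidal membrane potentials, steps x cells, mV.
#' @return LFP trace, mV, one value per step.
#' @export
compute_lfp <- function(v_pyr) {
  if (is.null(dim(v_pyr)) || ncol(v_pyr) < 1) stop("empty population")
  rowMeans(v_pyr)
}

#' Run a sequence of phases on one persistent network
#'
#' Executes phases in order, carrying the integration state and any
#' plasticity-induced weight changes across phases (the respiration clock
#' runs continuously).
#'
#' @param network An [build_network()] result.
#' @param phases A list; each element is a list with `odor` (an
#'   [odor_stimulus()]), `duration` (ms), and optionally `oxt_level`,
#'   `plasticity`, `label`, `record_v`.
#' @param settings Base [sim_settings()] supplying defaults (`alpha`,
#'   `weight_cap`, `dt`, ...).
#' @return A list with `records` (one `sim_record` per phase, named by phase
#'   label) and `network` (final weights).
#' @export
run_phases <- function(network, phases, settings = sim_settings()) {
  state <- NULL
  records <- list()
  for (i in seq_along(phases)) {
    ph <- phases[[i]]
    s <- settings
    s$duration <- ph$duration
    if (!is.null(ph$oxt_level)) s$oxt_level <- ph$oxt_level
    s$plasticity <- isTRUE(ph$plasticity)
    if (!is.null(ph$record_v)) s$record_v <- ph$record_v
    rec <- run_simulation(network, ph$odor, s, state)
    network <- rec$network
    state <- rec$state
    records[[if (!is.null(ph$label)) ph$label else as.character(i)]] <- rec
  }
  list(records = records, network = network)
}

#' Repeat an experiment over independent network instantiations
#'
#' Each seed gets a fresh network instantiation (new parameter jitter, new
#' connectivity, new spike randomness), as in the reported experiments where
#' every odor exposure is simulated on a newly initiated model.
#'
#' @param seeds Integer seeds, one per instantiation.
#' @param fn Function of one argument (the seed) performing the experiment;
#'   called after `set.seed(seed)`.
#' @return A list of `fn` results, one per seed.
#' @export
run_repeats <- function(seeds, fn) {
  if (length(seeds) < 1) stop("need at least one seed")
  if (anyDuplicated(seeds)) warning("duplicate seeds: instantiations will coincide")
  lapply(seeds, function(s) { set.seed(s); fn(s) })
}
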