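#' Population specification
#'
#' Per-cell-type membrane parameters. Defaults for the six populations are
#' provided by [aon_config()].
#'
#' @param name Cell-type label: OSN, PG, ET, MC, GC or Pyr.
#' @param n Number of cells.
#' @param tau Membrane time constant, ms.
#' @param v_rest Resting membrane potential, mV.
#' @param theta_min Spiking threshold, mV.
#' @param theta_max Saturation threshold, mV.
#' @param compartments 1, or 2 for mitral cells (apical + soma).
#' @return A list of class `population_spec`.
#' @export
population_spec <- function(name, n, tau, v_rest, theta_min, theta_max,
                            compartments = 1L) {
  if (n <= 0 || tau <= 0) stop("n and tau must be positive")
  if (theta_min >= theta_max) stop("theta_min must be below theta_max")
  structure(list(name = name, n = as.integer(n), tau = tau, v_rest = v_rest,
                 theta_min = theta_min, theta_max = theta_max,
                 compartments = as.integer(compartments)),
            class = "population_spec")
}

#' Synapse class specification
#'
#' One projection class (e.g. mitral soma to pyramidal). Reversal potentials
#' are stored with a `relative_to_rest` flag. Excitatory reversals (+70 mV)
#' are absolute, as printed, giving the ~135 mV driving force from rest that
#' the circuit needs to reach its odor-evoked firing regimes. The two
#' inhibitory reversals (-5 / -10 mV) are read as offsets from the -65 mV
#' resting potential (absolute -70 / -75 mV, GABA-A-like): an absolute
#' reading would make them depolarizing from rest, inverting the circuit
#' signs.
#'
#' @param pre,post Cell-type labels.
#' @param w_mean Mean synaptic weight (dimensionless, `>= 0`).
#' @param e_n Reversal potential, mV.
#' @param tau1,tau2 Conductance rise and decay times, ms (`tau1 < tau2`).
#' @param p Connection rule: a probability in `[0,1]`, `"column"` (one-to-one
#'   within the functional column), `"local"` (GC inhibits only its column's
#'   mitral cell) or `"surround"` (nearest-neighbour, +/-1 column with
#'   wrap-around).
#' @param post_compartment `"soma"` or `"apical"` (mitral-cell targets only).
#' @param relative_to_rest Interpret `e_n` as an offset from the
#'   postsynaptic resting potential?
#' @param plastic Is this class subject to Hebbian plasticity?
#' @param sign `"excitatory"` or `"inhibitory"` (bookkeeping; the sign of the
#'   drive follows from the reversal potential).
#' @return A list of class `synapse_spec`.
#' @export
synapse_spec <- function(pre, post, w_mean, e_n, tau1, tau2, p,
                         post_compartment = "soma", relative_to_rest = FALSE,
                         plastic = FALSE, sign = "excitatory") {
  check_kernel_taus(tau1, tau2)
  if (w_mean < 0) stop("w_mean must be non-negative")
  if (is.numeric(p) && (p < 0 || p > 1)) stop("connection probability must lie in [0,1]")
  structure(list(pre = pre, post = post, w_mean = w_mean, e_n = e_n,
                 tau1 = tau1, tau2 = tau2, p = p,
                 post_compartment = post_compartment,
                 relative_to_rest = relative_to_rest,
                 plastic = plastic, sign = sign),
            class = "synapse_spec")
}

#' Default network configuration
#'
#' All populations (100 cells each, organized in functional columns) and
#' synapse classes of the olfactory bulb + AON circuit, with the standard
#' parameter-table values: five OB populations (OSN, PG, ET, two-compartment
#' mitral cells, GC) and 100 AON pyramidal cells. Random projection
#' probabilities are p(MC->GC) = 0.25, p(MC->Pyr) = 0.2, p(Pyr->Pyr) = 0.15,
#' p(Pyr->ET) = 0.1, p(Pyr->GC) = 0.2; AON feedback to the bulb is kept very
#' weak (w = 0.0015). Pyr->Pyr synapses start low (1e-4) and are the only
#' plastic class.
#'
#' @param n Cells per population.
#' @param jitter_fraction Half-width of the uniform parameter jitter applied
#'   at network construction (0.10 means +/-10% around the mean).
#' @param respiration_hz Respiration (sniff) frequency, Hz.
#' @param osn_gain Peak OSN sensory drive, mV, for activation 1 at the
#'   respiration-envelope maximum.
#' @param osn_baseline Spontaneous OSN drive as a fraction of `osn_gain`.
#' @param pyr_pyr_w0 Initial Pyr->Pyr weight.
#' @param mc_coupling Mitral apical/soma voltage-coupling coefficient per ms.
#' @param et_surround Include nearest-neighbour ET->ET surround excitation?
#' @param adaptation An [adaptation_spec()] for the pyramidal cells.
#' @return A list of class `aon_config` with fields `populations`,
#'   `synapses`, `adaptation` and the scalar settings above.
#' @export
aon_config <- function(n = 100, jitter_fraction = 0.10, respiration_hz = 8,
                       osn_gain = 70, osn_baseline = 0.01,
                       pyr_pyr_w0 = 1e-4, mc_coupling = 0.8,
                       et_surround = TRUE, adaptation = adaptation_spec()) {
  if (jitter_fraction < 0 || jitter_fraction > 0.5)
    stop("jitter_fraction must lie in [0, 0.5]")
  if (mc_coupling < 0 || mc_coupling > 0.9)
    stop("mc_coupling must lie in [0, 0.9] (forward-Euler stability at 1 ms)")
  pops <- list(
    OSN = population_spec("OSN", n, tau = 1, v_rest = -65, theta_min = -65, theta_max = -55),
    MC  = population_spec("MC",  n, tau = 5, v_rest = -65, theta_min = -64, theta_max = -55,
                          compartments = 2L),
    PG  = population_spec("PG",  n, tau = 2, v_rest = -65, theta_min = -65, theta_max = -60),
    GC  = population_spec("GC",  n, tau = 4, v_rest = -65, theta_min = -64, theta_max = -60),
    ET  = population_spec("ET",  n, tau = 2, v_rest = -65, theta_min = -65, theta_max = -60),
    Pyr = population_spec("Pyr", n, tau = 10, v_rest = -65, theta_min = -62, theta_max = -55)
  )
  syn <- list(
    OSN_PG    = synapse_spec("OSN", "PG", 0.0015, 70, 1, 2, "column"),
    OSN_MC    = synapse_spec("OSN", "MC", 0.015, 70, 1, 2, "column",
                             post_compartment = "apical"),
    OSN_ET    = synapse_spec("OSN", "ET", 0.0015, 70, 1, 2, "column"),
    PG_MC     = synapse_spec("PG", "MC", 0.002, -5, 2, 4, "column",
                             post_compartment = "apical",
                             relative_to_rest = TRUE, sign = "inhibitory"),
    ET_MC     = synapse_spec("ET", "MC", 0.0015, 70, 1, 2, "column",
                             post_compartment = "apical"),
    ET_ET     = synapse_spec("ET", "ET", 0.0015, 70, 1, 2, "surround"),
    MC_GC     = synapse_spec("MC", "GC", 1e-4, 70, 1, 2, 0.25),
    GC_MC     = synapse_spec("GC", "MC", 0.0015, -10, 2, 4, "local",
                             relative_to_rest = TRUE, sign = "inhibitory"),
    MC_Pyr    = synapse_spec("MC", "Pyr", 0.007, 70, 1, 2, 0.20),
    Pyr_Pyr   = synapse_spec("Pyr", "Pyr", pyr_pyr_w0, 70, 1, 2, 0.15,
                             plastic = TRUE),
    Pyr_ET    = synapse_spec("Pyr", "ET", 0.0015, 70, 1, 2, 0.10),
    Pyr_GC    = synapse_spec("Pyr", "GC", 0.0015, 70, 1, 2, 0.20)
  )
  if (!et_surround) syn$ET_ET <- NULL
  structure(list(populations = pops, synapses = syn, adaptation = adaptation,
                 jitter_fraction = jitter_fraction,
                 respiration_hz = respiration_hz,
                 osn_gain = osn_gain, osn_baseline = osn_baseline,
                 mc_coupling = mc_coupling, et_surround = et_surround),
            class = "aon_config")
}

uniform_jitter <- function(mean, frac, n) {
  if (frac == 0) rep(mean, n)
  else stats::runif(n, mean * (1 - frac), mean * (1 + frac))
}

# jitter threshold offsets from rest rather than absolute potentials, so
# theta_min stays below theta_max and +/-10% means 10% of the rheobase margin
jitter_population <- function(spec, frac) {
  n <- spec$n
  list(name = spec$name, n = n,
       v_rest = spec$v_rest,
       tau = uniform_jitter(spec$tau, frac, n),
       theta_min = spec$v_rest +
         uniform_jitter(spec$theta_min - spec$v_rest, frac, n),
       theta_max = spec$v_rest +
         uniform_jitter(spec$theta_max - spec$v_rest, frac, n),
       compartments = spec$compartments)
}

connection_mask <- function(rule, n_post, n_pre, self_allowed = TRUE) {
  if (identical(rule, "column") || identical(rule, "local")) {
    diag(1, n_post, n_pre)
  } else if (identical(rule, "surround")) {
    m <- matrix(0, n_post, n_pre)
    idx <- seq_len(n_pre)
    m[cbind(idx %% n_post + 1L, idx)] <- 1               # +1 with wrap-around
    m[cbind((idx - 2L) %% n_post + 1L, idx)] <- 1        # -1 with wrap-around
    m
  } else {
    m <- matrix(as.numeric(stats::runif(n_post * n_pre) < rule), n_post, n_pre)
    if (!self_allowed && n_post == n_pre) diag(m) <- 0
    m
  }
}

#' Build a network instantiation
#'
#' Realizes one network from a configuration: draws every Bernoulli(p)
#' connection independently, wires the column-aligned classes (OSN -> PG / ET
#' / MC within column; GC -> MC strictly local; ET surround at +/-1 column),
#' and jitters all membrane time constants, threshold offsets and synaptic
#' weights uniformly within `jitter_fraction` of their means. Pyramidal
#' self-connections are excluded from the plastic Pyr->Pyr class.
#'
#' @param config An [aon_config()].
#' @param seed Integer seed; the same seed reproduces the identical network.
#' @return A list of class `aon_network` with per-population jittered
#'   parameter vectors (`pops`), per-class weight matrices and kinetics
#'   (`synapses`, each `W` is `n_post x n_pre`), the adaptation parameters
#'   (`adaptation`, with per-cell jittered `tau_ca`), and the originating
#'   `config` and `seed`.
#' @export
build_network <- function(config, seed = NULL) {
  stopifnot(inherits(config, "aon_config"))
  if (!is.null(seed)) set.seed(seed)
  frac <- config$jitter_fraction
  pops <- lapply(config$populations, jitter_population, frac = frac)
  synapses <- lapply(config$synapses, function(s) {
    n_pre <- pops[[s$pre]]$n
    n_post <- pops[[s$post]]$n
    mask <- connection_mask(s$p, n_post, n_pre,
                            self_allowed = !(s$pre == "Pyr" && s$post == "Pyr"))
    w <- matrix(uniform_jitter(s$w_mean, frac, n_post * n_pre), n_post, n_pre)
    e_abs <- if (s$relative_to_rest) config$populations[[s$post]]$v_rest + s$e_n
             else s$e_n
    list(pre = s$pre, post = s$post, post_compartment = s$post_compartment,
         W = w * mask, mask = mask, e_abs = e_abs,
         tau1 = s$tau1, tau2 = s$tau2, plastic = s$plastic, sign = s$sign)
  })
  ad <- config$adaptation
  adaptation <- list(a_ahc = ad$a_ahc, e_ahp = ad$e_ahp,
                     tau_ca = uniform_jitter(ad$tau_ca, frac, pops$Pyr$n),
                     ca_increment = ad$ca_increment)
  structure(list(config = config, pops = pops, synapses = synapses,
                 adaptation = adaptation, seed = seed),
            class = "aon_network")
}

#' @export
print.aon_config <- function(x, ...) {
  cat("OB+AON network configuration\n")
  cat(sprintf("  populations: %s (n = %s)\n",
              paste(names(x$populations), collapse = ", "),
              paste(vapply(x$populations, `[[`, 1L, "n"), collapse = ", ")))
  cat(sprintf("  synapse classes: %d; jitter +/-%d%%; respiration %g Hz\n",
              length(x$synapses), round(100 * x$jitter_fraction),
              x$respiration_hz))
  invisible(x)
}

#' @export
print.aon_network <- function(x, ...) {
  cat(sprintf("aon_network (seed %s)\n",
              if (is.null(x$seed)) "unset" else x$seed))
  for (nm in names(x$synapses)) {
    s <- x$synapses[[nm]]
    cat(sprintf("  %-8s %s -> %s%s: %d connections, mean w %.2g%s\n", nm,
                s$pre, s$post,
                if (s$post_compartment == "apical") " (apical)" else "",
                sum(s$mask > 0), mean(s$W[s$mask > 0]),
                if (s$plastic) " [plastic]" else ""))
  }
  invisible(x)
}

#' @export
summary.aon_network <- function(object, ...) {
  counts <- vapply(object$synapses, function(s) sum(s$mask > 0), 0)
  data.frame(class = names(object$synapses),
             pre = vapply(object$synapses, `[[`, "", "pre"),
             post = vapply(object$synapses, `[[`, "", "post"),
             connections = as.integer(counts),
             mean_weight = vapply(object$synapses, function(s)
               if (any(s$mask > 0)) mean(s$W[s$mask > 0]) else NA_real_, 0),
             plastic = vapply(object$synapses, `[[`, TRUE, "plastic"),
             row.names = NULL)
}

#' Export / import a connection set as tabular text
#'
#' Writes one synapse class as `(pre, post, weight)` triples, one row per
#' realized connection, for reproducibility and external inspection.
#'
#' @param network An [build_network()] result.
#' @param class_name Name of the synapse class (e.g. `"MC_Pyr"`).
#' @param file Path to a tab-separated text file.
#' @return `write_connections` returns the file path invisibly;
#'   `read_connections` returns a data.frame with columns `pre`, `post`,
#'   `weight`.
#' @export
write_connections <- function(network, class_name, file) {
  s <- network$synapses[[class_name]]
  if (is.null(s)) stop("unknown synapse class: ", class_name)
  idx <- which(s$mask > 0, arr.ind = TRUE)
  df <- data.frame(pre = idx[, 2], post = idx[, 1], weight = s$W[idx])
  df <- df[order(df$pre, df$post), ]
  utils::write.table(df, file, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' @rdname write_connections
#' @export
read_connections <- function(file) {
  utils::read.table(file, header = TRUE, sep = "\t")
}
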