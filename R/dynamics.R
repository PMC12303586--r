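#' Peak-normalized difference-of-exponentials conductance kernel
#'
#' Synaptic conductances follow a standard double-exponential time course
#' \eqn{g(t) = g^{max}(e^{-t/\tau_2} - e^{-t/\tau_1})} with rise time
#' \eqn{\tau_1} and decay time \eqn{\tau_2} (\eqn{\tau_1 < \tau_2}), scaled so
#' that the peak conductance equals 1; synaptic strength is carried entirely
#' by the synaptic weight \eqn{w}.
#'
#' @param t_since_spike Time since the presynaptic spike, ms. Vectorised.
#' @param tau1 Rise time constant, ms.
#' @param tau2 Decay time constant, ms. Must exceed `tau1`.
#' @return Conductance values in `[0, 1]`, dimensionless; 0 at `t = 0`,
#'   maximum 1 at the peak time `(tau1*tau2/(tau2-tau1))*log(tau2/tau1)`.
#' @examples
#' conductance_kernel(0:10, tau1 = 1, tau2 = 2)
#' @export
conductance_kernel <- function(t_since_spike, tau1, tau2) {
  check_kernel_taus(tau1, tau2)
  if (any(t_since_spike < 0)) stop("t_since_spike must be non-negative")
  (exp(-t_since_spike / tau2) - exp(-t_since_spike / tau1)) /
    kernel_peak_value(tau1, tau2)
}

check_kernel_taus <- function(tau1, tau2) {
  if (!is.finite(tau1) || !is.finite(tau2) || tau1 <= 0 || tau2 <= 0)
    stop("conductance time constants must be positive")
  if (tau1 >= tau2)
    stop("rise time tau1 must be smaller than decay time tau2")
  invisible(TRUE)
}

#' Peak time of the conductance kernel (closed form)
#' @param tau1,tau2 Rise and decay time constants, ms.
#' @return Time of the kernel maximum, ms.
#' @export
kernel_peak_time <- function(tau1, tau2) {
  check_kernel_taus(tau1, tau2)
  tau1 * tau2 / (tau2 - tau1) * log(tau2 / tau1)
}

# unnormalized kernel value at its peak
kernel_peak_value <- function(tau1, tau2) {
  tp <- tau1 * tau2 / (tau2 - tau1) * log(tau2 / tau1)
  exp(-tp / tau2) - exp(-tp / tau1)
}

#' Instantaneous firing probability from membrane potential
#'
#' The spiking output function is a piecewise-linear ramp between the spiking
#' threshold \eqn{\theta^{min}} and the saturation threshold
#' \eqn{\theta^{max}}: 0 at or below \eqn{\theta^{min}}, 1 at or above
#' \eqn{\theta^{max}}, linear in between. It is interpreted as a per-timestep
#' Bernoulli spike probability.
#'
#' @param v Membrane potential, mV. Vectorised.
#' @param theta_min Spiking threshold, mV.
#' @param theta_max Saturation threshold, mV. Must exceed `theta_min`
#'   elementwise.
#' @return Probabilities in `[0, 1]`.
#' @export
firing_probability <- function(v, theta_min, theta_max) {
  if (any(theta_min >= theta_max))
    stop("theta_min must be below theta_max")
  pmin(1, pmax(0, (v - theta_min) / (theta_max - theta_min)))
}

#' Synaptic voltage drive
#'
#' Contribution of one synapse class to the external-input term of the
#' membrane equation: \eqn{w \, g(t) \, (E_N - v)}, the conductance times the
#' driving force toward the synaptic reversal potential.
#'
#' @param w Synaptic weight (dimensionless, `>= 0`).
#' @param g Summed conductance kernel value (dimensionless, `>= 0`).
#' @param e_n_abs Absolute reversal potential, mV.
#' @param v Postsynaptic membrane potential, mV.
#' @return Voltage drive, mV (negative when `e_n_abs < v`).
#' @export
synaptic_drive <- function(w, g, e_n_abs, v) {
  w * g * (e_n_abs - v)
}

#' One forward-Euler update of the leaky membrane equation
#'
#' Integrates \eqn{\tau \, dv/dt + v = V^{ext}} for one step of length `dt`,
#' with `v` expressed as the deviation `u = v - V_rest` from rest so that the
#' resting state is the zero fixed point and `v_ext` is the summed external
#' drive (synaptic, sensory, adaptation).
#'
#' @param u Membrane potential deviation from rest, mV. Vectorised.
#' @param v_ext Total external drive, mV.
#' @param tau Membrane time constant, ms.
#' @param dt Integration step, ms.
#' @return Updated deviation from rest, mV.
#' @export
step_membrane <- function(u, v_ext, tau, dt) {
  if (any(dt <= 0) || any(tau <= 0)) stop("dt and tau must be positive")
  out <- u + dt / tau * (v_ext - u)
  if (any(!is.finite(out))) stop("membrane integration produced non-finite values")
  out
}

#' Spike-rate adaptation state update (calcium-dependent K+ current)
#'
#' Pyramidal cells carry a calcium-like adaptation variable that is
#' incremented at each spike and decays first-order with time constant
#' `tau_ca`; it gates a hyperpolarizing potassium conductance whose drive is
#' \eqn{A^{ahc} \, ca \, (E_{ahp} - v)}.
#'
#' @param ca Adaptation variable (dimensionless, `>= 0`). Vectorised.
#' @param spiked Logical (or 0/1) vector, spikes in the current step.
#' @param spec List with fields `a_ahc`, `e_ahp` (mV), `tau_ca` (ms),
#'   `ca_increment`; see [adaptation_spec()].
#' @param v Membrane potential, mV.
#' @param dt Step, ms.
#' @return List with `ca` (decayed then incremented) and `drive` (mV,
#'   computed from the pre-update calcium, i.e. the state entering the step).
#' @export
update_adaptation <- function(ca, spiked, spec, v, dt) {
  drive <- spec$a_ahc * ca * (spec$e_ahp - v)
  ca <- ca * exp(-dt / spec$tau_ca)
  ca <- ca + spec$ca_increment * as.numeric(spiked)
  list(ca = ca, drive = drive)
}

#' Adaptation parameters for pyramidal cells
#'
#' Defaults follow the pyramidal-cell adaptation row of the model parameter
#' table: amplitude \eqn{A^{ahc} = 10}, reversal \eqn{-90} mV (kept absolute:
#' a typical K+ reversal), calcium time constant 100 ms. The calcium increment
#' per spike is a calibration constant (only its product with `a_ahc`
#' matters); the default is calibrated jointly against the single-cell
#' adaptation profile (declining instantaneous rate over the first eight
#' action potentials) and the network-level learning dynamics, where the
#' afterhyperpolarization bounds recurrent excitation.
#'
#' @param a_ahc Amplitude of the K+ conductance effect (dimensionless).
#' @param e_ahp Reversal potential of the adaptation current, mV (absolute).
#' @param tau_ca Calcium decay time constant, ms.
#' @param ca_increment Calcium added per spike (dimensionless).
#' @return A list of class `adaptation_spec`.
#' @export
adaptation_spec <- function(a_ahc = 10, e_ahp = -90, tau_ca = 100,
                            ca_increment = 0.016) {
  if (tau_ca <= 0 || ca_increment <= 0)
    stop("tau_ca and ca_increment must be positive")
  structure(list(a_ahc = a_ahc, e_ahp = e_ahp, tau_ca = tau_ca,
                 ca_increment = ca_increment),
            class = "adaptation_spec")
}

#' Apply an oxytocin condition to the pyramidal population
#'
#' Oxytocin (OXT) increases AON pyramidal-cell excitability by lowering the
#' thresholds of the spiking output function (a rheobase decrease). Under
#' medium OXT the saturation threshold \eqn{\theta^{max}} drops from -55 to
#' its printed -60 mV while \eqn{\theta^{min}} keeps its printed -62 mV
#' (a 2 mV ramp). Under high OXT both thresholds drop a further 2 mV
#' (\eqn{\theta^{min}} -64, \eqn{\theta^{max}} -62): the printed high-OXT
#' saturation value (-65 mV) lies below both the resting potential and the
#' printed \eqn{\theta^{min}}, which would invert the ramp and make the
#' cells fire tonically at rest, so the high condition is represented as a
#' fixed-width ramp 2 mV below the medium one. At every membrane potential
#' the spike probability is non-decreasing in the OXT level, and cells stay
#' silent at rest under all three conditions.
#'
#' @param spec A pyramidal [population_spec()] (or any spec whose thresholds
#'   are stated for the no-OXT condition).
#' @param level One of `"low"`, `"medium"`, `"high"`.
#' @return The spec with shifted thresholds (see [oxt_shift_mv()]).
#' @export
apply_oxt_condition <- function(spec, level) {
  sh <- oxt_shift_mv(level)
  spec$theta_max <- spec$theta_max - sh[["theta_max"]]
  spec$theta_min <- pmin(spec$theta_min - sh[["theta_min"]],
                         spec$theta_max - 2)
  spec
}

#' Threshold shifts for an OXT level
#' @param level One of `"low"`, `"medium"`, `"high"`.
#' @return Named numeric vector with the downward shifts (mV) applied to
#'   `theta_min` and `theta_max` (0/0, 0/5, 2/7).
#' @export
oxt_shift_mv <- function(level) {
  switch(match.arg(level, c("low", "medium", "high")),
         low = c(theta_min = 0, theta_max = 0),
         medium = c(theta_min = 0, theta_max = 5),
         high = c(theta_min = 2, theta_max = 7))
}
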