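#' A voltage-gated gating variable
#'
#' Hodgkin-Huxley style gate with the minimal three-parameter kinetics: the
#' equilibrium value x∞(V) is a Boltzmann function with half voltage
#' `V_half` and slope `k_slope`, and the time constant τ(V) is a bell curve
#' peaking at `V_half` with value `tau_star`. Inactivation gates swap the
#' opening and closing rates, which inverts the Boltzmann.
#'
#' @param name gate label, e.g. "m", "h", "n", "q".
#' @param V_half half-(in)activation voltage (mV).
#' @param k_slope Boltzmann slope (mV), > 0.
#' @param tau_star peak time constant (ms), > 0.
#' @param exponent integer gate power (>= 1), e.g. 8 for n⁸.
#' @param is_inactivation swap opening/closing rates.
#' @param fixed_tau if `TRUE` the time constant is voltage-independent and
#'   equal to `tau_star` (used by the reduced point-Nav model); x∞ stays a
#'   Boltzmann.
#' @return An object of class `gating_variable`.
#' @export
gating_variable <- function(name, V_half, k_slope, tau_star, exponent = 1,
                            is_inactivation = FALSE, fixed_tau = FALSE) {
  if (k_slope <= 0) stop("k_slope must be > 0 (mV)")
  if (tau_star <= 0) stop("tau_star must be > 0 (ms)")
  if (exponent < 1 || exponent != round(exponent))
    stop("exponent must be a positive integer")
  structure(list(name = name, V_half = V_half, k_slope = k_slope,
                 tau_star = tau_star, exponent = as.integer(exponent),
                 is_inactivation = is_inactivation, fixed_tau = fixed_tau),
            class = "gating_variable")
}

# opening rate of an activation gate; the removable singularity at
# V = V_half is evaluated by series expansion
.alpha_raw <- function(V, V_half, k, tau_star) {
  u <- (V - V_half) / k
  small <- abs(u) < 1e-6
  out <- numeric(length(u))
  out[small] <- (1 + u[small] / 2) / (2 * tau_star)   # u/(1-e^-u) ~ 1 + u/2
  ub <- u[!small]
  out[!small] <- ub / (1 - exp(-ub)) / (2 * tau_star)
  out
}

#' Gate opening rate α(V)
#'
#' α(V) = (V − V_half) / (2·k·τ*·(1 − e^(−(V−V_half)/k))), with
#' α(V_half) = 1/(2τ*). For inactivation gates the roles of α and β are
#' exchanged.
#'
#' @param gv a [gating_variable()].
#' @param V membrane potential (mV), vectorized.
#' @return Rate in 1/ms.
#' @export
rate_alpha <- function(gv, V) {
  if (gv$is_inactivation)
    .alpha_raw(-V, -gv$V_half, gv$k_slope, gv$tau_star)
  else
    .alpha_raw(V, gv$V_half, gv$k_slope, gv$tau_star)
}

#' Gate closing rate β(V)
#'
#' β(V) = −(V − V_half) / (2·k·τ*·(1 − e^((V−V_half)/k))); the mirror image
#' of [rate_alpha()].
#'
#' @inheritParams rate_alpha
#' @return Rate in 1/ms.
#' @export
rate_beta <- function(gv, V) {
  if (gv$is_inactivation)
    .alpha_raw(V, gv$V_half, gv$k_slope, gv$tau_star)
  else
    .alpha_raw(-V, -gv$V_half, gv$k_slope, gv$tau_star)
}

#' Gate equilibrium value x∞(V)
#'
#' α/(α+β); analytically a Boltzmann 1/(1 + e^(−(V−V_half)/k)) for
#' activation gates (decreasing for inactivation gates).
#'
#' @inheritParams rate_alpha
#' @return Dimensionless equilibrium value in (0, 1).
#' @export
gate_inf <- function(gv, V) {
  s <- if (gv$is_inactivation) -1 else 1
  1 / (1 + exp(-s * (V - gv$V_half) / gv$k_slope))
}

#' Gate time constant τ(V)
#'
#' 1/(α+β) = 2·τ*·tanh(u/2)/u with u = (V − V_half)/k: a bell curve peaking
#' at `V_half` with value τ*. Constant for `fixed_tau` gates.
#'
#' @inheritParams rate_alpha
#' @return Time constant in ms.
#' @export
gate_tau <- function(gv, V) {
  if (gv$fixed_tau) return(rep(gv$tau_star, length(V)))
  u <- (V - gv$V_half) / gv$k_slope
  out <- rep(gv$tau_star, length(u))
  big <- abs(u) >= 1e-6
  out[big] <- 2 * gv$tau_star * tanh(u[big] / 2) / u[big]
  out
}

#' Temperature correction of a time constant
#'
#' Divides a peak time constant by Q10^((T_sim − T_ref)/10).
#'
#' @param tau_star time constant (ms).
#' @param T_sim simulation temperature (°C).
#' @param T_ref temperature at which the value was measured (°C).
#' @param Q10 rate temperature sensitivity, > 0.
#' @return Corrected time constant (ms).
#' @examples
#' q10_correct(0.150, 33, 23, 2.8)  # 150 µs -> ~54 µs
#' @export
q10_correct <- function(tau_star, T_sim = 33, T_ref = 23, Q10 = 2.8) {
  if (Q10 <= 0) stop("Q10 must be > 0")
  tau_star / Q10^((T_sim - T_ref) / 10)
}

#' A voltage-gated conductance
#'
#' @param name channel label.
#' @param gates list of [gating_variable()]s; empty list for a static
#'   (ungated) conductance.
#' @param E_rev reversal potential (mV).
#' @param density_map named numeric vector of surface conductance densities
#'   (S/m²) per region (`soma`, `dendrite`, `axon`, `ais`); regions absent
#'   from the map get zero density.
#' @return An object of class `channel_spec`.
#' @export
channel_spec <- function(name, gates, E_rev, density_map) {
  if (any(density_map < 0)) stop("densities must be >= 0")
  structure(list(name = name, gates = gates, E_rev = E_rev,
                 density_map = density_map),
            class = "channel_spec")
}

#' The standard channel set of the biophysical model
#'
#' Builds the Nav (one activation gate m, one inactivation gate h), Kv1
#' (n⁸) and Kv7 channel specifications with the default densities and
#' kinetics. Nav kinetics in the AIS are hyperpolarized by 5 mV relative to
#' the soma; Nav time constants (measured at 23 °C) are Q10-corrected to
#' the 33 °C simulation temperature, Kv1's is not (measured at 33 °C).
#'
#' Kv7 kinetics are not fully constrained by published fits; the default is
#' a single slow non-inactivating gate (V_half −30 mV, slope 9 mV,
#' τ* 100 ms), an assumption. For threshold work a static hyperpolarizing
#' conductance (reversal −90 mV) is the better-constrained alternative; see
#' [static_conductance()].
#'
#' @param g_na_ais AIS Nav density (S/m²; default 3500).
#' @param g_k_ais AIS Kv1 density (S/m²; default 1500).
#' @param g_kv7_ais AIS Kv7 density (S/m²; default 0 = absent).
#' @param T_sim simulation temperature (°C).
#' @return Named list of [channel_spec()]s: `Nav_soma`, `Nav_AIS`, `Kv1`,
#'   and (when `g_kv7_ais` > 0) `Kv7`.
#' @export
build_paper_channels <- function(g_na_ais = 3500, g_k_ais = 1500,
                                 g_kv7_ais = 0, T_sim = 33) {
  tau_m <- q10_correct(0.150, T_sim)   # 150 µs at 23 °C
  tau_h <- q10_correct(5, T_sim)       # 5 ms at 23 °C
  ch <- list(
    Nav_soma = channel_spec(
      "Nav_soma",
      list(gating_variable("m", -30, 5, tau_m),
           gating_variable("h", -60, 5, tau_h, is_inactivation = TRUE)),
      E_rev = 70,
      density_map = c(soma = 250, dendrite = 50, axon = 50)),
    Nav_AIS = channel_spec(
      "Nav_AIS",
      list(gating_variable("m", -35, 5, tau_m),
           gating_variable("h", -65, 5, tau_h, is_inactivation = TRUE)),
      E_rev = 70,
      density_map = c(ais = g_na_ais)),
    Kv1 = channel_spec(
      "Kv1",
      list(gating_variable("n", -70, 20, 1, exponent = 8)),
      E_rev = -90,
      density_map = c(soma = 250, dendrite = 50, axon = 50, ais = g_k_ais))
  )
  if (g_kv7_ais > 0) {
    ch$Kv7 <- channel_spec(
      "Kv7",
      list(gating_variable("q", -30, 9, 100)),
      E_rev = -90,
      density_map = c(ais_distal_half = g_kv7_ais))
  }
  ch
}

#' A static (ungated) conductance
#'
#' Ohmic conductance with a fixed density and reversal potential; the
#' stand-in for slow hyperpolarizing channels whose kinetics are irrelevant
#' at the time scale of spike initiation.
#'
#' @param density_map named densities (S/m²) per region; the extra region
#'   `ais_distal_half` targets the distal half of the AIS.
#' @param E_rev reversal potential (mV).
#' @param name channel label.
#' @return A [channel_spec()] with no gates.
#' @export
static_conductance <- function(density_map, E_rev = -90, name = "g_static") {
  channel_spec(name, list(), E_rev, density_map)
}
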