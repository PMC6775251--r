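# Gate kinetics and channel specifications.
#
# Every voltage-dependent gate follows a Boltzmann steady state
#   x_inf(v) = 1 / (1 + exp(-(v - v_half) / slope))
# (slope < 0 encodes inactivation) with a voltage-dependent time constant of
# one of three shapes: constant, Gaussian bell, or sigmoid. Ca2+-dependent
# gates (SK, BK) follow a Hill function of the intracellular concentration.

#' Voltage-dependent gate
#'
#' @param v_half half-activation (or half-inactivation) voltage, mV.
#' @param slope Boltzmann slope, mV; negative values encode inactivation.
#' @param exponent integer power the gate enters the conductance with.
#' @param tau_base,tau_amp,tau_vmax,tau_sigma parameters of the
#'   voltage-dependent time constant (ms; `tau_vmax`, `tau_sigma` in mV).
#' @param tau_shape one of `"constant"`, `"gaussian"` (bell centred at
#'   `tau_vmax`) or `"sigmoid"` (large below `tau_vmax`, small above).
#' @return a `gate` object.
#' @export
gate_v <- function(v_half, slope, exponent = 1, tau_base = 1,
                   tau_shape = c("constant", "gaussian", "sigmoid"),
                   tau_amp = 0, tau_vmax = -60, tau_sigma = 15) {
  tau_shape <- match.arg(tau_shape)
  if (slope == 0) stop_pyrexc("gate slope must be nonzero")
  structure(list(type = "v", v_half = v_half, slope = slope,
                 exponent = exponent, tau_shape = tau_shape,
                 tau_base = tau_base, tau_amp = tau_amp,
                 tau_vmax = tau_vmax, tau_sigma = tau_sigma),
            class = "gate")
}

#' Calcium-dependent gate (Hill activation)
#'
#' @param ca_half half-activation intracellular Ca2+ concentration, mM.
#' @param hill Hill exponent.
#' @param exponent gate power.
#' @param tau_base gate time constant, ms.
#' @export
gate_ca <- function(ca_half, hill, exponent = 1, tau_base = 1) {
  structure(list(type = "ca", ca_half = ca_half, hill = hill,
                 exponent = exponent, tau_base = tau_base),
            class = "gate")
}

#' Steady-state value of a gate
#'
#' @param gate a [gate_v()] or [gate_ca()] object.
#' @param v membrane potential, mV (voltage gates).
#' @param ca intracellular Ca2+, mM (calcium gates).
#' @export
gate_inf <- function(gate, v = NULL, ca = NULL) {
  if (gate$type == "v") 1 / (1 + exp(-(v - gate$v_half) / gate$slope))
  else 1 / (1 + (gate$ca_half / pmax(ca, 1e-9))^gate$hill)
}

#' Time constant of a gate
#' @inheritParams gate_inf
#' @export
gate_tau <- function(gate, v = NULL) {
  if (gate$type == "ca") return(rep(gate$tau_base, length(v %||% 1)))
  tau <- switch(gate$tau_shape,
    constant = rep(gate$tau_base, length(v)),
    gaussian = gate$tau_base +
      gate$tau_amp * exp(-((v - gate$tau_vmax) / gate$tau_sigma)^2),
    sigmoid = gate$tau_base +
      gate$tau_amp / (1 + exp((v - gate$tau_vmax) / gate$tau_sigma)))
  pmax(tau, 1e-4)
}

CHANNEL_NAMES <- c("Nat", "Nap", "Ih", "Im", "Kp", "Kt", "Kv31",
                   "CaHVA", "CaLVA", "CaMVA", "SK", "BK", "leak")

#' Channel specification
#'
#' @param name one of the 13 supported current names (`Nat`, `Nap`, `Ih`,
#'   `Im`, `Kp`, `Kt`, `Kv31`, `CaHVA`, `CaLVA`, `CaMVA`, `SK`, `BK`,
#'   `leak`).
#' @param reversal reversal potential in mV, or `"nernst-Ca"` for Ca2+
#'   currents computed from the instantaneous Nernst potential.
#' @param activation,inactivation [gate_v()] gates or `NULL`.
#' @param ca_gate [gate_ca()] gate or `NULL` (SK/BK only).
#' @export
channel_spec <- function(name, reversal, activation = NULL,
                         inactivation = NULL, ca_gate = NULL) {
  if (!name %in% CHANNEL_NAMES)
    stop_pyrexc("unknown channel name '%s'", name)
  is_ca <- name %in% c("CaHVA", "CaLVA", "CaMVA")
  structure(list(name = name, reversal = reversal, is_ca = is_ca,
                 activation = activation, inactivation = inactivation,
                 ca_gate = ca_gate),
            class = "channel_spec")
}

# Default gate kinetics for the 13 currents. These are package-authored
# Hodgkin-Huxley style parameterizations tuned to reproduce the qualitative
# firing regimes (tonic vs 3-5-spike bursting) of thick-tufted layer V
# pyramidal cells; they are not a replication of any published parameter set.
default_channel_specs <- function(e_na = 50, e_k = -85, e_h = -45,
                                  e_leak = -83) {
  list(
    Nat = channel_spec("Nat", e_na,
      activation = gate_v(-38, 7, exponent = 3, tau_shape = "gaussian",
                          tau_base = 0.05, tau_amp = 0.25, tau_vmax = -40,
                          tau_sigma = 18),
      inactivation = gate_v(-60, -7, tau_shape = "gaussian", tau_base = 0.4,
                            tau_amp = 7, tau_vmax = -62, tau_sigma = 20)),
    Nap = channel_spec("Nap", e_na,
      activation = gate_v(-50, 5, exponent = 1, tau_base = 1)),
    Ih = channel_spec("Ih", e_h,
      activation = gate_v(-91, -6, tau_shape = "gaussian", tau_base = 35,
                          tau_amp = 250, tau_vmax = -85, tau_sigma = 20)),
    Im = channel_spec("Im", e_k,
      activation = gate_v(-35, 10, tau_shape = "sigmoid", tau_base = 15,
                          tau_amp = 80, tau_vmax = -50, tau_sigma = 12)),
    Kp = channel_spec("Kp", e_k,
      activation = gate_v(-11, 12, exponent = 2, tau_shape = "sigmoid",
                          tau_base = 2, tau_amp = 40, tau_vmax = -45,
                          tau_sigma = 12),
      inactivation = gate_v(-64, -11, tau_base = 1000)),
    Kt = channel_spec("Kt", e_k,
      activation = gate_v(-20, 15, exponent = 4, tau_base = 1),
      inactivation = gate_v(-76, -10, tau_shape = "gaussian", tau_base = 8,
                            tau_amp = 30, tau_vmax = -60, tau_sigma = 20)),
    Kv31 = channel_spec("Kv31", e_k,
      activation = gate_v(5, 10, tau_shape = "sigmoid", tau_base = 0.4,
                          tau_amp = 3, tau_vmax = -20, tau_sigma = 10)),
    CaHVA = channel_spec("CaHVA", "nernst-Ca",
      activation = gate_v(-20, 7, exponent = 2, tau_base = 1),
      inactivation = gate_v(-45, -12, tau_base = 300)),
    CaLVA = channel_spec("CaLVA", "nernst-Ca",
      activation = gate_v(-47, 6, exponent = 2, tau_shape = "gaussian",
                          tau_base = 2, tau_amp = 10, tau_vmax = -60,
                          tau_sigma = 15),
      inactivation = gate_v(-80, -6, tau_shape = "gaussian", tau_base = 50,
                            tau_amp = 150, tau_vmax = -70, tau_sigma = 20)),
    # Medium-voltage-activated Ca2+ current: treated as a kinetic alias of
    # the LVA current with a modestly depolarized activation range.
    CaMVA = channel_spec("CaMVA", "nernst-Ca",
      activation = gate_v(-38, 6, exponent = 2, tau_shape = "gaussian",
                          tau_base = 2, tau_amp = 10, tau_vmax = -50,
                          tau_sigma = 15),
      inactivation = gate_v(-65, -6, tau_shape = "gaussian", tau_base = 50,
                            tau_amp = 150, tau_vmax = -65, tau_sigma = 20)),
    SK = channel_spec("SK", e_k,
      ca_gate = gate_ca(ca_half = 4.3e-4, hill = 4, tau_base = 30)),
    BK = channel_spec("BK", e_k,
      activation = gate_v(-10, 12, tau_base = 1),
      ca_gate = gate_ca(ca_half = 1e-3, hill = 2, tau_base = 1)),
    leak = channel_spec("leak", e_leak)
  )
}
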