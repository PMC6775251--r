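# Independent reference solutions used by the solver tests.

# Right-hand side of the single-compartment membrane ODE assembled from a
# compiled model, integrated by deSolve::lsoda (stiff-capable) as an oracle
# independent of the package's cable stepper.
one_comp_oracle <- function(model, stim_fun, times, v0 = model$v_init,
                            rtol = 1e-8, atol = 1e-10) {
  cmp <- pyrexc:::compile_model(model)
  chan <- cmp$chanlist
  cal <- cmp$calcium
  rhs <- function(t, y, parms) {
    V <- y[1]; Ca <- y[2]; gates <- y[-(1:2)]
    gi <- 0; Itot <- 0; ICa <- 0
    eca <- 13.3077 * log(cal$ca_out / max(Ca, 1e-9))
    for (ch in chan) {
      open <- 1
      for (g in ch$gates) { gi <- gi + 1; open <- open * gates[gi]^g$exponent }
      e <- if (ch$nernst_ca) eca else ch$erev
      I <- ch$gbar[1] * open * (V - e)
      Itot <- Itot + I
      if (ch$is_ca) ICa <- ICa + I
    }
    dV <- (-Itot + stim_fun(t)) / cmp$net$cm[1]
    influx <- max(0, -(ICa * 1e-6 / cal$area[1]) * cal$gamma *
                    0.05182136 / cal$depth)
    dCa <- influx + (cal$ca_rest - Ca) / cal$decay_tau
    dg <- numeric(length(gates)); gi <- 0
    for (ch in chan) for (g in ch$gates) {
      gi <- gi + 1
      if (g$type == 0) {
        inf <- 1 / (1 + exp(-(V - g$vhalf) / g$slope))
        tau <- switch(g$tau_shape + 1,
          g$tau_base,
          g$tau_base + g$tau_amp * exp(-((V - g$tau_vmax) / g$tau_sigma)^2),
          g$tau_base + g$tau_amp / (1 + exp((V - g$tau_vmax) / g$tau_sigma)))
      } else {
        inf <- 1 / (1 + (g$ca_half / max(Ca, 1e-9))^g$hill)
        tau <- g$ca_tau
      }
      dg[gi] <- (inf - gates[gi]) / max(tau, 1e-4)
    }
    list(c(dV, dCa, dg))
  }
  g0 <- unlist(lapply(chan, function(ch) vapply(ch$gates, function(g) {
    if (g$type == 0) 1 / (1 + exp(-(v0 - g$vhalf) / g$slope))
    else 1 / (1 + (g$ca_half / cal$ca_rest)^g$hill)
  }, 1.0)))
  y0 <- c(v0, cal$ca_rest, g0)
  deSolve::lsoda(y0, times, rhs, NULL, rtol = rtol, atol = atol)
}

# small helper: delta data frame from triplets
delta_df <- function(...) {
  x <- list(...)
  data.frame(parameter = vapply(x, `[[`, "", 1),
             kind = vapply(x, `[[`, "", 2),
             value = as.numeric(vapply(x, `[[`, "", 3)))
}
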