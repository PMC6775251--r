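# Numerical simulation: stimulus constructors, the simulate() front end over
# the compiled cable solver, spike detection and burst statistics.

#' Current stimuli
#'
#' `stim_dc()` is a direct current from `onset` onwards; `stim_pulse()` a
#' square pulse; `stim_epsp()` a double-exponential EPSP-like current whose
#' peak equals `amplitude`.
#'
#' @param site stimulation site (see [resolve_site()]).
#' @param amplitude nA (peak for the EPSP-like waveform).
#' @param onset,duration ms.
#' @param tau_rise,tau_decay ms (EPSP-like waveform).
#' @export
stim_dc <- function(site, amplitude, onset = 0) {
  structure(list(kind = "square", site = site, onset = onset, duration = Inf,
                 amplitude = amplitude), class = "current_stimulus")
}

#' @rdname stim_dc
#' @export
stim_pulse <- function(site, amplitude, onset, duration) {
  structure(list(kind = "square", site = site, onset = onset,
                 duration = duration, amplitude = amplitude),
            class = "current_stimulus")
}

#' @rdname stim_dc
#' @export
stim_epsp <- function(site, amplitude, onset, tau_rise = 0.5, tau_decay = 5) {
  if (tau_rise >= tau_decay) stop_pyrexc("tau_rise must be < tau_decay")
  structure(list(kind = "epsp", site = site, onset = onset,
                 amplitude = amplitude, tau_rise = tau_rise,
                 tau_decay = tau_decay), class = "current_stimulus")
}

stim_matrix <- function(model, stimuli, compiled, t_shift = 0) {
  if (!length(stimuli)) return(matrix(numeric(0), ncol = 7))
  rows <- lapply(stimuli, function(s) {
    i0 <- resolve_site(model, s$site)
    ic <- match(i0, compiled$order) - 1L
    if (s$kind == "square")
      c(ic, 0, s$onset + t_shift,
        if (is.finite(s$duration)) s$duration else 1e12, s$amplitude, 0, 0)
    else
      c(ic, 1, s$onset + t_shift, 0, s$amplitude, s$tau_rise, s$tau_decay)
  })
  do.call(rbind, rows)
}

#' Simulate a neuron model
#'
#' Deterministic given (model, stimuli, synaptic events, dt): all randomness
#' enters through the synapse event times generated upstream. Voltage and
#' Ca2+ are recorded on a shared grid at every `record_stride`-th step.
#'
#' @param model a `neuron_model`.
#' @param stimuli list of current stimuli ([stim_dc()] etc.).
#' @param duration total simulated time, ms.
#' @param dt time step, ms.
#' @param record_sites list of sites (default soma only).
#' @param synapses a `synapse_population` with resolved activation, or an
#'   event table from [population_events()], or `NULL`.
#' @param seed integer used to realize Poisson activation when `synapses`
#'   carries an unresolved Poisson activation; stored in the result.
#' @param record_stride record every n-th step.
#' @param theta implicitness of the integration scheme (0.5 =
#'   Crank-Nicolson-style).
#' @return a `simulation_result` with elements `time`, `v` (matrix, one
#'   column per site), `ca`, `spike_times` (soma upward 0 mV crossings,
#'   2 ms lockout), `dt`, `sites`, `seed`.
#' @export
simulate <- function(model, stimuli = list(), duration = 1000, dt = 0.025,
                     record_sites = list("soma"), synapses = NULL,
                     seed = NULL, record_stride = 1L, theta = 0.5) {
  if (duration <= 0 || dt <= 0) stop_pyrexc("duration and dt must be > 0")
  compiled <- compile_model(model)
  rec_orig <- vapply(record_sites, function(s) resolve_site(model, s), 1L)
  soma_orig <- resolve_site(model, "soma")
  rec_all <- unique(c(soma_orig, rec_orig))
  rec_idx <- match(rec_all, compiled$order) - 1L

  ev <- matrix(numeric(0), ncol = 4)
  syn_types <- matrix(numeric(0), ncol = 5)
  if (!is.null(synapses)) {
    if (is.list(synapses) && !is.null(synapses$events)) {
      ev <- synapses$events
      syn_types <- synapses$types
    } else {
      evs <- population_events(synapses, duration = duration, seed = seed)
      ev <- evs$events
      syn_types <- evs$types
    }
    if (nrow(ev)) {
      ev <- ev[order(ev[, 1]), , drop = FALSE]
      # map original compartment rows to compiled solver rows
      ev[, 2] <- match(ev[, 2] + 1L, compiled$order) - 1L
    }
  }

  res <- simulate_cable(compiled$net, compiled$chanlist, compiled$calcium,
                        stim_matrix(model, stimuli, compiled),
                        ev, syn_types, duration, dt, as.integer(rec_idx),
                        as.integer(record_stride), model$v_init, theta)
  if (isTRUE(res$diverged))
    stop_pyrexc("simulation diverged (non-finite state) at t = %.3f ms",
                res$t_diverge)
  ns <- res$n_samples
  keep <- match(c(soma_orig, rec_orig), rec_all)
  v <- res$v[seq_len(ns), keep, drop = FALSE]
  ca <- res$ca[seq_len(ns), keep, drop = FALSE]
  site_names <- c("soma", vapply(record_sites, function(s) {
    if (is.character(s)) s else if (is.numeric(s)) paste0("comp", s)
    else paste0(s$kind, "_", s$x)
  }, ""))
  colnames(v) <- colnames(ca) <- site_names
  out <- structure(list(
    time = res$time[seq_len(ns)],
    v = v, ca = ca, dt = dt, seed = seed,
    sites = site_names
  ), class = "simulation_result")
  out$spike_times <- detect_spikes(data.frame(time = out$time,
                                              v = out$v[, 1]))
  out
}

#' @export
print.simulation_result <- function(x, ...) {
  cat(sprintf("<simulation_result: %.1f ms, dt %.3g ms, %d spike(s)>\n",
              max(x$time), x$dt, length(x$spike_times)))
  invisible(x)
}

#' Detect spikes by upward threshold crossing
#'
#' Times where the trace crosses `threshold` upwards, with a refractory
#' lockout: crossings within `lockout` ms of the previous accepted spike are
#' ignored.
#'
#' @param trace a data frame with columns `time` (ms) and `v` (mV), or a
#'   `simulation_result` (soma trace is used).
#' @param threshold mV.
#' @param lockout ms.
#' @return numeric vector of spike times (ms), strictly increasing.
#' @export
detect_spikes <- function(trace, threshold = 0, lockout = 2) {
  if (inherits(trace, "simulation_result"))
    trace <- data.frame(time = trace$time, v = trace$v[, 1])
  v <- trace$v
  n <- length(v)
  if (n < 2) return(numeric(0))
  up <- which(v[-n] < threshold & v[-1] >= threshold) + 1L
  times <- trace$time[up]
  if (!length(times)) return(numeric(0))
  keep <- times[1]
  for (t in times[-1]) if (t - keep[length(keep)] > lockout) keep <- c(keep, t)
  keep
}

#' Spikes-per-burst distribution
#'
#' Groups spikes into bursts separated by inter-spike gaps larger than
#' `burst_gap`, discards the first `discard_first` bursts (initial
#' spike-frequency adaptation), and returns the fraction of bursts with each
#' spike count.
#'
#' @param spike_times increasing spike times, ms.
#' @param burst_gap ms; gaps larger than this separate bursts.
#' @param discard_first number of leading bursts to drop.
#' @return named numeric vector: names are spikes-per-burst counts, values
#'   the fraction of bursts; empty for empty input.
#' @export
spikes_per_burst <- function(spike_times, burst_gap = 50, discard_first = 2) {
  if (burst_gap <= 0) stop_pyrexc("burst_gap must be > 0")
  if (!length(spike_times)) return(setNames(numeric(0), character(0)))
  breaks <- c(0, which(diff(spike_times) > burst_gap), length(spike_times))
  sizes <- diff(breaks)
  if (discard_first > 0) sizes <- sizes[-seq_len(min(discard_first, length(sizes)))]
  if (!length(sizes)) return(setNames(numeric(0), character(0)))
  tab <- table(sizes)
  setNames(as.numeric(tab) / sum(tab), names(tab))
}

#' Modal spikes-per-burst
#'
#' The burst size carrying the largest fraction of bursts (ties broken
#' toward the larger count).
#' @inheritParams spikes_per_burst
#' @export
modal_spikes_per_burst <- function(spike_times, burst_gap = 50,
                                   discard_first = 2) {
  d <- spikes_per_burst(spike_times, burst_gap, discard_first)
  if (!length(d)) return(NA_real_)
  counts <- as.numeric(names(d))
  max(counts[d == max(d)])
}

#' Export recorded traces as CSV
#'
#' Long format with columns `time_ms`, `site`, `v_mV`, `ca_mM`.
#' @param result a `simulation_result`.
#' @param path output file.
#' @export
write_traces_csv <- function(result, path) {
  out <- do.call(rbind, lapply(seq_along(result$sites), function(j) {
    data.frame(time_ms = result$time, site = result$sites[j],
               v_mV = result$v[, j], ca_mM = result$ca[, j])
  }))
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}
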