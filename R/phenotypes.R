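# The four phenotype protocol families: steady-state f-I curves and their
# integral averages; simplistic and noisy up/down-state coincidence windows;
# prepulse-mediated adaptation curves.

#' Steady-state f-I curve
#'
#' Somatic DC of each amplitude; rate = spike count after the equilibration
#' period divided by the analysis window.
#'
#' @param model a `neuron_model`.
#' @param amplitudes increasing DC amplitudes, nA.
#' @param duration total stimulus time, ms (analysis window is
#'   `duration - equil`).
#' @param equil equilibration excluded from the rate, ms.
#' @param dt time step, ms.
#' @return an `fI_curve` with `amplitudes` (nA) and `rates` (Hz).
#' @export
fI_curve <- function(model, amplitudes = NULL, duration = 3500, equil = 500,
                     dt = 0.025) {
  amplitudes <- amplitudes %||% default_fI_spec(model)$amplitudes
  if (is.unsorted(amplitudes)) stop_pyrexc("amplitudes must be increasing")
  rates <- vapply(amplitudes, function(a) {
    res <- simulate(model, list(stim_dc("soma", a, onset = 0)),
                    duration = duration, dt = dt, record_stride = 4L)
    sum(res$spike_times > equil) / ((duration - equil) / 1000)
  }, 1.0)
  structure(list(amplitudes = amplitudes, rates = rates,
                 duration = duration), class = "fI_curve")
}

#' Integral average of an f-I curve
#'
#' Trapezoid integral of the rate over `range` divided by the range width.
#'
#' @param curve an `fI_curve` (or any list with `amplitudes`, `rates`).
#' @param range nA interval; defaults to the curve's full support.
#' @return average rate, Hz.
#' @export
fI_average <- function(curve, range = NULL) {
  range <- range %||% range(curve$amplitudes)
  lo <- max(range[1], min(curve$amplitudes))
  hi <- min(range[2], max(curve$amplitudes))
  if (hi <= lo) stop_pyrexc("empty overlap between range and curve support")
  xs <- curve$amplitudes
  inside <- xs > lo & xs < hi
  grid <- c(lo, xs[inside], hi)
  ys <- approx(xs, curve$rates, xout = grid)$y
  trapz(grid, ys) / (hi - lo)
}

#' Protocol presets for the coincidence-detection experiments
#'
#' Two named apical EPSP presets from the up-state protocol: site 600 um
#' with 50% relative amplitude (default) and site 850 um with 15%.
#'
#' @param epsp_site apical EPSP site, um.
#' @param epsp_frac EPSP amplitude as a fraction of its own somatic-spike
#'   threshold.
#' @param record_x recording site, um.
#' @param hold_frac 600-ms apical holding-pulse amplitude fraction (up
#'   state).
#' @param soma_frac somatic 5-ms pulse amplitude fraction (up state).
#' @param down_soma_frac somatic amplitude fraction in the down state.
#' @param noisy_epsp_frac EPSP fraction used in the noisy up state.
#' @export
coincidence_preset <- function(epsp_site = 600, epsp_frac = 0.5,
                               record_x = 700, hold_frac = 0.85,
                               soma_frac = 0.40, down_soma_frac = 1.35,
                               noisy_epsp_frac = 0.25) {
  list(epsp_site = epsp_site, epsp_frac = epsp_frac, record_x = record_x,
       hold_frac = hold_frac, soma_frac = soma_frac,
       down_soma_frac = down_soma_frac, noisy_epsp_frac = noisy_epsp_frac,
       hold_site = 200, hold_dur = 600, soma_dur = 5,
       epsp_tau = c(0.5, 5), response_window = 300)
}

# Thresholds the coincidence protocols are expressed against. The somatic
# 5-ms pulse threshold is resolved both at rest (down state) and under the
# 85% holding depolarization (up state), so the up-state pulse fraction is
# genuinely subthreshold in its own state.
coincidence_thresholds <- function(model, preset, tol = 0.01, dt = 0.025,
                                   equil = 500) {
  onset <- equil + 10
  t_soma <- bisect_threshold(function(a) {
    res <- simulate(model, list(stim_pulse("soma", a, onset, preset$soma_dur)),
                    duration = onset + 100, dt = dt)
    count_spikes_after(res, equil)
  }, hi = 1, tol = tol)
  t_hold <- bisect_threshold(function(a) {
    res <- simulate(model, list(stim_pulse(list(kind = "apical",
                                                x = preset$hold_site),
                                           a, onset, preset$hold_dur)),
                    duration = onset + preset$hold_dur + 50, dt = dt)
    count_spikes_after(res, equil)
  }, hi = 1, tol = tol)
  hold_stim <- stim_pulse(list(kind = "apical", x = preset$hold_site),
                          preset$hold_frac * t_hold, onset,
                          preset$hold_dur)
  t_soma_up <- bisect_threshold(function(a) {
    res <- simulate(model,
                    list(hold_stim,
                         stim_pulse("soma", a,
                                    onset + preset$hold_dur / 2,
                                    preset$soma_dur)),
                    duration = onset + preset$hold_dur + 50, dt = dt)
    count_spikes_after(res, onset + preset$hold_dur / 2 - 5)
  }, hi = 1, tol = tol)
  t_epsp <- bisect_threshold(function(a) {
    res <- simulate(model, list(stim_epsp(list(kind = "apical",
                                               x = preset$epsp_site),
                                          a, onset, preset$epsp_tau[1],
                                          preset$epsp_tau[2])),
                    duration = onset + 150, dt = dt)
    count_spikes_after(res, equil)
  }, hi = 2, tol = tol)
  list(soma = t_soma, soma_up = t_soma_up, hold = t_hold, epsp = t_epsp)
}

#' Up/down-state coincidence-detection window (noiseless)
#'
#' Up state: a 600-ms apical holding pulse at 200 um (85% of its own spike
#' threshold) with a 5-ms somatic pulse (40% of threshold) in its middle;
#' an EPSP-like current (rise 0.5 ms, decay 5 ms) at the preset apical site
#' offset by each inter-stimulus interval (positive ISI = apical after
#' somatic). Down state: no holding pulse, somatic amplitude 135% of
#' threshold. The response per ISI is the maximum membrane potential at the
#' recording site (default 700 um) over the post-stimulus window.
#'
#' @param model a `neuron_model`.
#' @param state `"up"` or `"down"`.
#' @param isi_grid ISI grid, ms (default -30..70 in 10-ms steps).
#' @param preset a [coincidence_preset()].
#' @param thresholds optional precomputed [coincidence_thresholds()]
#'   (per-model; computed when missing).
#' @param equil equilibration, ms.
#' @param dt time step, ms.
#' @return a `temporal_window` with `isi`, `response` (mV), `state`, `site`.
#' @export
coincidence_window <- function(model, state = c("up", "down"),
                               isi_grid = seq(-30, 70, by = 10),
                               preset = coincidence_preset(),
                               thresholds = NULL, equil = 500, dt = 0.025) {
  state <- match.arg(state)
  thr <- thresholds %||% coincidence_thresholds(model, preset, dt = dt,
                                                equil = equil)
  rec_site <- list(kind = "apical", x = preset$record_x)
  resp <- vapply(isi_grid, function(isi) {
    t_soma <- equil + max(50, 50 - isi) + if (state == "up")
      preset$hold_dur / 2 else 0
    stims <- list()
    if (state == "up") {
      stims <- c(stims, list(
        stim_pulse(list(kind = "apical", x = preset$hold_site),
                   preset$hold_frac * thr$hold,
                   onset = t_soma - preset$hold_dur / 2,
                   duration = preset$hold_dur),
        stim_pulse("soma", preset$soma_frac * thr$soma_up, t_soma,
                   preset$soma_dur)))
    } else {
      stims <- c(stims, list(
        stim_pulse("soma", preset$down_soma_frac * thr$soma, t_soma,
                   preset$soma_dur)))
    }
    stims <- c(stims, list(
      stim_epsp(list(kind = "apical", x = preset$epsp_site),
                preset$epsp_frac * thr$epsp, t_soma + isi,
                preset$epsp_tau[1], preset$epsp_tau[2])))
    res <- simulate(model, stims,
                    duration = t_soma + preset$response_window + 50,
                    dt = dt, record_sites = list(rec_site))
    win <- res$time >= min(t_soma, t_soma + isi) &
      res$time <= t_soma + preset$response_window
    max(res$v[win, 2])
  }, 1.0)
  structure(list(isi = isi_grid, response = resp, state = state,
                 site = preset$record_x), class = "temporal_window")
}

#' Integral of a temporal window above a baseline
#'
#' Trapezoid integral over ISI of (response - baseline), mV ms.
#'
#' @param window a `temporal_window`.
#' @param baseline mV (the published analysis subtracts -50 mV for the
#'   tonic-like and -40 mV for the bursting-like profile).
#' @export
window_integral <- function(window, baseline = -50) {
  trapz(window$isi, window$response - baseline)
}

#' Background rates of the noisy up and down states
#'
#' The excitatory drive is modulated from the in-vivo baseline of 0.72 Hz:
#' decreased by 30% in the down state (0.504 Hz), increased by 10% in the
#' up state (0.792 Hz).
#'
#' @param base_rate baseline glutamatergic activation rate, Hz.
#' @return named vector `c(down = , up = )`, Hz.
#' @export
updown_rates <- function(base_rate = 0.72) {
  c(down = base_rate * 0.7, up = base_rate * 1.1)
}

#' Noisy up/down-state coincidence window
#'
#' Up/down states are modelled by raised/lowered excitatory background
#' rates: down = 0.504 Hz (0.72 x 0.7), up = 0.792 Hz (0.72 x 1.1),
#' inhibitory rate 7.0 Hz throughout. Per ISI the response is the mean
#' apical membrane potential during the 20 ms following the somatic pulse,
#' averaged over `n_rep` repetitions differing only in the background seed.
#'
#' @inheritParams coincidence_window
#' @param n_rep repetitions (published protocol: 125).
#' @param seed integer; repetition r uses a seed derived from it.
#' @param n_background number of glutamatergic background synapses (the
#'   inhibitory count is scaled proportionally).
#' @return a `temporal_window` of mean responses.
#' @export
noisy_updown <- function(model, state = c("up", "down"),
                         isi_grid = seq(-30, 70, by = 20), n_rep = 125,
                         seed = 1, preset = coincidence_preset(),
                         thresholds = NULL, equil = 500, dt = 0.025,
                         n_background = 10000) {
  state <- match.arg(state)
  exc_rate <- unname(updown_rates()[state])
  thr <- thresholds %||% coincidence_thresholds(model, preset, dt = dt,
                                                equil = equil)
  soma_amp <- if (state == "up") preset$soma_frac * thr$soma
              else preset$down_soma_frac * thr$soma
  epsp_amp <- if (state == "up") preset$noisy_epsp_frac * thr$epsp
              else preset$epsp_frac * thr$epsp
  n_inh <- round(n_background / 4)
  pop <- background_population(model, seed = derive_seed(seed, "bg-place"),
                               exc_rate = exc_rate, n_exc = n_background,
                               n_inh = n_inh)
  rec_site <- list(kind = "apical", x = preset$record_x)
  resp <- vapply(isi_grid, function(isi) {
    t_soma <- equil + max(50, 50 - isi)
    dur <- t_soma + 100
    means <- vapply(seq_len(n_rep), function(r) {
      stims <- list(
        stim_pulse("soma", soma_amp, t_soma, preset$soma_dur),
        stim_epsp(list(kind = "apical", x = preset$epsp_site), epsp_amp,
                  t_soma + isi, preset$epsp_tau[1], preset$epsp_tau[2]))
      res <- simulate(model, stims, duration = dur, dt = dt,
                      record_sites = list(rec_site), synapses = pop,
                      seed = derive_seed(seed, "rep", r, round(isi)))
      win <- res$time >= t_soma & res$time <= t_soma + 20
      mean(res$v[win, 2])
    }, 1.0)
    mean(means)
  }, 1.0)
  structure(list(isi = isi_grid, response = resp, state = state,
                 site = preset$record_x, n_rep = n_rep),
            class = "temporal_window")
}

#' Background-only firing rate
#'
#' Firing rate of the model under the Poisson background alone (no other
#' stimuli); used to characterize the noisy up and down states.
#'
#' @param model a `neuron_model`.
#' @param exc_rate excitatory background rate, Hz.
#' @param duration ms.
#' @param seed integer.
#' @param n_background glutamatergic synapse count.
#' @export
background_rate <- function(model, exc_rate, duration = 5500, equil = 500,
                            seed = 1, dt = 0.025, n_background = 10000) {
  pop <- background_population(model, seed = derive_seed(seed, "bg-place"),
                               exc_rate = exc_rate,
                               n_exc = n_background,
                               n_inh = round(n_background / 4))
  res <- simulate(model, duration = duration, dt = dt, synapses = pop,
                  seed = seed, record_stride = 4L)
  sum(res$spike_times > equil) / ((duration - equil) / 1000)
}

#' Prepulse-mediated adaptation curve
#'
#' A synchronized apical alpha-synapse probe (default 3000 synapses at path
#' distance >= 300 um) is activated at t = 0 at 110% of its threshold
#' conductance g_th, and again after each inter-stimulus interval at
#' `factor x g_th`; the threshold factor for an additional spike (any spike
#' after the second activation) is found by bisection per ISI. ISIs short
#' enough that no conductance up to `factor_cap` g_th elicits an additional
#' spike (absolute refractoriness of the adaptation current) record the
#' censored value `factor_cap`; the default grid therefore starts at
#' 200 ms, past the reduced model's absolutely refractory window.
#'
#' @param model a `neuron_model`.
#' @param isi_grid ISIs, ms.
#' @param population optional probe population ([place_synapses()]); the
#'   default 3000-synapse probe is built with `seed`.
#' @param n_synapses probe size when building the default population.
#' @param seed placement seed.
#' @param tol bisection tolerance on the factor.
#' @param factor_cap upper bracket of the factor bisection; ISIs with no
#'   additional spike at the cap are recorded at this (censored) value.
#' @param equil equilibration, ms.
#' @param dt time step, ms.
#' @return a `prepulse_curve` with `isi`, `threshold_factor` and `g_th`
#'   (per-synapse threshold conductance, nS).
#' @export
prepulse_curve <- function(model, isi_grid = c(200, 300, 500, 1000, 2000),
                           population = NULL, n_synapses = 3000, seed = 1,
                           tol = 0.01, factor_cap = 4, equil = 500,
                           dt = 0.025) {
  pop <- population %||% place_synapses(
    model, n_synapses, syn_kinetics("alpha", g_max = 1, e_rev = 0,
                                    tau_decay = 5),
    kind = "apical", dist_min = 300, seed = derive_seed(seed, "prepulse"))
  g_th <- bisect_threshold(function(s) {
    ev <- population_events(pop, activations = data.frame(time = equil,
                                                          scale = s))
    res <- simulate(model, synapses = ev, duration = equil + 200, dt = dt)
    count_spikes_after(res, equil)
  }, hi = 0.01, tol = tol / 2)
  factors <- vapply(isi_grid, function(isi) {
    f <- function(fac) {
      ev <- population_events(pop, activations = data.frame(
        time = c(equil, equil + isi), scale = c(1.10, fac) * g_th))
      res <- simulate(model, synapses = ev, duration = equil + isi + 200,
                      dt = dt, record_stride = 2L)
      count_spikes_after(res, equil + isi)
    }
    tryCatch(bisect_threshold(f, lo = 0.05, hi = factor_cap, tol = tol,
                              max_expand = 0),
             error = function(e) factor_cap)
  }, 1.0)
  structure(list(isi = isi_grid, threshold_factor = factors, g_th = g_th),
            class = "prepulse_curve")
}

#' Maximal prepulse threshold factor
#'
#' Maximum of the adaptation curve over ISIs larger than `isi_min`
#' (the published analysis excludes the first 40 ms).
#'
#' @param curve a `prepulse_curve`.
#' @param isi_min ms.
#' @export
max_prepulse_factor <- function(curve, isi_min = 40) {
  sel <- curve$isi > isi_min & is.finite(curve$threshold_factor)
  if (!any(sel)) return(NA_real_)
  max(curve$threshold_factor[sel])
}
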