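# Conductance-based synapses: kernels, NMDA Mg2+ block, short-term
# depression, Poisson drive, placement rules and the in-vivo-like background
# population.

#' Synapse kinetics
#'
#' Dual-exponential (`AMPA`, `NMDA`, `GABA`) or alpha-function (`alpha`)
#' conductance kernels, normalized so the single-event peak equals `g_max`.
#'
#' @param receptor `"AMPA"`, `"NMDA"`, `"GABA"` or `"alpha"`.
#' @param g_max peak conductance, nS.
#' @param e_rev reversal potential, mV.
#' @param tau_rise,tau_decay kernel time constants, ms; for the alpha kernel
#'   only `tau_decay` is used (the alpha time constant).
#' @param mg_block logical; apply the voltage-dependent Mg2+ block (NMDA).
#' @param depression `NULL` or `list(D = <ms>, U_se = <fraction>)`:
#'   depression-only resource model.
#' @export
syn_kinetics <- function(receptor = c("AMPA", "NMDA", "GABA", "alpha"),
                         g_max, e_rev = 0, tau_rise = 0.3, tau_decay = 3,
                         mg_block = identical(receptor, "NMDA"),
                         depression = NULL) {
  receptor <- match.arg(receptor)
  if (receptor != "alpha" && tau_rise >= tau_decay)
    stop_pyrexc("tau_rise must be < tau_decay for dual-exponential kernels")
  if (!is.null(depression)) {
    if (depression$U_se <= 0 || depression$U_se > 1 || depression$D <= 0)
      stop_pyrexc("depression needs 0 < U_se <= 1 and D > 0")
  }
  structure(list(receptor = receptor, g_max = g_max, e_rev = e_rev,
                 tau_rise = tau_rise, tau_decay = tau_decay,
                 mg_block = isTRUE(mg_block), depression = depression),
            class = "syn_kinetics")
}

# default receptor parameter sets used by the background population
default_receptors <- function() {
  list(
    AMPA = syn_kinetics("AMPA", g_max = 0.4, e_rev = 0, tau_rise = 0.3,
                        tau_decay = 3,
                        depression = list(D = 800, U_se = 0.6)),
    NMDA = syn_kinetics("NMDA", g_max = 0.4, e_rev = 0, tau_rise = 2,
                        tau_decay = 65, mg_block = TRUE,
                        depression = list(D = 800, U_se = 0.6)),
    GABA = syn_kinetics("GABA", g_max = 1.0, e_rev = -80, tau_rise = 1,
                        tau_decay = 20,
                        depression = list(D = 800, U_se = 0.25))
  )
}

#' Voltage-dependent Mg2+ block factor
#'
#' The sigmoid NMDA-conductance factor (Jahr-Stevens form)
#' `1 / (1 + exp(-0.062 v) * mg / 3.57)`: strictly increasing in `v`, tends
#' to 1 at depolarized and 0 at hyperpolarized potentials.
#'
#' @param v membrane potential, mV.
#' @param mg extracellular Mg2+ concentration, mM.
#' @export
mg_block_factor <- function(v, mg = 1) {
  if (mg <= 0) stop_pyrexc("mg must be > 0")
  1 / (1 + exp(-0.062 * v) * mg / 3.57)
}

#' Short-term depression release fractions
#'
#' Depression-only resource recursion: with resources `R_1 = 1`, event n
#' releases `U_se * R_n`, and
#' `R_{n+1} = 1 - (1 - R_n (1 - U_se)) exp(-dt_n / D)`.
#'
#' @param event_times sorted event times, ms.
#' @param D recovery time constant, ms.
#' @param U_se single-release consumption fraction.
#' @return per-event release fractions in (0, U_se].
#' @export
depression_scale <- function(event_times, D = 800, U_se = 0.6) {
  n <- length(event_times)
  if (!n) return(numeric(0))
  rel <- numeric(n)
  R <- 1
  for (i in seq_len(n)) {
    rel[i] <- U_se * R
    if (i < n) {
      dt <- event_times[i + 1] - event_times[i]
      R <- 1 - (1 - R * (1 - U_se)) * exp(-dt / D)
    }
  }
  rel
}

#' Synaptic conductance waveform
#'
#' Analytic sum over events of peak-normalized kernels times `g_max`, the
#' per-event depression scale and (for NMDA) the Mg2+-block factor
#' evaluated on the supplied voltage trace.
#'
#' @param kin a [syn_kinetics()].
#' @param event_times sorted event times, ms.
#' @param t evaluation grid, ms.
#' @param v optional voltage trace aligned with `t` (required when
#'   `kin$mg_block`).
#' @param mg Mg2+ concentration, mM.
#' @return conductance trace, nS.
#' @export
conductance_waveform <- function(kin, event_times, t, v = NULL, mg = 1) {
  g <- numeric(length(t))
  if (!length(event_times)) return(g)
  scale <- if (!is.null(kin$depression))
    depression_scale(event_times, kin$depression$D, kin$depression$U_se) /
      kin$depression$U_se
  else rep(1, length(event_times))
  for (i in seq_along(event_times)) {
    dt <- t - event_times[i]
    on <- dt >= 0
    if (kin$receptor == "alpha") {
      tau <- kin$tau_decay
      k <- ifelse(on, dt / tau * exp(1 - dt / tau), 0)
    } else {
      tr <- kin$tau_rise; td <- kin$tau_decay
      tp <- tr * td / (td - tr) * log(td / tr)
      norm <- 1 / (exp(-tp / td) - exp(-tp / tr))
      k <- ifelse(on, norm * (exp(-dt / td) - exp(-dt / tr)), 0)
    }
    g <- g + kin$g_max * scale[i] * k
  }
  if (kin$mg_block) {
    if (is.null(v)) stop_pyrexc("mg_block requires a voltage trace")
    g <- g * mg_block_factor(v, mg)
  }
  g
}

#' Homogeneous Poisson event times
#'
#' @param rate Hz.
#' @param duration ms.
#' @param seed integer; reproducible realizations.
#' @export
poisson_times <- function(rate, duration, seed = NULL) {
  if (rate < 0) stop_pyrexc("rate must be >= 0")
  if (rate == 0 || duration <= 0) return(numeric(0))
  with_local_seed(seed, {
    # expected count = rate(Hz) * duration(s)
    n_exp <- rate * duration / 1000
    n <- stats::rpois(1, n_exp)
    sort(runif(n, 0, duration))
  })
}

#' Place synapses over a dendritic region
#'
#' Members are placed uniformly over the eligible path length (not uniformly
#' over compartments) of compartments of `kind` whose path distance lies in
#' `[dist_min, dist_max)`.
#'
#' @param model a `neuron_model`.
#' @param n number of synapses.
#' @param kin a [syn_kinetics()].
#' @param kind compartment kind(s), default `"apical"`.
#' @param dist_min,dist_max eligible path-distance window, um.
#' @param seed integer.
#' @return a `synapse_population`.
#' @export
place_synapses <- function(model, n, kin, kind = "apical", dist_min = 0,
                           dist_max = Inf, seed = NULL) {
  m <- model$morph
  lo <- m$path_distance - m$length / 2
  hi <- m$path_distance + m$length / 2
  elig <- which(m$kind %in% kind & hi > dist_min & lo < dist_max)
  if (!length(elig)) stop_pyrexc("empty eligible region for synapse placement")
  seg_lo <- pmax(lo[elig], dist_min)
  seg_hi <- pmin(hi[elig], dist_max)
  seg_len <- seg_hi - seg_lo
  if (n == 0) {
    members <- data.frame(comp = integer(0), distance = numeric(0),
                          group = integer(0), kin_id = integer(0))
  } else {
    pos <- with_local_seed(seed, runif(n, 0, sum(seg_len)))
    cum <- cumsum(seg_len)
    sel <- findInterval(pos, c(0, cum), rightmost.closed = TRUE)
    sel[sel > length(elig)] <- length(elig)
    dist <- seg_lo[sel] + (pos - c(0, cum)[sel])
    members <- data.frame(comp = elig[sel], distance = dist,
                          group = seq_len(n), kin_id = 1L)
  }
  structure(list(members = members, kinetics = list(kin),
                 activation = NULL),
            class = "synapse_population")
}

#' @export
print.synapse_population <- function(x, ...) {
  cat(sprintf("<synapse_population: %d member(s), %d receptor type(s)>\n",
              nrow(x$members), length(x$kinetics)))
  invisible(x)
}

#' In-vivo-like background synapse population
#'
#' 10,000 glutamatergic synapses (co-located AMPA + NMDA sharing event
#' times, peak 0.4 nS per receptor, depression U_se = 0.6) and 2,500
#' GABAergic synapses (1.0 nS, U_se = 0.25) placed uniformly over the apical
#' and basal dendrites, Poisson-activated at `exc_rate` / `inh_rate`.
#'
#' @param model a `neuron_model`.
#' @param seed integer driving placement (activation times are drawn at
#'   simulation time from the simulation seed).
#' @param exc_rate,inh_rate Poisson rates, Hz.
#' @param n_exc,n_inh synapse counts.
#' @export
background_population <- function(model, seed = NULL, exc_rate = 0.72,
                                  inh_rate = 7.0, n_exc = 10000,
                                  n_inh = 2500) {
  if (exc_rate < 0 || inh_rate < 0) stop_pyrexc("rates must be >= 0")
  rec <- default_receptors()
  glut <- place_synapses(model, n_exc, rec$AMPA, kind = c("apical", "basal"),
                         seed = derive_seed(seed, "bg-exc"))
  gaba <- place_synapses(model, n_inh, rec$GABA, kind = c("apical", "basal"),
                         seed = derive_seed(seed, "bg-inh"))
  # glutamatergic members appear twice (AMPA kin 1, NMDA kin 2) with a shared
  # event group so AMPA and NMDA see identical presynaptic spike trains
  members <- rbind(
    transform(glut$members, kin_id = 1L),
    transform(glut$members, kin_id = 2L),
    transform(gaba$members, group = gaba$members$group + n_exc, kin_id = 3L))
  structure(list(
    members = members,
    kinetics = list(rec$AMPA, rec$NMDA, rec$GABA),
    activation = list(mode = "poisson",
                      rate = c(rep(exc_rate, n_exc), rep(inh_rate, n_inh)))),
    class = "synapse_population")
}

#' Realize a population's activation into solver events
#'
#' @param pop a `synapse_population`.
#' @param duration ms (Poisson activation).
#' @param activations for simultaneous activation: a data frame with columns
#'   `time` (ms) and `scale` (conductance factor applied to `g_max`);
#'   overrides the population's stored activation.
#' @param seed integer for Poisson realizations.
#' @return list with `events` (matrix: time, 0-based compartment row, 0-based
#'   receptor-type index, peak conductance in uS) and `types` (matrix of
#'   receptor parameters).
#' @export
population_events <- function(pop, duration = NULL, activations = NULL,
                              seed = NULL) {
  types <- do.call(rbind, lapply(pop$kinetics, function(k) {
    c(tau_rise = k$tau_rise, tau_decay = k$tau_decay, e_rev = k$e_rev,
      mg_on = as.numeric(k$mg_block),
      alpha = as.numeric(k$receptor == "alpha"))
  }))
  mem <- pop$members
  if (!nrow(mem))
    return(list(events = matrix(numeric(0), ncol = 4), types = types))

  ev_list <- list()
  if (!is.null(activations)) {
    for (r in seq_len(nrow(activations))) {
      t0 <- activations$time[r]
      sc <- activations$scale[r]
      k <- vapply(mem$kin_id, function(id) pop$kinetics[[id]]$g_max, 1)
      ev_list[[r]] <- cbind(t0, mem$comp - 1L, mem$kin_id - 1L,
                            k * sc * 1e-3)
    }
    ev <- do.call(rbind, ev_list)
    # per-group depression across repeated activations
    ev <- apply_event_depression(ev, mem, pop, rep(mem$group,
                                                   nrow(activations)))
    return(list(events = ev, types = types))
  }

  act <- pop$activation
  if (is.null(act)) stop_pyrexc("population has no activation; supply `activations`")
  if (act$mode == "poisson") {
    if (is.null(duration)) stop_pyrexc("Poisson activation needs a duration")
    groups <- sort(unique(mem$group))
    rates <- act$rate
    rate_of <- if (length(rates) == 1) rep(rates, length(groups))
               else rates[groups]
    # one presynaptic spike train per group, shared by all of the group's
    # receptors; drawn in fixed group order under a single seeded RNG
    ev <- with_local_seed(seed, {
      counts <- stats::rpois(length(groups), rate_of * duration / 1000)
      g_times <- lapply(counts, function(k) sort(runif(k, 0, duration)))
      # per-group, per-receptor depression scale on the shared train
      rel_of <- function(times, kin) {
        if (is.null(kin$depression) || length(times) < 2)
          return(rep(1, length(times)))
        depression_scale(times, kin$depression$D, kin$depression$U_se) /
          kin$depression$U_se
      }
      gidx <- match(mem$group, groups)
      nev_mem <- counts[gidx]
      keep <- nev_mem > 0
      if (!any(keep)) matrix(numeric(0), ncol = 4)
      else {
        mm <- mem[keep, , drop = FALSE]
        gi <- gidx[keep]
        times_list <- g_times[gi]
        w_list <- lapply(seq_len(nrow(mm)), function(j) {
          kin <- pop$kinetics[[mm$kin_id[j]]]
          kin$g_max * rel_of(times_list[[j]], kin) * 1e-3
        })
        cbind(unlist(times_list),
              rep(mm$comp - 1L, lengths(times_list)),
              rep(mm$kin_id - 1L, lengths(times_list)),
              unlist(w_list))
      }
    })
    return(list(events = ev, types = types))
  }
  stop_pyrexc("unknown activation mode '%s'", act$mode)
}

# scale repeated-activation events by the depression recursion, per synapse
apply_event_depression <- function(ev, mem, pop, groups) {
  if (!nrow(ev)) return(ev)
  kin_by_row <- ev[, 3] + 1L
  for (g in unique(groups)) {
    for (k in unique(kin_by_row)) {
      kin <- pop$kinetics[[k]]
      if (is.null(kin$depression)) next
      sel <- which(groups == g & kin_by_row == k)
      if (length(sel) < 2) next
      o <- order(ev[sel, 1])
      rel <- depression_scale(ev[sel[o], 1], kin$depression$D,
                              kin$depression$U_se) / kin$depression$U_se
      ev[sel[o], 4] <- ev[sel[o], 4] * rel
    }
  }
  ev
}
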