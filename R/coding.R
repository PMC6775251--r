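# Neural coding analysis: dendritic region partition, per-region synaptic
# thresholds, discretized 128-pattern response tables, Hamming distances,
# output diversity and input-output correlations.

#' Dendritic region partition
#'
#' Six apical regions (0-200, 200-400, 400-600, 600-800, 800-1000, > 1000
#' um from the soma) plus the basal dendrites as the seventh region.
#'
#' @return a data frame with columns `region`, `kind`, `lo`, `hi` (um,
#'   half-open `[lo, hi)`).
#' @export
region_partition <- function() {
  data.frame(
    region = c(paste0("apic", 1:6), "basal"),
    kind = c(rep("apical", 6), "basal"),
    lo = c(0, 200, 400, 600, 800, 1000, 0),
    hi = c(200, 400, 600, 800, 1000, Inf, Inf),
    stringsAsFactors = FALSE)
}

#' Discretization specification for output patterns
#'
#' Spike counts are capped at `spike_cap`; the per-region Ca2+ level is 0
#' below `ca_low`, 1 between `ca_low` and `ca_high`, 2 above `ca_high`.
#'
#' @param ca_low,ca_high mM.
#' @param spike_cap maximal recorded spike count.
#' @export
discretization_spec <- function(ca_low = 0.00011, ca_high = 0.00012,
                                spike_cap = 3) {
  if (ca_low >= ca_high) stop_pyrexc("ca_low must be < ca_high")
  list(ca_low = ca_low, ca_high = ca_high, spike_cap = spike_cap)
}

#' Binary input patterns over the region partition
#'
#' All 2^n binary activation patterns in little-endian order (pattern p,
#' counted from 0, activates region k iff bit k of p is set).
#'
#' @param n_regions number of regions (7 for the standard partition).
#' @return logical matrix, 2^n x n.
#' @export
input_patterns <- function(n_regions = 7) {
  n_pat <- 2^n_regions
  m <- t(vapply(seq_len(n_pat) - 1L,
                function(p) as.logical(bitwAnd(p, 2^(0:(n_regions - 1)))),
                logical(n_regions)))
  colnames(m) <- paste0("in", seq_len(n_regions))
  m
}

#' Size of the discretized output alphabet
#'
#' `(spike_cap + 1) * 3^n_ca`: capped spike counts times three Ca2+ levels
#' per read-out region.
#'
#' @param spec a [discretization_spec()].
#' @param n_ca number of Ca2+ read-out regions (6 apical; 7 when basal
#'   Ca2+ is modelled).
#' @export
output_alphabet_size <- function(spec = discretization_spec(), n_ca = 6) {
  (spec$spike_cap + 1) * 3^n_ca
}

#' Somatic bias grid for diversity averaging
#'
#' Eleven amplitudes from -0.1 to 0.1 nA in 0.02-nA steps.
#' @export
diversity_bias_grid <- function() seq(-0.1, 0.1, by = 0.02)

# place the per-region probe populations (alpha, tau 5 ms, Erev 0)
region_populations <- function(model, partition = region_partition(),
                               n_per_region = 1000, seed = 1) {
  kin <- syn_kinetics("alpha", g_max = 1, e_rev = 0, tau_decay = 5)
  pops <- vector("list", nrow(partition))
  names(pops) <- partition$region
  for (i in seq_len(nrow(partition))) {
    pops[[i]] <- place_synapses(model, n_per_region, kin,
                                kind = partition$kind[i],
                                dist_min = partition$lo[i],
                                dist_max = partition$hi[i],
                                seed = derive_seed(seed, "region", i))
  }
  pops
}

# midpoints where the Ca2+ response of each apical region is read out
region_midpoints <- function(model, partition = region_partition()) {
  apical <- partition[partition$kind == "apical", ]
  max_x <- max(model$morph$path_distance[model$morph$kind == "apical"])
  mids <- ifelse(is.finite(apical$hi), (apical$lo + apical$hi) / 2,
                 (apical$lo + max_x) / 2)
  lapply(mids, function(x) list(kind = "apical", x = x))
}

#' Per-region threshold conductances
#'
#' For each region, the bisected per-synapse peak conductance (nS; also
#' reported as total uS) at which simultaneous activation of that region's
#' probe alone elicits a somatic spike.
#'
#' @param model a `neuron_model`.
#' @param partition a [region_partition()].
#' @param n_per_region synapses per region.
#' @param seed placement seed.
#' @param tol bisection tolerance.
#' @param equil equilibration, ms.
#' @param dt time step, ms.
#' @param populations optional precomputed [region_populations()].
#' @return data frame with `region`, `g_th_nS` (per synapse) and
#'   `g_th_uS_total`.
#' @export
region_thresholds <- function(model, partition = region_partition(),
                              n_per_region = 1000, seed = 1, tol = 0.01,
                              equil = 500, dt = 0.025, populations = NULL) {
  pops <- populations %||% region_populations(model, partition, n_per_region,
                                              seed)
  g <- vapply(seq_along(pops), function(i) {
    tryCatch(bisect_threshold(function(s) {
      ev <- population_events(pops[[i]],
                              activations = data.frame(time = equil,
                                                       scale = s))
      res <- simulate(model, synapses = ev, duration = equil + 200, dt = dt)
      count_spikes_after(res, equil)
    }, hi = 0.01, tol = tol),
    error = function(e) stop_pyrexc("no spike bracket for region %s: %s",
                                    partition$region[i], conditionMessage(e)))
  }, 1.0)
  data.frame(region = partition$region, g_th_nS = g,
             g_th_uS_total = g * n_per_region * 1e-3)
}

#' Response to one binary input pattern
#'
#' Synapses of all active regions are activated simultaneously; the output
#' is the capped somatic spike count plus the discretized maximal Ca2+
#' concentration at each apical region midpoint over the response window.
#'
#' @param model a `neuron_model`.
#' @param active logical 7-vector over the partition's regions.
#' @param g_spec either `list(mode = "relative", fraction = 0.5,
#'   thresholds = <region_thresholds>)` or `list(mode = "absolute",
#'   g_nS = <per-synapse nS>)`.
#' @param spec a [discretization_spec()].
#' @param bias somatic DC offset, nA.
#' @param populations precomputed [region_populations()].
#' @param window response window after activation, ms.
#' @inheritParams region_thresholds
#' @return integer vector `c(n_spikes, ca1..ca6)` (plus `ca_basal` when the
#'   model carries basal Ca2+ dynamics).
#' @export
response_pattern <- function(model, active, g_spec, spec = discretization_spec(),
                             bias = 0, populations = NULL,
                             partition = region_partition(), seed = 1,
                             equil = 500, window = 300, dt = 0.025) {
  pops <- populations %||% region_populations(model, partition, seed = seed)
  ev <- pattern_events(pops, active, g_spec, equil)
  run_response(model, ev, spec, bias, partition, equil, window, dt)
}

pattern_events <- function(pops, active, g_spec, t0) {
  evs <- list(); types <- NULL
  key_parts <- character(0)
  for (i in seq_along(pops)) {
    if (!active[i]) next
    scale <- if (g_spec$mode == "relative")
      g_spec$fraction * g_spec$thresholds$g_th_nS[i]
    else g_spec$g_nS
    if (scale > 0) key_parts <- c(key_parts, sprintf("%d:%.12g", i, scale))
    e <- population_events(pops[[i]],
                          activations = data.frame(time = t0, scale = scale))
    evs[[length(evs) + 1]] <- e$events
    types <- e$types
  }
  if (is.null(types))
    types <- matrix(c(0, 5, 0, 0, 1), nrow = 1)
  ev <- if (length(evs)) do.call(rbind, evs) else matrix(numeric(0), ncol = 4)
  # key identifies the realized stimulus: regions with nonzero conductance
  list(events = ev, types = types,
       key = if (length(key_parts)) paste(key_parts, collapse = ";")
             else "silent")
}

run_response <- function(model, ev, spec, bias, partition, equil, window, dt) {
  mids <- region_midpoints(model, partition)
  basal_ca <- "basal" %in% (model$calcium$kinds %||% character(0))
  rec <- mids
  if (basal_ca) rec <- c(rec, list(list(kind = "basal", x = 0)))
  stims <- if (bias != 0) list(stim_dc("soma", bias, onset = 0)) else list()
  res <- simulate(model, stims, synapses = ev, duration = equil + window,
                  dt = dt, record_sites = rec, record_stride = 2L)
  n_spk <- min(sum(res$spike_times > equil), spec$spike_cap)
  win <- res$time > equil
  ca_max <- apply(res$ca[win, -1, drop = FALSE], 2, max)
  levels <- as.integer(findInterval(ca_max, c(spec$ca_low, spec$ca_high)))
  out <- c(n_spikes = n_spk, setNames(levels, paste0("ca", seq_along(levels))))
  out
}

#' All-pattern discretized response table
#'
#' Evaluates all 2^7 = 128 binary input patterns in deterministic
#' little-endian order (pattern id p activates region k iff bit k of p is
#' set, k = 1..7). Patterns whose realized stimulus is identical (e.g. all
#' conductances zero) share one simulation.
#'
#' @inheritParams response_pattern
#' @return a `coding_result`: list with `table` (128 x outputs integer
#'   matrix), `masks` (128 x 7 logical), `g_spec`, `bias`.
#' @export
response_table <- function(model, g_spec, spec = discretization_spec(),
                           bias = 0, populations = NULL,
                           partition = region_partition(), seed = 1,
                           equil = 500, window = 300, dt = 0.025) {
  pops <- populations %||% region_populations(model, partition, seed = seed)
  n_reg <- nrow(partition)
  n_pat <- 2^n_reg
  masks <- input_patterns(n_reg)
  # per-region event blocks are mask-independent; build them once
  scales <- vapply(seq_len(n_reg), function(i) {
    if (g_spec$mode == "relative")
      g_spec$fraction * g_spec$thresholds$g_th_nS[i]
    else g_spec$g_nS
  }, 1.0)
  blocks <- lapply(seq_len(n_reg), function(i) {
    population_events(pops[[i]],
                      activations = data.frame(time = equil,
                                               scale = scales[i]))
  })
  types <- blocks[[1]]$types
  cache <- new.env(parent = emptyenv())
  rows <- vector("list", n_pat)
  for (p in seq_len(n_pat)) {
    on <- which(masks[p, ] & scales > 0)
    key <- if (length(on)) paste(on, collapse = ",") else "silent"
    if (!is.null(cache[[key]])) rows[[p]] <- cache[[key]]
    else {
      ev <- list(events = do.call(rbind, c(list(matrix(numeric(0), ncol = 4)),
                                           lapply(blocks[on], `[[`,
                                                  "events"))),
                 types = types)
      rows[[p]] <- run_response(model, ev, spec, bias, partition, equil,
                                window, dt)
      cache[[key]] <- rows[[p]]
    }
  }
  tab <- do.call(rbind, rows)
  structure(list(table = tab, masks = masks, g_spec = g_spec, bias = bias),
            class = "coding_result")
}

#' Hamming distance between two response tables
#'
#' Number of disagreeing entries over all patterns and output components.
#'
#' @param a,b `coding_result`s (or plain matrices) with identical pattern
#'   ordering and output arity.
#' @export
hamming_distance <- function(a, b) {
  ta <- if (inherits(a, "coding_result")) a$table else a
  tb <- if (inherits(b, "coding_result")) b$table else b
  if (!all(dim(ta) == dim(tb)))
    stop_pyrexc("response tables differ in shape (%s vs %s)",
                paste(dim(ta), collapse = "x"), paste(dim(tb), collapse = "x"))
  sum(ta != tb)
}

#' Output diversity over a conductance sweep
#'
#' For each absolute per-synapse conductance, the number of distinct output
#' patterns over the 128-pattern table, averaged over the somatic bias grid
#' (default -0.1..0.1 nA in 0.02-nA steps, eleven values).
#'
#' @param model a `neuron_model`.
#' @param g_values per-synapse conductances, nS.
#' @param bias_grid somatic bias amplitudes, nA.
#' @inheritParams response_table
#' @return data frame with `g_nS` and `mean_diversity`.
#' @export
output_diversity <- function(model, g_values, bias_grid = diversity_bias_grid(),
                             spec = discretization_spec(), populations = NULL,
                             partition = region_partition(), seed = 1,
                             equil = 500, window = 300, dt = 0.025) {
  pops <- populations %||% region_populations(model, partition, seed = seed)
  div <- vapply(g_values, function(g) {
    counts <- vapply(bias_grid, function(b) {
      tab <- response_table(model, list(mode = "absolute", g_nS = g), spec,
                            bias = b, populations = pops,
                            partition = partition, equil = equil,
                            window = window, dt = dt)
      nrow(unique(tab$table))
    }, 1.0)
    mean(counts)
  }, 1.0)
  data.frame(g_nS = g_values, mean_diversity = div)
}

#' Input-output correlation matrix
#'
#' Pearson correlation between each region's binary activation indicator
#' and each output measure (spike count and per-region Ca2+ level) across
#' the 128 patterns. Constant outputs yield NA (not 0).
#'
#' @param result a `coding_result`.
#' @return matrix, regions x output measures.
#' @export
io_correlations <- function(result) {
  x <- result$masks * 1
  y <- result$table
  out <- matrix(NA_real_, ncol(x), ncol(y),
                dimnames = list(colnames(result$masks) %||%
                                  paste0("in", seq_len(ncol(x))),
                                colnames(y)))
  for (i in seq_len(ncol(x))) for (j in seq_len(ncol(y))) {
    if (stats::sd(y[, j]) == 0 || stats::sd(x[, i]) == 0) next
    out[i, j] <- cor(x[, i], y[, j])
  }
  out
}

#' Export a coding result as CSV
#'
#' Columns `pattern_id`, `region_mask` (bit string), `n_spikes`, `ca1..`.
#' @param result a `coding_result`.
#' @param path file path.
#' @export
write_coding_csv <- function(result, path) {
  mask_str <- apply(result$masks, 1, function(m) paste(as.integer(m),
                                                       collapse = ""))
  df <- data.frame(pattern_id = seq_len(nrow(result$table)) - 1L,
                   region_mask = mask_str)
  df <- cbind(df, as.data.frame(result$table))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
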