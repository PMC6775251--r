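# Variant representation, threshold-amplitude probes, the downscaling scheme
# (threshold conditions I-IV, threshold scale c, epsilon scalings) and
# variant combination.

#' Define a gene variant as a set of parameter deltas
#'
#' @param gene gene label (e.g. `"CACNA1C"`).
#' @param gene_class one of `"Ca-channel"`, `"Ca-transporter"`,
#'   `"Na-channel"`, `"K-channel"`, `"HCN"`.
#' @param deltas data frame with columns `parameter` (dotted path, see
#'   [apply_parameter_deltas()]), `kind` (`"add"` for mV shifts on
#'   half-activation voltages, `"mult"` for factors) and `value`.
#' @param source citation tag.
#' @export
variant_definition <- function(gene, gene_class, deltas, source = "synthetic") {
  classes <- c("Ca-channel", "Ca-transporter", "Na-channel", "K-channel", "HCN")
  if (!gene_class %in% classes)
    stop_pyrexc("gene_class must be one of %s", paste(classes, collapse = ", "))
  if (!nrow(deltas)) stop_pyrexc("a variant needs at least one delta")
  add_bad <- deltas$kind == "add" & !grepl("\\.v_half$", deltas$parameter)
  if (any(add_bad))
    stop_pyrexc("additive deltas are only valid for v_half parameters")
  deltas <- deltas[, c("parameter", "kind", "value")]
  rownames(deltas) <- NULL
  structure(list(gene = gene, gene_class = gene_class, deltas = deltas,
                 source = source),
            class = "variant_definition")
}

#' @export
print.variant_definition <- function(x, ...) {
  cat(sprintf("<variant %s (%s): %d delta(s)>\n", x$gene, x$gene_class,
              nrow(x$deltas)))
  invisible(x)
}

#' Scale a variant by c * epsilon
#'
#' Additive deltas scale linearly (`d -> c e d`); multiplicative factors
#' scale linearly in the effect (`f -> 1 + c e (f - 1)`), so the
#' epsilon = -1/2 variant is the exact mirror of epsilon = +1/2.
#'
#' @param variant a [variant_definition()].
#' @param c threshold scale in (0, 2].
#' @param epsilon one of +1/2, +1/4, -1/4, -1/2.
#' @return a `scaled_variant` carrying `effective_deltas`.
#' @export
scale_variant <- function(variant, c, epsilon) {
  if (!isTRUE(all.equal(abs(epsilon), 0.5)) &&
      !isTRUE(all.equal(abs(epsilon), 0.25)))
    stop_pyrexc("epsilon must be one of +-1/2, +-1/4")
  eff <- scale_deltas(variant$deltas, c * epsilon)
  structure(list(base = variant, c = c, epsilon = epsilon,
                 effective_deltas = eff),
            class = "scaled_variant")
}

scale_deltas <- function(deltas, scale) {
  out <- deltas
  for (i in seq_len(nrow(out))) {
    if (out$kind[i] == "add") out$value[i] <- scale * out$value[i]
    else {
      f <- 1 + scale * (out$value[i] - 1)
      if (f <= 0)
        stop_pyrexc("scaling produces a non-positive factor for %s",
                    out$parameter[i])
      out$value[i] <- f
    }
  }
  out
}

#' Combine scaled variants into one delta set
#'
#' Additive deltas on the same parameter sum; multiplicative effective
#' factors multiply. Order-independent.
#'
#' @param scaled list of `scaled_variant` (or delta data frames).
#' @return a delta data frame usable with [apply_parameter_deltas()].
#' @export
combine_variants <- function(scaled) {
  dfs <- lapply(scaled, function(s) {
    if (inherits(s, "scaled_variant")) s$effective_deltas else s
  })
  all <- do.call(rbind, dfs)
  if (is.null(all) || !nrow(all))
    return(data.frame(parameter = character(0), kind = character(0),
                      value = numeric(0)))
  keys <- unique(all[, c("parameter", "kind")])
  keys <- keys[order(keys$parameter, keys$kind), ]
  vals <- mapply(function(p, k) {
    v <- all$value[all$parameter == p & all$kind == k]
    if (k == "add") sum(v) else prod(v)
  }, keys$parameter, keys$kind)
  data.frame(parameter = keys$parameter, kind = keys$kind,
             value = unname(vals), row.names = NULL)
}

# ---- threshold probes -------------------------------------------------------

# generic bisection for a one-spike threshold; f(amp) returns a spike count
bisect_threshold <- function(f, lo = 0, hi, tol = 0.005, max_expand = 6) {
  n_hi <- f(hi)
  k <- 0
  while (n_hi < 1 && k < max_expand) {
    lo <- hi; hi <- hi * 2; k <- k + 1
    n_hi <- f(hi)
  }
  if (n_hi < 1)
    stop_pyrexc("no spike even at the bracket maximum (%.4g)", hi)
  while ((hi - lo) / hi > tol) {
    mid <- (lo + hi) / 2
    if (f(mid) >= 1) hi <- mid else lo <- mid
  }
  hi
}

# alpha-shaped conductance probe as a ready event set (tau = 5 ms, Erev 0)
alpha_probe_events <- function(model, site, g_uS, onset) {
  comp <- resolve_site(model, site)
  list(events = matrix(c(onset, comp - 1L, 0, g_uS), nrow = 1),
       types = matrix(c(0, 5, 0, 0, 1), nrow = 1,
                      dimnames = list(NULL, c("tau_rise", "tau_decay",
                                              "e_rev", "mg_on", "alpha"))))
}

count_spikes_after <- function(res, t0) sum(res$spike_times > t0)

#' Threshold amplitudes for the downscaling conditions
#'
#' A1: threshold amplitude (nA) of a 5-ms somatic square pulse. A2:
#' threshold peak conductance (uS) of a distal apical alpha conductance
#' (tau = 5 ms, Erev = 0). A3: the joint threshold of the combined stimulus
#' (somatic pulse, alpha conductance 2.5 ms later) expressed as the scale
#' `s` applied to the fixed base pair `(A1_ref, A2_ref)`; `A3a = s * A1_ref`
#' and `A3b = s * A2_ref`.
#'
#' @param model a `neuron_model`.
#' @param tol relative bisection tolerance.
#' @param distal_x path distance of the distal apical probe, um.
#' @param base_pair optional `(A1, A2)` pair fixing the combined-stimulus
#'   ratio (defaults to this model's own A1, A2; pass the control pair when
#'   probing variants).
#' @param equil equilibration discarded before the probe, ms.
#' @param dt time step, ms.
#' @return list with `A1` (nA), `A2` (uS), `A3_scale`, `A3a`, `A3b`.
#' @export
threshold_amplitudes <- function(model, tol = 0.005, distal_x = 850,
                                 base_pair = NULL, equil = 500, dt = 0.025) {
  onset <- equil + 10
  sim_a1 <- function(amp) {
    res <- simulate(model, list(stim_pulse("soma", amp, onset, 5)),
                    duration = onset + 100, dt = dt)
    count_spikes_after(res, equil)
  }
  A1 <- bisect_threshold(sim_a1, lo = 0, hi = 1, tol = tol)
  sim_a2 <- function(g) {
    res <- simulate(model, synapses = alpha_probe_events(
      model, list(kind = "apical", x = distal_x), g, onset),
      duration = onset + 150, dt = dt)
    count_spikes_after(res, equil)
  }
  A2 <- bisect_threshold(sim_a2, lo = 0, hi = 0.05, tol = tol)
  bp <- base_pair %||% c(A1, A2)
  sim_a3 <- function(s) {
    res <- simulate(model, list(stim_pulse("soma", s * bp[1], onset, 5)),
                    synapses = alpha_probe_events(
                      model, list(kind = "apical", x = distal_x),
                      s * bp[2], onset + 2.5),
                    duration = onset + 150, dt = dt)
    count_spikes_after(res, equil)
  }
  A3 <- bisect_threshold(sim_a3, lo = 0, hi = 1, tol = tol)
  list(A1 = A1, A2 = A2, A3_scale = A3, A3a = A3 * bp[1], A3b = A3 * bp[2],
       base_pair = bp)
}

#' Downscaling condition report
#'
#' Relative changes of the three threshold amplitudes (conditions I-III,
#' bound 15%) and the integrated absolute f-I difference relative to the
#' control f-I integral (condition IV, bound 10%).
#'
#' @param control,variant_model `neuron_model`s.
#' @param fI_spec list with `amplitudes` (nA grid) and `duration` (ms);
#'   defaults to 12 amplitudes over the control model's analysis range and
#'   3.5 s.
#' @param control_ref optional precomputed control reference from
#'   [threshold_reference()] (avoids recomputation in scans).
#' @param tol bisection tolerance.
#' @param dt time step, ms.
#' @return a `condition_report` list with `rel_change_A1/A2/A3`,
#'   `fI_rel_integral_diff`, per-condition `passed` and `all_passed`.
#' @export
condition_report <- function(control, variant_model, fI_spec = NULL,
                             control_ref = NULL, tol = 0.005, dt = 0.025) {
  fI_spec <- fI_spec %||% default_fI_spec(control)
  ref <- control_ref %||% threshold_reference(control, fI_spec, tol, dt)
  thr <- threshold_amplitudes(variant_model, tol = tol,
                              base_pair = ref$thresholds$base_pair, dt = dt)
  fI_v <- fI_curve(variant_model, fI_spec$amplitudes,
                   duration = fI_spec$duration, dt = dt)
  rel <- c(A1 = thr$A1 / ref$thresholds$A1 - 1,
           A2 = thr$A2 / ref$thresholds$A2 - 1,
           A3 = thr$A3_scale / ref$thresholds$A3_scale - 1)
  denom <- trapz(ref$fI$amplitudes, ref$fI$rates)
  fI_diff <- trapz(fI_spec$amplitudes, abs(fI_v$rates - ref$fI$rates)) /
    max(denom, 1e-12)
  passed <- c(I = abs(rel["A1"]) <= 0.15, II = abs(rel["A2"]) <= 0.15,
              III = abs(rel["A3"]) <= 0.15, IV = fI_diff <= 0.10)
  names(passed) <- c("I", "II", "III", "IV")
  structure(list(rel_change_A1 = unname(rel["A1"]),
                 rel_change_A2 = unname(rel["A2"]),
                 rel_change_A3 = unname(rel["A3"]),
                 fI_rel_integral_diff = fI_diff,
                 passed = passed, all_passed = all(passed)),
            class = "condition_report")
}

default_fI_spec <- function(model, n = 12, duration = 3500) {
  list(amplitudes = seq(model$fI_range[1], model$fI_range[2], length.out = n),
       duration = duration)
}

#' Precompute the control-side reference for condition scans
#' @inheritParams condition_report
#' @export
threshold_reference <- function(control, fI_spec = NULL, tol = 0.005,
                                dt = 0.025) {
  fI_spec <- fI_spec %||% default_fI_spec(control)
  list(thresholds = threshold_amplitudes(control, tol = tol, dt = dt),
       fI = fI_curve(control, fI_spec$amplitudes,
                     duration = fI_spec$duration, dt = dt),
       fI_spec = fI_spec)
}

# lazy condition check: stops at the first failing condition
conditions_hold <- function(control, variant_model, ref, tol, dt) {
  onset <- 510
  thr <- tryCatch(
    threshold_amplitudes(variant_model, tol = tol,
                         base_pair = ref$thresholds$base_pair, dt = dt),
    error = function(e) NULL)
  if (is.null(thr)) return(FALSE)
  if (abs(thr$A1 / ref$thresholds$A1 - 1) > 0.15) return(FALSE)
  if (abs(thr$A2 / ref$thresholds$A2 - 1) > 0.15) return(FALSE)
  if (abs(thr$A3_scale / ref$thresholds$A3_scale - 1) > 0.15) return(FALSE)
  fI_v <- tryCatch(
    fI_curve(variant_model, ref$fI_spec$amplitudes,
             duration = ref$fI_spec$duration, dt = dt),
    error = function(e) NULL)
  if (is.null(fI_v)) return(FALSE)
  denom <- trapz(ref$fI$amplitudes, ref$fI$rates)
  diff <- trapz(ref$fI_spec$amplitudes, abs(fI_v$rates - ref$fI$rates)) /
    max(denom, 1e-12)
  diff <= 0.10
}

#' Find the threshold scale c of a variant
#'
#' Scans scales over (0, 2] at resolution `grid_step` (ascending) and
#' returns the smallest scanned scale at which any condition I-IV fails.
#' If no scale below 2 fails, returns 2 (the original variant then serves
#' as the epsilon = 1/2 variant).
#'
#' @param control control `neuron_model`.
#' @param variant a [variant_definition()].
#' @param grid_step scan resolution.
#' @param fI_spec f-I settings, see [condition_report()].
#' @param tol bisection tolerance.
#' @param dt time step, ms.
#' @param control_ref optional precomputed [threshold_reference()].
#' @export
find_threshold_scale <- function(control, variant, grid_step = 0.05,
                                 fI_spec = NULL, tol = 0.005, dt = 0.025,
                                 control_ref = NULL) {
  if (grid_step <= 0) stop_pyrexc("grid_step must be > 0")
  if (!nrow(variant$deltas)) return(2)
  fI_spec <- fI_spec %||% default_fI_spec(control)
  ref <- control_ref %||% threshold_reference(control, fI_spec, tol, dt)
  ref$fI_spec <- fI_spec
  scales <- seq(grid_step, 2, by = grid_step)
  for (s in scales) {
    vm <- tryCatch(
      apply_parameter_deltas(control, scale_deltas(variant$deltas, s)),
      error = function(e) NULL)
    if (is.null(vm)) return(s)   # scaling made a factor non-positive
    if (!conditions_hold(control, vm, ref, tol, dt)) return(min(s, 2))
  }
  2
}

# ---- variant table CSV dialect ---------------------------------------------

#' Read / write variant tables
#'
#' CSV dialect: columns `gene`, `gene_class`, `parameter`, `delta_kind`
#' (`add`/`mult`), `value`, `citation`; one row per delta.
#'
#' @param variants list of [variant_definition()].
#' @param path file path.
#' @export
write_variant_table <- function(variants, path) {
  rows <- do.call(rbind, lapply(variants, function(v) {
    data.frame(gene = v$gene, gene_class = v$gene_class,
               parameter = v$deltas$parameter, delta_kind = v$deltas$kind,
               value = v$deltas$value, citation = v$source)
  }))
  write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_variant_table
#' @export
read_variant_table <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  lapply(split(df, factor(df$gene, levels = unique(df$gene))), function(d) {
    variant_definition(d$gene[1], d$gene_class[1],
                       data.frame(parameter = d$parameter,
                                  kind = d$delta_kind, value = d$value),
                       source = d$citation[1])
  })
}
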