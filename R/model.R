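# Model construction: reduced morphology, channel distribution rules,
# reference profiles, parameter deltas, and compilation to the solver form.

#' Reduced layer-V pyramidal cell morphology
#'
#' Soma plus `n_apical` apical segments of `apical_seg_len` um (path distances
#' spanning the full apical extent, so all protocol sites from 200 um to
#' beyond 1000 um are resolvable) and one lumped basal cylinder.
#'
#' @param n_apical number of apical segments.
#' @param apical_seg_len segment length, um.
#' @param apical_diam apical diameter, um (constant along the trunk).
#' @param soma_len,soma_diam soma cylinder dimensions, um.
#' @param basal_len,basal_diam lumped basal cylinder dimensions, um.
#' @return a compartment table (`data.frame`) with columns `id`, `parent`
#'   (NA for the soma), `path_distance` (um to segment centre), `length`,
#'   `diameter` and `kind`.
#' @export
reduced_morphology <- function(n_apical = 12, apical_seg_len = 100,
                               apical_diam = 2.5, soma_len = 25,
                               soma_diam = 25, basal_len = 300,
                               basal_diam = 7) {
  apical_x <- (seq_len(n_apical) - 0.5) * apical_seg_len
  morph <- data.frame(
    id = seq_len(n_apical + 2L),
    parent = c(NA, 1L, 1L, if (n_apical > 1) 2L + seq_len(n_apical - 1L)),
    path_distance = c(0, basal_len / 2, apical_x),
    length = c(soma_len, basal_len, rep(apical_seg_len, n_apical)),
    diameter = c(soma_diam, basal_diam, rep(apical_diam, n_apical)),
    kind = c("soma", "basal", rep("apical", n_apical)),
    stringsAsFactors = FALSE
  )
  validate_morphology(morph)
}

validate_morphology <- function(morph) {
  req <- c("id", "parent", "path_distance", "length", "diameter", "kind")
  if (!all(req %in% names(morph)))
    stop_pyrexc("morphology must have columns %s", paste(req, collapse = ", "))
  if (sum(morph$kind == "soma") != 1)
    stop_pyrexc("morphology must contain exactly one soma compartment")
  if (!is.na(morph$parent[morph$kind == "soma"]))
    stop_pyrexc("the soma must have no parent")
  if (any(morph$path_distance < 0)) stop_pyrexc("negative path distance")
  idx <- match(morph$parent, morph$id)
  if (any(is.na(idx[morph$kind != "soma"])))
    stop_pyrexc("disconnected compartment(s) in morphology")
  morph
}

#' Read an SWC morphology file
#'
#' Parses the standard 7-column SWC format (id, type, x, y, z, radius,
#' parent; 1-based ids, parent -1 for the root) into the compartment table
#' used by [build_reference_model()]. SWC types 1/2/3/4 map to soma, axon,
#' basal and apical. Path distance is measured from the soma centre along
#' the neurite path.
#'
#' @param path file path.
#' @export
read_swc <- function(path) {
  raw <- read.table(path, comment.char = "#",
                    col.names = c("id", "type", "x", "y", "z", "r", "parent"))
  kind_map <- c("1" = "soma", "2" = "axon", "3" = "basal", "4" = "apical")
  kind <- unname(kind_map[as.character(raw$type)])
  kind[is.na(kind)] <- "apical"
  o <- order(raw$id)
  raw <- raw[o, ]; kind <- kind[o]
  pidx <- match(raw$parent, raw$id)
  seg_len <- rep(0, nrow(raw))
  ok <- !is.na(pidx)
  seg_len[ok] <- sqrt((raw$x[ok] - raw$x[pidx[ok]])^2 +
                      (raw$y[ok] - raw$y[pidx[ok]])^2 +
                      (raw$z[ok] - raw$z[pidx[ok]])^2)
  # cumulative path distance from root
  path_d <- rep(0, nrow(raw))
  for (i in seq_len(nrow(raw))) if (ok[i]) path_d[i] <- path_d[pidx[i]] + seg_len[i]
  morph <- data.frame(
    id = seq_len(nrow(raw)),
    parent = ifelse(is.na(pidx), NA_integer_, pidx),
    path_distance = path_d,
    length = ifelse(seg_len > 0, seg_len, raw$r * 2),
    diameter = raw$r * 2,
    kind = kind, stringsAsFactors = FALSE
  )
  # collapse multiple soma points to one root if needed
  if (sum(morph$kind == "soma") > 1) {
    soma_rows <- which(morph$kind == "soma")
    keep <- soma_rows[1]
    morph$parent[morph$parent %in% soma_rows] <- keep
    morph$parent[keep] <- NA
    drop <- setdiff(soma_rows, keep)
    morph <- morph[-drop, ]
    remap <- setNames(seq_len(nrow(morph)), morph$id)
    morph$parent <- unname(remap[as.character(morph$parent)])
    morph$id <- seq_len(nrow(morph))
  }
  validate_morphology(morph)
}

#' Channel distribution rule
#'
#' Density profile of one channel over one compartment kind, as a function of
#' path distance x (um): `constant`; `exponential`
#' (`g * (a + b * exp(x / lambda))`); `linear-then-constant`
#' (`g * (1 - (1 - f_end) * min(x, x_end) / x_end)`); `sigmoid`
#' (`g * (f0 + (f1 - f0) / (1 + exp(-(x - x_mid) / w)))`); `hot-zone`
#' (`g`, multiplied by `fold` inside the interval `[hot_lo, hot_hi)`).
#'
#' @param kind compartment kind the rule applies to.
#' @param g_max base maximal conductance density, S/cm^2.
#' @param profile profile name.
#' @param params named list of profile parameters (see above).
#' @export
distribution_rule <- function(kind, g_max,
                              profile = c("constant", "exponential",
                                          "linear-then-constant", "sigmoid",
                                          "hot-zone"),
                              params = list()) {
  profile <- match.arg(profile)
  structure(list(kind = kind, g_max = g_max, profile = profile,
                 params = params), class = "distribution_rule")
}

# evaluate a rule at path distances x (um); returns S/cm^2
eval_rule <- function(rule, x) {
  g <- rule$g_max
  p <- rule$params
  out <- switch(rule$profile,
    constant = rep(g, length(x)),
    exponential = g * ((p$a %||% 0) + (p$b %||% 1) * exp(x / p$lambda)),
    `linear-then-constant` = {
      f_end <- p$f_end %||% 0.2
      x_end <- p$x_end %||% 500
      g * (1 - (1 - f_end) * pmin(x, x_end) / x_end)
    },
    sigmoid = {
      f0 <- p$f0 %||% 0; f1 <- p$f1 %||% 1
      g * (f0 + (f1 - f0) / (1 + exp(-(x - p$x_mid) / p$w)))
    },
    `hot-zone` = {
      lo <- p$hot_lo %||% 685; hi <- p$hot_hi %||% 885
      fold <- p$fold %||% 10
      g * ifelse(x >= lo & x < hi, fold, 1)
    })
  if (any(out < 0)) stop_pyrexc("negative channel density from profile '%s'",
                                rule$profile)
  out
}

#' Build a neuron model from a configuration
#'
#' @param config a model configuration list with elements `morphology`,
#'   `channels` (each a list with `spec` and `dist`), `calcium`, `cm`
#'   (uF/cm^2), `ra` (Ohm cm), `v_init`, `reference_dc` (nA) and
#'   `fI_range` (nA); see [fixture_model_config()].
#' @param profile_label label stored on the model.
#' @return a `neuron_model` object.
#' @export
build_model <- function(config, profile_label = config$label %||% "custom") {
  morph <- validate_morphology(config$morphology)
  model <- structure(list(
    morph = morph,
    channels = config$channels,
    calcium = config$calcium,
    cm = config$cm %||% 1,
    ra = config$ra %||% 150,
    v_init = config$v_init %||% -78,
    reference_dc = config$reference_dc %||% 0.75,
    fI_range = config$fI_range %||% c(0.3, 1.4),
    profile_label = profile_label
  ), class = "neuron_model")
  model
}

#' Build a reference layer-V pyramidal cell model
#'
#' `"tonic"` yields a regular-spiking profile (single spikes at the reference
#' DC); `"bursting"` a rhythmically bursting profile with 3-5 spikes per
#' burst. An altered model is obtained by supplying `deltas`.
#'
#' @param profile `"tonic"` or `"bursting"`.
#' @param config optional configuration overriding the packaged one.
#' @param deltas optional parameter-delta table (see
#'   [apply_parameter_deltas()]) defining an altered model.
#' @export
build_reference_model <- function(profile = c("tonic", "bursting"),
                                  config = NULL, deltas = NULL) {
  profile <- match.arg(profile)
  if (is.null(config))
    config <- fixture_model_config(paste0(profile, "-reduced"))
  label <- if (is.null(deltas)) profile else paste0(profile, "-altered")
  model <- build_model(config, profile_label = label)
  if (!is.null(deltas)) model <- apply_parameter_deltas(model, deltas)
  model
}

#' @export
print.neuron_model <- function(x, ...) {
  cat(sprintf("<neuron_model '%s': %d compartments, %d channels>\n",
              x$profile_label, nrow(x$morph), length(x$channels)))
  invisible(x)
}

#' Resolve a recording/stimulation site to a compartment index
#'
#' @param model a `neuron_model`.
#' @param site `"soma"`, a compartment id, or `list(kind=, x=)` giving a
#'   compartment kind and a path distance in um (nearest compartment of that
#'   kind is used).
#' @export
resolve_site <- function(model, site) {
  m <- model$morph
  if (is.character(site) && length(site) == 1 && site == "soma")
    return(which(m$kind == "soma")[1])
  if (is.numeric(site) && length(site) == 1) {
    i <- match(site, m$id)
    if (is.na(i)) stop_pyrexc("no compartment with id %s", site)
    return(i)
  }
  if (is.list(site)) {
    cand <- which(m$kind == site$kind)
    if (!length(cand)) stop_pyrexc("no compartments of kind '%s'", site$kind)
    return(cand[which.min(abs(m$path_distance[cand] - site$x))])
  }
  stop_pyrexc("cannot resolve site")
}

#' Apply a set of parameter deltas to a model
#'
#' Deltas address parameters by dotted paths: `"<Channel>.gbar"` or
#' `"<Channel>.gbar.<kind>"` (multiplicative conductance factor);
#' `"<Channel>.act.v_half"` / `"<Channel>.inact.v_half"` (additive, mV);
#' `"<Channel>.act.slope"`, `"<Channel>.act.tau"` (multiplicative;
#' `tau` scales both the base and voltage-dependent amplitude);
#' `"<Channel>.cagate.ca_half"` (multiplicative); `"calcium.decay_tau"`
#' and `"calcium.gamma"` (multiplicative, Ca2+ extrusion/handling).
#'
#' @param model a `neuron_model`.
#' @param deltas a data frame with columns `parameter`, `kind`
#'   (`"add"`/`"mult"`) and `value`, or a `variant_definition`.
#' @return a new `neuron_model`; the input is unchanged.
#' @export
apply_parameter_deltas <- function(model, deltas) {
  if (inherits(deltas, "variant_definition")) deltas <- deltas$deltas
  if (inherits(deltas, "scaled_variant")) deltas <- deltas$effective_deltas
  if (is.null(deltas) || nrow(deltas) == 0) return(model)
  for (i in seq_len(nrow(deltas))) {
    path <- strsplit(deltas$parameter[i], ".", fixed = TRUE)[[1]]
    kind <- deltas$kind[i]
    val <- deltas$value[i]
    model <- apply_one_delta(model, path, kind, val)
  }
  model
}

apply_one_delta <- function(model, path, kind, val) {
  head <- path[1]
  if (head == "calcium") {
    field <- path[2]
    if (!field %in% c("decay_tau", "gamma"))
      stop_pyrexc("unknown calcium parameter '%s'", field)
    if (kind != "mult") stop_pyrexc("calcium.%s takes multiplicative deltas", field)
    model$calcium[[field]] <- model$calcium[[field]] * val
    if (model$calcium$decay_tau <= 0) stop_pyrexc("calcium decay_tau must stay > 0")
    return(model)
  }
  ch <- model$channels[[head]]
  if (is.null(ch))
    stop_pyrexc("delta targets channel '%s', absent from this model", head)
  what <- path[2]
  if (what == "gbar") {
    if (kind != "mult") stop_pyrexc("gbar takes multiplicative deltas")
    region <- if (length(path) >= 3) path[3] else NULL
    for (j in seq_along(ch$dist)) {
      if (is.null(region) || ch$dist[[j]]$kind == region)
        ch$dist[[j]]$g_max <- ch$dist[[j]]$g_max * val
    }
  } else if (what %in% c("act", "inact", "cagate")) {
    slot <- switch(what, act = "activation", inact = "inactivation",
                   cagate = "ca_gate")
    g <- ch$spec[[slot]]
    if (is.null(g))
      stop_pyrexc("channel '%s' has no %s gate", head, what)
    field <- path[3]
    if (field == "v_half") {
      if (kind != "add") stop_pyrexc("v_half takes additive deltas (mV)")
      g$v_half <- g$v_half + val
    } else if (field == "slope") {
      if (kind != "mult") stop_pyrexc("slope takes multiplicative deltas")
      g$slope <- g$slope * val
    } else if (field == "tau") {
      if (kind != "mult") stop_pyrexc("tau takes multiplicative deltas")
      g$tau_base <- g$tau_base * val
      if (!is.null(g$tau_amp)) g$tau_amp <- g$tau_amp * val
    } else if (field == "ca_half") {
      if (kind != "mult") stop_pyrexc("ca_half takes multiplicative deltas")
      g$ca_half <- g$ca_half * val
    } else stop_pyrexc("unknown gate field '%s'", field)
    ch$spec[[slot]] <- g
  } else stop_pyrexc("unknown delta target '%s'", paste(path, collapse = "."))
  model$channels[[head]] <- ch
  model
}

# ---- compilation to the solver's flat form ----------------------------------

compartment_areas <- function(morph) {
  pi * morph$diameter * morph$length * 1e-8  # um^2 -> cm^2
}

# axial coupling conductance between each compartment and its parent, uS
axial_conductances <- function(morph, ra) {
  n <- nrow(morph)
  g <- numeric(n)
  pidx <- match(morph$parent, morph$id)
  for (i in seq_len(n)) {
    if (is.na(pidx[i])) next
    p <- pidx[i]
    # series of two half-cylinder axial resistances, Ohm
    r_half <- function(j) {
      a_cross <- pi * (morph$diameter[j] * 1e-4)^2 / 4     # cm^2
      ra * (morph$length[j] * 1e-4 / 2) / a_cross          # Ohm
    }
    g[i] <- 1 / (r_half(i) + r_half(p)) * 1e6              # S -> uS
  }
  g
}

# order compartments so each parent precedes its children (Hines ordering)
hines_order <- function(morph) {
  n <- nrow(morph)
  pidx <- match(morph$parent, morph$id)
  order_out <- integer(0)
  visited <- rep(FALSE, n)
  queue <- which(is.na(pidx))
  while (length(queue)) {
    i <- queue[1]; queue <- queue[-1]
    if (visited[i]) next
    visited[i] <- TRUE
    order_out <- c(order_out, i)
    queue <- c(queue, which(pidx == i & !visited))
  }
  if (length(order_out) != n) stop_pyrexc("morphology tree is not connected")
  order_out
}

gate_to_c <- function(g) {
  shape_id <- if (g$type == "ca") 0L else
    match(g$tau_shape, c("constant", "gaussian", "sigmoid")) - 1L
  list(type = if (g$type == "v") 0L else 1L,
       exponent = as.double(g$exponent),
       vhalf = as.double(g$v_half %||% 0),
       slope = as.double(g$slope %||% 1),
       tau_shape = shape_id,
       tau_base = as.double(g$tau_base %||% 1),
       tau_amp = as.double(g$tau_amp %||% 0),
       tau_vmax = as.double(g$tau_vmax %||% -60),
       tau_sigma = as.double(g$tau_sigma %||% 15),
       ca_half = as.double(g$ca_half %||% 1e-3),
       hill = as.double(g$hill %||% 1),
       ca_tau = as.double(g$tau_base %||% 1))
}

#' @keywords internal
compile_model <- function(model) {
  m <- model$morph
  ord <- hines_order(m)
  m <- m[ord, ]
  remap <- match(m$parent, m$id)           # row index of parent, NA for root
  areas <- compartment_areas(m)
  g_ax <- axial_conductances(m, model$ra)
  cm_nf <- model$cm * areas * 1e3          # uF/cm^2 * cm^2 -> uF -> nF (x1e3)

  chanlist <- list()
  for (nm in names(model$channels)) {
    ch <- model$channels[[nm]]
    gbar_dens <- numeric(nrow(m))
    for (rule in ch$dist) {
      sel <- m$kind == rule$kind
      if (!any(sel)) next
      gbar_dens[sel] <- gbar_dens[sel] + eval_rule(rule, m$path_distance[sel])
    }
    if (all(gbar_dens == 0)) next
    gbar_us <- gbar_dens * areas * 1e6     # S/cm^2 * cm^2 -> S -> uS
    spec <- ch$spec
    gates <- Filter(Negate(is.null),
                    list(spec$activation, spec$inactivation, spec$ca_gate))
    chanlist[[nm]] <- list(
      gbar = gbar_us,
      erev = if (identical(spec$reversal, "nernst-Ca")) 0 else as.double(spec$reversal),
      nernst_ca = identical(spec$reversal, "nernst-Ca"),
      is_ca = isTRUE(spec$is_ca),
      gates = lapply(gates, gate_to_c))
  }

  cal <- model$calcium
  has_ca <- m$kind %in% (cal$kinds %||% c("soma", "apical"))
  list(
    morph = m,
    net = list(parent = ifelse(is.na(remap), -1L, remap - 1L),
               g_axial = g_ax, cm = cm_nf),
    chanlist = chanlist,
    calcium = list(gamma = cal$gamma, decay_tau = cal$decay_tau,
                   ca_rest = cal$ca_rest, depth = cal$shell_depth %||% 0.1,
                   ca_out = cal$ca_out %||% 2,
                   area = areas, has_ca = has_ca),
    areas = areas,
    order = ord
  )
}
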