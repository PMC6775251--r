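# Synthetic variant-table generator: reproducible gene variants with the
# structure of a functional-genomics effect table (per-gene deltas on
# half-activation voltages, slopes, time constants, conductances and Ca2+
# extrusion), consistent with each gene class's channel targets.

# gene class -> admissible channels and example gene labels
GENE_CLASS_MAP <- list(
  "Ca-channel" = list(channels = c("CaHVA", "CaLVA"),
                      genes = c("CACNA1C", "CACNA1D", "CACNB2", "CACNA1I",
                                "CACNA1G", "CACNA1H")),
  "Ca-transporter" = list(channels = "calcium",
                          genes = c("ATP2A2", "ATP2B2", "ATP2B1")),
  "Na-channel" = list(channels = c("Nat", "Nap"),
                      genes = c("SCN1A", "SCN2A", "SCN3A", "SCN9A")),
  "K-channel" = list(channels = c("Kv31", "Kt", "Kp", "Im", "SK", "BK"),
                     genes = c("KCNB1", "KCNS3", "KCNN3", "KCNMA1")),
  "HCN" = list(channels = "Ih", genes = c("HCN1", "HCN2"))
)

#' Configuration for the synthetic variant generator
#'
#' Delta magnitudes: half-activation shifts ~ Uniform(-10, 10) mV; slope
#' factors ~ log-uniform on [0.8, 1.25]; time-constant, conductance and
#' Ca2+ decay-tau factors ~ log-uniform on [0.5, 2].
#'
#' @param n_variants number of variants to generate.
#' @param class_mix named fractions over gene classes (must sum to 1).
#' @param deltas_per_variant range of deltas per variant (1-4).
#' @param channels restrict targets to channels present in the model the
#'   table is intended for (default: the tonic profile's channel set plus
#'   the calcium pool).
#' @param seed integer.
#' @export
variant_generator_config <- function(n_variants = 20,
                                     class_mix = c("Ca-channel" = 0.4,
                                                   "Ca-transporter" = 0.1,
                                                   "Na-channel" = 0.2,
                                                   "K-channel" = 0.2,
                                                   "HCN" = 0.1),
                                     deltas_per_variant = c(1, 4),
                                     channels = NULL, seed = 1) {
  if (abs(sum(class_mix) - 1) > 1e-9)
    stop_pyrexc("class_mix fractions must sum to 1")
  if (!all(names(class_mix) %in% names(GENE_CLASS_MAP)))
    stop_pyrexc("unknown gene class in class_mix")
  channels <- channels %||% c("Nat", "Nap", "Ih", "Im", "Kp", "Kt", "Kv31",
                              "CaHVA", "CaLVA", "SK", "calcium")
  list(n_variants = n_variants, class_mix = class_mix,
       deltas_per_variant = deltas_per_variant, channels = channels,
       seed = seed)
}

# admissible (parameter, kind) pairs for one channel
channel_param_space <- function(channel) {
  if (channel == "calcium")
    return(data.frame(parameter = "calcium.decay_tau", kind = "mult",
                      family = "tau"))
  gates <- switch(channel,
    Nat = c("act", "inact"), Nap = "act", Ih = "act", Im = "act",
    Kp = c("act", "inact"), Kt = c("act", "inact"), Kv31 = "act",
    CaHVA = c("act", "inact"), CaLVA = c("act", "inact"),
    CaMVA = c("act", "inact"), SK = "cagate", BK = "act")
  rows <- list(data.frame(parameter = paste0(channel, ".gbar"),
                          kind = "mult", family = "conductance"))
  for (g in gates) {
    if (g == "cagate") {
      rows[[length(rows) + 1]] <-
        data.frame(parameter = paste0(channel, ".cagate.ca_half"),
                   kind = "mult", family = "slope")
      next
    }
    rows[[length(rows) + 1]] <- data.frame(
      parameter = paste0(channel, ".", g, c(".v_half", ".slope", ".tau")),
      kind = c("add", "mult", "mult"),
      family = c("v_half", "slope", "tau"))
  }
  do.call(rbind, rows)
}

draw_delta_value <- function(family) {
  switch(family,
    v_half = runif(1, -10, 10),
    slope = exp(runif(1, log(0.8), log(1.25))),
    tau = exp(runif(1, log(0.5), log(2))),
    conductance = exp(runif(1, log(0.5), log(2))))
}

#' Generate a synthetic variant table
#'
#' Reproducible by seed; every variant's parameter targets are drawn from
#' its gene class's channel mapping only.
#'
#' @param config a [variant_generator_config()].
#' @return list of [variant_definition()].
#' @export
generate_variant_table <- function(config = variant_generator_config()) {
  if (config$n_variants == 0) return(list())
  with_local_seed(config$seed, {
    classes <- sample(names(config$class_mix), config$n_variants,
                      replace = TRUE, prob = config$class_mix)
    lapply(seq_len(config$n_variants), function(i) {
      cls <- classes[i]
      chans <- intersect(GENE_CLASS_MAP[[cls]]$channels, config$channels)
      if (!length(chans))
        stop_pyrexc("gene class %s has no admissible channels in this model",
                    cls)
      space <- do.call(rbind, lapply(chans, channel_param_space))
      k <- sample(seq(config$deltas_per_variant[1],
                      config$deltas_per_variant[2]), 1)
      k <- min(k, nrow(space))
      picks <- space[sample(nrow(space), k), , drop = FALSE]
      deltas <- data.frame(
        parameter = picks$parameter, kind = picks$kind,
        value = vapply(picks$family, draw_delta_value, 1.0))
      gene_pool <- GENE_CLASS_MAP[[cls]]$genes
      variant_definition(
        gene = sprintf("%s_v%02d", gene_pool[1 + (i - 1) %% length(gene_pool)],
                       i),
        gene_class = cls, deltas = deltas, source = "synthetic")
    })
  })
}

#' Synthetic Ca2+-channel gate variants
#'
#' A focused ensemble touching only CaHVA/CaLVA activation and
#' inactivation gates (half-activation shifts and conductance factors),
#' used for the direction-replication analysis of the Ca2+-gene phenotype
#' correlations.
#'
#' @param n number of variants.
#' @param seed integer.
#' @param channels Ca2+ channels present in the target model.
#' @export
generate_ca_gate_variants <- function(n = 20, seed = 1,
                                      channels = c("CaHVA", "CaLVA")) {
  with_local_seed(seed, {
    lapply(seq_len(n), function(i) {
      ch <- sample(channels, 1)
      gate <- sample(c("act", "inact"), 1)
      choice <- sample(c("v_half", "gbar"), 1)
      if (choice == "v_half")
        deltas <- data.frame(
          parameter = paste0(ch, ".", gate, ".v_half"), kind = "add",
          value = runif(1, -10, 10))
      else
        deltas <- data.frame(parameter = paste0(ch, ".gbar"), kind = "mult",
                             value = exp(runif(1, log(0.5), log(2))))
      variant_definition(sprintf("CACNA_syn%02d", i), "Ca-channel", deltas,
                         source = "synthetic")
    })
  })
}
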