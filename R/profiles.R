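# Packaged model configurations: the reduced tonic and bursting reference
# profiles and a one-compartment configuration for solver verification.
#
# Conductance densities (S/cm^2) are package-tuned to satisfy the regime
# requirements: a stable resting state; the tonic profile fires regular
# single spikes at the reference DC while raising apical fast-Na+ density
# pushes it toward bursting; the bursting profile fires rhythmic bursts of
# 3-5 spikes whose size shrinks as SK density grows. Ca2+ channels in the
# tonic profile are concentrated in the apical "hot zone" (685-885 um, 10x
# HVA / 100x LVA); the bursting profile distributes Ca2+ and SK currents
# along the whole tree with linearly decaying apical densities.

#' Packaged model configurations
#'
#' @param name `"tonic-reduced"`, `"bursting-reduced"` or
#'   `"one-compartment"`.
#' @return a model configuration list accepted by [build_model()].
#' @export
fixture_model_config <- function(name = c("tonic-reduced", "bursting-reduced",
                                          "one-compartment")) {
  name <- match.arg(name)
  specs <- default_channel_specs()
  chan <- function(spec, ...) list(spec = spec, dist = list(...))
  cr <- function(kind, g) distribution_rule(kind, g, "constant")

  if (name == "one-compartment") {
    morph <- data.frame(id = 1L, parent = NA_integer_, path_distance = 0,
                        length = 25, diameter = 25, kind = "soma",
                        stringsAsFactors = FALSE)
    channels <- list(
      Nat = chan(specs$Nat, cr("soma", 0.9)),
      Kv31 = chan(specs$Kv31, cr("soma", 0.5)),
      Kt = chan(specs$Kt, cr("soma", 0.04)),
      SK = chan(specs$SK, cr("soma", 0.03)),
      CaHVA = chan(specs$CaHVA, cr("soma", 1.5e-5)),
      Ih = chan(specs$Ih, cr("soma", 1e-4)),
      leak = chan(specs$leak, cr("soma", 4e-5)))
    return(list(label = "one-compartment", morphology = morph,
                channels = channels,
                calcium = list(gamma = 0.05, decay_tau = 120, ca_rest = 1e-4,
                               shell_depth = 0.1, ca_out = 2,
                               kinds = "soma"),
                cm = 1, ra = 150, v_init = -78,
                reference_dc = 0.2, fI_range = c(0.05, 0.5)))
  }

  morph <- reduced_morphology()

  if (name == "tonic-reduced") {
    channels <- list(
      Nat = chan(specs$Nat, cr("soma", 1.6), cr("apical", 0.012)),
      Nap = chan(specs$Nap, cr("soma", 1.2e-3)),
      Kv31 = chan(specs$Kv31, cr("soma", 0.7), cr("apical", 1e-3)),
      Kt = chan(specs$Kt, cr("soma", 0.05)),
      Kp = chan(specs$Kp, cr("soma", 3e-3)),
      Im = chan(specs$Im, cr("apical", 6e-5)),
      SK = chan(specs$SK, cr("soma", 0.018), cr("apical", 1.5e-3)),
      CaHVA = chan(specs$CaHVA,
        distribution_rule("apical", 1.5e-5, "hot-zone",
                          list(hot_lo = 685, hot_hi = 885, fold = 10)),
        cr("soma", 1e-3)),
      CaLVA = chan(specs$CaLVA,
        distribution_rule("apical", 1e-6, "hot-zone",
                          list(hot_lo = 685, hot_hi = 885, fold = 100)),
        cr("soma", 1.5e-5)),
      Ih = chan(specs$Ih, cr("soma", 8e-5), cr("basal", 8e-5),
        distribution_rule("apical", 8e-5, "exponential",
                          list(a = -0.87, b = 2.09, lambda = 323))),
      leak = chan(specs$leak, cr("soma", 3.5e-5), cr("apical", 5e-5),
                  cr("basal", 4.5e-5)))
    return(list(label = "tonic", morphology = morph, channels = channels,
                calcium = list(gamma = 0.02, decay_tau = 120, ca_rest = 1e-4,
                               shell_depth = 0.1, ca_out = 2,
                               kinds = c("soma", "apical")),
                cm = 1, ra = 150, v_init = -78,
                reference_dc = 0.75, fI_range = c(0.3, 1.4)))
  }

  # bursting-reduced: a two-region burster. The apical trunk carries a dense
  # HVA Ca2+ conductance that supports a collective plateau (Ca2+ spike)
  # ignited by back-propagating action potentials; apical SK (slow gate)
  # terminates the plateau after a few somatic spikes, and the dendritic
  # Ca2+ pool (gamma scaled so plateau transients peak a few-fold above the
  # SK half-activation) sets the interburst interval.
  channels <- list(
    Nat = chan(specs$Nat, cr("soma", 1.4),
      distribution_rule("apical", 0.03, "linear-then-constant",
                        list(f_end = 0.3, x_end = 600)),
      cr("basal", 0.01)),
    Kv31 = chan(specs$Kv31, cr("soma", 0.35)),
    Kt = chan(specs$Kt, cr("soma", 0.02)),
    Kp = chan(specs$Kp, cr("soma", 3e-3),
      distribution_rule("apical", 2e-3, "exponential",
                        list(a = 0, b = 1, lambda = -400))),
    SK = chan(specs$SK, cr("soma", 0.005),
      distribution_rule("apical", 1.5e-3, "linear-then-constant",
                        list(f_end = 0.4, x_end = 600)),
      cr("basal", 1e-3)),
    CaHVA = chan(specs$CaHVA, cr("soma", 4e-4), cr("apical", 3e-3),
      cr("basal", 1e-4)),
    CaMVA = chan(specs$CaMVA, cr("soma", 1e-4),
      distribution_rule("apical", 1.5e-4, "linear-then-constant",
                        list(f_end = 0.5, x_end = 600)),
      cr("basal", 5e-5)),
    BK = chan(specs$BK, cr("soma", 5e-3), cr("apical", 5e-4)),
    Ih = chan(specs$Ih, cr("soma", 8e-5), cr("basal", 8e-5),
      distribution_rule("apical", 8e-5, "sigmoid",
                        list(f0 = 1, f1 = 8, x_mid = 600, w = 120))),
    leak = chan(specs$leak, cr("soma", 3.5e-5), cr("apical", 5e-5),
                cr("basal", 4.5e-5)))
  list(label = "bursting", morphology = reduced_morphology(apical_diam = 4),
       channels = channels,
       calcium = list(gamma = 1.6e-3, decay_tau = 150, ca_rest = 1e-4,
                      shell_depth = 0.1, ca_out = 2,
                      kinds = c("soma", "apical", "basal")),
       cm = 1, ra = 150, v_init = -78,
       reference_dc = 0.75, fI_range = c(0.65, 0.9))
}
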