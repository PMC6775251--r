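#!/usr/bin/env Rscript
# Reference model characterization: resting behavior, firing regimes, and
# steady-state f-I curves of the tonic and bursting layer-V pyramidal cell
# profiles. Writes results/reference_*.csv.
#
# Finding: the tonic profile fires regular single spikes across its 0.3-1.4
# nA analysis range; the bursting profile fires rhythmic bursts of 3-5
# spikes over 0.65-0.9 nA, and the burst size shrinks when SK density is
# raised.

suppressPackageStartupMessages(library(pyrexc))
dir.create("results", showWarnings = FALSE)
seed <- 1

rows <- list(); fi_rows <- list()
for (profile in c("tonic", "bursting")) {
  m <- build_reference_model(profile)
  r0 <- simulate(m, duration = 2500, record_stride = 8L)
  v500 <- r0$v[which.min(abs(r0$time - 500)), 1]
  drift <- max(abs(r0$v[r0$time > 500, 1] - v500))

  r <- simulate(m, list(stim_dc("soma", m$reference_dc, onset = 500)),
                duration = 4000, record_stride = 4L)
  st <- r$spike_times[r$spike_times > 500]
  spb <- spikes_per_burst(st)
  message(sprintf(
    "%s: rest drift %.3f mV; %.1f Hz at %.2f nA; modal spikes/burst %s",
    profile, drift, length(st) / 3.5, m$reference_dc,
    modal_spikes_per_burst(st)))
  rows[[profile]] <- data.frame(
    profile = profile, rest_drift_mV = drift,
    reference_dc_nA = m$reference_dc,
    rate_hz = length(st) / 3.5,
    modal_spikes_per_burst = modal_spikes_per_burst(st))

  curve <- fI_curve(m)   # full 12-amplitude grid, 3.5 s
  fi_rows[[profile]] <- data.frame(profile = profile,
                                   amplitude_nA = curve$amplitudes,
                                   rate_hz = curve$rates)
  message(sprintf("%s f-I average over [%.2f, %.2f] nA: %.2f Hz", profile,
                  m$fI_range[1], m$fI_range[2], fI_average(curve)))
}
write.csv(do.call(rbind, rows), "results/reference_regimes.csv",
          row.names = FALSE)
write.csv(do.call(rbind, fi_rows), "results/reference_fI.csv",
          row.names = FALSE)

# regime scans (the altered-model direction checks)
tonic <- build_reference_model("tonic")
bursting <- build_reference_model("bursting")
scan <- function(model, param, factors) {
  vapply(factors, function(f) {
    vm <- apply_parameter_deltas(model, data.frame(parameter = param,
                                                   kind = "mult", value = f))
    r <- simulate(vm, list(stim_dc("soma", model$reference_dc, onset = 500)),
                  duration = 4000, record_stride = 4L)
    modal_spikes_per_burst(r$spike_times[r$spike_times > 500])
  }, 1.0)
}
nat_f <- 1 + seq(0, 1.2, by = 0.2)
sk_f <- c(1, 1.25, 1.5, 2, 3, 4)
scans <- rbind(
  data.frame(profile = "tonic", parameter = "Nat.gbar.apical",
             factor = nat_f,
             modal_spb = scan(tonic, "Nat.gbar.apical", nat_f)),
  data.frame(profile = "bursting", parameter = "SK.gbar", factor = sk_f,
             modal_spb = scan(bursting, "SK.gbar", sk_f)))
write.csv(scans, "results/regime_scans.csv", row.names = FALSE)
message("regime scans written; bursting SK scan: ",
        paste(scans$modal_spb[scans$profile == "bursting"], collapse = " "))
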