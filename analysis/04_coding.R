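#!/usr/bin/env Rscript
# Neural coding analysis on the tonic profile: per-region synaptic
# thresholds, the 128-pattern discretized response table, input-output
# correlations, and the output-diversity curve over a per-synapse
# conductance sweep. Writes results/region_thresholds.csv,
# results/response_table.csv, results/io_correlations.csv and
# results/output_diversity.csv.

suppressPackageStartupMessages(library(pyrexc))
dir.create("results", showWarnings = FALSE)
seed <- 1

run_stage("coding", list(profile = "tonic"), out_dir = "results",
          seed = seed)
tab <- read.csv("results/response_table.csv")
uniq <- nrow(unique(tab[, -(1:2)]))
message(sprintf("control response table: %d patterns, %d unique outputs",
                nrow(tab), uniq))
io <- read.csv("results/io_correlations.csv", row.names = 1)
message("strongest input-output correlation per output measure:")
print(round(apply(io, 2, function(x)
  if (all(is.na(x))) NA else max(x, na.rm = TRUE)), 2))

# diversity over a conductance sweep (5 of the 21 published sweep points;
# three bias amplitudes -- desk-scale, see the methods vignette)
model <- build_reference_model("tonic")
pops <- pyrexc:::region_populations(model, seed = seed)
dv <- output_diversity(model,
                       g_values = c(0.0025, 0.01, 0.02, 0.035, 0.05),
                       bias_grid = c(-0.05, 0, 0.05), populations = pops)
write.csv(dv, "results/output_diversity.csv", row.names = FALSE)
print(dv)

# a variant's imprint on the coding table: Hamming distance to control
thr <- read.csv("results/region_thresholds.csv")
gs <- list(mode = "relative", fraction = 0.5, thresholds = thr)
ctrl_tab <- response_table(model, gs, populations = pops)
v <- generate_ca_gate_variants(1, seed = seed)[[1]]
vm <- apply_parameter_deltas(model, scale_variant(v, 1, 0.5))
var_tab <- response_table(vm, gs, populations = pops)
message(sprintf("Hamming distance control vs %s (eps = 1/2): %d",
                v$gene, hamming_distance(ctrl_tab, var_tab)))
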