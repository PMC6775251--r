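#!/usr/bin/env Rscript
# Per-variant phenotype effects on the tonic profile: f-I integral average,
# up-state coincidence-window integral, and maximal prepulse threshold
# factor, for the scaled variant table from 02_variant_scaling.R at
# epsilon = +-1/2. Writes results/phenotype_effects.csv.

suppressPackageStartupMessages(library(pyrexc))
seed <- 1
stopifnot(file.exists("results/variants.csv"),
          file.exists("results/scales.csv"))

model <- build_reference_model("tonic")
fI <- list(amplitudes = seq(model$fI_range[1], model$fI_range[2],
                            length.out = 6),
           duration = 2000)
run_stage("phenotype",
          list(profile = "tonic",
               variants = "results/variants.csv",
               scales = "results/scales.csv",
               phenotypes = c("fI_avg", "window_integral_up",
                              "max_prepulse_factor"),
               epsilons = c(0.5, -0.5),
               protocols = list(fI_spec = fI,
                                isi_grid = seq(-30, 70, by = 20),
                                prepulse_isi = c(200, 300, 500),
                                prepulse_n = 1500)),
          out_dir = "results", seed = seed)
eff <- read.csv("results/phenotype_effects.csv")
print(eff[, c("variant_id", "gene_class", "epsilon", "fI_avg",
              "window_integral_up", "max_prepulse_factor")])

# near-linearity report: |(P+ - P0) + (P- - P0)| / |P+ - P-| per variant
phen <- c("fI_avg", "window_integral_up", "max_prepulse_factor")
pos <- eff[eff$epsilon == 0.5, ]
neg <- eff[eff$epsilon == -0.5, ]
neg <- neg[match(pos$gene, neg$gene), ]
asym <- sapply(phen, function(p) {
  num <- abs(pos[[p]] + neg[[p]])
  den <- abs(pos[[p]] - neg[[p]])
  round(ifelse(den > 1e-9, num / den, NA), 2)
})
asym <- data.frame(gene = pos$gene, asym)
write.csv(asym, "results/epsilon_asymmetry.csv", row.names = FALSE)
message("epsilon-pair asymmetry (0 = perfectly linear):")
print(asym)
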