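# Pipeline stage runner: configuration handling, stage execution, results
# serialization and a run manifest. The numbered scripts under analysis/
# are thin drivers over this function.

#' Run one pipeline stage
#'
#' Stages: `synth` (generate a variant table), `scale` (find threshold
#' scales c for a variant table), `phenotype` (per-variant phenotype
#' effects), `coding` (response table + diversity for the control model),
#' `correlate` (cross-phenotype correlations from a phenotype CSV),
#' `simulate` (a single protocol simulation with trace export).
#'
#' All randomness flows from the single `seed`, expanded deterministically
#' per stage. Outputs are CSV/JSON under `out_dir`; a JSON manifest listing
#' them is written alongside and returned invisibly.
#'
#' @param stage stage name.
#' @param config named list of stage settings (profile, scaled-down
#'   protocol sizes, input paths); unknown entries are ignored by each
#'   stage.
#' @param out_dir output directory (created if missing).
#' @param seed integer master seed.
#' @export
run_stage <- function(stage = c("synth", "scale", "phenotype", "coding",
                                "correlate", "simulate"),
                      config = list(), out_dir = "results", seed = 1) {
  stage <- match.arg(stage)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  t0 <- Sys.time()
  stage_seed <- derive_seed(seed, stage)
  outputs <- switch(stage,
    synth = stage_synth(config, out_dir, stage_seed),
    scale = stage_scale(config, out_dir, stage_seed),
    phenotype = stage_phenotype(config, out_dir, stage_seed),
    coding = stage_coding(config, out_dir, stage_seed),
    correlate = stage_correlate(config, out_dir, stage_seed),
    simulate = stage_simulate(config, out_dir, stage_seed))
  manifest <- list(stage = stage, seed = seed,
                   tool_version = as.character(utils::packageVersion("pyrexc")),
                   started = format(t0, "%Y-%m-%dT%H:%M:%S"),
                   finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                   outputs = outputs)
  man_path <- file.path(out_dir, paste0("manifest_", stage, ".json"))
  jsonlite::write_json(manifest, man_path, auto_unbox = TRUE, pretty = TRUE)
  missing <- outputs[!file.exists(unlist(outputs))]
  if (length(missing))
    stop_pyrexc("stage '%s' did not produce: %s", stage,
                paste(unlist(missing), collapse = ", "))
  invisible(manifest)
}

stage_model <- function(config) {
  build_reference_model(config$profile %||% "tonic")
}

stage_synth <- function(config, out_dir, seed) {
  cfg <- variant_generator_config(
    n_variants = config$n_variants %||% 20,
    channels = config$channels %||% NULL,
    seed = seed)
  tab <- generate_variant_table(cfg)
  path <- file.path(out_dir, "variants.csv")
  write_variant_table(tab, path)
  list(variants = path)
}

stage_scale <- function(config, out_dir, seed) {
  model <- stage_model(config)
  variants <- read_variant_table(config$variants %||%
                                   file.path(out_dir, "variants.csv"))
  fI_spec <- config$fI_spec %||% default_fI_spec(model)
  ref <- threshold_reference(model, fI_spec)
  rows <- lapply(variants, function(v) {
    c_val <- find_threshold_scale(model, v,
                                  grid_step = config$grid_step %||% 0.05,
                                  fI_spec = fI_spec, control_ref = ref)
    data.frame(gene = v$gene, gene_class = v$gene_class, c = c_val)
  })
  path <- file.path(out_dir, "scales.csv")
  write.csv(do.call(rbind, rows), path, row.names = FALSE)
  list(scales = path)
}

stage_phenotype <- function(config, out_dir, seed) {
  model <- stage_model(config)
  variants <- read_variant_table(config$variants %||%
                                   file.path(out_dir, "variants.csv"))
  scales <- if (!is.null(config$scales) || file.exists(file.path(out_dir, "scales.csv"))) {
    s <- read.csv(config$scales %||% file.path(out_dir, "scales.csv"))
    setNames(s$c, s$gene)
  } else NULL
  eps <- config$epsilons %||% c(0.5, -0.5)
  scaled <- list()
  for (v in variants) {
    cv <- if (!is.null(scales) && v$gene %in% names(scales))
      scales[[v$gene]] else 2
    for (e in eps)
      scaled[[length(scaled) + 1]] <- scale_variant(v, cv, e)
  }
  tab <- phenotype_effect_table(model, scaled,
                                phenotypes = config$phenotypes %||%
                                  c("fI_avg", "window_integral_up",
                                    "max_prepulse_factor"),
                                protocols = config$protocols %||% list(),
                                seed = seed)
  path <- file.path(out_dir, "phenotype_effects.csv")
  write.csv(tab, path, row.names = FALSE)
  list(phenotype_effects = path)
}

stage_coding <- function(config, out_dir, seed) {
  model <- stage_model(config)
  n_per <- config$n_per_region %||% 1000
  pops <- region_populations(model, n_per_region = n_per, seed = seed)
  thr <- region_thresholds(model, n_per_region = n_per, seed = seed,
                           populations = pops)
  thr_path <- file.path(out_dir, "region_thresholds.csv")
  write.csv(thr, thr_path, row.names = FALSE)
  tab <- response_table(model,
                        list(mode = "relative", fraction = 0.5,
                             thresholds = thr),
                        populations = pops)
  tab_path <- file.path(out_dir, "response_table.csv")
  write_coding_csv(tab, tab_path)
  cors <- io_correlations(tab)
  cor_path <- file.path(out_dir, "io_correlations.csv")
  write.csv(as.data.frame(cors), cor_path, row.names = TRUE)
  list(region_thresholds = thr_path, response_table = tab_path,
       io_correlations = cor_path)
}

stage_correlate <- function(config, out_dir, seed) {
  path_in <- config$phenotype_effects %||%
    file.path(out_dir, "phenotype_effects.csv")
  tab <- read.csv(path_in, stringsAsFactors = FALSE)
  class(tab) <- c("effect_table", class(tab))
  rep <- effect_correlations(tab,
                             use_epsilon = config$use_epsilon %||% 0.5)
  path <- file.path(out_dir, "correlations.csv")
  write.csv(rep, path, row.names = FALSE)
  list(correlations = path)
}

stage_simulate <- function(config, out_dir, seed) {
  model <- stage_model(config)
  amp <- config$amplitude %||% model$reference_dc
  res <- simulate(model, list(stim_dc("soma", amp, onset = 500)),
                  duration = config$duration %||% 2000,
                  record_sites = list("soma",
                                      list(kind = "apical", x = 700)),
                  record_stride = 8L)
  path <- file.path(out_dir, "traces.csv")
  write_traces_csv(res, path)
  list(traces = path)
}
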