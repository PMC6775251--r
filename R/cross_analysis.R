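# Cross-phenotype analysis: per-variant phenotype effect tables and their
# correlations, overall and stratified by gene class.

#' Scalar phenotype summary of a model
#'
#' Computes the requested subset of the phenotype battery: `fI_avg` (Hz),
#' `window_integral_up` / `window_integral_down` (mV ms),
#' `max_prepulse_factor`, `diversity_small_g` / `diversity_large_g`.
#'
#' @param model a `neuron_model`.
#' @param phenotypes character vector of phenotype names to compute.
#' @param protocols list of protocol settings: `fI_spec`
#'   (amplitudes/duration), `isi_grid`, `preset`
#'   ([coincidence_preset()]), `prepulse_isi`, `g_small`, `g_large` (nS),
#'   `bias_grid`, `baseline` (mV), `dt`.
#' @param seed integer.
#' @param populations optional shared coding populations.
#' @return named numeric vector.
#' @export
phenotype_summary <- function(model,
                              phenotypes = c("fI_avg", "window_integral_up",
                                             "max_prepulse_factor"),
                              protocols = list(), seed = 1,
                              populations = NULL) {
  p <- modifyList(list(
    fI_spec = default_fI_spec(model),
    isi_grid = seq(-30, 70, by = 10),
    preset = coincidence_preset(),
    prepulse_isi = c(50, 100, 200, 300, 500, 1000),
    g_small = 0.02, g_large = 0.045,
    bias_grid = seq(-0.1, 0.1, by = 0.02),
    baseline = -50, dt = 0.025, prepulse_n = 3000
  ), protocols)
  out <- c()
  if ("fI_avg" %in% phenotypes) {
    curve <- fI_curve(model, p$fI_spec$amplitudes,
                      duration = p$fI_spec$duration, dt = p$dt)
    out["fI_avg"] <- fI_average(curve)
  }
  need_coin <- any(c("window_integral_up", "window_integral_down") %in%
                     phenotypes)
  if (need_coin) {
    thr <- coincidence_thresholds(model, p$preset, dt = p$dt)
    if ("window_integral_up" %in% phenotypes) {
      w <- coincidence_window(model, "up", p$isi_grid, p$preset,
                              thresholds = thr, dt = p$dt)
      out["window_integral_up"] <- window_integral(w, p$baseline)
    }
    if ("window_integral_down" %in% phenotypes) {
      w <- coincidence_window(model, "down", p$isi_grid, p$preset,
                              thresholds = thr, dt = p$dt)
      out["window_integral_down"] <- window_integral(w, p$baseline)
    }
  }
  if ("max_prepulse_factor" %in% phenotypes) {
    curve <- prepulse_curve(model, p$prepulse_isi, seed = seed,
                            n_synapses = p$prepulse_n, dt = p$dt)
    out["max_prepulse_factor"] <- max_prepulse_factor(curve)
  }
  if (any(c("diversity_small_g", "diversity_large_g") %in% phenotypes)) {
    pops <- populations %||% region_populations(model, seed = seed)
    if ("diversity_small_g" %in% phenotypes)
      out["diversity_small_g"] <- output_diversity(
        model, p$g_small, p$bias_grid, populations = pops,
        dt = p$dt)$mean_diversity
    if ("diversity_large_g" %in% phenotypes)
      out["diversity_large_g"] <- output_diversity(
        model, p$g_large, p$bias_grid, populations = pops,
        dt = p$dt)$mean_diversity
  }
  out[phenotypes]
}

#' Per-variant phenotype effect table
#'
#' One row per (variant, epsilon) holding the phenotype deltas
#' (variant value - control value), all computed against the same control
#' run with shared seeds.
#'
#' @param control control `neuron_model`.
#' @param variants list of `scaled_variant` objects.
#' @param phenotypes,protocols,seed passed to [phenotype_summary()].
#' @return an `effect_table` data frame with columns `variant_id`, `gene`,
#'   `gene_class`, `epsilon`, one column per phenotype delta, and `error`
#'   (NA or the failure message; failed rows carry NA deltas).
#' @export
phenotype_effect_table <- function(control, variants,
                                   phenotypes = c("fI_avg",
                                                  "window_integral_up",
                                                  "max_prepulse_factor"),
                                   protocols = list(), seed = 1) {
  ctrl <- phenotype_summary(control, phenotypes, protocols, seed = seed)
  rows <- list()
  rows[[1]] <- data.frame(variant_id = "control", gene = "control",
                          gene_class = "control", epsilon = 0,
                          as.list(setNames(rep(0, length(phenotypes)),
                                           phenotypes)),
                          error = NA_character_, stringsAsFactors = FALSE)
  for (i in seq_along(variants)) {
    sv <- variants[[i]]
    row_id <- sprintf("%s_c%.3g_e%+.2f", sv$base$gene, sv$c, sv$epsilon)
    res <- tryCatch({
      vm <- apply_parameter_deltas(control, sv)
      phenotype_summary(vm, phenotypes, protocols, seed = seed) - ctrl
    }, error = function(e) conditionMessage(e))
    if (is.character(res)) {
      vals <- setNames(rep(NA_real_, length(phenotypes)), phenotypes)
      err <- res
    } else {
      vals <- res; err <- NA_character_
    }
    rows[[i + 1]] <- data.frame(variant_id = row_id, gene = sv$base$gene,
                                gene_class = sv$base$gene_class,
                                epsilon = sv$epsilon, as.list(vals),
                                error = err, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  class(out) <- c("effect_table", class(out))
  out
}

#' Cross-phenotype effect correlations
#'
#' Pearson correlation between phenotype-effect columns across variants,
#' overall and stratified into Ca2+ genes (Ca-channel + Ca-transporter) vs
#' the rest. Strata with fewer than `min_n` rows yield NA. The control row
#' and epsilon values other than `use_epsilon` are excluded.
#'
#' @param table an [phenotype_effect_table()] result.
#' @param use_epsilon which epsilon rows enter (default +1/2); `NULL` pools
#'   all.
#' @param min_n minimal stratum size.
#' @return a `correlation_report` data frame with `phenotype_a`,
#'   `phenotype_b`, `stratum`, `r`, `n`.
#' @export
effect_correlations <- function(table, use_epsilon = 0.5, min_n = 3) {
  phen <- setdiff(names(table), c("variant_id", "gene", "gene_class",
                                  "epsilon", "error"))
  d <- table[table$gene_class != "control", ]
  if (!is.null(use_epsilon))
    d <- d[abs(d$epsilon - use_epsilon) < 1e-9, ]
  is_ca <- d$gene_class %in% c("Ca-channel", "Ca-transporter")
  strata <- list(all = rep(TRUE, nrow(d)), ca = is_ca, non_ca = !is_ca)
  out <- list()
  for (a in seq_along(phen)) for (b in seq_along(phen)) {
    if (b <= a) next
    for (s in names(strata)) {
      rows <- d[strata[[s]], c(phen[a], phen[b])]
      rows <- rows[stats::complete.cases(rows), ]
      r <- if (nrow(rows) >= min_n && stats::sd(rows[[1]]) > 0 &&
               stats::sd(rows[[2]]) > 0)
        cor(rows[[1]], rows[[2]]) else NA_real_
      out[[length(out) + 1]] <- data.frame(
        phenotype_a = phen[a], phenotype_b = phen[b], stratum = s,
        r = r, n = nrow(rows), stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  class(res) <- c("correlation_report", class(res))
  res
}
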