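# Shared fixture models, built once per test run.
.model_cache <- new.env(parent = emptyenv())

cached_model <- function(name) {
  if (is.null(.model_cache[[name]])) {
    .model_cache[[name]] <- switch(name,
      tonic = build_reference_model("tonic"),
      bursting = build_reference_model("bursting"),
      onecomp = build_model(fixture_model_config("one-compartment")))
  }
  .model_cache[[name]]
}

# reduced protocol settings used by the heavier tests; the full-scale
# defaults are exercised in the analysis scripts
fast_fI_spec <- function(model, n = 6, duration = 2000)
  list(amplitudes = seq(model$fI_range[1], model$fI_range[2],
                        length.out = n),
       duration = duration)

fast_protocols <- function(model) {
  list(fI_spec = fast_fI_spec(model),
       isi_grid = seq(-30, 70, by = 20),
       prepulse_isi = c(200, 300, 500),
       prepulse_n = 1500)
}

spikes_at_dc <- function(model, amp, duration = 3000, equil = 500) {
  r <- simulate(model, list(stim_dc("soma", amp, onset = equil)),
                duration = duration, record_stride = 4L)
  r$spike_times[r$spike_times > equil]
}
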