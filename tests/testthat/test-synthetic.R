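# Synthetic variant generator: reproducibility, class consistency, delta
# distributions.

test_that("the generator is empty at n = 0 and reproducible by seed", {
  expect_length(generate_variant_table(variant_generator_config(0)), 0)
  a <- generate_variant_table(variant_generator_config(15, seed = 4))
  b <- generate_variant_table(variant_generator_config(15, seed = 4))
  expect_equal(length(a), 15)
  for (i in seq_along(a)) expect_equal(a[[i]]$deltas, b[[i]]$deltas)
  c2 <- generate_variant_table(variant_generator_config(15, seed = 5))
  expect_false(identical(lapply(a, `[[`, "deltas"),
                         lapply(c2, `[[`, "deltas")))
})

test_that("every delta targets a channel admissible for its gene class", {
  map <- pyrexc:::GENE_CLASS_MAP
  vars <- generate_variant_table(variant_generator_config(200, seed = 8))
  for (v in vars) {
    heads <- vapply(strsplit(v$deltas$parameter, ".", fixed = TRUE),
                    `[[`, "", 1)
    expect_true(all(heads %in% map[[v$gene_class]]$channels),
                info = paste(v$gene, v$gene_class,
                             paste(heads, collapse = ",")))
  }
  # Ca-transporter variants touch only the Ca2+ decay time constant
  ct <- Filter(function(v) v$gene_class == "Ca-transporter", vars)
  for (v in ct)
    expect_true(all(v$deltas$parameter == "calcium.decay_tau"))
})

test_that("delta magnitudes follow the configured distributions", {
  vars <- generate_variant_table(
    variant_generator_config(4000, class_mix = c("Ca-channel" = 1),
                             deltas_per_variant = c(1, 1), seed = 12))
  all_d <- do.call(rbind, lapply(vars, function(v)
    cbind(v$deltas, gene = v$gene)))
  shifts <- all_d$value[grepl("v_half$", all_d$parameter)]
  expect_gt(length(shifts), 200)
  expect_true(all(shifts >= -10 & shifts <= 10))
  # mean within 3 standard errors of 0 for Uniform(-10, 10)
  se <- 20 / sqrt(12) / sqrt(length(shifts))
  expect_lt(abs(mean(shifts)), 3 * se)
  gfac <- all_d$value[grepl("gbar$", all_d$parameter)]
  expect_true(all(gfac >= 0.5 & gfac <= 2))
  lg <- log(gfac)
  expect_lt(abs(mean(lg)), 3 * (log(2) - log(0.5)) / sqrt(12) /
              sqrt(length(lg)))
})

test_that("generated variants scale and apply cleanly to the tonic model", {
  m <- cached_model("tonic")
  vars <- generate_variant_table(variant_generator_config(10, seed = 21))
  for (v in vars) {
    sv <- scale_variant(v, 1, 0.25)
    vm <- apply_parameter_deltas(m, sv)
    expect_s3_class(vm, "neuron_model")
  }
})

test_that("fixture configurations satisfy their regime claims", {
  one <- fixture_model_config("one-compartment")
  expect_equal(nrow(one$morphology), 1)
  r <- simulate(build_model(one), duration = 1500, record_stride = 4L)
  expect_length(r$spike_times, 0)

  st_t <- spikes_at_dc(cached_model("tonic"),
                       cached_model("tonic")$reference_dc, duration = 4000)
  expect_equal(modal_spikes_per_burst(st_t), 1)

  st_b <- spikes_at_dc(cached_model("bursting"),
                       cached_model("bursting")$reference_dc,
                       duration = 4000)
  expect_true(modal_spikes_per_burst(st_b) %in% 3:5)
  expect_error(fixture_model_config("no-such"), "arg")
})
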