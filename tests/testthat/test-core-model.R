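# Core model construction, spike handling, and solver correctness.

test_that("reduced morphology satisfies the compartment invariants", {
  m <- reduced_morphology()
  expect_equal(sum(m$kind == "soma"), 1)
  expect_true(is.na(m$parent[m$kind == "soma"]))
  expect_true(all(m$path_distance >= 0))
  # connected: every non-root parent resolves
  expect_false(anyNA(match(m$parent[!is.na(m$parent)], m$id)))
  # spans all protocol sites
  apical <- m$path_distance[m$kind == "apical"]
  for (x in c(200, 600, 700, 850, 1100))
    expect_lt(min(abs(apical - x)), 100)
})

test_that("distribution profiles evaluate as specified", {
  x <- c(0, 300, 684, 685, 800, 884, 885, 1200)
  hot <- distribution_rule("apical", 1e-4, "hot-zone",
                           list(hot_lo = 685, hot_hi = 885, fold = 10))
  g <- pyrexc:::eval_rule(hot, x)
  expect_equal(g, 1e-4 * c(1, 1, 1, 10, 10, 10, 1, 1))
  lin <- distribution_rule("apical", 1, "linear-then-constant",
                           list(f_end = 0.4, x_end = 600))
  gl <- pyrexc:::eval_rule(lin, c(0, 300, 600, 1200))
  expect_equal(gl, c(1, 0.7, 0.4, 0.4))
  expect_true(all(pyrexc:::eval_rule(
    distribution_rule("apical", 1, "sigmoid",
                      list(f0 = 1, f1 = 8, x_mid = 600, w = 120)),
    seq(0, 1200, 100)) > 0))
})

test_that("parameter deltas apply additively/multiplicatively and copy", {
  m <- cached_model("tonic")
  expect_identical(apply_parameter_deltas(m, data.frame(
    parameter = character(0), kind = character(0), value = numeric(0))), m)

  d <- delta_df(c("SK.gbar", "mult", "1.1"))
  m2 <- apply_parameter_deltas(m, d)
  expect_equal(m2$channels$SK$dist[[1]]$g_max,
               m$channels$SK$dist[[1]]$g_max * 1.1)
  # original untouched
  expect_equal(m$channels$SK$dist[[1]]$g_max,
               fixture_model_config("tonic-reduced")$channels$SK$dist[[1]]$g_max)

  # v_half shift symmetry: shifted steady state at V equals original at V+5
  m3 <- apply_parameter_deltas(m, delta_df(c("CaHVA.act.v_half", "add", "-5")))
  g0 <- m$channels$CaHVA$spec$activation
  g1 <- m3$channels$CaHVA$spec$activation
  v <- seq(-80, 0, by = 5)
  expect_equal(gate_inf(g1, v = v), gate_inf(g0, v = v + 5))

  expect_error(apply_parameter_deltas(m, delta_df(c("BK.gbar", "mult", "2"))),
               "BK")
})

test_that("spike detection crosses threshold upward with lockout", {
  t <- seq(0, 300, by = 0.1)
  expect_length(detect_spikes(data.frame(time = t, v = rep(-70, length(t)))),
                0)
  v <- rep(-70, length(t))
  v[t >= 100 & t < 101] <- 10
  v[t >= 200 & t < 201] <- 10
  st <- detect_spikes(data.frame(time = t, v = v))
  expect_equal(round(st), c(100, 200))
  # two crossings within the lockout collapse to one
  v2 <- rep(-70, length(t))
  v2[t >= 100 & t < 100.5] <- 10
  v2[t >= 101 & t < 101.5] <- 10
  expect_length(detect_spikes(data.frame(time = t, v = v2)), 1)
  expect_length(detect_spikes(data.frame(time = numeric(0), v = numeric(0))),
                0)
})

test_that("burst grouping fractions and modal statistic behave", {
  expect_length(spikes_per_burst(numeric(0)), 0)
  # regular 10 Hz train: every burst is one spike
  d <- spikes_per_burst(seq(0, 2000, by = 100), burst_gap = 50,
                        discard_first = 0)
  expect_equal(d, c("1" = 1))
  # doublets 10 ms apart, 250 ms between pairs, first two bursts dropped
  pairs <- as.vector(vapply(seq(0, 2000, by = 250),
                            function(t0) c(t0, t0 + 10), numeric(2)))
  d2 <- spikes_per_burst(pairs, burst_gap = 50, discard_first = 2)
  expect_equal(d2, c("2" = 1))
  expect_equal(modal_spikes_per_burst(pairs), 2)
})

test_that("reference models rest stably and zero input produces no spikes", {
  for (name in c("tonic", "bursting")) {
    r <- simulate(cached_model(name), duration = 2500, record_stride = 8L)
    expect_length(r$spike_times, 0)
    v500 <- r$v[which.min(abs(r$time - 500)), 1]
    expect_lt(max(abs(r$v[r$time > 500, 1] - v500)), 1)
  }
})

test_that("calcium decouples from voltage when Ca2+ conductances are zero", {
  m <- cached_model("tonic")
  m0 <- apply_parameter_deltas(m, delta_df(c("CaHVA.gbar", "mult", "0"),
                                           c("CaLVA.gbar", "mult", "0")))
  r <- simulate(m0, list(stim_dc("soma", 0.75, onset = 200)),
                duration = 1500,
                record_sites = list(list(kind = "apical", x = 700)))
  expect_gt(length(r$spike_times), 2)  # still spiking
  expect_lt(max(abs(r$ca - m$calcium$ca_rest)), 1e-9)
})

test_that("single-compartment voltage matches a stiff ODE reference", {
  skip_if_not_installed("deSolve")
  m <- cached_model("onecomp")
  times <- seq(0, 500, by = 0.25)
  sol <- one_comp_oracle(m, function(t) if (t >= 100 && t <= 400) 0.12 else 0,
                         times)
  res <- simulate(m, list(stim_pulse("soma", 0.12, 100, 300)), duration = 500)
  v_sim <- approx(res$time, res$v[, 1], xout = times)$y
  expect_lt(max(abs(v_sim - sol[, 2])), 0.5)
  # the probe actually excursions, so the comparison is nontrivial
  expect_gt(diff(range(sol[, 2])), 10)
})

test_that("simulation is deterministic and converges under dt halving", {
  m <- cached_model("tonic")
  stim <- list(stim_dc("soma", 0.75, onset = 200))
  r1 <- simulate(m, stim, duration = 900)
  r2 <- simulate(m, stim, duration = 900)
  expect_identical(r1$v, r2$v)
  expect_identical(r1$spike_times, r2$spike_times)

  st_half <- simulate(m, stim, duration = 900, dt = 0.0125)$spike_times
  expect_length(st_half, length(r1$spike_times))
  expect_lt(max(abs(st_half - r1$spike_times)), 1)
})

test_that("rheobase bracketing is sharp around the bisected threshold", {
  m <- cached_model("tonic")
  thr <- pyrexc:::bisect_threshold(function(a) {
    length(spikes_at_dc(m, a, duration = 1500))
  }, hi = 1, tol = 0.005)
  expect_gte(length(spikes_at_dc(m, 1.01 * thr, duration = 1500)), 1)
  expect_length(spikes_at_dc(m, 0.97 * thr, duration = 1500), 0)
})

test_that("divergent states raise an error naming the offending time", {
  m <- cached_model("onecomp")
  expect_error(simulate(m, list(stim_dc("soma", 1e5, onset = 0)),
                        duration = 100),
               "diverged")
})

test_that("SWC morphologies round-trip into the compartment table", {
  path <- tempfile(fileext = ".swc")
  writeLines(c(
    "# synthetic three-point morphology",
    "1 1 0 0 0 10 -1",
    "2 4 0 0 100 2 1",
    "3 4 0 0 220 1.5 2",
    "4 3 0 -150 0 3 1"), path)
  m <- read_swc(path)
  expect_equal(nrow(m), 4)
  expect_equal(m$kind, c("soma", "apical", "apical", "basal"))
  expect_equal(m$path_distance, c(0, 100, 220, 150))
  model <- build_model(list(
    morphology = m,
    channels = fixture_model_config("one-compartment")$channels,
    calcium = fixture_model_config("one-compartment")$calcium))
  r <- simulate(model, duration = 300)
  expect_length(r$spike_times, 0)
})
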