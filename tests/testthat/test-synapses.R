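# Synapse kernels, Mg2+ block, short-term depression, Poisson drive and
# placement rules.

test_that("kernel peaks are normalized to g_max", {
  t <- seq(0, 400, by = 0.01)
  for (kin in list(syn_kinetics("AMPA", 0.4, tau_rise = 0.3, tau_decay = 3),
                   syn_kinetics("NMDA", 0.4, tau_rise = 2, tau_decay = 65,
                                mg_block = FALSE),
                   syn_kinetics("GABA", 1.0, tau_rise = 1, tau_decay = 20),
                   syn_kinetics("alpha", 2.5, tau_decay = 5))) {
    g <- conductance_waveform(kin, 10, t)
    expect_lt(abs(max(g) / kin$g_max - 1), 1e-3)
  }
  # alpha kernel peaks exactly one time constant after the event
  kin <- syn_kinetics("alpha", 1, tau_decay = 5)
  g <- conductance_waveform(kin, 10, t)
  expect_equal(t[which.max(g)], 15, tolerance = 1e-3)
  expect_equal(conductance_waveform(kin, numeric(0), t), rep(0, length(t)))
})

test_that("Mg2+ block is a saturating increasing sigmoid", {
  expect_gt(mg_block_factor(100), 0.95)
  v <- seq(-100, 50, by = 1)
  f <- mg_block_factor(v)
  expect_true(all(diff(f) > 0))
  expect_true(all(f > 0 & f < 1))
  # closed form at v = 0, 1 mM
  expect_equal(mg_block_factor(0, 1), 1 / (1 + 1 / 3.57))
  expect_error(mg_block_factor(0, 0), "mg")
})

test_that("depression follows the resource-recovery recursion", {
  expect_equal(depression_scale(0, D = 800, U_se = 0.6), 0.6)
  expect_equal(depression_scale(c(0, 1e9), D = 800, U_se = 0.6),
               c(0.6, 0.6), tolerance = 1e-6)
  # hand-iterated recursion, 5 events at 50 ms spacing
  D <- 800; U <- 0.6
  R <- 1; expected <- numeric(5)
  for (i in 1:5) {
    expected[i] <- U * R
    R <- 1 - (1 - R * (1 - U)) * exp(-50 / D)
  }
  got <- depression_scale(seq(0, 200, by = 50), D = D, U_se = U)
  expect_equal(got, expected)
  expect_true(all(got > 0 & got <= U))
  expect_true(all(diff(got) <= 0))
})

test_that("poisson trains are seed-reproducible with consistent rates", {
  expect_length(poisson_times(0, 1000, seed = 1), 0)
  expect_identical(poisson_times(7, 10000, seed = 5),
                   poisson_times(7, 10000, seed = 5))
  counts <- vapply(1:400, function(s)
    length(poisson_times(7, 10000, seed = 1000 + s)), 1L)
  # mean count 70, se = sqrt(70)/sqrt(n)
  expect_lt(abs(mean(counts) - 70), 3 * sqrt(70 / 400))
  p <- stats::chisq.test(table(cut(counts, quantile(counts, 0:4 / 4),
                                   include.lowest = TRUE)))$p.value
  expect_gt(p, 0.01)
})

test_that("placement is uniform over eligible path length", {
  m <- cached_model("tonic")
  kin <- syn_kinetics("alpha", 1, tau_decay = 5)
  expect_equal(nrow(place_synapses(m, 0, kin)$members), 0)
  pop <- place_synapses(m, 3000, kin, kind = "apical", dist_min = 300,
                        seed = 11)
  d <- pop$members$distance
  expect_true(all(d >= 300))
  max_x <- 1200
  ks <- suppressWarnings(stats::ks.test(d, "punif", 300, max_x))
  expect_gt(ks$p.value, 0.01)
  expect_error(place_synapses(m, 10, kin, kind = "apical", dist_min = 5000),
               "empty")
})

test_that("per-region placements respect their distance windows", {
  m <- cached_model("tonic")
  pops <- pyrexc:::region_populations(m, n_per_region = 200, seed = 3)
  part <- region_partition()
  for (i in seq_len(nrow(part))) {
    expect_equal(nrow(pops[[i]]$members), 200)
    d <- pops[[i]]$members$distance
    kinds <- m$morph$kind[pops[[i]]$members$comp]
    expect_true(all(kinds == part$kind[i]))
    if (part$kind[i] == "apical")
      expect_true(all(d >= part$lo[i] - 1e-9 & d < part$hi[i] + 1e-9))
  }
})

test_that("background population matches the in-vivo-like composition", {
  m <- cached_model("tonic")
  pop <- background_population(m, seed = 2)
  k <- vapply(pop$members$kin_id, function(i) pop$kinetics[[i]]$receptor, "")
  expect_equal(sum(k == "AMPA"), 10000)
  expect_equal(sum(k == "NMDA"), 10000)
  expect_equal(sum(k == "GABA"), 2500)
  # AMPA and NMDA share presynaptic event groups
  expect_identical(pop$members$group[k == "AMPA"],
                   pop$members$group[k == "NMDA"])
  expect_equal(pop$kinetics[[1]]$g_max, 0.4)
  expect_equal(pop$kinetics[[3]]$g_max, 1.0)
  expect_equal(pop$kinetics[[1]]$e_rev, 0)
  expect_equal(pop$kinetics[[3]]$e_rev, -80)
  expect_equal(pop$kinetics[[1]]$depression$U_se, 0.6)
  expect_equal(pop$kinetics[[3]]$depression$U_se, 0.25)
  expect_equal(unname(pop$activation$rate[1]), 0.72)
  expect_equal(unname(pop$activation$rate[10001]), 7.0)
  # placement restricted to the dendritic trees
  expect_true(all(m$morph$kind[pop$members$comp] %in% c("apical", "basal")))
})

test_that("event realization is reproducible and shares trains within groups", {
  m <- cached_model("tonic")
  pop <- background_population(m, seed = 2, n_exc = 200, n_inh = 50)
  e1 <- population_events(pop, duration = 2000, seed = 9)
  e2 <- population_events(pop, duration = 2000, seed = 9)
  expect_identical(e1$events, e2$events)
  e3 <- population_events(pop, duration = 2000, seed = 10)
  expect_false(identical(e1$events, e3$events))
})

test_that("NMDA conductance in the solver is Mg2+-gated", {
  # the same event with the Mg2+ block enabled moves the resting membrane
  # far less than the unblocked kernel (block factor ~0.03 near -78 mV)
  m <- cached_model("onecomp")
  ev <- function(mg_on) list(
    events = matrix(c(100, 0, 0, 0.01), nrow = 1),
    types = matrix(c(2, 65, 0, mg_on, 0), nrow = 1))
  r_blk <- simulate(m, synapses = ev(1), duration = 300)
  r_opn <- simulate(m, synapses = ev(0), duration = 300)
  v0 <- approx(r_blk$time, r_blk$v[, 1], 99.9)$y
  win <- r_blk$time > 100 & r_blk$time < 250
  epsp_blk <- max(r_blk$v[win, 1]) - v0
  epsp_opn <- max(r_opn$v[win, 1]) - v0
  expect_gt(epsp_opn, 0.5)
  expect_lt(epsp_blk, 0.5 * epsp_opn)
})
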