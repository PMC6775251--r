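# Phenotype protocols: f-I curves, coincidence windows, prepulse adaptation,
# noisy up/down states.

test_that("f-I curves are zero below rheobase and monotone for the tonic cell", {
  m <- cached_model("tonic")
  amps <- c(0, 0.1, seq(0.3, 1.4, length.out = 5))
  curve <- fI_curve(m, amps, duration = 2000)
  expect_equal(curve$rates[1], 0)
  expect_true(all(curve$rates >= 0))
  # monotone tail over the analysis range, tolerating one grid-cell dip
  tail_r <- curve$rates[amps >= 0.3]
  expect_lte(sum(diff(tail_r) < 0), 1)
})

test_that("f-I average is a trapezoid mean matching closed forms", {
  const <- list(amplitudes = seq(0, 1, 0.1), rates = rep(7, 11))
  expect_equal(fI_average(const, c(0.2, 0.8)), 7)
  ramp <- list(amplitudes = seq(0, 1, 0.01), rates = seq(0, 10, 0.1))
  expect_equal(fI_average(ramp, c(0, 1)), 5)
  # partial range on the ramp: mean of endpoints
  expect_equal(fI_average(ramp, c(0.25, 0.75)), 5)
  expect_error(fI_average(const, c(2, 3)), "overlap")
  # dense-grid quadrature agreement for an irregular curve
  f <- function(x) 5 + 4 * sin(3 * x)
  coarse <- list(amplitudes = seq(0.3, 1.4, length.out = 25),
                 rates = f(seq(0.3, 1.4, length.out = 25)))
  dense <- list(amplitudes = seq(0.3, 1.4, length.out = 2000),
                rates = f(seq(0.3, 1.4, length.out = 2000)))
  expect_lt(abs(fI_average(coarse) / fI_average(dense) - 1), 0.01)
})

test_that("window integral is a baseline-subtracted trapezoid", {
  w <- structure(list(isi = seq(-30, 70, by = 10),
                      response = rep(-50, 11), state = "up", site = 700),
                 class = "temporal_window")
  expect_equal(window_integral(w, baseline = -50), 0)
  w$response <- rep(-40, 11)  # +10 mV over the 100-ms ISI span
  expect_equal(window_integral(w, baseline = -50), 1000)
})

test_that("coincident stimuli produce at least the late-ISI dendritic response", {
  m <- cached_model("tonic")
  thr <- pyrexc:::coincidence_thresholds(m, coincidence_preset())
  for (state in c("up", "down")) {
    w <- coincidence_window(m, state, isi_grid = c(-30, 0, 10, 70),
                            thresholds = thr)
    peak <- max(w$response[w$isi %in% c(0, 10)])
    expect_gte(peak, w$response[w$isi == 70] - 1e-9)
    expect_true(all(is.finite(w$response)))
  }
})

test_that("prepulse threshold factor converges to 1 at long ISI", {
  m <- cached_model("tonic")
  curve <- prepulse_curve(m, isi_grid = c(300, 2000), n_synapses = 1500,
                          seed = 1)
  expect_gt(curve$g_th, 0)
  expect_true(all(curve$threshold_factor > 0))
  expect_lt(abs(curve$threshold_factor[curve$isi == 2000] - 1), 0.02)
  # adaptation: the short-ISI factor is at least the long-ISI one
  expect_gte(curve$threshold_factor[1], curve$threshold_factor[2])
  expect_equal(max_prepulse_factor(curve), max(curve$threshold_factor))
})

test_that("noisy up/down states use the modulated background rates", {
  expect_equal(unname(updown_rates()["down"]), 0.504)
  expect_equal(unname(updown_rates()["up"]), 0.792)
  expect_equal(unname(updown_rates(1)["up"]), 1.1)
})

test_that("noisy window means repetitions and is seed-reproducible", {
  m <- cached_model("tonic")
  thr <- pyrexc:::coincidence_thresholds(m, coincidence_preset())
  w1 <- noisy_updown(m, "up", isi_grid = c(0, 20), n_rep = 3, seed = 5,
                     thresholds = thr, n_background = 2000)
  w2 <- noisy_updown(m, "up", isi_grid = c(0, 20), n_rep = 3, seed = 5,
                     thresholds = thr, n_background = 2000)
  expect_identical(w1$response, w2$response)
  expect_true(all(is.finite(w1$response)))
})

test_that("repetition averaging shrinks the noisy response spread", {
  m <- cached_model("tonic")
  thr <- pyrexc:::coincidence_thresholds(m, coincidence_preset())
  one_rep <- function(seed, n_rep) {
    noisy_updown(m, "up", isi_grid = 0, n_rep = n_rep, seed = seed,
                 thresholds = thr, n_background = 2000)$response
  }
  few <- vapply(1:6, one_rep, 1.0, n_rep = 2)
  many <- vapply(101:106, one_rep, 1.0, n_rep = 8)
  # sd of the mean should shrink roughly as 1/sqrt(n_rep); allow slack
  expect_lt(sd(many), sd(few))
})
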