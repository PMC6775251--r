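# Coding analysis: partition, thresholds, response tables, Hamming
# distances, diversity, input-output correlations.

test_that("the region partition is seven disjoint regions", {
  p <- region_partition()
  expect_equal(nrow(p), 7)
  apical <- p[p$kind == "apical", ]
  expect_equal(apical$lo, c(0, 200, 400, 600, 800, 1000))
  expect_equal(apical$hi[-6], apical$lo[-1])  # half-open, contiguous
  expect_equal(sum(p$kind == "basal"), 1)
})

test_that("input patterns enumerate all binary combinations", {
  m <- input_patterns(7)
  expect_equal(dim(m), c(128, 7))
  expect_equal(nrow(unique(m)), 128)
  # co-activation of any fixed pair occurs in 2^5 patterns
  expect_equal(sum(m[, 2] & m[, 5]), 32)
  expect_equal(output_alphabet_size(), 4 * 3^6)
})

test_that("discretization thresholds split Ca2+ peaks into three levels", {
  spec <- discretization_spec()
  expect_equal(findInterval(c(1e-4, 0.000115, 2e-4),
                            c(spec$ca_low, spec$ca_high)),
               c(0L, 1L, 2L))
  expect_error(discretization_spec(ca_low = 2e-4, ca_high = 1e-4), "ca_low")
})

test_that("region thresholds are positive and the silent pattern is null", {
  m <- cached_model("tonic")
  pops <- pyrexc:::region_populations(m, n_per_region = 1000, seed = 1)
  thr <- region_thresholds(m, populations = pops)
  expect_true(all(thr$g_th_nS > 0))
  out <- response_pattern(m, rep(FALSE, 7),
                          list(mode = "relative", fraction = 0.5,
                               thresholds = thr),
                          populations = pops)
  expect_equal(unname(out), rep(0L, 7))
})

test_that("response tables cover 128 patterns reproducibly", {
  m <- cached_model("tonic")
  pops <- pyrexc:::region_populations(m, n_per_region = 400, seed = 1)
  thr <- region_thresholds(m, n_per_region = 400, populations = pops)
  gs <- list(mode = "relative", fraction = 0.5, thresholds = thr)
  tab <- response_table(m, gs, populations = pops)
  expect_equal(nrow(tab$table), 128)
  expect_true(all(tab$table[, 1] <= 3))
  expect_true(all(tab$table[, -1] %in% 0:2))
  tab2 <- response_table(m, gs, populations = pops)
  expect_identical(tab$table, tab2$table)
  expect_equal(hamming_distance(tab, tab2), 0)
  # some input patterns spike and some do not (informative table)
  expect_gt(nrow(unique(tab$table)), 2)
})

test_that("hamming distance counts disagreements and is a metric", {
  a <- matrix(0L, 128, 7)
  b <- a; b[5, 3] <- 1L; b[100, 1] <- 2L; b[100, 7] <- 1L
  expect_equal(hamming_distance(a, b), 3)
  expect_equal(hamming_distance(b, a), 3)
  expect_equal(hamming_distance(a, a), 0)
  set.seed(42)
  rnd <- function() matrix(sample(0:2, 128 * 7, TRUE), 128, 7)
  for (k in 1:20) {
    x <- rnd(); y <- rnd(); z <- rnd()
    expect_equal(hamming_distance(x, y), hamming_distance(y, x))
    expect_lte(hamming_distance(x, z),
               hamming_distance(x, y) + hamming_distance(y, z))
    expect_equal(hamming_distance(x, y) == 0, identical(x, y))
  }
  expect_error(hamming_distance(a, a[, 1:3]), "shape")
})

test_that("diversity is 1 at zero drive and respects the counting bounds", {
  m <- cached_model("tonic")
  pops <- pyrexc:::region_populations(m, n_per_region = 400, seed = 1)
  dv <- output_diversity(m, g_values = c(0, 0.02),
                         bias_grid = c(-0.02, 0, 0.02),
                         populations = pops)
  expect_equal(dv$mean_diversity[1], 1)
  expect_true(all(dv$mean_diversity <= min(128, output_alphabet_size())))
  expect_gt(dv$mean_diversity[2], 1)
})

test_that("unique-pattern counting agrees with brute-force set construction", {
  set.seed(7)
  tab <- matrix(sample(0:2, 128 * 7, TRUE, prob = c(0.7, 0.2, 0.1)), 128, 7)
  brute <- length(unique(apply(tab, 1, paste, collapse = "/")))
  expect_equal(nrow(unique(tab)), brute)
})

test_that("io correlations match a direct Pearson formula", {
  masks <- input_patterns(7)
  # output identically equal to region-3 indicator
  res <- structure(list(table = cbind(n_spikes = as.integer(masks[, 3]),
                                      matrix(0L, 128, 6,
                                             dimnames = list(NULL,
                                                             paste0("ca", 1:6)))),
                        masks = masks), class = "coding_result")
  io <- io_correlations(res)
  expect_equal(io[3, 1], 1)
  expect_true(all(is.na(io[, 2:7])))  # constant outputs are NA, not zero

  set.seed(99)
  tab <- matrix(sample(0:3, 128 * 7, TRUE), 128, 7,
                dimnames = list(NULL, c("n_spikes", paste0("ca", 1:6))))
  res2 <- structure(list(table = tab, masks = masks), class = "coding_result")
  io2 <- io_correlations(res2)
  pearson <- function(x, y) {
    n <- length(x)
    (n * sum(x * y) - sum(x) * sum(y)) /
      sqrt((n * sum(x^2) - sum(x)^2) * (n * sum(y^2) - sum(y)^2))
  }
  for (i in 1:7) for (j in 1:7)
    expect_equal(io2[i, j], pearson(masks[, i] * 1, tab[, j]),
                 tolerance = 1e-10)
  expect_true(all(abs(io2) <= 1))
})
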