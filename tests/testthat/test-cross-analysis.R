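# Cross-phenotype effect tables and stratified correlations.

fake_effect_table <- function(n = 12, seed = 5) {
  set.seed(seed)
  cls <- rep(c("Ca-channel", "Na-channel"), each = n / 2)
  x <- rnorm(n)
  tab <- data.frame(
    variant_id = paste0("v", 1:n), gene = paste0("g", 1:n),
    gene_class = cls, epsilon = 0.5,
    fI_avg = x,
    window_integral_up = -2 * x + rnorm(n, sd = 0.01),
    max_prepulse_factor = 3 * x,
    error = NA_character_, stringsAsFactors = FALSE)
  class(tab) <- c("effect_table", class(tab))
  tab
}

test_that("exact linear relations give unit-magnitude coefficients", {
  tab <- fake_effect_table()
  rep <- effect_correlations(tab)
  r_fp <- rep$r[rep$phenotype_a == "fI_avg" &
                rep$phenotype_b == "max_prepulse_factor" &
                rep$stratum == "all"]
  expect_equal(r_fp, 1)
  r_fw <- rep$r[rep$phenotype_a == "fI_avg" &
                rep$phenotype_b == "window_integral_up" &
                rep$stratum == "all"]
  expect_lt(r_fw, -0.99)
})

test_that("strata partition the variants and small strata yield NA", {
  tab <- fake_effect_table()
  rep <- effect_correlations(tab)
  one <- rep[rep$phenotype_a == "fI_avg" &
             rep$phenotype_b == "max_prepulse_factor", ]
  expect_equal(one$n[one$stratum == "ca"] + one$n[one$stratum == "non_ca"],
               one$n[one$stratum == "all"])
  tiny <- fake_effect_table(n = 4)
  tiny <- tiny[tiny$gene_class == "Ca-channel", ][1:2, ]
  class(tiny) <- c("effect_table", class(tiny))
  rep2 <- effect_correlations(tiny)
  expect_true(all(is.na(rep2$r[rep2$stratum == "ca"])))
})

test_that("coefficients match the covariance formula on a random fixture", {
  set.seed(31)
  tab <- fake_effect_table()
  tab$window_integral_up <- rnorm(12)
  rep <- effect_correlations(tab)
  ca <- tab$gene_class == "Ca-channel"
  direct <- function(x, y) sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  got <- rep$r[rep$phenotype_a == "fI_avg" &
               rep$phenotype_b == "window_integral_up" & rep$stratum == "ca"]
  expect_equal(got, direct(tab$fI_avg[ca], tab$window_integral_up[ca]),
               tolerance = 1e-12)
})

test_that("epsilon filtering selects the requested scaling rows", {
  tab <- fake_effect_table()
  tab2 <- tab
  tab2$epsilon <- -0.5
  both <- rbind(tab, tab2)
  class(both) <- c("effect_table", class(both))
  rep_pos <- effect_correlations(both, use_epsilon = 0.5)
  expect_equal(max(rep_pos$n), 12)
  rep_all <- effect_correlations(both, use_epsilon = NULL)
  expect_equal(max(rep_all$n), 24)
})

test_that("the effect table carries a zero control row and epsilon pairs", {
  m <- cached_model("tonic")
  vars <- generate_ca_gate_variants(2, seed = 3)
  scaled <- list(scale_variant(vars[[1]], 1, 0.5),
                 scale_variant(vars[[1]], 1, -0.5),
                 scale_variant(vars[[2]], 1, 0.5),
                 scale_variant(vars[[2]], 1, -0.5))
  prot <- list(fI_spec = fast_fI_spec(m, n = 4, duration = 1500))
  tab <- phenotype_effect_table(m, scaled, phenotypes = "fI_avg",
                                protocols = prot, seed = 1)
  expect_equal(nrow(tab), 5)
  expect_equal(tab$fI_avg[1], 0)
  expect_setequal(tab$epsilon[-1], c(0.5, -0.5, 0.5, -0.5))
  tab2 <- phenotype_effect_table(m, scaled, phenotypes = "fI_avg",
                                 protocols = prot, seed = 1)
  expect_identical(tab$fI_avg, tab2$fI_avg)
})
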