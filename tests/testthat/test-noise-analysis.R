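# Delta-noise/delta-fitness residual analysis, optimum classification,
# correlation and permutation machinery, robustness grid.

make_panel <- function(n = 40, seed = 1, planted = NULL) {
  set.seed(seed)
  expr <- sort(runif(n, 0, 124))
  noise <- 60 + 120 * exp(-expr / 35) + rnorm(n, 0, 8)
  fitness <- 1 - 0.061 * pmax(0, 1 - expr / 100)^1.8 + rnorm(n, 0, 0.001)
  if (!is.null(planted)) noise[planted$i] <- noise[planted$i] + planted$dn
  data.frame(genotype_id = sprintf("g%02d", 1:n),
             median_expression_pct = expr, noise_pct = noise,
             fitness = fitness)
}

test_that("delta_metrics recovers planted residual offsets and applies the cap", {
  base <- make_panel(40, seed = 2)
  flat <- base
  flat$noise_pct <- 100 - 0.2 * flat$median_expression_pct  # exactly smooth
  dt0 <- delta_metrics(flat)
  expect_lt(max(abs(dt0$delta_noise)), 1e-6)
  # a +20% noise offset on one mid-panel genotype shows up in its residual
  pl <- flat
  pl$noise_pct[20] <- pl$noise_pct[20] + 20
  dt1 <- delta_metrics(pl)
  expect_gt(dt1$delta_noise[20], 14)
  # genotypes above the expression cap carry no residuals
  capped <- base
  capped$median_expression_pct[40] <- 130
  expect_false("g40" %in% delta_metrics(capped)$genotype_id)
  expect_error(delta_metrics(base[, -3]), "noise_pct")
})

test_that("optimum_split finds the analytic drop point of a plateau", {
  # plateau truth: fitness = 1 below a knee at known drop locations
  expr <- seq(0, 120, length.out = 80)
  fitness <- 1 - 0.061 * pmax(0, 1 - expr / 100)^1.8
  fit <- loess_fit(expr, fitness, span = 0.35)
  sp <- optimum_split(fit, analysis_config(fitness_drop = 0.005))
  analytic <- 100 * (1 - (0.005 / 0.061)^(1 / 1.8))
  expect_lt(abs(sp$threshold - analytic), 4)
  # drop of zero puts the threshold at the argmax
  sp0 <- optimum_split(fit, analysis_config(fitness_drop = 0))
  expect_equal(sp0$threshold, sp0$optimum)
  # monotone increasing curve: threshold sits on the low-expression side
  mono <- loess_fit(expr, expr / 120, span = 0.75)
  spm <- optimum_split(mono, analysis_config(fitness_drop = 0.05))
  expect_lt(spm$threshold, spm$optimum)
  # a flat curve never drops: everything classed close, with a warning
  flat <- loess_fit(expr, rep(1, 80) + 1e-9 * expr, span = 1)
  expect_warning(spf <- optimum_split(flat, analysis_config(fitness_drop = 0.01)),
                 "never drops")
  expect_lt(spf$threshold, min(expr))
})

test_that("pearson_test matches cor.test and handles collinearity", {
  set.seed(30)
  dx <- rnorm(25)
  dy <- 0.5 * dx + rnorm(25)
  mine <- pearson_test(dx, dy)
  ref <- cor.test(dx, dy)
  expect_equal(mine$r, unname(ref$estimate))
  expect_equal(mine$p, ref$p.value)
  expect_equal(mine$r_squared, mine$r^2)
  perfect <- pearson_test(c(1, 2, 3), c(2, 4, 6))
  expect_equal(perfect$r, 1)
  expect_equal(perfect$p, 0)
})

test_that("permutation test matches exhaustive enumeration on small sets", {
  # {1,2} vs {3,4}: enumeration gives exactly 1/3 for the median difference
  ex <- permutation_median_test(c(1, 2, 3, 4), c("a", "a", "b", "b"),
                                exact = TRUE)
  expect_equal(ex$p, 1 / 3)
  expect_equal(ex$p, enumerate_perm_p(c(1, 2, 3, 4), 2))
  # identical groups: observed delta 0, p = 1
  same <- permutation_median_test(rep(c(5, 6), 4), rep(c("a", "b"), each = 4),
                                  n_perm = 500, seed = 1)
  expect_equal(same$delta_obs, 0)
  expect_equal(same$p, 1)
  # Monte-Carlo converges to enumeration within 3 binomial SEs
  set.seed(31)
  vals <- c(2.1, 0.3, 1.7, 0.9, 2.8, 1.1, 0.2, 2.2)
  labs <- rep(c("a", "b"), each = 4)
  p_true <- enumerate_perm_p(vals, 4)
  mc <- permutation_median_test(vals, labs, n_perm = 20000L, seed = 5)
  se <- sqrt(p_true * (1 - p_true) / 20000)
  expect_lt(abs(mc$p - p_true), 3 * se)
  # disjoint supports: p bounded by the enumeration minimum
  far <- permutation_median_test(c(1:10, 101:110), rep(c("a", "b"), each = 10),
                                 n_perm = 20000L, seed = 6)
  expect_lte(far$p_upper, 1e-3)
})

test_that("permutation test supports mean and sd statistics", {
  set.seed(32)
  a <- rnorm(15, 0, 1)
  b <- rnorm(15, 0, 3)
  r_sd <- permutation_median_test(c(a, b), rep(c("a", "b"), each = 15),
                                  statistic = "sd", n_perm = 2000, seed = 2)
  expect_lt(r_sd$p, 0.05)
  r_mean <- permutation_median_test(c(a, a + 5), rep(c("a", "b"), each = 15),
                                    statistic = "mean", n_perm = 2000, seed = 3)
  expect_lte(r_mean$p_upper, 0.01)
})

test_that("classify_noise_groups applies the band boundaries", {
  expect_identical(classify_noise_groups(c(-1.5, 0.5, 1.01, -1, 1)),
                   c("low", "middle", "high", "middle", "middle"))
})

test_that("delta residuals are uncorrelated with median expression", {
  sp <- gen_study_panel(43, noise_effect = 1e-4, seed = 21, emit = character(0))
  dt <- delta_metrics(sp$panel)
  expect_gt(pearson_test(dt$median_expression_pct, dt$delta_noise)$p, 0.01)
  expect_gt(pearson_test(dt$median_expression_pct, dt$delta_fitness)$p, 0.01)
})

test_that("robustness grid spans 100 parameter combinations", {
  sp <- gen_study_panel(30, noise_effect = 3e-4, seed = 22, emit = character(0))
  g <- robustness_grid(sp$panel)
  expect_identical(nrow(g), 100L)
  # a strong planted effect keeps the far-class correlation positive
  # throughout the grid
  expect_true(all(g$r_far > 0, na.rm = TRUE))
})

test_that("null panels give centred correlations and calibrated p-values", {
  ps <- vapply(1:12, function(i) {
    sp <- gen_study_panel(43, noise_effect = 0, seed = 400 + i,
                          emit = character(0))
    an <- suppressWarnings(
      delta_metrics(sp$panel, analysis_config()))
    sel <- an$optimum_class == "far"
    pearson_test(an$delta_noise[sel], an$delta_fitness[sel])$p
  }, numeric(1))
  # roughly uniform: not all small, not all large
  expect_gt(mean(ps), 0.15)
  expect_gt(sum(ps < 0.5), 1)
})
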