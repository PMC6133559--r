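# Fitness estimation: doublet correction, generations bookkeeping, slope
# estimators and replicate aggregation.

test_that("doublet_correct solves the random-pairing equations exactly", {
  r <- doublet_correct(doublet_counts(1000, 1000, 0))
  expect_equal(c(r$NY, r$NG), c(1000, 1000))
  r <- doublet_correct(doublet_counts(1000, 1000, 20))
  expect_equal(c(r$DY, r$DG), c(10, 10))
  expect_equal(c(r$NY, r$NG), c(1030, 1030))
  r <- doublet_correct(doublet_counts(900, 400, 12))
  expect_equal(c(r$DY, r$DG), c(9, 4))
  expect_equal(c(r$NY, r$NG), c(921, 416))
  expect_equal(2 * sqrt(r$DY * r$DG), 12)
  expect_equal(r$DY / r$TY, r$DG / r$TG)
  expect_error(doublet_correct(doublet_counts(0, 400, 5)), "empty colour")
})

test_that("doublet_correct satisfies its invariants on random inputs", {
  set.seed(77)
  for (i in 1:200) {
    TY <- sample(1:100000, 1)
    TG <- sample(1:100000, 1)
    DYG <- sample(0:500, 1)
    r <- doublet_correct(doublet_counts(TY, TG, DYG))
    # pairing ratio and equal doublet proportions hold to 1e-9 relative
    if (DYG > 0) {
      expect_equal(2 * sqrt(r$DY * r$DG), DYG, tolerance = 1e-9)
      expect_equal(r$DY / TY, r$DG / TG, tolerance = 1e-9)
    }
    # conservation: cells = singlets + same-colour doublet cells + 2 per mixed
    expect_equal(r$NY + r$NG, TY + TG + r$DY + r$DG + 2 * DYG,
                 tolerance = 1e-9)
  }
})

test_that("classify_two_color separates the three populations", {
  tc <- gen_two_color_events(5000, 5000, doublet_frac = 0.02, seed = 6)
  dc <- classify_two_color(tc)
  frac <- dc$DYG / (dc$TY + dc$TG + dc$DYG)
  expect_lt(abs(frac - 0.02), 0.005)
  expect_gt(dc$TY, 4500)
  expect_gt(dc$TG, 4500)
  # mirrored channels swap labels consistently
  mir <- tc
  mir$fl1 <- tc$fl2
  mir$fl2 <- tc$fl1
  dm <- classify_two_color(mir)
  expect_identical(c(dm$TY, dm$TG, dm$DYG), c(dc$TG, dc$TY, dc$DYG))
  # pure samples collapse to one class with no mixed doublets
  pure <- classify_two_color(gen_two_color_events(4000, 0, 0, seed = 7))
  expect_identical(c(pure$TY, pure$TG, pure$DYG), c(4000L, 0L, 0L))
  expect_error(classify_two_color(event_table(1, 1, 1)), "both fluorescence")
})

test_that("generations_from_densities converts density/dilution logs", {
  g <- generations_from_densities(c(5e6, 5e6), 512)
  expect_equal(g$per_cycle, 9)
  expect_equal(g$cumulative, c(0, 9))
  # constant density, no real dilution factor > 1 allowed; near-1 factor
  expect_equal(generations_from_densities(c(1e6, 1e6 / 1.0001), 1.0001)$per_cycle,
               0, tolerance = 1e-9)
  d <- 5e6 * 2^c(0, 7.3, 14.6, 21.9) / 2^c(0, 7.3, 14.6, 21.9)  # constant
  g3 <- generations_from_densities(rep(5e6, 4), rep(2^7.3, 3))
  expect_equal(g3$cumulative, c(0, 7.3, 14.6, 21.9))
  expect_equal(plate_generations(rbind(c(7, 7, 7), c(8, 8, 8),
                                       c(7.5, 7.5, 7.5)))$per_cycle,
               c(7.5, 7.5, 7.5))
})

test_that("fitness_from_series recovers exact geometric enrichment", {
  s <- competition_series(c(0, 10), NY = c(100, 200), NG = c(100, 100))
  expect_equal(fitness_from_series(s)$w, exp(log(2) / 10))
  s <- competition_series(c(0, 7, 14, 21), NY = c(1, 1.5, 2.25, 3.375),
                          NG = rep(1, 4))
  f <- fitness_from_series(s)
  expect_equal(f$w, exp(log(1.5) / 7))
  expect_equal(f$se, 0, tolerance = 1e-10)
  # constant ratio gives w = 1
  s <- competition_series(c(0, 7, 14), NY = c(500, 500, 500),
                          NG = c(500, 500, 500))
  expect_equal(fitness_from_series(s)$w, 1)
  expect_error(fitness_from_series(
    competition_series(c(0, 7), NY = c(0, 10), NG = c(10, 10))), "zero count")
})

test_that("fitness_from_series is scale invariant and label exchange inverts w", {
  s1 <- competition_series(c(0, 7, 14), NY = c(100, 150, 210),
                           NG = c(100, 90, 85))
  s2 <- competition_series(c(0, 7, 14), NY = 17 * c(100, 150, 210),
                           NG = 17 * c(100, 90, 85))
  expect_equal(fitness_from_series(s1)$w, fitness_from_series(s2)$w)
  flip <- competition_series(c(0, 7, 14), NY = c(100, 90, 85),
                             NG = c(100, 150, 210))
  expect_equal(fitness_from_series(flip)$w, 1 / fitness_from_series(s1)$w)
})

test_that("relative_fitness aggregates replicates with MAD screening", {
  set.seed(8)
  w_ref <- 1 + rnorm(8, 0, 0.002)
  ident <- relative_fitness(w_ref, w_ref)
  expect_equal(ident$w_rel, 1, tolerance = 0.01)
  w <- 0.95 + rnorm(8, 0, 0.002)
  r <- relative_fitness(w, 1 + rnorm(8, 0, 0.002))
  expect_equal(r$w_rel, 0.95, tolerance = 0.005)
  expect_lt(r$p_value, 1e-6)
  # an outlier beyond 5 MAD (of the full replicate set) is excluded
  base <- c(1.000, 1.001, 0.999, 1.0005, 0.9995, 1.0002, 0.9998)
  r2 <- relative_fitness(c(base, 1.01), rep(1, 8))
  expect_identical(r2$n_excluded, 1L)
  expect_identical(r2$n_replicates, 7L)
  expect_equal(r2$w_rel, mean(base))
})

test_that("direct_fitness uses log-odds slopes and the peak-height rule", {
  expect_equal(direct_fitness(c(0.5, 0.5), c(0, 42))$w, 1)
  f <- direct_fitness(c(0.5, 0.6), c(0, 42))
  expect_equal(f$w, exp(log(0.6 / 0.4 / 1) / 42))
  expect_equal(f$w, exp(log(1.5) / 42), tolerance = 1e-12)
  ex <- direct_fitness(c(0.5, 0.6), c(0, 42), peak_heights = c(4.9, 4.9))
  expect_true(ex$excluded)
  ok <- direct_fitness(c(0.5, 0.6), c(0, 42), peak_heights = c(5.2, 5.0))
  expect_false(ok$excluded)
})

test_that("doubling_time inverts the log2 growth slope", {
  tt <- seq(0, 600, 60)
  expect_equal(doubling_time(1e5 * 2^(tt / 80), tt), 80)
  expect_error(doubling_time(rep(1e5, 5), 1:5 * 60), "non-positive")
  set.seed(12)
  noisy <- 1e5 * 2^(tt / 80) * exp(rnorm(length(tt), 0, 0.02))
  expect_equal(doubling_time(noisy, tt), 80, tolerance = 2 / 80)
})
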