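# Event gating, size normalisation, calibration, sample summaries, batch
# and autofluorescence corrections, MAD filtering, genotype aggregation.

test_that("filter_events drops artifacts and keeps homogeneous singlets", {
  ev <- gen_flow_events(1, 0.1, 10000, seed = 5, doublet_frac = 0)
  kept <- filter_events(ev)
  expect_gte(nrow(kept) / nrow(ev), 0.99)
  # zero-valued scatter removed before the log transform
  bad <- ev
  bad$fsc_a[1] <- 0
  expect_false(1 %in% which(filter_events(bad)$fsc_a == 0))
  expect_equal(nrow(filter_events(bad, quantile_bounds = c(0, 1),
                                  density_quantile = NULL)),
               nrow(ev) - 1L)
  # the identity configuration only strips non-positive values
  ident <- filter_events(ev, quantile_bounds = c(0, 1), density_quantile = 1)
  expect_identical(nrow(ident), nrow(ev))
})

test_that("filter_events removes a planted doublet population", {
  ev <- gen_flow_events(1, 0.1, 20000, seed = 5, doublet_frac = 0.03)
  kept <- filter_events(ev)
  # doublets are appended last by the generator
  n_doub <- floor(20000 * 0.03)
  doub_fsc <- tail(ev$fsc_a, n_doub)
  expect_lt(sum(kept$fsc_a %in% doub_fsc) / n_doub, 0.05)
  expect_error(filter_events(event_table(-1, -1, -1)), "no events")
})

test_that("size_normalize cancels pure size variation and is permutation invariant", {
  # cells on the centroid ray: zero rotation, output is exactly FL1/FSC
  s <- seq(0.6, 0.9, length.out = 100)
  ray <- event_table(fsc_a = 10^s, fsc_h = 10^(s - 0.08), fl1 = 10^(8 * s))
  expect_equal(size_normalize(ray), rep(8, 100), tolerance = 1e-9)
  # size-only variation (log FL1 = log FSC + const) collapses
  off <- event_table(fsc_a = 10^s, fsc_h = 1, fl1 = 10^(s + 0.5))
  expect_lt(var(size_normalize(off)), 1e-6 * var(log10(off$fl1)))
  # duplicated dataset gives identical output
  ev <- gen_flow_events(1, 0.15, 500, seed = 9, doublet_frac = 0)
  expect_identical(size_normalize(ev), size_normalize(ev))
  same <- event_table(rep(2, 10), rep(2, 10), rep(5, 10))
  expect_error(size_normalize(same), "degenerate")
})

test_that("size_normalize is invariant to rescaling up to the centroid-ray convention", {
  # points exactly on the centroid ray: rescaling that keeps them on a ray
  # through the origin leaves the output identical
  s <- seq(0.6, 0.9, length.out = 120)
  ray <- event_table(fsc_a = 10^s, fsc_h = 10^(s - 0.08), fl1 = 10^(8 * s))
  resc <- event_table(fsc_a = 3 * 10^s, fsc_h = 3 * 10^(s - 0.08),
                      fl1 = 3^8 * 10^(8 * s))
  expect_equal(size_normalize(resc), size_normalize(ray), tolerance = 1e-9)
  # a noisy cloud keeps its rotation/ratio structure (ordering and scale)
  # though the centroid ray itself moves slightly
  ev <- gen_flow_events(1, 0.12, 2000, seed = 10, doublet_frac = 0)
  base <- fluor_to_mrna(size_normalize(ev))
  resc2 <- ev
  resc2$fsc_a <- ev$fsc_a * 3
  resc2$fsc_h <- ev$fsc_h * 3
  resc2$fl1 <- ev$fl1 * 3^8
  shifted <- fluor_to_mrna(size_normalize(resc2))
  expect_gt(cor(base, shifted, method = "spearman"), 0.999)
  expect_lt(abs(median(shifted) - median(base)), 0.15)
})

test_that("fluor_to_mrna applies the log-log calibration", {
  cal <- mrna_calibration()
  expect_equal(cal$a, 10.469)
  expect_equal(cal$b, -9.586)
  expect_equal(fluor_to_mrna(10^(9.586 / 10.469), cal), 1, tolerance = 1e-9)
  expect_equal(fluor_to_mrna(10, cal), 10^0.883)
  expect_equal(fluor_to_mrna(c(2, 5), mrna_calibration(1, 0)), c(2, 5))
  # strictly monotone and exactly log-log linear
  x <- 10^seq(0.5, 1.2, length.out = 50)
  y <- fluor_to_mrna(x, cal)
  expect_true(all(diff(y) > 0))
  expect_equal(cor(log10(y), log10(x))^2, 1)
  expect_error(fluor_to_mrna(-1, cal))
})

test_that("summarize_sample computes consistent noise metrics", {
  x <- c(rep(1, 500), rep(0.8, 250), rep(1.2, 250))
  s <- summarize_sample(x, min_cells = 100)
  expect_equal(s$noise_strength, s$s^2 / s$m)
  expect_equal(s$cv, s$s / s$m)
  expect_equal(s$log_cv, log10(s$cv))
  expect_equal(s$noise_strength, s$cv^2 * s$m)
  const <- summarize_sample(rep(2, 1500))
  expect_equal(const$s, 0)
  expect_equal(const$noise_strength, 0)
  short <- summarize_sample(rnorm(500, 1, 0.1))
  expect_false(short$pass_n)
  expect_true(is.na(short$m))
})

test_that("correct_batch removes planted flow-run offsets", {
  set.seed(9)
  mk <- function(run, off) make_summary_rows(
    m = 10^(0.2 + off + rnorm(12, 0, 0.01)), s = 0.12, flow_run = run,
    row = rep(c("A", "B"), 6))
  controls <- rbind(mk("R1", 0), mk("R2", 0.1), mk("R3", -0.05))
  corrected <- correct_batch(controls, controls)
  run_means <- tapply(log10(corrected$m), corrected$flow_run, mean)
  before <- tapply(log10(controls$m), controls$flow_run, mean)
  expect_lt(var(run_means) * 10, var(before))
  # identical controls across runs: correction is the identity
  flat <- rbind(make_summary_rows(rep(1.5, 6), 0.15, "R1"),
                make_summary_rows(rep(1.5, 6), 0.15, "R2"))
  expect_equal(correct_batch(flat, flat)$m, flat$m, tolerance = 1e-12)
  # single run and row: identity
  solo <- make_summary_rows(c(1, 1.1, 0.9), 0.1)
  expect_identical(correct_batch(solo, solo)$m, solo$m)
  other <- make_summary_rows(1, 0.1, flow_run = "R9")
  expect_error(correct_batch(other, flat), "R9")
})

test_that("subtract_autofluorescence shifts summaries by the blank means", {
  s <- make_summary_rows(c(1.05, 0.06), c(0.12, 0.02))
  blank <- make_summary_rows(c(0.05, 0.05), c(0.01, 0.01))
  out <- subtract_autofluorescence(s, blank)
  expect_equal(out$m, c(1.00, 0.01))
  expect_equal(out$s, c(0.11, 0.01))
  expect_equal(out$noise_strength, out$s^2 / out$m)
  zero_blank <- make_summary_rows(0, 0)
  expect_equal(subtract_autofluorescence(s, zero_blank)$m, s$m)
})

test_that("mad_filter uses the raw MAD with the degenerate-zero rule", {
  expect_identical(mad_filter(c(1, 1, 1, 1, 100), 4),
                   c(TRUE, TRUE, TRUE, TRUE, FALSE))
  expect_true(all(mad_filter(rep(3, 6), 4)))
  expect_true(all(mad_filter(c(0.99, 1.00, 1.01, 1.02), 5)))
  expect_error(mad_filter(c(1, 2), 4))
})

test_that("aggregate_genotype reports percentages relative to the reference", {
  ref <- make_summary_rows(rep(c(1.0, 1.02, 0.98), 2), 0.1)
  ident <- aggregate_genotype(ref, ref)
  expect_equal(ident$median_expression_pct, 100)
  expect_true(ident$median_expression_ci_lo < 100 &&
                ident$median_expression_ci_hi > 100)
  half <- make_summary_rows(rep(mean(ref$m) / 2, 6), 0.05)
  expect_equal(aggregate_genotype(half, ref)$median_expression_pct, 50)
  # too few surviving replicates: no CI reported
  three <- make_summary_rows(c(1, 1.01, 0.99), 0.1)
  expect_true(is.na(aggregate_genotype(three, ref)$median_expression_ci_lo))
})

test_that("end-to-end expression recovery from synthetic events is within 3%", {
  ev <- gen_flow_events(1, 0.1, 10000, seed = 4)
  s <- expression_from_events(ev)
  true_median <- exp(log(1) - 0.5 * log(1 + 0.01))  # log-normal median
  expect_lt(abs(s$m - true_median) / true_median, 0.03)
  expect_lt(abs(s$noise_strength - 0.1^2 / true_median) / (0.1^2 / true_median),
            0.15)
  expect_lt(abs(s$s - 0.1) / 0.1, 0.05)
})
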