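# Ground-truth generators: reproducibility, noise-free limits, and
# round-trip recovery through the estimation pipeline.

test_that("gen_flow_events inverts exactly in the zero-noise case", {
  ev <- gen_flow_events(1, 0, 2000, seed = 3, doublet_frac = 0,
                        autofluorescence = 0)
  expr <- fluor_to_mrna(size_normalize(ev))
  expect_equal(expr, rep(1, 2000), tolerance = 1e-9)
  ev2 <- gen_flow_events(0.5, 0, 500, seed = 3, doublet_frac = 0,
                         autofluorescence = 0)
  expect_equal(median(fluor_to_mrna(size_normalize(ev2))), 0.5,
               tolerance = 1e-9)
  one <- gen_flow_events(1, 0.1, 1, seed = 1, doublet_frac = 0)
  expect_identical(nrow(one), 1L)
  expect_true(all(is.finite(c(one$fsc_a, one$fsc_h, one$fl1))))
  expect_error(gen_flow_events(-1, 0.1, 10))
  expect_error(gen_flow_events(1, -0.1, 10))
})

test_that("gen_flow_events median recovery at n = 10000 is within 2%", {
  ev <- gen_flow_events(1, 0.1, 10000, seed = 4)
  s <- expression_from_events(ev)
  expect_lt(abs(s$m - 1), 0.02)
})

test_that("generators are bit-reproducible for a fixed seed", {
  expect_identical(gen_flow_events(1, 0.2, 300, seed = 7),
                   gen_flow_events(1, 0.2, 300, seed = 7))
  expect_identical(gen_competition_series(1.03, seed = 5),
                   gen_competition_series(1.03, seed = 5))
  expect_identical(gen_pyrogram(0.3, seed = 2), gen_pyrogram(0.3, seed = 2))
  p1 <- gen_study_panel(12, seed = 3, emit = character(0))
  p2 <- gen_study_panel(12, seed = 3, emit = character(0))
  expect_identical(p1$panel, p2$panel)
})

test_that("gen_competition_series has the stated noise-free limits", {
  flat <- gen_competition_series(1, 4, 7, Inf, Inf, 0.37, seed = 1)
  expect_equal(flat$NY / (flat$NY + flat$NG), rep(0.37, 4))
  s <- gen_competition_series(exp(0.05), 4, 7, Inf, Inf, 0.5, seed = 1)
  slopes <- diff(log(s$NY / s$NG)) / diff(s$generations)
  expect_equal(slopes, rep(0.05, 3), tolerance = 1e-12)
  expect_error(gen_competition_series(1.02, start_freq = 0))
})

test_that("fitness estimator on generated series is unbiased (Monte-Carlo oracle)", {
  w_hat <- vapply(1:300, function(r) {
    fitness_from_series(gen_competition_series(
      1.02, 4, 7, 50000, 10000, 0.5, seed = derive_seed(99, r)))$w
  }, numeric(1))
  expect_lt(abs(mean(w_hat) - 1.02), 0.002)
})

test_that("gen_pyrogram encodes frequency with the A-peak bias", {
  p0 <- gen_pyrogram(0, bias = 1, noise_sd = 0, seed = 1)
  expect_equal(p0$h_g, 0)
  p1 <- gen_pyrogram(1, noise_sd = 0, seed = 1)
  expect_equal(p1$h_a, 0)
  # biased raw frequency is wrong; the 0.86 correction restores it
  p <- gen_pyrogram(0.5, bias = 1 / 0.86, noise_sd = 0, seed = 1)
  raw <- p$h_g / (p$h_g + p$h_a)
  expect_false(isTRUE(all.equal(raw, 0.5)))
  expect_equal(freq_from_peaks(p$h_g, p$h_a), 0.5)
})

test_that("gen_study_panel spans the design space and carries its invariants", {
  sp <- gen_study_panel(43, seed = 2, emit = c("series", "pyrograms"))
  expect_identical(nrow(sp$truth), 43L)
  expect_false(any(duplicated(sp$truth$genotype_id)))
  expect_true(all(sp$truth$mu_true >= 0 & sp$truth$mu_true <= 1.25))
  expect_true(all(sp$truth$sigma_true >= 0))
  expect_true(all(sp$truth$w_true > 0))
  expect_true(all(sp$truth$copies_true %in% 1:3))
  expect_identical(min(sp$truth$mu_true), 0)  # deletion genotype present
  expect_true(1 %in% sp$truth$mu_true)        # wild type present
  expect_length(sp$series, 43L)
  expect_gt(length(sp$pyrograms), 0L)
  expect_error(gen_study_panel(5))
})

test_that("study panel fitness recovery matches truth through the estimator", {
  sp <- gen_study_panel(12, seed = 6, emit = "series")
  for (i in c(1L, 5L, 12L)) {
    w_hat <- mean(vapply(sp$series[[i]], function(s)
      fitness_from_series(s)$w, numeric(1)))
    expect_lt(abs(w_hat - sp$truth$w_true[i]), 0.005)
  }
})

test_that("writers and readers round-trip the CSV/TSV formats", {
  td <- withr::local_tempdir()
  ev <- gen_flow_events(1, 0.1, 200, seed = 1)
  f <- file.path(td, "events.csv")
  write_event_csv(ev, f)
  back <- read_event_csv(f)
  expect_equal(back$fsc_a, ev$fsc_a)
  expect_equal(back$fl1, ev$fl1)
  suppressWarnings(expect_error(read_event_csv(tempfile()),
                                "not found|cannot open"))
  s <- gen_competition_series(1.02, seed = 1)
  fs <- file.path(td, "series.csv")
  write_series_csv(s, fs)
  expect_equal(read.csv(fs)$NY, s$NY)
  sp <- gen_study_panel(10, seed = 1, emit = character(0))
  ft <- file.path(td, "truth.tsv")
  write_truth_tsv(sp$truth, ft)
  expect_equal(read.delim(ft)$mu_true, sp$truth$mu_true)
})
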