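# Synthetic-data generators. Every input the pipeline consumes can be
# produced here with known ground truth: flow-cytometry event tables,
# serial-dilution competition count trajectories, pyrogram peak heights and
# whole study panels. Single-cell expression is drawn log-normally
# (positive support) with the requested arithmetic mean and SD; the
# empirical distribution family of the real data is not known, so this is a
# documented modelling assumption, not a measurement.

lnorm_pars <- function(mu, sigma) {
  # log-normal meanlog/sdlog matching an arithmetic mean and SD
  stopifnot(mu > 0, sigma >= 0)
  if (sigma == 0) return(c(meanlog = log(mu), sdlog = 0))
  s2 <- log(1 + (sigma / mu)^2)
  c(meanlog = log(mu) - s2 / 2, sdlog = sqrt(s2))
}

#' Generate synthetic flow-cytometry events for one sample
#'
#' Per-event forward scatter is log-normal; per-event fluorescence is the
#' true single-cell expression (log-normal around `mu` with SD `sigma`)
#' passed through the inverse of the log-log mRNA calibration and scaled by
#' cell size, plus additive autofluorescence. The size scaling places log10
#' fluorescence at `x * log10(FSC.A)` where `x` is the calibrated
#' fluorescence-per-size value, so the pipeline's PCA rotation and ratio
#' recover expression. A configurable fraction of events are doublets
#' formed by random pairing: their scatter areas and fluorescences add,
#' while the scatter height saturates near the larger cell's height, which
#' is what lets the density gate find them.
#'
#' @param mu Mean expression (relative units, wild type = 1), >= 0.
#' @param sigma Expression SD (relative units), >= 0.
#' @param n_events Number of events (>= 1).
#' @param seed Integer seed; the generator is bit-reproducible.
#' @param cal [mrna_calibration()] used for the inverse mapping.
#' @param doublet_frac Fraction of events that are doublets (default 0.02).
#' @param autofluorescence Additive fluorescence on the linear FL1 scale
#'   (default 50, small relative to expressed signal).
#' @param size_meanlog,size_sdlog Mean and SD of log10 FSC.A (defaults 0.75
#'   and 0.05).
#' @param sample_id,flow_run,row Batch labels for the output table.
#' @return An [event_table()].
#' @export
gen_flow_events <- function(mu, sigma, n_events, seed = 1L,
                            cal = mrna_calibration(), doublet_frac = 0.02,
                            autofluorescence = 50,
                            size_meanlog = 0.75, size_sdlog = 0.05,
                            sample_id = "S1", flow_run = "R1", row = "A") {
  stop_if_not_scalar(mu, "mu", nonneg = TRUE)
  stop_if_not_scalar(sigma, "sigma", nonneg = TRUE)
  stopifnot(n_events >= 1L, doublet_frac >= 0, doublet_frac < 1)
  set.seed(seed)
  n_doublet <- floor(n_events * doublet_frac)
  n_cells <- n_events + n_doublet  # doublets consume two cells
  e <- if (mu == 0) rep(0, n_cells) else if (sigma == 0) rep(mu, n_cells) else {
    p <- lnorm_pars(mu, sigma)
    rlnorm(n_cells, p["meanlog"], p["sdlog"])
  }
  s <- rnorm(n_cells, size_meanlog, size_sdlog)  # log10 FSC.A per cell
  x <- mrna_to_fluor(e, cal)                     # fluorescence-per-size
  fl1 <- 10^(x * s) + autofluorescence
  fl1[e == 0] <- autofluorescence
  fsc_a <- 10^s
  fsc_h <- fsc_a / 1.2 * 10^rnorm(n_cells, 0, 0.01)
  if (n_doublet > 0) {
    i <- seq_len(n_doublet)
    j <- n_events + i  # partner cells
    fsc_a_d <- fsc_a[i] + fsc_a[j]
    fsc_h_d <- pmax(fsc_h[i], fsc_h[j]) * 1.05
    fl1_d <- fl1[i] + fl1[j] - autofluorescence
    fsc_a <- c(fsc_a[seq_len(n_events)][-i], fsc_a_d)
    fsc_h <- c(fsc_h[seq_len(n_events)][-i], fsc_h_d)
    fl1 <- c(fl1[seq_len(n_events)][-i], fl1_d)
  } else {
    fsc_a <- fsc_a[seq_len(n_events)]
    fsc_h <- fsc_h[seq_len(n_events)]
    fl1 <- fl1[seq_len(n_events)]
  }
  event_table(fsc_a = fsc_a, fsc_h = fsc_h, fl1 = fl1,
              sample_id = sample_id, flow_run = flow_run, row = row)
}

#' Generate synthetic two-colour competition events
#'
#' Events for a YFP/GFP competition sample: YFP cells are bright in channel
#' 2, GFP cells in channel 1, and a fraction of events are mixed doublets
#' whose linear signals add. Used to exercise [classify_two_color()].
#'
#' @param n_y,n_g Numbers of YFP and GFP singlet events.
#' @param doublet_frac Fraction of total events that are mixed doublets.
#' @param seed Integer seed.
#' @param bright_meanlog,dim_meanlog,sdlog Log10 fluorescence of the bright
#'   and dim channel of a cell, and the per-channel SD.
#' @param size_sdlog SD of the common per-cell size factor (log10) that
#'   scales both channels; shared size variation is what makes one
#'   principal component a size axis and the other the colour contrast.
#' @return An [event_table()] with both `fl1` and `fl2` set.
#' @export
gen_two_color_events <- function(n_y, n_g, doublet_frac = 0.02, seed = 1L,
                                 bright_meanlog = 5, dim_meanlog = 3.5,
                                 sdlog = 0.12, size_sdlog = 0.3) {
  stopifnot(n_y >= 0, n_g >= 0, doublet_frac >= 0, doublet_frac < 1)
  set.seed(seed)
  n_d <- floor((n_y + n_g) * doublet_frac / (1 - doublet_frac))
  one_colour <- function(n, bright_is_fl1) {
    size <- rnorm(n, 0, size_sdlog)  # common log10 size factor
    b <- 10^(rnorm(n, bright_meanlog, sdlog) + size)
    d <- 10^(rnorm(n, dim_meanlog, sdlog) + size)
    fl <- if (bright_is_fl1) list(fl1 = b, fl2 = d) else
      list(fl1 = d, fl2 = b)
    fl$size <- 10^(0.75 + size * 0.125)
    fl
  }
  yfp <- one_colour(n_y + n_d, bright_is_fl1 = FALSE)
  gfp <- one_colour(n_g + n_d, bright_is_fl1 = TRUE)
  fl1 <- c(gfp$fl1[seq_len(n_g)], yfp$fl1[seq_len(n_y)])
  fl2 <- c(gfp$fl2[seq_len(n_g)], yfp$fl2[seq_len(n_y)])
  fsc <- c(gfp$size[seq_len(n_g)], yfp$size[seq_len(n_y)])
  if (n_d > 0) {
    iy <- n_y + seq_len(n_d)
    ig <- n_g + seq_len(n_d)
    fl1 <- c(fl1, yfp$fl1[iy] + gfp$fl1[ig])
    fl2 <- c(fl2, yfp$fl2[iy] + gfp$fl2[ig])
    fsc <- c(fsc, yfp$size[iy] + gfp$size[ig])
  }
  event_table(fsc_a = fsc, fsc_h = fsc / 1.2, fl1 = fl1, fl2 = fl2)
}

#' Simulate a serial-dilution competition count series
#'
#' The focal (YFP) genotype frequency follows deterministic exponential
#' enrichment -- the slope of `ln(f/(1-f))` is `ln(w)` per generation --
#' with binomial genetic drift applied at each bottleneck (dilution) and
#' binomial counting noise at each assessment. Assessments happen at
#' generations `0, g, 2g, ...`; the bottleneck precedes each growth phase.
#' Passing `Inf` for `n_counted` or `bottleneck` switches the corresponding
#' noise source off (the noise-free limit returns exact frequencies).
#'
#' @param w True competitive fitness per generation (> 0).
#' @param n_timepoints Number of assessments (>= 2).
#' @param gens_per_cycle Generations per growth cycle.
#' @param n_counted Cells scored per assessment (may be `Inf`).
#' @param bottleneck Cells transferred at each dilution (may be `Inf`).
#' @param start_freq Starting focal-genotype frequency in (0, 1).
#' @param seed Integer seed.
#' @return A [competition_series()] with `NY`, `NG` columns (counts, or
#'   exact frequencies in the noise-free limit).
#' @export
gen_competition_series <- function(w, n_timepoints = 4L, gens_per_cycle = 7,
                                   n_counted = 50000, bottleneck = 10000,
                                   start_freq = 0.5, seed = 1L) {
  stopifnot(w > 0, start_freq > 0, start_freq < 1, n_timepoints >= 2L,
            gens_per_cycle > 0)
  set.seed(seed)
  f <- start_freq
  gens <- (seq_len(n_timepoints) - 1L) * gens_per_cycle
  NY <- numeric(n_timepoints)
  NG <- numeric(n_timepoints)
  count <- function(f) {
    if (is.infinite(n_counted)) return(c(f, 1 - f))
    k <- rbinom(1L, n_counted, f)
    c(k, n_counted - k)
  }
  cnt <- count(f)
  NY[1L] <- cnt[1L]; NG[1L] <- cnt[2L]
  for (t in seq_len(n_timepoints - 1L)) {
    if (is.finite(bottleneck)) f <- rbinom(1L, bottleneck, f) / bottleneck
    if (f <= 0 || f >= 1)
      stop("genotype lost through drift; increase bottleneck", call. = FALSE)
    odds <- f / (1 - f) * w^gens_per_cycle
    f <- odds / (1 + odds)
    cnt <- count(f)
    NY[t + 1L] <- cnt[1L]; NG[t + 1L] <- cnt[2L]
  }
  competition_series(generations = gens, NY = NY, NG = NG)
}

#' Simulate pyrogram peak heights for a two-allele sample
#'
#' Two peak heights whose ratio reflects the true G-allele frequency
#' distorted by a multiplicative A-peak bias (the chemistry over-call the
#' standard 0.86 factor corrects), with log-normal multiplicative noise.
#'
#' @param freq True G-allele frequency in `[0, 1]`.
#' @param depth Mean total peak height (default 30).
#' @param bias Multiplicative factor applied to the A peak (default
#'   `1/0.86`, the over-call inverted by [freq_from_peaks()]).
#' @param noise_sd SD of multiplicative log-normal noise (default 0.05;
#'   0 gives exact heights).
#' @param seed Integer seed.
#' @return List of class `peak_heights` with `h_g`, `h_a` and base labels.
#' @export
gen_pyrogram <- function(freq, depth = 30, bias = 1 / 0.86, noise_sd = 0.05,
                         seed = 1L) {
  stopifnot(freq >= 0, freq <= 1, depth > 0, bias > 0, noise_sd >= 0)
  set.seed(seed)
  jitter <- function(h) if (noise_sd == 0) h else h * rlnorm(1L, 0, noise_sd)
  structure(list(h_g = jitter(depth * freq),
                 h_a = jitter(depth * (1 - freq) * bias),
                 allele1_base = "G", allele2_base = "A"),
            class = "peak_heights")
}

# Plateau-shaped truth linking mean expression (relative, wild type = 1) to
# competitive fitness: a steep cost of under-expression saturating to a
# plateau near the wild-type level and a mild over-expression cost.
# Calibrated so that a deletion (mu = 0) costs 6.1%, a 14.6% reduction in
# expression costs 0.19%, and a duplication-level 207% costs about 0.9%.
plateau_fitness <- function(mu) {
  below <- pmax(0, 1 - mu)
  above <- pmax(0, mu - 1)
  1 - 0.061 * below^1.8 - 0.00786 * above^2
}

# Mean-noise trend (percent of wild type) used by the study-panel
# generator; noise strength falls with increasing mean activity.
panel_noise_trend <- function(mu_pct) {
  60 + 120 * exp(-mu_pct / 35)
}

#' Generate a synthetic study panel with known ground truth
#'
#' Builds a panel of promoter genotypes spanning mean expression 0-125% of
#' wild type, with a smooth mean-noise trend plus independent noise
#' perturbations, and a true fitness given by a plateau function of mean
#' expression plus `noise_effect` times the noise perturbation applied only
#' below the optimum region. Emits the measured panel (replicate-averaged
#' expression, noise and fitness with realistic measurement error) plus
#' matched raw datasets: flow-cytometry events, competition count series
#' and pyrograms for multi-copy genotypes.
#'
#' @param n_genotypes Number of genotypes (>= 10, default 43).
#' @param noise_effect True fitness change per percentage point of noise
#'   perturbation, applied far from the expression optimum (default 1e-4;
#'   0 gives a null panel).
#' @param seed Integer seed; sub-seeds for each dataset are derived
#'   deterministically.
#' @param n_replicates Replicate populations per genotype (default 6).
#' @param emit Which raw datasets to generate: any of "events", "series",
#'   "pyrograms" (default `c("series", "pyrograms")`; events are the
#'   largest and are opt-in).
#' @param n_events Events per flow sample when events are emitted.
#' @param expr_meas_sd,noise_meas_sd,fitness_meas_sd Measurement SDs of the
#'   per-genotype mean expression (%), noise (%), and fitness; defaults
#'   1.5, 5 and 0.001 reflect replicate-averaged assay precision (the
#'   fitness assays resolve about 0.2% at 95% confidence).
#' @return List of class `study_panel` with `truth` (the ground-truth
#'   table), `panel` (measured genotype table with columns `genotype_id`,
#'   `median_expression_pct`, `noise_pct`, `fitness`), and the requested
#'   raw datasets.
#' @export
gen_study_panel <- function(n_genotypes = 43L, noise_effect = 1e-4,
                            seed = 1L, n_replicates = 6L,
                            emit = c("series", "pyrograms"),
                            n_events = 2000L,
                            expr_meas_sd = 1.5, noise_meas_sd = 5,
                            fitness_meas_sd = 0.001) {
  stopifnot(n_genotypes >= 10L)
  set.seed(derive_seed(seed, 0L))
  # deletion at 0, the rest spread over (0.02, 1.25) with the wild type at 1
  mu <- c(0, 1, sort(runif(n_genotypes - 2L, 0.02, 1.25)))
  mu_pct <- mu * 100
  perturb <- rnorm(n_genotypes, 0, 30)  # noise deviation from trend, in %
  noise_pct_true <- pmax(3, panel_noise_trend(mu_pct) + perturb)
  # fitness effect of extra noise fades out as the mean approaches optimum
  far_weight <- pmin(1, pmax(0, (0.85 - mu) / 0.10))
  w_true <- plateau_fitness(mu) + noise_effect * perturb * far_weight
  copies <- ifelse(mu > 1.02, 2L, 1L)
  truth <- data.frame(
    genotype_id = sprintf("g%02d", seq_len(n_genotypes)),
    mu_true = mu,
    sigma_true = sqrt(pmax(0, noise_pct_true / 100 * 0.0225 * mu)),
    w_true = w_true,
    copies_true = copies,
    noise_pct_true = noise_pct_true,
    stringsAsFactors = FALSE)
  class(truth) <- c("truth_panel", "data.frame")

  panel <- data.frame(
    genotype_id = truth$genotype_id,
    median_expression_pct = mu_pct + rnorm(n_genotypes, 0, expr_meas_sd),
    noise_pct = noise_pct_true + rnorm(n_genotypes, 0, noise_meas_sd),
    fitness = w_true + rnorm(n_genotypes, 0, fitness_meas_sd),
    n_replicates = n_replicates,
    stringsAsFactors = FALSE)

  out <- list(truth = truth, panel = panel, seed = seed,
              noise_effect = noise_effect)
  if ("events" %in% emit) {
    out$events <- lapply(seq_len(n_genotypes), function(i) {
      lapply(seq_len(n_replicates), function(r) {
        gen_flow_events(mu[i], truth$sigma_true[i], n_events,
                        seed = derive_seed(seed, i * 1000L + r),
                        sample_id = sprintf("%s_rep%d", truth$genotype_id[i], r))
      })
    })
    names(out$events) <- truth$genotype_id
  }
  if ("series" %in% emit) {
    out$series <- lapply(seq_len(n_genotypes), function(i) {
      lapply(seq_len(n_replicates), function(r) {
        gen_competition_series(w_true[i],
                               seed = derive_seed(seed, i * 2000L + r))
      })
    })
    names(out$series) <- truth$genotype_id
  }
  if ("pyrograms" %in% emit) {
    multi <- which(copies > 1L)
    out$pyrograms <- lapply(multi, function(i) {
      lapply(1:5, function(r) {
        gen_pyrogram(expected_copy_freq(copies[i], 1),
                     seed = derive_seed(seed, i * 3000L + r))
      })
    })
    names(out$pyrograms) <- truth$genotype_id[multi]
  }
  class(out) <- "study_panel"
  out
}

#' @export
print.study_panel <- function(x, ...) {
  cat(sprintf("Synthetic study panel: %d genotypes, noise effect %g, seed %d\n",
              nrow(x$truth), x$noise_effect, x$seed))
  invisible(x)
}

# ---- plain-text writers ----------------------------------------------------

#' Write an event table as CSV (columns FSC.A, FSC.H, FL1, FL2)
#' @param events An [event_table()]. @param path Output file.
#' @export
write_event_csv <- function(events, path) {
  d <- data.frame(FSC.A = events$fsc_a, FSC.H = events$fsc_h,
                  FL1 = events$fl1, FL2 = events$fl2, check.names = FALSE)
  write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' Read an event-table CSV
#'
#' @param path CSV with columns FSC.A, FSC.H, FL1 and optionally FL2 (the
#'   channel names can be remapped via `channels`).
#' @param channels Named character vector mapping the standard names to the
#'   file's column names.
#' @param ... Batch labels passed to [event_table()].
#' @export
read_event_csv <- function(path,
                           channels = c(fsc_a = "FSC.A", fsc_h = "FSC.H",
                                        fl1 = "FL1", fl2 = "FL2"), ...) {
  d <- read.csv(path, check.names = FALSE)
  need <- channels[c("fsc_a", "fsc_h", "fl1")]
  missing_ch <- setdiff(need, names(d))
  if (length(missing_ch) > 0L)
    stop(sprintf("event file %s lacks column(s): %s", path,
                 paste(missing_ch, collapse = ", ")), call. = FALSE)
  fl2 <- if (channels[["fl2"]] %in% names(d)) d[[channels[["fl2"]]]] else NA_real_
  event_table(fsc_a = d[[channels[["fsc_a"]]]],
              fsc_h = d[[channels[["fsc_h"]]]],
              fl1 = d[[channels[["fl1"]]]], fl2 = fl2, ...)
}

#' Write a competition series as CSV
#' @param series A [competition_series()]. @param path Output file.
#' @export
write_series_csv <- function(series, path) {
  write.csv(as.data.frame(series), path, row.names = FALSE)
  invisible(path)
}

#' Write a truth panel as TSV
#' @param truth A `truth_panel`. @param path Output file.
#' @export
write_truth_tsv <- function(truth, path) {
  write.table(as.data.frame(truth), path, sep = "\t", row.names = FALSE,
              quote = FALSE)
  invisible(path)
}
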