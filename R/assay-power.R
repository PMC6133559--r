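# Simulation-based power analysis for serial-dilution competition assays.
# Each simulated assay combines deterministic per-generation enrichment,
# binomial genetic drift at every bottleneck, and binomial counting noise
# at every assessment; the estimator is the OLS slope of the empirical
# log-odds on generations (the same estimator the fitness module uses).
# Repeating the simulation gives the standard deviation of the selection
# coefficient, from which the minimum detectable fitness difference for a
# replicated experiment follows by noncentral-t power inversion.

#' Power-analysis configuration for a competition assay design
#'
#' The bottleneck size is set by the design: cultures grow to `final_pop`
#' cells before each dilution and are diluted `2^gens_per_cycle`-fold, so
#' `bottleneck = final_pop / 2^gens_per_cycle` cells are transferred.
#'
#' @param n_replicates Biological replicates per strain (default 8).
#' @param start_freq Starting focal frequency (default 0.5).
#' @param fitness_diff True selection coefficient, per generation
#'   (default 0).
#' @param gens_per_cycle Generations per growth cycle (default 8).
#' @param n_cycles Number of dilution cycles; assessments happen at
#'   `n_cycles + 1` timepoints including the start (default 4).
#' @param n_counted Cells scored per assessment (default 50000).
#' @param final_pop Population size reached before each dilution
#'   (default 2.5e6: 5e6 cells/ml in a 0.5 ml well).
#' @param n_sims Simulated assays per configuration (default 5000).
#' @param alpha Significance level (default 0.05).
#' @param power_target Target power (default 0.95).
#' @param seed Integer seed.
#' @return List of class `power_config`.
#' @export
power_config <- function(n_replicates = 8L, start_freq = 0.5,
                         fitness_diff = 0, gens_per_cycle = 8,
                         n_cycles = 4L, n_counted = 50000,
                         final_pop = 2.5e6, n_sims = 5000L, alpha = 0.05,
                         power_target = 0.95, seed = 1L) {
  stopifnot(start_freq > 0, start_freq < 1, gens_per_cycle > 0,
            n_cycles >= 1L, n_counted > 0, final_pop > 1, n_sims >= 1L)
  structure(list(n_replicates = n_replicates, start_freq = start_freq,
                 fitness_diff = fitness_diff,
                 gens_per_cycle = gens_per_cycle, n_cycles = n_cycles,
                 n_counted = n_counted, final_pop = final_pop,
                 n_sims = n_sims, alpha = alpha,
                 power_target = power_target, seed = seed,
                 bottleneck = max(1, round(final_pop / 2^gens_per_cycle))),
            class = "power_config")
}

# Vectorised engine: simulates n trajectories at once and returns the
# estimated selection coefficients (slope of empirical log-odds on
# generations, continuity-corrected so finite counts never yield infinities).
simulate_assays <- function(cfg, n) {
  g <- cfg$gens_per_cycle
  gens <- (0:cfg$n_cycles) * g
  f <- rep(cfg$start_freq, n)
  B <- cfg$bottleneck
  count_freq <- function(f) {
    if (is.infinite(cfg$n_counted)) return(f)
    k <- rbinom(length(f), cfg$n_counted, f)
    (k + 0.5) / (cfg$n_counted + 1)  # empirical logit correction
  }
  obs <- matrix(NA_real_, n, cfg$n_cycles + 1L)
  obs[, 1L] <- count_freq(f)
  for (t in seq_len(cfg$n_cycles)) {
    if (is.finite(B)) {
      k <- rbinom(n, B, f)
      f <- pmin(pmax(k, 0.5), B - 0.5) / B  # keep lost lineages estimable
    }
    odds <- f / (1 - f) * exp(cfg$fitness_diff * g)
    f <- odds / (1 + odds)
    obs[, t + 1L] <- count_freq(f)
  }
  lo <- log(obs / (1 - obs))
  gc_ <- gens - mean(gens)
  drop(lo %*% gc_) / sum(gc_^2)
}

#' Simulate one competition assay and estimate its selection coefficient
#'
#' @param cfg A [power_config()].
#' @param seed Integer seed.
#' @return Estimated selection coefficient (slope of log-odds per
#'   generation).
#' @export
simulate_assay <- function(cfg = power_config(), seed = 1L) {
  set.seed(seed)
  simulate_assays(cfg, 1L)
}

#' Standard deviation of the selection-coefficient estimator
#'
#' Runs `cfg$n_sims` independent simulated assays and returns the SD of the
#' estimates, the precision currency of the assay design.
#'
#' @param cfg A [power_config()] (`n_sims >= 100`).
#' @param seed Integer seed (defaults to `cfg$seed`).
#' @return List with `sd`, `mean` and `n_sims`.
#' @export
sd_selection <- function(cfg = power_config(), seed = NULL) {
  stopifnot(cfg$n_sims >= 100L)
  set.seed(seed %||% cfg$seed)
  est <- simulate_assays(cfg, cfg$n_sims)
  list(sd = sd(est), mean = mean(est), n_sims = cfg$n_sims)
}

#' Minimum detectable fitness difference for a replicated design
#'
#' Inverts the two-sample t-test power function (noncentral t, via
#' [stats::power.t.test()]) for the given estimator SD and replicate count:
#' the smallest true difference in selection coefficient detectable at
#' significance `alpha` with the requested power.
#'
#' @param sd Standard deviation of the per-replicate estimator (>= 0).
#' @param n_replicates Replicates per group (>= 2).
#' @param alpha Significance level (default 0.05).
#' @param power_target Power (default 0.95).
#' @return Minimal detectable difference (same units as the selection
#'   coefficient); 0 when `sd` is 0.
#' @export
min_detectable <- function(sd, n_replicates, alpha = 0.05,
                           power_target = 0.95) {
  stopifnot(sd >= 0, n_replicates >= 2L)
  if (sd == 0) return(0)
  power.t.test(n = n_replicates, sd = sd, sig.level = alpha,
               power = power_target, type = "two.sample",
               alternative = "two.sided")$delta
}

#' Sweep assay precision over design parameters
#'
#' Computes the estimator SD and minimum detectable difference for each row
#' of a design grid (any subset of the [power_config()] fields may vary).
#'
#' @param grid Data frame whose columns override `power_config` fields.
#' @param base Base [power_config()].
#' @param seed Integer seed; each row gets a derived sub-seed.
#' @return `grid` with `sd_selection` and `min_detectable` columns added.
#' @export
power_sweep <- function(grid, base = power_config(), seed = 1L) {
  stopifnot(nrow(grid) >= 1L)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    cfg <- base
    for (nm in names(grid)) cfg[[nm]] <- grid[[nm]][i]
    cfg$bottleneck <- max(1, round(cfg$final_pop / 2^cfg$gens_per_cycle))
    s <- sd_selection(cfg, seed = derive_seed(seed, i))
    data.frame(sd_selection = s$sd,
               min_detectable = min_detectable(s$sd, cfg$n_replicates,
                                               cfg$alpha, cfg$power_target))
  })
  cbind(grid, do.call(rbind, res))
}
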