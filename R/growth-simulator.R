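# Individual-based stochastic model linking single-cell expression levels
# to population growth. Each cell's expression is drawn from a normal
# distribution (truncated at zero) at every division and mapped to a
# doubling time; clonal populations expand for a fixed wall-clock duration
# and competitive fitness compares final counts against a reference
# genotype with mean expression 1 and SD 0.1.

#' Doubling time as a function of single-cell expression
#'
#' Two selection regimes are supported: a linear function
#' `DT = -40*E + 160` (directional selection: more expression, faster
#' division) and an inverted-Gaussian function
#' `DT = -160*exp(-(E - 1)^2 / 0.18) + 240` (stabilising selection: fastest
#' division, 80 min, at the optimum E = 1). Doubling times are clamped
#' below at `floor_min` minutes so high-expression cells under the linear
#' function cannot divide in non-positive time.
#'
#' @param E Expression level (vectorised, finite).
#' @param kind "linear" or "gaussian".
#' @param floor_min Lower clamp in minutes (default 1).
#' @return Doubling times in minutes.
#' @export
dt_function <- function(E, kind = c("linear", "gaussian"), floor_min = 1) {
  kind <- match.arg(kind)
  stopifnot(all(is.finite(E)), floor_min > 0)
  dt <- switch(kind,
               linear = -40 * E + 160,
               gaussian = -160 * exp(-(E - 1)^2 / 0.18) + 240)
  pmax(dt, floor_min)
}

#' Expression SD implied by a noise value under a given metric
#'
#' Noise can be specified as a standard deviation (`sigma = nu`), a
#' coefficient of variation (`sigma = nu * mu`) or a Fano factor
#' (`sigma = sqrt(nu * mu)`).
#'
#' @param metric "sd", "cv" or "fano".
#' @param nu Noise value (>= 0).
#' @param mu Mean expression (>= 0).
#' @return Expression standard deviation.
#' @export
sigma_from_noise <- function(metric = c("sd", "cv", "fano"), nu, mu) {
  metric <- match.arg(metric)
  stopifnot(all(nu >= 0), all(mu >= 0))
  switch(metric, sd = nu + 0 * mu, cv = nu * mu, fano = sqrt(nu * mu))
}

#' Simulation genotype
#'
#' @param mu_E Mean expression in `[0, 2]`.
#' @param nu_E Noise value in `[0, 3]` under `noise_metric`.
#' @param noise_metric "sd", "cv" or "fano".
#' @param dt_kind "linear" or "gaussian".
#' @return List of class `sim_genotype` (with the implied `sigma_E`).
#' @export
sim_genotype <- function(mu_E, nu_E, noise_metric = "sd",
                         dt_kind = c("linear", "gaussian")) {
  stopifnot(mu_E >= 0, mu_E <= 2, nu_E >= 0, nu_E <= 3)
  structure(list(mu_E = mu_E, nu_E = nu_E, noise_metric = noise_metric,
                 dt_kind = match.arg(dt_kind),
                 sigma_E = sigma_from_noise(noise_metric, nu_E, mu_E)),
            class = "sim_genotype")
}

#' Simulation configuration
#'
#' @param T Experiment duration in minutes (default 1000).
#' @param seed_cells Founder count (default 1000).
#' @param replicates Stochastic replicates (default 100).
#' @param reference Reference [sim_genotype()] (default mean 1, SD 0.1,
#'   same DT function as the focal genotype unless overridden).
#' @param dt_floor Doubling-time floor in minutes (default 1).
#' @param pop_cap Hard population cap; exceeding it is an error suggesting
#'   a shorter duration (default 5e7).
#' @param paired Share replicate seeds between focal and reference runs
#'   (default TRUE; reduces between-replicate variance of fitness).
#' @return List of class `sim_config`.
#' @export
sim_config <- function(T = 1000, seed_cells = 1000L, replicates = 100L,
                       reference = NULL, dt_floor = 1, pop_cap = 5e7,
                       paired = TRUE) {
  stopifnot(T > 0, seed_cells >= 1L, replicates >= 1L, pop_cap > seed_cells)
  structure(list(T = T, seed_cells = seed_cells, replicates = replicates,
                 reference = reference, dt_floor = dt_floor,
                 pop_cap = pop_cap, paired = paired),
            class = "sim_config")
}

# expression draws truncated at zero by redrawing
draw_expression <- function(n, mu, sigma) {
  if (sigma == 0) return(rep(mu, n))
  e <- rnorm(n, mu, sigma)
  while (any(bad <- e < 0)) e[bad] <- rnorm(sum(bad), mu, sigma)
  e
}

# Grow a cohort of cells until no scheduled division fits inside T.
# `tnext` is each cell's absolute time of next division.
grow_until <- function(E, tnext, T, g, cfg) {
  repeat {
    div <- tnext <= T
    if (!any(div)) break
    n_div <- sum(div)
    E_new <- draw_expression(2L * n_div, g$mu_E, g$sigma_E)
    dt_new <- dt_function(E_new, g$dt_kind, cfg$dt_floor)
    t_parent <- rep(tnext[div], 2L)
    E <- c(E[!div], E_new)
    tnext <- c(tnext[!div], t_parent + dt_new)
    if (length(E) > cfg$pop_cap)
      stop("population cap exceeded; shorten the experiment duration T",
           call. = FALSE)
  }
  list(E = E, tnext = tnext)
}

#' Simulate the growth of one clonal population
#'
#' A seed experiment desynchronises the population: `seed_cells` cells are
#' drawn from the expression distribution, their first doubling time is
#' scaled by a uniform random value in (0, 1) to randomise the time to
#' first division, and the population grows for the full duration. Founders
#' for the main run are then drawn at random from the end of the seed
#' experiment, carrying their expression state and residual time to next
#' division, and the main run grows for the full duration again: whenever a
#' cell's doubling time fits into its remaining time it divides, and mother
#' and daughter both redraw expression (truncated normal, `E >= 0`) and
#' hence doubling time. The final cell count is returned.
#'
#' @param genotype A [sim_genotype()].
#' @param cfg A [sim_config()].
#' @param seed Integer seed.
#' @return Final cell count `N_i` (integer, >= `seed_cells`).
#' @export
simulate_population <- function(genotype, cfg = sim_config(), seed = 1L) {
  set.seed(seed)
  n0 <- cfg$seed_cells
  E0 <- draw_expression(n0, genotype$mu_E, genotype$sigma_E)
  dt0 <- dt_function(E0, genotype$dt_kind, cfg$dt_floor)
  seed_run <- grow_until(E0, runif(n0) * dt0, cfg$T, genotype, cfg)
  pick <- sample.int(length(seed_run$E), n0)
  main <- grow_until(seed_run$E[pick], seed_run$tnext[pick] - cfg$T,
                     cfg$T, genotype, cfg)
  length(main$E)
}

#' Competitive fitness from final population sizes
#'
#' `fitness = exp(ln(N_i / N_ref) / T)`: the per-minute growth-rate
#' advantage of the focal genotype over the reference, exponentiated.
#' Values are extremely close to 1 because the exponent is per minute; the
#' convenience helper [fitness_per_generation()] rescales to the
#' reference's 80-minute doubling time.
#'
#' @param N_i,N_ref Final cell counts (> 0).
#' @param T Experiment duration in minutes (> 0).
#' @return Competitive fitness (dimensionless).
#' @export
competitive_fitness_sim <- function(N_i, N_ref, T) {
  stopifnot(all(N_i > 0), all(N_ref > 0), T > 0)
  exp(log(N_i / N_ref) / T)
}

#' Per-generation rescaling of simulated fitness
#' @param fitness Output of [competitive_fitness_sim()].
#' @param gen_minutes Minutes per reference generation (default 80).
#' @return Fitness per reference generation.
#' @export
fitness_per_generation <- function(fitness, gen_minutes = 80) {
  fitness^gen_minutes
}

#' Sweep simulated fitness over a grid of genotypes
#'
#' Runs paired focal/reference simulations for every genotype of a grid and
#' summarises mean fitness with Student-t 95% confidence intervals across
#' replicates. With `cfg$paired = TRUE` (default) the reference replicate
#' `r` shares its seed stream index with focal replicate `r`, so
#' between-replicate variation partially cancels in the comparison.
#'
#' @param grid Data frame with columns `mu_E`, `nu_E` and optionally
#'   `noise_metric`, `dt_kind` per row (or pass defaults here).
#' @param cfg A [sim_config()].
#' @param noise_metric,dt_kind Defaults used when the grid lacks those
#'   columns.
#' @param seed Integer seed; replicate sub-seeds are derived from it.
#' @return Data frame of class `sim_result`: per genotype the mean
#'   `fitness`, `ci_lo`, `ci_hi`, `fitness_per_gen` and mean final `N_i`,
#'   with per-replicate values in `attr(, "replicates")`.
#' @export
sweep_fitness <- function(grid, cfg = sim_config(), noise_metric = "sd",
                          dt_kind = "gaussian", seed = 1L) {
  stopifnot(nrow(grid) >= 1L)
  reps <- cfg$replicates
  # one reference simulation set, shared across the grid
  ref_g <- cfg$reference %||% sim_genotype(1, 0.1, "sd", dt_kind)
  N_ref <- vapply(seq_len(reps), function(r)
    simulate_population(ref_g, cfg, derive_seed(seed, 500000L + r)),
    numeric(1))
  rep_values <- vector("list", nrow(grid))
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    g <- sim_genotype(grid$mu_E[i], grid$nu_E[i],
                      (grid$noise_metric %||% rep(noise_metric, nrow(grid)))[i],
                      (grid$dt_kind %||% rep(dt_kind, nrow(grid)))[i])
    N_i <- vapply(seq_len(reps), function(r) {
      off <- if (cfg$paired) 500000L + r else i * 1000000L + r
      simulate_population(g, cfg, derive_seed(seed, off))
    }, numeric(1))
    # paired seeds: focal replicate r is compared to reference replicate r
    fit <- competitive_fitness_sim(N_i, N_ref, cfg$T)
    rep_values[[i]] <<- fit
    ci <- t_ci(fit)
    data.frame(mu_E = g$mu_E, nu_E = g$nu_E, sigma_E = g$sigma_E,
               noise_metric = g$noise_metric, dt_kind = g$dt_kind,
               fitness = ci[["mean"]], ci_lo = ci[["lower"]],
               ci_hi = ci[["upper"]],
               fitness_per_gen = fitness_per_generation(ci[["mean"]]),
               mean_N = mean(N_i), replicates = reps,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "replicates") <- rep_values
  class(out) <- c("sim_result", "data.frame")
  out
}
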