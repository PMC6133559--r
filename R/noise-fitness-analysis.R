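# Residual-based analysis of the relationship between expression noise and
# fitness: local-regression residuals of noise and fitness on median
# expression (delta-noise and delta-fitness), classification of genotypes
# by distance to the expression optimum, correlation and permutation tests,
# and a robustness grid over the tunable smoothing/threshold parameters.

#' Analysis configuration
#'
#' Bundles the tunable parameters of the noise-fitness analysis with their
#' standard defaults: LOESS span 2/3 for both regressions, a 0.005 fitness
#' drop defining the optimum threshold, a 125% expression cap above which
#' genotypes are excluded, a +/-1% delta-noise band separating low/high
#' noise groups, and 1e5 permutations.
#'
#' @param span_noise,span_fitness LOESS spans (default 2/3).
#' @param fitness_drop Fitness reduction from the maximum defining the
#'   close/far expression threshold (default 0.005).
#' @param expression_cap Median-expression exclusion bound, percent
#'   (default 125).
#' @param noise_cut Absolute delta-noise boundary for the low/high groups
#'   (default 1).
#' @param n_permutations Number of random shuffles (default 1e5).
#' @param noise_metric One of "strength", "sd", "cv", "logcv".
#' @param seed Integer seed for permutation draws.
#' @return List of class `analysis_config`.
#' @export
analysis_config <- function(span_noise = 2 / 3, span_fitness = 2 / 3,
                            fitness_drop = 0.005, expression_cap = 125,
                            noise_cut = 1, n_permutations = 100000L,
                            noise_metric = c("strength", "sd", "cv", "logcv"),
                            seed = 1L) {
  noise_metric <- match.arg(noise_metric)
  stopifnot(span_noise > 0, span_fitness > 0, fitness_drop >= 0,
            expression_cap > 0, n_permutations >= 1L)
  structure(list(span_noise = span_noise, span_fitness = span_fitness,
                 fitness_drop = fitness_drop, expression_cap = expression_cap,
                 noise_cut = noise_cut, n_permutations = n_permutations,
                 noise_metric = noise_metric, seed = seed),
            class = "analysis_config")
}

#' Delta-noise and delta-fitness residuals for a genotype panel
#'
#' Excludes genotypes above the expression cap, then computes per genotype
#' the residual of a LOESS regression of noise on median expression
#' (delta-noise: noise variation independent of the mean) and of fitness on
#' median expression (delta-fitness), classifies each genotype as close to
#' or far from the expression optimum (see [optimum_split()]) and into
#' low/middle/high noise groups (see [classify_noise_groups()]).
#'
#' @param panel Data frame with columns `genotype_id`,
#'   `median_expression_pct`, `noise_pct` and `fitness`.
#' @param cfg An [analysis_config()].
#' @return Data frame of class `delta_table` with `delta_noise`,
#'   `delta_fitness`, `optimum_class` ("far"/"close") and `noise_class`
#'   ("low"/"middle"/"high"), plus attributes `threshold` (expression at
#'   the optimum boundary) and `fits`.
#' @export
delta_metrics <- function(panel, cfg = analysis_config()) {
  need <- c("genotype_id", "median_expression_pct", "noise_pct", "fitness")
  miss <- setdiff(need, names(panel))
  if (length(miss) > 0L)
    stop(sprintf("panel lacks column(s): %s", paste(miss, collapse = ", ")),
         call. = FALSE)
  keep <- panel$median_expression_pct <= cfg$expression_cap
  d <- panel[keep, , drop = FALSE]
  fit_noise <- loess_fit(d$median_expression_pct, d$noise_pct,
                         span = cfg$span_noise)
  fit_fitness <- loess_fit(d$median_expression_pct, d$fitness,
                           span = cfg$span_fitness)
  split <- optimum_split(fit_fitness, cfg)
  out <- data.frame(genotype_id = d$genotype_id,
                    median_expression_pct = d$median_expression_pct,
                    delta_noise = fit_noise$residuals,
                    delta_fitness = fit_fitness$residuals,
                    stringsAsFactors = FALSE)
  out$optimum_class <- ifelse(d$median_expression_pct < split$threshold,
                              "far", "close")
  out$noise_class <- classify_noise_groups(out$delta_noise, cfg$noise_cut)
  attr(out, "threshold") <- split$threshold
  attr(out, "fits") <- list(noise = fit_noise, fitness = fit_fitness)
  class(out) <- c("delta_table", "data.frame")
  out
}

#' Expression threshold separating genotypes close to and far from optimum
#'
#' Evaluates the fitness LOESS on a dense grid (2001 points over the
#' observed expression range), locates the maximal predicted fitness, and
#' finds on the low-expression side the point where the prediction crosses
#' `max - fitness_drop` (linear interpolation between grid points).
#' Genotypes with median expression below the threshold are "far" from the
#' optimum, the rest "close". If the prediction never drops by
#' `fitness_drop` below its maximum on the low side, every genotype is
#' classed close, with a warning.
#'
#' @param fitness_fit A [loess_fit()] of fitness on median expression.
#' @param cfg An [analysis_config()] (uses `fitness_drop`).
#' @param n_grid Grid resolution (default 2001).
#' @return List with `threshold`, `optimum` (expression at maximal
#'   predicted fitness) and `max_fitness`.
#' @export
optimum_split <- function(fitness_fit, cfg = analysis_config(),
                          n_grid = 2001L) {
  grid <- seq(min(fitness_fit$x), max(fitness_fit$x), length.out = n_grid)
  pred <- fitness_fit$predict(grid)
  i_max <- which.max(pred)
  target <- pred[i_max] - cfg$fitness_drop
  below <- which(grid <= grid[i_max] & pred < target)
  if (length(below) == 0L) {
    if (cfg$fitness_drop > 0)
      warning("predicted fitness never drops by fitness_drop below the optimum; all genotypes classed close")
    threshold <- grid[1L] - .Machine$double.eps
    if (cfg$fitness_drop == 0) threshold <- grid[i_max]
  } else {
    i <- max(below)  # last grid point below the target on the low side
    if (i < n_grid && pred[i + 1L] > pred[i]) {
      threshold <- grid[i] + (target - pred[i]) /
        (pred[i + 1L] - pred[i]) * (grid[i + 1L] - grid[i])
    } else {
      threshold <- grid[i]
    }
  }
  list(threshold = threshold, optimum = grid[i_max], max_fitness = pred[i_max])
}

#' Pearson correlation with a t-distribution test
#'
#' Pearson's r between two residual vectors, with a two-sided p-value from
#' the t distribution on n - 2 degrees of freedom and the coefficient of
#' determination. Perfectly collinear inputs give |r| = 1 and p = 0.
#'
#' @param dx,dy Numeric vectors (>= 3 pairs).
#' @return List with `r`, `p`, `r_squared`, `n`.
#' @export
pearson_test <- function(dx, dy) {
  stopifnot(length(dx) == length(dy), length(dx) >= 3L)
  n <- length(dx)
  r <- cor(dx, dy)
  p <- if (abs(r) >= 1) 0 else {
    tval <- r * sqrt((n - 2) / (1 - r^2))
    2 * pt(-abs(tval), df = n - 2)
  }
  list(r = r, p = p, r_squared = r^2, n = n)
}

group_stat <- function(statistic) {
  switch(statistic, median = median, mean = mean, sd = sd,
         stop("unknown statistic", call. = FALSE))
}

#' Permutation test for a two-group difference in a statistic
#'
#' Shuffles the observed values between the two groups and reports the
#' proportion of shuffles whose absolute difference in the group statistic
#' is at least the observed absolute difference (the identity assignment
#' counts, making the p-value a valid permutation p; on small instances the
#' Monte-Carlo value converges to the exhaustive-enumeration value, which
#' `exact = TRUE` computes directly). The statistic is the median by
#' default, switchable to the mean or SD for doubling-time comparisons.
#'
#' @param values Numeric observations from both groups.
#' @param group_labels Two-level grouping of `values`.
#' @param statistic "median", "mean" or "sd".
#' @param n_perm Number of random shuffles (default 1e5).
#' @param seed Integer seed.
#' @param exact Enumerate all label assignments instead of sampling
#'   (feasible for small groups; overrides `n_perm`).
#' @return List with `p`, `delta_obs`, `n_exceed`, `n_perm`, `exact`. When
#'   no random shuffle reaches the observed difference the Monte-Carlo `p`
#'   is 0 and `p_upper = 1/n_perm` bounds it.
#' @export
permutation_median_test <- function(values, group_labels,
                                    statistic = c("median", "mean", "sd"),
                                    n_perm = 100000L, seed = 1L,
                                    exact = FALSE) {
  statistic <- match.arg(statistic)
  f <- group_stat(statistic)
  g <- factor(group_labels)
  stopifnot(nlevels(g) == 2L)
  n1 <- sum(g == levels(g)[1L])
  n <- length(values)
  stopifnot(n1 >= 1L, n - n1 >= 1L)
  delta <- function(idx1) f(values[idx1]) - f(values[-idx1])
  obs <- abs(delta(which(g == levels(g)[1L])))
  if (exact) {
    combos <- utils::combn(n, n1)
    diffs <- abs(apply(combos, 2L, delta))
    n_exceed <- sum(diffs >= obs - 1e-12)
    n_perm <- ncol(combos)
  } else {
    set.seed(seed)
    n_exceed <- 0L
    for (b in seq_len(n_perm)) {
      if (abs(delta(sample.int(n, n1))) >= obs - 1e-12) n_exceed <- n_exceed + 1L
    }
  }
  p <- n_exceed / n_perm
  list(p = p, delta_obs = obs, n_exceed = n_exceed, n_perm = n_perm,
       exact = exact, p_upper = if (n_exceed == 0L) 1 / n_perm else p)
}

#' Permutation test for a correlation
#'
#' Shuffles the pairing between `dx` and `dy` and reports the proportion of
#' shuffles whose absolute Pearson correlation is at least the observed
#' absolute correlation.
#'
#' @param dx,dy Paired numeric vectors.
#' @param n_perm Number of shuffles (default 1e5).
#' @param seed Integer seed.
#' @return List with `r`, `p`, `n_perm`.
#' @export
permutation_cor_test <- function(dx, dy, n_perm = 100000L, seed = 1L) {
  stopifnot(length(dx) == length(dy), length(dx) >= 3L)
  set.seed(seed)
  r_obs <- cor(dx, dy)
  # vectorised: correlations of dy against permuted dx columns
  xs <- scale(dx)[, 1L]
  ys <- scale(dy)[, 1L]
  n <- length(dx)
  r_perm <- vapply(seq_len(n_perm), function(b)
    sum(xs[sample.int(n)] * ys) / (n - 1), numeric(1))
  n_exceed <- sum(abs(r_perm) >= abs(r_obs) - 1e-12)
  list(r = r_obs, p = n_exceed / n_perm, n_perm = n_perm,
       p_upper = if (n_exceed == 0L) 1 / n_perm else n_exceed / n_perm)
}

#' Classify genotypes into low/middle/high noise groups
#'
#' Genotypes with delta-noise below `-cut` are "low", above `+cut` "high";
#' the middle band is excluded from group comparisons.
#'
#' @param delta_noise Numeric vector of delta-noise values (percent).
#' @param cut Band half-width (default 1).
#' @return Character vector of labels.
#' @export
classify_noise_groups <- function(delta_noise, cut = 1) {
  ifelse(delta_noise < -cut, "low",
         ifelse(delta_noise > cut, "high", "middle"))
}

#' Robustness grid over smoothing and threshold parameters
#'
#' Recomputes the delta-noise/delta-fitness correlations per optimum class
#' for every combination of noise span (5 values), fitness span (5 values)
#' and fitness drop (4 values): 100 rows.
#'
#' @param panel Genotype panel as in [delta_metrics()].
#' @param cfg Base [analysis_config()].
#' @param spans Candidate spans (default `c(2/6, 3/6, 4/6, 5/6, 1)`).
#' @param drops Candidate fitness drops
#'   (default `c(0.0025, 0.005, 0.0075, 0.01)`).
#' @return Data frame with one row per combination: correlations, t-based
#'   p-values and group sizes for the far and close classes.
#' @export
robustness_grid <- function(panel, cfg = analysis_config(),
                            spans = c(2, 3, 4, 5, 6) / 6,
                            drops = c(0.0025, 0.005, 0.0075, 0.01)) {
  grid <- expand.grid(span_noise = spans, span_fitness = spans,
                      fitness_drop = drops, KEEP.OUT.ATTRS = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    cfg_i <- cfg
    cfg_i$span_noise <- grid$span_noise[i]
    cfg_i$span_fitness <- grid$span_fitness[i]
    cfg_i$fitness_drop <- grid$fitness_drop[i]
    dt <- suppressWarnings(delta_metrics(panel, cfg_i))
    one_class <- function(cls) {
      sel <- dt$optimum_class == cls
      if (sum(sel) >= 3L) {
        pt <- pearson_test(dt$delta_noise[sel], dt$delta_fitness[sel])
        c(r = pt$r, p = pt$p, n = pt$n)
      } else c(r = NA_real_, p = NA_real_, n = sum(sel))
    }
    far <- one_class("far")
    close <- one_class("close")
    data.frame(r_far = far[["r"]], p_far = far[["p"]], n_far = far[["n"]],
               r_close = close[["r"]], p_close = close[["p"]],
               n_close = close[["n"]])
  })
  cbind(grid, do.call(rbind, res))
}

#' Full noise-fitness analysis of a genotype panel
#'
#' Composition used by the pipeline: delta metrics, per-class correlations
#' with both t-based and permutation p-values, and the low-vs-high noise
#' group permutation test on delta-fitness.
#'
#' @param panel Genotype panel (see [delta_metrics()]).
#' @param cfg An [analysis_config()].
#' @return List of class `noise_fitness_analysis` with the `delta_table`,
#'   `correlations` (per optimum class) and `group_tests`.
#' @export
analyze_noise_fitness <- function(panel, cfg = analysis_config()) {
  dt <- delta_metrics(panel, cfg)
  correlations <- lapply(c(far = "far", close = "close"), function(cls) {
    sel <- dt$optimum_class == cls
    if (sum(sel) < 3L) return(NULL)
    ct <- pearson_test(dt$delta_noise[sel], dt$delta_fitness[sel])
    perm <- permutation_cor_test(dt$delta_noise[sel], dt$delta_fitness[sel],
                                 n_perm = cfg$n_permutations,
                                 seed = derive_seed(cfg$seed, 11L))
    c(ct, list(p_perm = perm$p))
  })
  group_tests <- lapply(c(far = "far", close = "close"), function(cls) {
    sel <- dt$optimum_class == cls & dt$noise_class != "middle"
    if (length(unique(dt$noise_class[sel])) < 2L) return(NULL)
    permutation_median_test(dt$delta_fitness[sel], dt$noise_class[sel],
                            statistic = "median",
                            n_perm = cfg$n_permutations,
                            seed = derive_seed(cfg$seed, 13L))
  })
  structure(list(delta_table = dt, correlations = correlations,
                 group_tests = group_tests, config = cfg,
                 threshold = attr(dt, "threshold")),
            class = "noise_fitness_analysis")
}

#' @export
print.noise_fitness_analysis <- function(x, ...) {
  cat(sprintf("Noise-fitness analysis: %d genotypes, optimum threshold %.1f%%\n",
              nrow(x$delta_table), x$threshold))
  for (cls in names(x$correlations)) {
    co <- x$correlations[[cls]]
    if (!is.null(co))
      cat(sprintf("  %s from optimum (n=%d): r = %.3f, p(t) = %.3g, p(perm) = %.3g\n",
                  cls, co$n, co$r, co$p, co$p_perm))
  }
  invisible(x)
}
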