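# Per-event cytometry processing: gating, PCA size normalisation, the
# log-log fluorescence-to-mRNA calibration, per-sample summary statistics
# (median expression and four noise metrics), batch and autofluorescence
# correction, MAD replicate filtering and genotype-level aggregation
# relative to a reference strain.

#' Construct a cytometry event table
#'
#' @param fsc_a,fsc_h Forward-scatter area and height (arbitrary units).
#' @param fl1 Fluorescence channel 1 (YFP in expression assays, GFP-weighted
#'   in two-colour fitness assays).
#' @param fl2 Optional second fluorescence channel.
#' @param sample_id,plate,row,column,flow_run Batch labels.
#' @return Data frame of class `event_table`.
#' @export
event_table <- function(fsc_a, fsc_h, fl1, fl2 = NA_real_,
                        sample_id = "S1", plate = "P1", row = "A",
                        column = 1L, flow_run = "R1") {
  d <- data.frame(fsc_a = fsc_a, fsc_h = fsc_h, fl1 = fl1, fl2 = fl2,
                  sample_id = sample_id, plate = plate, row = row,
                  column = column, flow_run = flow_run,
                  stringsAsFactors = FALSE)
  class(d) <- c("event_table", "data.frame")
  d
}

#' mRNA calibration constants for the log-log fluorescence relation
#'
#' The relationship between the relative mRNA level `y` of the reporter and
#' the size-normalised fluorescence `x` is `log10(y) = a*log10(x) + b`.
#' The default constants are the least-squares estimates from parallel
#' pyrosequencing/cytometry measurements on a BD Accuri C6: `a = 10.469`,
#' `b = -9.586`.
#'
#' @param a Slope (> 0). @param b Intercept (log10 units).
#' @return List of class `mrna_calibration`.
#' @export
mrna_calibration <- function(a = 10.469, b = -9.586) {
  stop_if_not_scalar(a, "a", positive = TRUE)
  stop_if_not_scalar(b, "b")
  structure(list(a = a, b = b), class = "mrna_calibration")
}

# Deterministic robust location/scatter by iterative trimming: classical
# moments refined on the best `trim` fraction (smallest Mahalanobis
# distances), with the standard consistency correction for the truncated
# chi-square so the scatter stays unbiased for clean Gaussian data.
robust_cov_trimmed <- function(m, trim = 0.95, iterations = 3L) {
  ctr <- colMeans(m)
  cv <- stats::cov(m)
  k2 <- stats::qchisq(trim, df = ncol(m))
  consistency <- trim / stats::pchisq(k2, df = ncol(m) + 2L)
  for (i in seq_len(iterations)) {
    if (any(!is.finite(cv)) || det(cv) <= 0) break
    md <- stats::mahalanobis(m, ctr, cv)
    keep <- md <= quantile(md, trim)
    ctr <- colMeans(m[keep, , drop = FALSE])
    cv <- stats::cov(m[keep, , drop = FALSE]) * consistency
  }
  list(center = ctr, cov = cv)
}

#' Gate cytometry events
#'
#' Removes events with non-positive scatter or fluorescence (which cannot be
#' log-transformed), events outside quantile bounds on log FSC.A, log FSC.H
#' and log FL1 (extreme-value artifacts), and events falling in low-density
#' regions of the (log FSC.A, log FSC.H) plane, which are predominantly
#' doublets and debris rather than single cells. The density gate fits a
#' robust (deterministically trimmed) Gaussian density to the 2-D log
#' scatter and drops events outside its `density_quantile` contour, i.e.
#' squared Mahalanobis distance above `qchisq(density_quantile, 2)`; a
#' doublet population shifted along FSC.A sits far outside the singlet
#' contour and is removed without sacrificing singlet retention.
#'
#' @param raw An `event_table`.
#' @param quantile_bounds Length-2 vector of lower/upper quantile bounds
#'   applied to each log channel (default `c(0.001, 0.999)`). Use `c(0, 1)`
#'   to disable.
#' @param density_quantile Retention contour of the robust density gate
#'   (default 0.9999). Use `NULL` or 1 to disable.
#' @return The gated `event_table`.
#' @export
filter_events <- function(raw, quantile_bounds = c(0.001, 0.999),
                          density_quantile = 0.9999) {
  stopifnot(nrow(raw) >= 1L, length(quantile_bounds) == 2L)
  keep <- raw$fsc_a > 0 & raw$fsc_h > 0 & raw$fl1 > 0
  ev <- raw[keep, , drop = FALSE]
  if (nrow(ev) == 0L)
    stop("no events left after removing non-positive values", call. = FALSE)
  for (ch in c("fsc_a", "fsc_h", "fl1")) {
    lx <- log10(ev[[ch]])
    qb <- quantile(lx, quantile_bounds, names = FALSE)
    ev <- ev[log10(ev[[ch]]) >= qb[1L] & log10(ev[[ch]]) <= qb[2L], ,
             drop = FALSE]
    if (nrow(ev) == 0L) stop("all events removed by quantile gate", call. = FALSE)
  }
  if (!is.null(density_quantile) && density_quantile < 1 && nrow(ev) >= 20L) {
    m <- cbind(log10(ev$fsc_a), log10(ev$fsc_h))
    if (sd(m[, 1L]) > 0 && sd(m[, 2L]) > 0) {
      rc <- robust_cov_trimmed(m)
      if (all(is.finite(rc$cov)) && det(rc$cov) > 0) {
        md <- stats::mahalanobis(m, rc$center, rc$cov)
        ev <- ev[md <= stats::qchisq(density_quantile, df = 2L), ,
                 drop = FALSE]
      }
    }
  }
  if (nrow(ev) == 0L) stop("all events removed by density gate", call. = FALSE)
  class(ev) <- c("event_table", "data.frame")
  ev
}

#' Size-normalised fluorescence per event
#'
#' Scales fluorescence by cell size using a PCA rotation in the
#' (log10 FSC.A, log10 FL1) plane. The eigenvectors of the 2-D log data
#' intersect at the data centroid; let `nu` be the vector from the origin to
#' that centroid. The data are rotated about the centroid by the angle
#' between the first (larger-eigenvalue) eigenvector and `nu`, so that the
#' major axis of the cloud points along the centroid ray; each rotated FL1
#' value is then divided by the rotated FSC.A value. The first eigenvector's
#' sign is fixed to a positive dot product with `nu`, and the rotation maps
#' it onto `nu`; a global multiplicative rescaling of all channels shifts
#' the log cloud but leaves the ratio structure intact up to this centroid
#' convention.
#'
#' @param events An `event_table` with >= 2 events, positive `fsc_a`, `fl1`.
#' @return Numeric vector of per-event fluorescence-per-size values.
#' @export
size_normalize <- function(events) {
  stopifnot(nrow(events) >= 2L)
  stopifnot(all(events$fsc_a > 0), all(events$fl1 > 0))
  m <- cbind(log10(events$fsc_a), log10(events$fl1))
  ctr <- colMeans(m)
  cv <- stats::cov(m)
  if (!all(is.finite(cv)) || sum(diag(cv)) <= .Machine$double.eps)
    stop("degenerate covariance: all events identical", call. = FALSE)
  e <- eigen(cv, symmetric = TRUE)
  v1 <- e$vectors[, 1L]
  nu <- ctr
  if (sum(v1 * nu) < 0) v1 <- -v1
  theta <- atan2(nu[2L], nu[1L]) - atan2(v1[2L], v1[1L])
  rot <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2L, 2L)
  centred <- sweep(m, 2L, ctr)
  rotated <- sweep(centred %*% t(rot), 2L, ctr, `+`)
  if (any(abs(rotated[, 1L]) < .Machine$double.eps))
    stop("rotated scatter hit zero; cannot form fluorescence/size ratio",
         call. = FALSE)
  rotated[, 2L] / rotated[, 1L]
}

#' Convert size-normalised fluorescence to relative mRNA level
#'
#' Applies the log-log calibration `y = 10^(a*log10(x) + b)`; strictly
#' increasing in `x`.
#'
#' @param x Size-normalised fluorescence, > 0 (vectorised).
#' @param cal An [mrna_calibration()].
#' @return Relative mRNA level.
#' @export
fluor_to_mrna <- function(x, cal = mrna_calibration()) {
  stopifnot(all(x > 0))
  10^(cal$a * log10(x) + cal$b)
}

# Inverse of the calibration: the fluorescence that maps to mRNA level y.
mrna_to_fluor <- function(y, cal = mrna_calibration()) {
  out <- rep(0, length(y))
  pos <- y > 0
  out[pos] <- 10^((log10(y[pos]) - cal$b) / cal$a)
  out
}

#' Summarise a sample's single-cell expression distribution
#'
#' Computes the median `m`, standard deviation `s` and four noise metrics of
#' per-cell expression: noise strength `s^2/m` (a Fano-factor-like measure
#' with a median denominator), `cv = s/m`, and `log_cv = log10(s/m)`.
#' Samples with fewer cells than `min_cells` are flagged and not summarised.
#'
#' @param expr Per-cell relative mRNA values.
#' @param min_cells Minimum cell count for a reliable summary (default 1000).
#' @param sample_id,flow_run,row Batch labels carried into the summary.
#' @return One-row data frame of class `sample_expression` with columns
#'   `m`, `s`, `noise_strength`, `cv`, `log_cv`, `n_cells`, `pass_n`.
#' @export
summarize_sample <- function(expr, min_cells = 1000L, sample_id = "S1",
                             flow_run = "R1", row = "A") {
  n <- length(expr)
  if (n < min_cells) {
    out <- data.frame(sample_id = sample_id, flow_run = flow_run, row = row,
                      m = NA_real_, s = NA_real_, noise_strength = NA_real_,
                      cv = NA_real_, log_cv = NA_real_, n_cells = n,
                      pass_n = FALSE, stringsAsFactors = FALSE)
  } else {
    m <- median(expr)
    s <- sd(expr)
    out <- data.frame(sample_id = sample_id, flow_run = flow_run, row = row,
                      m = m, s = s, n_cells = n, pass_n = TRUE,
                      stringsAsFactors = FALSE)
    out <- recompute_noise_metrics(out)
  }
  class(out) <- c("sample_expression", "data.frame")
  out
}

# Noise metrics are always derived from (m, s) so they stay mutually
# consistent after batch/autofluorescence corrections.
recompute_noise_metrics <- function(samples) {
  m <- samples$m
  s <- samples$s
  samples$noise_strength <- ifelse(m > 0, s^2 / m, NA_real_)
  samples$cv <- ifelse(m > 0, s / m, NA_real_)
  samples$log_cv <- ifelse(m > 0 & s > 0, log10(s / m), NA_real_)
  samples
}

#' Remove batch effects from sample summaries using plate controls
#'
#' The dominant batch effect in plate-based cytometry is run-to-run drift in
#' detector sensitivity ("flow run"), which acts multiplicatively on
#' fluorescence. Control replicates of the reference strain present on every
#' plate are used to fit fixed-effects linear models, with factors
#' `flow_run` and `row`, of (i) `u = log10(m)` and (ii) `v = s/(m*ln 10)`,
#' the first-order (delta-method) approximation of the SD of log10
#' expression. The fitted batch deviations (centred on the control mean) are
#' subtracted from every sample on those scales and `(m, s)` are
#' back-transformed; noise metrics are recomputed from the corrected values.
#'
#' @param samples Data frame of sample summaries (rows as returned by
#'   [summarize_sample()]).
#' @param controls Sample summaries of the control (reference) strain; every
#'   `flow_run` and `row` level present in `samples` must occur here.
#' @return `samples` with corrected `m`, `s` and noise metrics.
#' @export
correct_batch <- function(samples, controls) {
  stopifnot(nrow(controls) >= 1L)
  for (fac in c("flow_run", "row")) {
    missing_lv <- setdiff(unique(samples[[fac]]), unique(controls[[fac]]))
    if (length(missing_lv) > 0L)
      stop(sprintf("no control samples for %s level(s): %s", fac,
                   paste(missing_lv, collapse = ", ")), call. = FALSE)
  }
  u_c <- log10(controls$m)
  v_c <- controls$s / (controls$m * log(10))
  terms <- character(0)
  if (length(unique(controls$flow_run)) > 1L) terms <- c(terms, "flow_run")
  if (length(unique(controls$row)) > 1L) terms <- c(terms, "row")
  if (length(terms) == 0L) return(samples)  # single batch: identity
  dat_c <- data.frame(u = u_c, v = v_c,
                      flow_run = factor(controls$flow_run),
                      row = factor(controls$row))
  form <- stats::as.formula(paste("~", paste(terms, collapse = " + ")))
  fit_u <- lm(stats::update(form, u ~ .), data = dat_c)
  fit_v <- lm(stats::update(form, v ~ .), data = dat_c)
  newdat <- data.frame(
    flow_run = factor(samples$flow_run, levels = levels(dat_c$flow_run)),
    row = factor(samples$row, levels = levels(dat_c$row)))
  adj_u <- predict(fit_u, newdata = newdat) - mean(predict(fit_u))
  adj_v <- predict(fit_v, newdata = newdat) - mean(predict(fit_v))
  u <- log10(samples$m) - adj_u
  v <- samples$s / (samples$m * log(10)) - adj_v
  samples$m <- 10^u
  samples$s <- v * samples$m * log(10)
  recompute_noise_metrics(samples)
}

#' Subtract autofluorescence measured on a non-fluorescent strain
#'
#' Subtracts the mean `m` and mean `s` of the blank (non-fluorescent) strain
#' replicates from every sample; null-promoter genotypes end up near zero.
#'
#' @param samples Sample summaries to correct.
#' @param blank Sample summaries of the non-fluorescent strain (>= 1 row).
#' @return Corrected samples with recomputed noise metrics.
#' @export
subtract_autofluorescence <- function(samples, blank) {
  stopifnot(nrow(blank) >= 1L)
  samples$m <- samples$m - mean(blank$m)
  samples$s <- samples$s - mean(blank$s)
  recompute_noise_metrics(samples)
}

#' MAD outlier filter for replicate measurements
#'
#' Retains values within `k` raw median absolute deviations of the median
#' (no consistency constant). When the MAD is zero only values strictly
#' different from the median are dropped.
#'
#' @param values Replicate measurements (>= 3).
#' @param k MAD multiplier (4 for expression replicates, 5 for fitness).
#' @return Logical mask of retained values.
#' @export
mad_filter <- function(values, k) {
  stopifnot(length(values) >= 3L, k >= 0)
  med <- median(values)
  mad_raw <- median(abs(values - med))
  abs(values - med) <= k * mad_raw
}

#' Aggregate replicate samples into a genotype summary
#'
#' Replicates failing a 4-MAD filter on `m` or `s` are discarded; the
#' surviving values of median expression and each noise metric are divided
#' by the mean of the corresponding reference-strain replicates and
#' expressed as percentages, then averaged with Student-t 95% confidence
#' intervals. CIs require at least `min_ci_replicates` survivors.
#'
#' @param samples Replicate summaries of the genotype.
#' @param reference_samples Replicate summaries of the reference strain.
#' @param genotype_id Label for the output row.
#' @param k MAD multiplier (default 4).
#' @param min_ci_replicates Minimum replicates for reporting a CI (default 4).
#' @return One-row data frame of class `genotype_summary` with
#'   `median_expression_pct`, `<metric>_pct`, their CIs and `n_replicates`.
#' @export
aggregate_genotype <- function(samples, reference_samples,
                               genotype_id = "g1", k = 4,
                               min_ci_replicates = 4L) {
  keep_s <- mad_filter(samples$m, k) & mad_filter(samples$s, k)
  keep_r <- mad_filter(reference_samples$m, k) &
    mad_filter(reference_samples$s, k)
  s <- samples[keep_s, , drop = FALSE]
  r <- reference_samples[keep_r, , drop = FALSE]
  metrics <- c(median_expression = "m", noise_strength = "noise_strength",
               sd = "s", cv = "cv", logcv = "log_cv")
  out <- data.frame(genotype_id = genotype_id, n_replicates = nrow(s),
                    stringsAsFactors = FALSE)
  for (i in seq_along(metrics)) {
    rel <- 100 * s[[metrics[i]]] / mean(r[[metrics[i]]])
    nm <- names(metrics)[i]
    out[[paste0(nm, "_pct")]] <- mean(rel)
    ci <- if (nrow(s) >= min_ci_replicates) t_ci(rel) else
      c(lower = NA_real_, upper = NA_real_)
    out[[paste0(nm, "_ci_lo")]] <- ci[["lower"]]
    out[[paste0(nm, "_ci_hi")]] <- ci[["upper"]]
  }
  class(out) <- c("genotype_summary", "data.frame")
  out
}

#' Full expression pipeline for one sample's raw events
#'
#' Convenience composition: gate events, size-normalise, apply the mRNA
#' calibration and summarise.
#'
#' @param raw An `event_table` of raw events.
#' @param cal An [mrna_calibration()].
#' @param min_cells Floor passed to [summarize_sample()].
#' @param ... Passed to [filter_events()].
#' @return A `sample_expression` row.
#' @export
expression_from_events <- function(raw, cal = mrna_calibration(),
                                   min_cells = 1000L, ...) {
  ev <- filter_events(raw, ...)
  expr <- fluor_to_mrna(size_normalize(ev), cal)
  summarize_sample(expr, min_cells = min_cells,
                   sample_id = ev$sample_id[1L], flow_run = ev$flow_run[1L],
                   row = ev$row[1L])
}
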