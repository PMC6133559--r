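# Competitive-fitness estimation from serial-dilution competition assays:
# two-colour event classification with doublet correction (indirect assays
# against a common fluorescent reference) and allele-frequency trajectories
# (direct pairwise assays read out by pyrosequencing).

#' Classify two-colour cytometry events into YFP, GFP and mixed doublets
#'
#' Performs a PCA on the log heights of the two fluorescence channels.
#' In typical data the first component captures cell-size variation and the
#' second separates the two fluorophores; the colour component is
#' identified as the one whose scores correlate most strongly with the
#' channel contrast `log(fl1) - log(fl2)` (the second component in the
#' size-dominated case). The kernel density of colour scores shows three
#' modes: GFP cells (high score), YFP cells (low score) and a smaller
#' intermediate population of mixed doublets (one YFP plus one GFP cell
#' captured as a single event). Scores are split at the density minima
#' between the three largest modes.
#'
#' @param events An event table (see [event_table()]) with both `fl1` and
#'   `fl2` strictly positive. `fl1` is the GFP-weighted channel and `fl2`
#'   the YFP-weighted channel.
#' @return An object of class `doublet_counts`: list with integer fields
#'   `TY` (total YFP events), `TG` (total GFP events) and `DYG` (mixed
#'   doublets).
#' @export
classify_two_color <- function(events) {
  stopifnot(is.data.frame(events))
  if (is.null(events$fl1) || is.null(events$fl2) || all(is.na(events$fl2)))
    stop("both fluorescence channels are required", call. = FALSE)
  keep <- events$fl1 > 0 & events$fl2 > 0
  l1 <- log10(events$fl1[keep])
  l2 <- log10(events$fl2[keep])
  pc <- prcomp(cbind(l1, l2), center = TRUE, scale. = FALSE)
  contrast <- l1 - l2
  cors <- suppressWarnings(apply(pc$x, 2L, cor, y = contrast))
  cors[is.na(cors)] <- 0
  comp <- if (abs(cors[2L]) >= abs(cors[1L])) 2L else 1L
  score <- pc$x[, comp]
  # orient so that GFP cells (high fl1 relative to fl2) have high scores
  if (cors[comp] < 0) score <- -score
  if (length(unique(round(score, 10))) < 3L)
    return(doublet_counts(TY = 0L, TG = sum(keep), DYG = 0L))
  d <- density(score)
  dy <- d$y
  peaks <- which(diff(sign(diff(dy))) == -2) + 1L
  # ignore baseline micro-wiggles and merge near-coincident peaks
  peaks <- peaks[dy[peaks] >= 0.005 * max(dy)]
  if (length(peaks) > 1L) {
    min_sep <- 0.05 * diff(range(d$x))
    keep_pk <- rep(TRUE, length(peaks))
    for (i in seq_along(peaks)[-1L]) {
      prev <- max(which(keep_pk[seq_len(i - 1L)]))
      if (d$x[peaks[i]] - d$x[peaks[prev]] < min_sep) {
        if (dy[peaks[i]] > dy[peaks[prev]]) keep_pk[prev] <- FALSE
        else keep_pk[i] <- FALSE
      }
    }
    peaks <- peaks[keep_pk]
  }
  if (length(peaks) < 2L) {
    # single mode: a pure sample; orient by absolute channel balance
    yfp <- median(l2 - l1) > 0
    return(doublet_counts(TY = if (yfp) length(score) else 0L,
                          TG = if (yfp) 0L else length(score), DYG = 0L))
  }
  peaks <- peaks[order(dy[peaks], decreasing = TRUE)]
  peaks <- sort(head(peaks, 3L))
  cuts <- vapply(seq_len(length(peaks) - 1L), function(i) {
    span <- seq(peaks[i], peaks[i + 1L])
    d$x[span[which.min(dy[span])]]
  }, numeric(1))
  if (length(cuts) == 1L) {
    warning("fewer than two density minima; no mixed-doublet population resolved")
    lo <- cuts
    hi <- cuts
  } else {
    lo <- cuts[1L]
    hi <- cuts[2L]
  }
  TY <- sum(score < lo)
  TG <- sum(score > hi)
  DYG <- sum(score >= lo & score <= hi)
  if (length(cuts) == 1L) DYG <- 0L
  doublet_counts(TY = TY, TG = TG, DYG = DYG)
}

#' Construct raw two-colour event counts
#'
#' @param TY Total YFP events. @param TG Total GFP events.
#' @param DYG Mixed YFP-GFP doublet events.
#' @return Object of class `doublet_counts`.
#' @export
doublet_counts <- function(TY, TG, DYG) {
  stopifnot(TY >= 0, TG >= 0, DYG >= 0)
  structure(list(TY = TY, TG = TG, DYG = DYG), class = "doublet_counts")
}

#' Doublet-corrected cell numbers from raw event counts
#'
#' Mixed doublets (one YFP plus one GFP cell in a single event) are directly
#' observable, but same-colour doublets are not. Assuming doublets form by
#' random pairing of cells, the mixed count relates to the hidden same-colour
#' counts like the heterozygote class of a Hardy-Weinberg ratio,
#' `DYG = 2 * sqrt(DY * DG)`, and random pairing also implies equal doublet
#' proportions in the two populations, `DY/TY = DG/TG`. The unique solution is
#' `DY = (DYG/2) * sqrt(TY/TG)` and `DG = (DYG/2) * sqrt(TG/TY)`, giving cell
#' numbers `NY = TY + DY + DYG` and `NG = TG + DG + DYG`.
#'
#' @param counts A `doublet_counts` object (or list with `TY`, `TG`, `DYG`).
#' @return Object of class `cell_counts`: list with `NY`, `NG`, `DY`, `DG`
#'   plus the input counts.
#' @export
doublet_correct <- function(counts) {
  TY <- counts$TY; TG <- counts$TG; DYG <- counts$DYG
  stopifnot(TY >= 0, TG >= 0, DYG >= 0)
  if (DYG > 0 && (TY == 0 || TG == 0))
    stop("mixed doublets observed with an empty colour class; random-pairing assumption violated",
         call. = FALSE)
  if (DYG == 0) {
    DY <- 0; DG <- 0
  } else {
    DY <- DYG / 2 * sqrt(TY / TG)
    DG <- DYG / 2 * sqrt(TG / TY)
  }
  structure(list(NY = TY + DY + DYG, NG = TG + DG + DYG,
                 DY = DY, DG = DG, TY = TY, TG = TG, DYG = DYG),
            class = "cell_counts")
}

#' Generations elapsed per growth cycle from densities and dilution factors
#'
#' A culture at density `D[t-1]` is diluted by `f[t]`, grows, and reaches
#' density `D[t]` before the next dilution, so the cycle spans
#' `g[t] = log2(D[t] * f[t] / D[t-1])` generations. Cumulative generations
#' at each assessment are the running sum (starting at 0).
#'
#' @param densities Cell densities measured before each dilution
#'   (length `n_cycles + 1`, all > 0).
#' @param dilution_factors Dilution factor applied at each cycle
#'   (length `n_cycles`, all > 1).
#' @return List with `per_cycle` generations and `cumulative` generations at
#'   each assessment (length `n_cycles + 1`, starting at 0).
#' @export
generations_from_densities <- function(densities, dilution_factors) {
  stopifnot(all(densities > 0), all(dilution_factors > 1),
            length(densities) == length(dilution_factors) + 1L)
  n <- length(dilution_factors)
  g <- log2(densities[-1L] * dilution_factors / densities[-(n + 1L)])
  list(per_cycle = g, cumulative = c(0, cumsum(g)))
}

#' Plate-level generations per cycle
#'
#' The per-cycle generation number used for all samples of a 96-well plate is
#' the median across wells of that plate.
#'
#' @param per_cycle_matrix Matrix of per-cycle generations, wells in rows.
#' @return List with `per_cycle` medians and `cumulative` generations.
#' @export
plate_generations <- function(per_cycle_matrix) {
  g <- apply(as.matrix(per_cycle_matrix), 2L, median)
  list(per_cycle = g, cumulative = c(0, cumsum(g)))
}

#' Construct a competition series
#'
#' @param generations Cumulative generations at each assessment.
#' @param NY,NG Doublet-corrected cell numbers (indirect assays), or leave
#'   `NULL` and supply `freq` for direct assays.
#' @param freq High-noise-genotype allele frequencies at each assessment.
#' @param peak_heights Optional mean pyrogram peak height per assessment.
#' @return Object of class `competition_series` (a data frame).
#' @export
competition_series <- function(generations, NY = NULL, NG = NULL,
                               freq = NULL, peak_heights = NULL) {
  stopifnot(!is.unsorted(generations))
  if (!is.null(NY)) {
    s <- data.frame(generations = generations, NY = NY, NG = NG)
  } else {
    stopifnot(all(freq > 0 & freq < 1))
    s <- data.frame(generations = generations, freq = freq)
  }
  if (!is.null(peak_heights)) s$peak_height <- peak_heights
  class(s) <- c("competition_series", "data.frame")
  s
}

fit_log_ratio_slope <- function(g, lr) {
  fit <- lm(lr ~ g)
  slope <- unname(coef(fit)[2L])
  # exact geometric series fit perfectly; the perfect-fit warning is moot
  se <- suppressWarnings(summary(fit)$coefficients[2L, 2L])
  df <- fit$df.residual
  half <- if (df > 0) qt(0.975, df) * se else NA_real_
  list(slope = slope, se = se,
       ci95 = c(lower = slope - half, upper = slope + half))
}

#' Competitive fitness from a two-colour count series
#'
#' Competitive fitness per generation is the exponential of the slope of
#' `ln(NY/NG)` regressed (ordinary least squares) on cumulative generations.
#'
#' @param series A `competition_series` with `NY`, `NG` columns, or a data
#'   frame with `generations`, `NY`, `NG`.
#' @return Object of class `fitness_estimate`: list with `w`, `ci95`
#'   (on the fitness scale), `slope`, `se` and `n_timepoints`.
#' @export
fitness_from_series <- function(series) {
  stopifnot(nrow(series) >= 2L)
  if (any(series$NY <= 0) || any(series$NG <= 0))
    stop("zero count at a used timepoint; cannot form log ratio", call. = FALSE)
  f <- fit_log_ratio_slope(series$generations, log(series$NY / series$NG))
  structure(list(w = exp(f$slope), ci95 = exp(f$ci95), slope = f$slope,
                 se = f$se, n_timepoints = nrow(series)),
            class = "fitness_estimate")
}

#' Relative fitness across replicates against a reference genotype
#'
#' Per-replicate competitive fitness values of the focal and reference
#' genotypes are first screened with a 5-MAD outlier filter (see
#' [mad_filter()]); each surviving focal replicate is divided by the mean
#' fitness of the surviving reference replicates. The mean relative fitness,
#' its Student-t 95% CI and a one-sample t-test against 1 are reported.
#'
#' @param w Per-replicate competitive fitness of the focal genotype.
#' @param w_reference Per-replicate competitive fitness of the reference.
#' @param k MAD multiplier for outlier exclusion (default 5).
#' @return Object of class `fitness_estimate` with fields `w_rel`,
#'   `w_rel_replicates`, `ci95`, `p_value` (t-test against 1),
#'   `n_replicates`, and `n_excluded`.
#' @export
relative_fitness <- function(w, w_reference, k = 5) {
  keep_w <- mad_filter(w, k)
  keep_r <- mad_filter(w_reference, k)
  wr <- w[keep_w] / mean(w_reference[keep_r])
  ci <- t_ci(wr)
  p <- if (length(wr) >= 2L && sd(wr) > 0) t.test(wr, mu = 1)$p.value else NA_real_
  structure(list(w_rel = mean(wr), w_rel_replicates = wr,
                 ci95 = ci[c("lower", "upper")], p_value = p,
                 n_replicates = length(wr),
                 n_excluded = sum(!keep_w)),
            class = "fitness_estimate")
}

#' Fitness from an allele-frequency trajectory (direct pairwise assay)
#'
#' For two genotypes competed head to head and read out by pyrosequencing,
#' fitness of the high-noise genotype relative to the low-noise genotype is
#' the exponential of the slope of `ln(fH/fL)` on generations, with
#' `fH + fL = 1`; a fitness above 1 means the high-noise strain grew faster.
#' Samples whose average pyrogram peak height falls below `min_peak_height`
#' are excluded as unreliable (weak PCR).
#'
#' @param freq High-noise allele frequencies `fH` at each assessment,
#'   strictly inside (0, 1).
#' @param generations Cumulative generations at each assessment.
#' @param peak_heights Optional per-assessment mean peak heights.
#' @param min_peak_height Exclusion threshold on the series-average peak
#'   height (default 5).
#' @return A `fitness_estimate` (fields `w`, `ci95`, `slope`, `se`), or an
#'   object with `excluded = TRUE` when the peak-height criterion fails.
#' @export
direct_fitness <- function(freq, generations, peak_heights = NULL,
                           min_peak_height = 5) {
  stopifnot(length(freq) == length(generations), length(freq) >= 2L)
  if (!is.null(peak_heights) && mean(peak_heights) < min_peak_height)
    return(structure(list(excluded = TRUE,
                          mean_peak_height = mean(peak_heights)),
                     class = "fitness_estimate"))
  stopifnot(all(freq > 0 & freq < 1))
  f <- fit_log_ratio_slope(generations, log(freq / (1 - freq)))
  structure(list(w = exp(f$slope), ci95 = exp(f$ci95), slope = f$slope,
                 se = f$se, excluded = FALSE, n_timepoints = length(freq)),
            class = "fitness_estimate")
}

#' Doubling time from a log-phase density series
#'
#' The doubling time in minutes is the inverse of the slope of `log2(D)`
#' regressed on time, over points the user marks as logarithmic phase.
#'
#' @param densities Cell densities (or OD) during log phase, > 0.
#' @param times Times in minutes.
#' @return Doubling time in minutes.
#' @export
doubling_time <- function(densities, times) {
  stopifnot(length(densities) == length(times), length(times) >= 2L,
            all(densities > 0))
  slope <- unname(coef(lm(log2(densities) ~ times))[2L])
  if (!is.finite(slope) || slope < 1e-10)
    stop("non-positive growth slope; not a log-phase series", call. = FALSE)
  1 / slope
}

#' @export
print.fitness_estimate <- function(x, ...) {
  if (isTRUE(x$excluded)) {
    cat("Fitness estimate: excluded (mean peak height",
        format(x$mean_peak_height), ")\n")
  } else if (!is.null(x$w_rel)) {
    cat(sprintf("Relative fitness: %.4f [%.4f, %.4f], n = %d\n",
                x$w_rel, x$ci95[1L], x$ci95[2L], x$n_replicates))
  } else {
    cat(sprintf("Competitive fitness: %.4f [%.4f, %.4f]\n",
                x$w, x$ci95[1L], x$ci95[2L]))
  }
  invisible(x)
}
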