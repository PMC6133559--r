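# Allele-frequency quantification from pyrosequencing peak heights,
# PCR-bias corrections, relative-expression ratios and promoter copy-number
# inference. Pyrosequencing reads out the relative abundance of two alleles
# in a template pool as light-peak heights; incorporation chemistry
# over-calls A peaks by a known factor, and PCR can add a locus-specific
# bias, both of which are corrected here before frequencies are interpreted.

#' Allele frequency from pyrogram peak heights
#'
#' Converts the raw heights of the two allele peaks of a pyrogram into the
#' frequency of the G-marked allele. A peaks are systematically over-called
#' by the sequencing chemistry, so the A-peak height is multiplied by a
#' correction factor (conventionally 0.86) before the ratio is formed:
#' `freq = h_G / (h_G + a_correction * h_A)`.
#'
#' @param h_g Height of the G-allele peak (arbitrary units, >= 0).
#' @param h_a Height of the A-allele peak (arbitrary units, >= 0).
#' @param a_correction Multiplicative factor applied to A-peak heights
#'   (default 0.86).
#' @return Frequency of the G allele in `[0, 1]`.
#' @seealso [linear_bias_correct()], [expression_ratio()]
#' @export
freq_from_peaks <- function(h_g, h_a, a_correction = 0.86) {
  stopifnot(all(h_g >= 0), all(h_a >= 0))
  if (any(h_g + h_a == 0))
    stop("both peak heights are zero; frequency undefined", call. = FALSE)
  h_g / (h_g + a_correction * h_a)
}

#' Linear PCR-bias correction of an observed allele frequency
#'
#' Applies the fixed linear correction `y = x * (0.5/0.45) - 0.111`
#' calibrated on a single-copy control strain whose true G frequency is 0.5
#' but whose observed frequency is 0.55 (a PCR bias towards G caused by the
#' two alleles sitting at different genomic positions). Results are clipped
#' to `[0, 1]`.
#'
#' @param x Observed G-allele frequency in `[0, 1]` (vectorised).
#' @return Corrected frequency in `[0, 1]`.
#' @export
linear_bias_correct <- function(x) {
  stopifnot(all(x >= 0 & x <= 1))
  pmin(1, pmax(0, x * (0.5 / 0.45) - 0.111))
}

#' Monotone spline correction of allele-frequency bias
#'
#' Calibrates a smooth monotone map from observed to true allele frequencies
#' using gDNA control samples of known composition (typically truth levels
#' 0, 0.5 and 1 measured in replicate), for later application to gDNA and
#' cDNA measurements. A cubic smoothing spline of truth on observation is
#' fitted and constrained to be non-decreasing (isotonic projection on a
#' fine grid); when fewer than four distinct observed values are available
#' the fit degenerates gracefully to monotone linear interpolation of the
#' per-level means.
#'
#' @param known True frequencies, one per observed measurement (replicates
#'   share a truth value).
#' @param observed Measured frequencies for the control samples.
#' @return A function mapping observed frequencies to corrected frequencies
#'   in `[0, 1]`.
#' @export
spline_bias_correct <- function(known, observed) {
  stopifnot(length(known) == length(observed), length(known) >= 2L)
  levels_tru <- sort(unique(known))
  if (length(levels_tru) < 2L)
    stop("need at least 2 distinct truth levels", call. = FALSE)
  grid <- seq(min(observed), max(observed), length.out = 501L)
  if (length(levels_tru) >= 4L && length(unique(observed)) >= 4L) {
    fit <- smooth.spline(observed, known,
                         df = min(4, length(unique(observed))))
    pred <- predict(fit, grid)$y
  } else {
    # few calibration levels: interpolate their replicate means linearly
    # (exact for an affine bias, and free of spline wiggle between the
    # widely spaced control levels)
    mo <- vapply(levels_tru, function(l) mean(observed[known == l]),
                 numeric(1))
    ord <- order(mo)
    pred <- approxfun(mo[ord], levels_tru[ord], rule = 2)(grid)
  }
  pred <- isoreg(grid, pred)$yf  # enforce monotonicity
  pred <- pmin(1, pmax(0, pred))
  f <- approxfun(grid, pred, rule = 2)
  function(x) pmin(1, pmax(0, f(x)))
}

#' Relative mRNA abundance from gDNA and cDNA allele frequencies
#'
#' In a pooled sample containing two alleles, the cDNA frequency `C` of the
#' marked allele relates to its gDNA frequency `G` through the relative
#' per-copy expression `A`: `C = A*G / (A*G + (1 - G))`. Inverting gives
#' `A = (1 - G) * C / ((1 - C) * G)`, the expression of the marked allele
#' relative to the other allele.
#'
#' @param G Frequency of the marked allele in genomic DNA, in `(0, 1)`.
#' @param C Frequency of the marked allele in cDNA, in `[0, 1)`.
#' @return Relative abundance `A >= 0`.
#' @export
expression_ratio <- function(G, C) {
  stopifnot(all(G > 0 & G < 1), all(C >= 0 & C < 1))
  (1 - G) * C / ((1 - C) * G)
}

#' cDNA frequency implied by a gDNA frequency and expression ratio
#'
#' Forward form of [expression_ratio()]: `C = A*G / (A*G + (1 - G))`.
#'
#' @param A Relative abundance of the marked allele (>= 0).
#' @param G Frequency of the marked allele in genomic DNA, in `(0, 1)`.
#' @return cDNA frequency in `[0, 1)`.
#' @export
cdna_freq <- function(A, G) {
  stopifnot(all(A >= 0), all(G > 0 & G < 1))
  A * G / (A * G + (1 - G))
}

#' Expected marked-allele frequency for a given copy number
#'
#' With `n_marked` marked promoter copies and `n_other` unmarked copies in
#' the genome, the expected frequency of the marked allele across all copies
#' is `n_marked / (n_marked + n_other)`: 0.5 for one marked plus one native
#' copy, 2/3 for two marked copies, 0.75 for three.
#'
#' @param n_marked Number of marked copies (>= 0).
#' @param n_other Number of unmarked copies (>= 1).
#' @return Expected allele frequency.
#' @export
expected_copy_freq <- function(n_marked, n_other = 1) {
  stopifnot(all(n_marked >= 0), all(n_other >= 1))
  n_marked / (n_marked + n_other)
}

#' Infer promoter copy number from replicate allele frequencies
#'
#' Assigns the candidate copy number whose expected frequency (against one
#' unmarked native copy) is nearest to the replicate mean, and flags strains
#' whose frequency is significantly above the expectation for the claimed
#' copy number (one-sided one-sample t-test), indicating extra integrated
#' copies that should be excluded from analysis.
#'
#' @param replicate_freqs Measured marked-allele frequencies (>= 3 replicates).
#' @param candidate_counts Candidate numbers of marked copies (default 1:3).
#' @param claimed Claimed number of marked copies to test against (default 2,
#'   the double-copy construct design).
#' @param n_other Number of unmarked copies (default 1).
#' @param alpha Significance level for the exceedance flag (default 0.05).
#' @return List with `copies` (nearest candidate), `flagged` (logical),
#'   `p_value` of the one-sided test against the claimed expectation, and
#'   `mean_freq`.
#' @export
infer_copies <- function(replicate_freqs, candidate_counts = 1:3,
                         claimed = 2, n_other = 1, alpha = 0.05) {
  stopifnot(length(replicate_freqs) >= 3L, claimed %in% candidate_counts)
  expect <- expected_copy_freq(candidate_counts, n_other)
  m <- mean(replicate_freqs)
  copies <- candidate_counts[which.min(abs(expect - m))]
  mu0 <- expected_copy_freq(claimed, n_other)
  p <- if (sd(replicate_freqs) == 0) {
    if (m > mu0) 0 else 1
  } else {
    t.test(replicate_freqs, mu = mu0, alternative = "greater")$p.value
  }
  list(copies = copies, flagged = p < alpha, p_value = p, mean_freq = m,
       claimed = claimed)
}

#' Average allele frequencies over multiple variable positions
#'
#' When the sequenced region of a pyrogram covers two (or more) variable
#' positions, a frequency is obtained per position and their mean is used as
#' the allele frequency of the sample.
#'
#' @param freqs Numeric vector of per-position frequencies.
#' @return Mean frequency.
#' @export
average_position_freqs <- function(freqs) {
  stopifnot(length(freqs) >= 1L, all(freqs >= 0 & freqs <= 1))
  mean(freqs)
}
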