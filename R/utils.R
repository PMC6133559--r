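# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Derive a reproducible sub-seed from a global seed
#'
#' All stochastic operations in the package take a single integer seed and
#' derive per-dataset sub-seeds deterministically from it, so that one global
#' seed reproduces an entire study bit-for-bit while replicate datasets remain
#' independent.
#'
#' @param seed Integer global seed.
#' @param offset Integer offset identifying the dataset or replicate.
#' @return An integer seed in `[0, 2^31)`.
#' @export
derive_seed <- function(seed, offset = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  # 104729 is prime; keeps distinct offsets well separated modulo 2^31 - 1
  as.integer((abs(seed) + 104729 * abs(offset)) %% (.Machine$integer.max - 1L)) + 1L
}

with_seed <- function(seed, expr) {
  if (!is.null(seed)) set.seed(seed)
  expr
}

stop_if_not_scalar <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a finite numeric scalar", name), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("'%s' must be > 0", name), call. = FALSE)
  if (nonneg && x < 0)
    stop(sprintf("'%s' must be >= 0", name), call. = FALSE)
  invisible(x)
}

# Student-t 95% confidence interval for a mean across replicates.
t_ci <- function(x, level = 0.95) {
  x <- x[is.finite(x)]
  n <- length(x)
  m <- mean(x)
  if (n < 2L) return(c(lower = NA_real_, upper = NA_real_, mean = m, n = n))
  half <- qt(1 - (1 - level) / 2, df = n - 1L) * sd(x) / sqrt(n)
  c(lower = m - half, upper = m + half, mean = m, n = n)
}
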