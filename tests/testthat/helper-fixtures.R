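# Shared fixtures built in code.

# sample-summary rows with explicit batch labels, for batch-correction tests
make_summary_rows <- function(m, s, flow_run = "R1", row = "A",
                              sample_id = NULL) {
  d <- data.frame(
    sample_id = sample_id %||% paste0(flow_run, "_", seq_along(m)),
    flow_run = flow_run, row = row, m = m, s = s,
    n_cells = 1000L, pass_n = TRUE, stringsAsFactors = FALSE)
  noisefit:::recompute_noise_metrics(d)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# exhaustive permutation oracle: all two-group label assignments
enumerate_perm_p <- function(values, n1, statistic = median) {
  combos <- utils::combn(length(values), n1)
  deltas <- apply(combos, 2L, function(idx)
    abs(statistic(values[idx]) - statistic(values[-idx])))
  obs <- abs(statistic(values[seq_len(n1)]) -
               statistic(values[-seq_len(n1)]))
  mean(deltas >= obs - 1e-12)
}
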