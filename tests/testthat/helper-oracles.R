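# Independent oracles used to freeze expected values. These deliberately do
# not reuse the package's code paths.

# Exact two-tailed signed-rank p by enumerating all 2^n sign assignments.
enum_wilcoxon_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  stopifnot(n <= 16)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  vs <- vapply(0:(2^n - 1), function(mask) {
    signs <- bitwAnd(mask, 2^(0:(n - 1))) > 0
    sum(r[signs])
  }, numeric(1))
  min(1, 2 * min(mean(vs <= v_obs), mean(vs >= v_obs)))
}

# Friedman chi-square from within-row average ranks, classic formula.
hand_friedman_stat <- function(m) {
  ranks <- t(apply(m, 1, rank))
  n <- nrow(m); k <- ncol(m)
  12 / (n * k * (k + 1)) * sum(colSums(ranks)^2) - 3 * n * (k + 1)
}

# Brute-force 1-D segmentation: backward-difference velocity, threshold
# crossings paired with the next opposite-signed crossing.
oracle_segment_1d <- function(t, x, thr, max_spike_ms) {
  v <- c(NA, diff(x) / diff(t))
  hot <- which(abs(v) > thr)
  out <- list()
  while (length(hot)) {
    on <- hot[1]
    off <- hot[hot > on & sign(v[hot]) != sign(v[on])][1]
    if (is.na(off)) break
    dur <- t[off] - t[on]
    out[[length(out) + 1]] <- list(
      start_ms = t[on], end_ms = t[off],
      kind = if (dur <= max_spike_ms) "transient_spike"
             else "spatial_displacement")
    hot <- hot[hot > off]
  }
  out
}

# short constant-position recording helper
const_recording <- function(n = 100, x = 840, y = 525, dt = 1) {
  gaze_recording((seq_len(n) - 1) * dt, rep(x, n), rep(y, n))
}
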