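# Independent oracles used across test files.

# Truncated-normal CDF: P(theta <= m) for a threshold drawn from
# N(mean, sd) truncated below at `floor`.
trunc_norm_cdf <- function(m, mean, sd, floor) {
  pf <- pnorm(floor, mean, sd)
  pmax(0, (pnorm(m, mean, sd) - pf) / (1 - pf))
}

# Brute-force committable drive of a membrane trace: the largest threshold u
# for which the trace stays >= u over a full critical-period window starting
# at some sample (plain double loop; independent of the package's
# rolling-min/cummax machinery).
brute_commit_drive <- function(v, w) {
  n <- length(v)
  best <- -Inf
  for (t in seq_len(n)) {
    hi <- min(n, t + w)
    best <- max(best, min(v[t:hi]))
  }
  best
}

# Brute-force compound trace: loop over spikes, evaluating the unitary
# response directly at every sample.
brute_compound <- function(spikes, dists, t_ms, urp) {
  n_elec <- nrow(dists)
  v <- matrix(0, length(t_ms), n_elec)
  if (nrow(spikes) == 0) return(v)
  for (j in seq_len(nrow(spikes))) {
    u <- unitary_response(t_ms - spikes$time_ms[j], urp)
    for (e in seq_len(n_elec)) {
      v[, e] <- v[, e] + u * 10^(-2 * dists[e, spikes$fiber[j]] / 20)
    }
  }
  v
}

# Small configuration for desk-scale experiment tests.
tiny_config <- function(...) {
  args <- utils::modifyList(
    list(n_fibers = 60, profiles = "short", charge_step = 2, seed = 42),
    list(...))
  do.call(experiment_config, args)
}
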