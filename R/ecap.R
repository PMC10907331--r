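#' Parameters of the unitary response
#'
#' The stereotyped voltage waveform contributed by one fiber's action
#' potential at the recording electrode: a negative lobe before `t0` and a
#' positive lobe after, each a Gaussian-windowed linear ramp,
#' \deqn{U(t) = (u_X / \partial_X^2)(t - t_0) e^{0.5 - (t - t_0)^2 /
#' (2 \partial_X^2)}}
#' with the `N` branch for `t < t0` and the `P` branch otherwise. The
#' support is `t` in `[-0.6, 1.1]` ms around the spike time. The time offset
#' is -60 µs (-0.06 ms).
#'
#' @param t0_ms Time offset in ms (default -0.06).
#' @param u_n,u_p Lobe amplitudes in µV (12 and 45).
#' @param d_n,d_p Lobe widths in ms (0.12 and 0.15).
#' @param support Support interval in ms.
#' @return An object of class `ur_params`.
#' @export
ur_params <- function(t0_ms = -0.06, u_n = 12, u_p = 45,
                      d_n = 0.12, d_p = 0.15, support = c(-0.6, 1.1)) {
  stopifnot(u_n > 0, u_p > 0, d_n > 0, d_p > 0, support[1] < support[2])
  structure(list(t0_ms = t0_ms, u_n = u_n, u_p = u_p, d_n = d_n, d_p = d_p,
                 support = support),
            class = "ur_params")
}

#' Evaluate the unitary response
#'
#' @param t_ms Times in ms relative to the spike (support `[-0.6, 1.1]` ms;
#'   zero outside).
#' @param params A [ur_params()].
#' @return Voltage in µV. `U(t0) = 0`; one negative lobe before `t0`
#'   (minimum at `t0 - d_n`), one positive lobe after (maximum at
#'   `t0 + d_p`), vanishing at the support edges.
#' @export
unitary_response <- function(t_ms, params = ur_params()) {
  dtm <- t_ms - params$t0_ms
  u <- ifelse(dtm < 0,
              params$u_n / params$d_n^2 * dtm * exp(0.5 - dtm^2 / (2 * params$d_n^2)),
              params$u_p / params$d_p^2 * dtm * exp(0.5 - dtm^2 / (2 * params$d_p^2)))
  u[t_ms < params$support[1] - 1e-9 | t_ms > params$support[2] + 1e-9] <- 0
  u
}

# Sampled unitary-response kernel on the dt grid, with the index of t = 0.
ur_kernel <- function(params, dt_us) {
  t_ms <- seq(params$support[1], params$support[2], by = dt_us / 1000)
  list(u = unitary_response(t_ms, params),
       zero_index = which.min(abs(t_ms)))
}

#' Compound eCAP response at the recording electrodes
#'
#' Sums the unitary responses of all spiking fibers, each attenuated by
#' 2 dB/mm over its Euclidean distance to the recording electrode:
#' \deqn{V(t) = \sum_i (o_i * U)(t) \, 10^{-2 |r_r(i)| / 20}.}
#' The response is linear in the spikes: the trace of a union of spike
#' trains is the sum of the individual traces.
#'
#' @param spikes Data frame with columns `fiber` and `time_ms` (spike times
#'   relative to the trace's `t = 0`, typically the pulse onset).
#' @param rec_distances_mm Matrix of fiber-to-recording-electrode distances,
#'   `n_electrodes x n_fibers` (a single electrode may be given as a
#'   vector). Fiber indices in `spikes` must not exceed the fiber count.
#' @param t_max_ms Trace length in ms (sampled from 0 to `t_max_ms`).
#' @param dt_us Sampling step in µs.
#' @param params A [ur_params()].
#' @return Matrix of voltages in µV, one row per time sample (attribute
#'   `time_ms`) and one column per recording electrode.
#' @export
compound_response <- function(spikes, rec_distances_mm, t_max_ms = 2.2,
                              dt_us = 1, params = ur_params()) {
  if (is.null(dim(rec_distances_mm))) {
    rec_distances_mm <- matrix(rec_distances_mm, nrow = 1)
  }
  n_fibers <- ncol(rec_distances_mm)
  n_elec <- nrow(rec_distances_mm)
  if (nrow(spikes) > 0 && max(spikes$fiber) > n_fibers) {
    stop("spike train and distance matrix cover different fiber sets")
  }
  n_t <- floor(t_max_ms * 1000 / dt_us) + 1L
  t_ms <- (seq_len(n_t) - 1L) * dt_us / 1000

  v <- matrix(0, n_t, n_elec)
  if (nrow(spikes) > 0) {
    wts <- t(attenuation_factor(rec_distances_mm))   # n_fibers x n_elec
    bins <- round(spikes$time_ms * 1000 / dt_us) + 1L
    keep <- bins >= 1L
    bins <- bins[keep]
    h <- rowsum(wts[spikes$fiber[keep], , drop = FALSE], group = bins)
    ubins <- as.integer(rownames(h))

    ker <- ur_kernel(params, dt_us)
    nk <- length(ker$u)
    # linear convolution via FFT, batched over electrodes
    nfft <- stats::nextn(n_t + nk - 1L, 2)
    hh <- matrix(0, nfft, n_elec)
    inb <- ubins <= n_t + ker$zero_index  # spikes late enough to matter are few
    hh[ubins[inb & ubins <= nfft], ] <- h[inb & ubins <= nfft, , drop = FALSE]
    kk <- c(ker$u, rep(0, nfft - nk))
    conv <- Re(stats::mvfft(stats::mvfft(hh) * c(stats::fft(kk)), inverse = TRUE)) / nfft
    # kernel index zero_index corresponds to lag 0
    rows <- seq_len(n_t) + ker$zero_index - 1L
    v <- conv[rows, , drop = FALSE]
  }
  attr(v, "time_ms") <- t_ms
  attr(v, "dt_us") <- dt_us
  v
}

#' Average the traces of a polarity pair
#'
#' Pointwise mean of the anodic-leading and cathodic-leading eCAP traces of
#' one charge level.
#'
#' @param trace_anodic,trace_cathodic Numeric vectors (or single-column
#'   matrices) sampled on the same window.
#' @return Numeric vector, the pointwise mean.
#' @export
average_polarity_pair <- function(trace_anodic, trace_cathodic) {
  a <- as.numeric(trace_anodic); b <- as.numeric(trace_cathodic)
  if (length(a) != length(b)) stop("mismatched trace windows")
  (a + b) / 2
}

#' Extract the N1-P2 eCAP amplitude from a trace
#'
#' Searches the negative N1 peak within the first 300 µs of the recording
#' window and the positive P2 peak within 400 µs after N1; the eCAP
#' amplitude is `V(P2) - V(N1)` (always >= 0).
#'
#' @param trace Voltage samples in µV covering the full recording window
#'   (window start at the first sample).
#' @param dt_us Sampling step in µs.
#' @param n1_window_us N1 search range from window start (default 300).
#' @param p2_window_us P2 search range from the N1 peak (default 400).
#' @return List with `amplitude_uv`, `n1_time_us`, `p2_time_us` (relative to
#'   window start) and `degenerate` (flat trace flag).
#' @export
extract_ecap_amplitude <- function(trace, dt_us = 1,
                                   n1_window_us = 300, p2_window_us = 400) {
  v <- as.numeric(trace)
  n <- length(v)
  if (n * dt_us < n1_window_us) stop("trace shorter than the N1 window")
  i_n1_max <- min(n, floor(n1_window_us / dt_us) + 1L)
  i_n1 <- which.min(v[seq_len(i_n1_max)])
  i_p2_max <- min(n, i_n1 + floor(p2_window_us / dt_us))
  i_p2 <- i_n1 - 1L + which.max(v[i_n1:i_p2_max])
  amp <- v[i_p2] - v[i_n1]
  list(amplitude_uv = amp,
       n1_time_us = (i_n1 - 1L) * dt_us,
       p2_time_us = (i_p2 - 1L) * dt_us,
       degenerate = amp == 0)
}

#' Export an eCAP trace as CSV
#'
#' @param trace Numeric voltage vector (µV).
#' @param time_ms Matching time axis in ms.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_trace_csv <- function(trace, time_ms, path) {
  utils::write.csv(data.frame(time_ms = time_ms, v_uv = as.numeric(trace)),
                   path, row.names = FALSE)
  invisible(path)
}
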