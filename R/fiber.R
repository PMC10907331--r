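#' Parameters of the stochastic leaky integrate-and-fire ANF model
#'
#' Phenomenological single-fiber model of one excitation site of an auditory
#' nerve fiber. The fiber low-pass filters (leaky-integrates) the incoming
#' current; a spike is released when the membrane trace crosses a stochastic
#' threshold drawn per pulse from a normal law, provided the membrane is not
#' repolarized below that threshold within a short critical period after the
#' crossing (the mechanism by which the charge-balancing phase can cancel the
#' spike, and hence by which a longer inter-phase gap raises spiking
#' probability). Separate anodic and cathodic thresholds share the same mean;
#' refractoriness and spike-rate adaptation raise both thresholds after a
#' spike, facilitation lowers the leading-polarity threshold after
#' subthreshold stimulation.
#'
#' The threshold standard deviation and the two IIR gain coefficients carry
#' the study's modified values (twice and three times the original
#' single-fiber values, respectively); [original_fiber_params()] restores the
#' originals. The mean threshold is a calibration parameter, chosen once so
#' that fitted eCAP thresholds of the full 2-D model land in the 10.01 ±
#' 3.31 nC range reported for CI users (see `scripts/calibrate.R`).
#'
#' @param threshold_sd Threshold standard deviation δ in µV (modified: 9.2).
#' @param gain_b0,gain_b1 Gain coefficients of the first-order IIR leaky
#'   integrator (modified: 602.6e-6 each).
#' @param mean_threshold Mean threshold in µV (calibrated default).
#' @param membrane_tau_us Membrane (integrator) time constant in µs.
#' @param critical_period_us Time after a threshold crossing during which
#'   repolarization below the drawn threshold cancels the spike, in µs.
#' @param refractory_increment Threshold elevation after a spike, µV.
#' @param refractory_tau_ms Decay time constant of the refractory elevation.
#' @param abs_refractory_ms Absolute refractory period (no spike possible).
#' @param adaptation_increment Cumulative threshold elevation per spike, µV.
#' @param adaptation_tau_ms Decay time constant of adaptation.
#' @param facilitation_decrement Leading-polarity threshold reduction after a
#'   subthreshold pulse, µV.
#' @param facilitation_tau_ms Decay time constant of facilitation.
#' @param threshold_floor_frac Lower bound for drawn thresholds, as a
#'   fraction of `mean_threshold` (thresholds are drawn from a normal law
#'   truncated below at this floor).
#' @param latency_min_us,latency_max_us Range of the crossing-to-spike
#'   latency map, µs.
#' @param latency_rate Decay rate of latency with the suprathreshold drive
#'   ratio (dimensionless); latency is
#'   `min + (max - min) * exp(-rate * (r - 1))` with `r = peak drive /
#'   threshold`, so it decreases monotonically with stimulus amplitude.
#' @return An object of class `fiber_params`.
#' @export
fiber_params <- function(threshold_sd = 9.2,
                         gain_b0 = 602.6e-6,
                         gain_b1 = 602.6e-6,
                         mean_threshold = 75,
                         membrane_tau_us = 100,
                         critical_period_us = 20,
                         refractory_increment = 5,
                         refractory_tau_ms = 2,
                         abs_refractory_ms = 0.5,
                         adaptation_increment = 0.5,
                         adaptation_tau_ms = 50,
                         facilitation_decrement = 1,
                         facilitation_tau_ms = 0.5,
                         threshold_floor_frac = 0.2,
                         latency_min_us = 320,
                         latency_max_us = 450,
                         latency_rate = 2) {
  stopifnot(threshold_sd > 0, gain_b0 > 0, gain_b1 > 0, mean_threshold > 0,
            membrane_tau_us > 0, critical_period_us >= 0,
            refractory_tau_ms > 0, adaptation_tau_ms > 0,
            facilitation_tau_ms > 0, abs_refractory_ms >= 0,
            threshold_floor_frac > 0, threshold_floor_frac < 1,
            latency_min_us > 0, latency_max_us >= latency_min_us,
            latency_rate >= 0)
  structure(as.list(environment()), class = "fiber_params")
}

#' Original (unmodified) single-fiber parameters
#'
#' Same contract as [fiber_params()] but with the original threshold standard
#' deviation (4.6 µV) and integrator gains (200.9e-6): the study's values are
#' exactly double and triple these, respectively.
#'
#' @param ... Overrides passed on to [fiber_params()].
#' @return A `fiber_params` object.
#' @export
original_fiber_params <- function(...) {
  fiber_params(threshold_sd = 4.6, gain_b0 = 200.9e-6, gain_b1 = 200.9e-6, ...)
}

#' Attenuate a current waveform with distance
#'
#' Applies the model's 2 dB/mm field attenuation: the current reaching a
#' neuron at Euclidean distance `d` mm is scaled by `10^(-2 d / 20)`.
#'
#' @param i_ua Current waveform in µA.
#' @param distance_mm Distance in mm (scalar).
#' @return Scaled waveform, shape preserved.
#' @export
attenuate_current <- function(i_ua, distance_mm) {
  stopifnot(length(distance_mm) == 1L, distance_mm >= 0)
  i_ua * 10^(-2 * distance_mm / 20)
}

#' Attenuation factor at a distance
#'
#' @param distance_mm Distances in mm.
#' @param db_per_mm Attenuation rate (default 2 dB/mm).
#' @return `10^(-db_per_mm * d / 20)`.
#' @export
attenuation_factor <- function(distance_mm, db_per_mm = 2) {
  10^(-db_per_mm * distance_mm / 20)
}

#' Leaky integration of a current waveform
#'
#' First-order recursive (IIR) low-pass of the input current: the membrane
#' trace obeys `v[n] = a v[n-1] + b0 I[n] + b1 I[n-1]` with
#' `a = exp(-dt / tau)`. Zero input decays exponentially toward rest; the
#' response is linear in the input for a fixed initial state.
#'
#' @param i_ua Input current in µA, sampled at `dt_us`.
#' @param params A [fiber_params()].
#' @param dt_us Time step in µs.
#' @param v0 Initial membrane potential in µV.
#' @return Membrane trace in µV, same length as the input.
#' @export
integrate_membrane <- function(i_ua, params, dt_us = 1, v0 = 0) {
  stopifnot(inherits(params, "fiber_params"))
  if (any(!is.finite(i_ua))) stop("non-finite input current")
  a <- exp(-dt_us / params$membrane_tau_us)
  x <- params$gain_b0 * i_ua + params$gain_b1 * c(0, i_ua[-length(i_ua)])
  x[1] <- x[1] + a * v0
  as.numeric(stats::filter(x, a, method = "recursive"))
}

# Commitment machinery for one drive channel: given a membrane trace c (the
# channel's depolarizing excursion), a spike with drawn threshold u is
# committed iff the trace stays >= u over a full critical period starting at
# some crossing; the earliest such start is the crossing time.
channel_basis <- function(c_trace, w) {
  n <- length(c_trace)
  rmin <- c_trace
  if (w > 0) {
    for (k in seq_len(w)) {
      shifted <- c(c_trace[-seq_len(k)], rep(c_trace[n], k))
      rmin <- pmin(rmin, shifted)
    }
  }
  M <- cummax(rmin)
  list(M = M, mmax = M[n], peak = max(c_trace))
}

# Earliest committed crossing index for thresholds u (vector) against a
# non-decreasing committable-drive envelope M; NA where u > max(M).
first_commit_index <- function(u, M) {
  idx <- findInterval(u, M, left.open = TRUE) + 1L
  idx[u > M[length(M)]] <- NA_integer_
  idx
}

# Truncated-normal threshold draw (lower bound `floor`), vectorized.
draw_thresholds <- function(n, mean, sd, floor) {
  p_f <- stats::pnorm(floor, mean, sd)
  u <- stats::runif(n)
  q <- stats::qnorm(p_f + u * (1 - p_f), mean, sd)
  pmax(q, floor)  # guard numerical edge at p_f ~ 1
}

latency_us <- function(r, params) {
  r <- pmax(r, 1)
  params$latency_min_us +
    (params$latency_max_us - params$latency_min_us) *
    exp(-params$latency_rate * (r - 1))
}

#' Initial state of a set of fibers
#'
#' @param n Number of fibers.
#' @param time_ms Model time at which the state is defined.
#' @return An object of class `fiber_state`: per-fiber refractory (`R`) and
#'   adaptation (`A`) threshold elevations, polarity-specific facilitation
#'   reductions (`F_a`, `F_c`), last spike times and the state's clock.
#' @export
new_fiber_state <- function(n = 1, time_ms = 0) {
  structure(list(R = numeric(n), A = numeric(n),
                 F_a = numeric(n), F_c = numeric(n),
                 last_spike_ms = rep(-Inf, n), time_ms = time_ms, n = n),
            class = "fiber_state")
}

decay_state <- function(state, to_ms, params) {
  dt <- to_ms - state$time_ms
  if (dt < 0) stop("fiber state can only evolve forward in time")
  if (dt > 0) {
    state$R <- state$R * exp(-dt / params$refractory_tau_ms)
    state$A <- state$A * exp(-dt / params$adaptation_tau_ms)
    state$F_a <- state$F_a * exp(-dt / params$facilitation_tau_ms)
    state$F_c <- state$F_c * exp(-dt / params$facilitation_tau_ms)
    state$time_ms <- to_ms
  }
  state
}

# Decide spikes for all fibers for one pulse, given channel bases and drive
# scales. Returns spike times (NA = no spike) and winning drive ratios.
decide_spikes <- function(s, th_a, th_c, basis_a, basis_c, dt_us, params) {
  n <- length(s)
  t_spk <- rep(NA_real_, n)
  active <- s > 0
  if (!any(active)) return(t_spk)
  u_a <- th_a / s
  u_c <- th_c / s
  ia <- first_commit_index(u_a, basis_a$M)
  ic <- first_commit_index(u_c, basis_c$M)
  la <- ifelse(is.na(ia), Inf,
               (ia - 1) * dt_us + latency_us(basis_a$peak / u_a, params))
  lc <- ifelse(is.na(ic), Inf,
               (ic - 1) * dt_us + latency_us(basis_c$peak / u_c, params))
  t <- pmin(la, lc)
  ok <- active & is.finite(t)
  t_spk[ok] <- t[ok]
  t_spk
}

#' Response of a single fiber to one (attenuated) pulse
#'
#' Reference single-fiber contract: integrates the incoming current, draws
#' the per-pulse stochastic thresholds about the current effective means
#' (mean threshold plus refractory and adaptation elevations, minus the
#' polarity-specific facilitation), finds the earliest threshold crossing
#' that survives the critical period on either the anodic (positive membrane
#' excursion) or cathodic (negative excursion) channel, and maps the crossing
#' to a spike time through the monotone latency map. At most one spike is
#' produced per pulse; on a spike the refractory and adaptation elevations
#' are applied to both polarities, on subthreshold stimulation the
#' facilitation decrement is applied to the leading polarity.
#'
#' @param i_tilde Attenuated current waveform in µA (see
#'   [attenuate_current()]).
#' @param params A [fiber_params()].
#' @param state A single-fiber [new_fiber_state()]; updated and returned.
#' @param onset_ms Pulse onset on the model clock, in ms.
#' @param dt_us Sampling step of the waveform, µs.
#' @return List with `spike` (logical), `latency_us` (spike time relative to
#'   pulse onset, or `NA`), `spike_time_ms` and the updated `state`.
#' @export
simulate_pulse_response <- function(i_tilde, params, state = new_fiber_state(1),
                                    onset_ms = state$time_ms, dt_us = 1) {
  stopifnot(inherits(params, "fiber_params"), state$n == 1L)
  if (any(!is.finite(i_tilde))) stop("non-finite input current")
  state <- decay_state(state, onset_ms, params)

  if (all(i_tilde == 0)) {
    return(list(spike = FALSE, latency_us = NA_real_,
                spike_time_ms = NA_real_, state = state))
  }

  w <- round(params$critical_period_us / dt_us)
  tail_n <- max(w + 1L, round(120 / dt_us))
  v <- integrate_membrane(c(i_tilde, rep(0, tail_n)), params, dt_us)
  ba <- channel_basis(v, w)
  bc <- channel_basis(-v, w)

  floor_uv <- params$threshold_floor_frac * params$mean_threshold
  mu_a <- params$mean_threshold + state$R + state$A - state$F_a
  mu_c <- params$mean_threshold + state$R + state$A - state$F_c
  th_a <- draw_thresholds(1, mu_a, params$threshold_sd, floor_uv)
  th_c <- draw_thresholds(1, mu_c, params$threshold_sd, floor_uv)

  refractory <- (onset_ms - state$last_spike_ms) < params$abs_refractory_ms
  t_spk <- if (refractory) NA_real_ else
    decide_spikes(1, th_a, th_c, ba, bc, dt_us, params)

  leading <- if (i_tilde[which(i_tilde != 0)[1]] > 0) "anodic" else "cathodic"
  if (!is.na(t_spk)) {
    state$last_spike_ms <- onset_ms + t_spk / 1000
    state$R <- state$R + params$refractory_increment
    state$A <- state$A + params$adaptation_increment
    list(spike = TRUE, latency_us = t_spk,
         spike_time_ms = onset_ms + t_spk / 1000, state = state)
  } else {
    if (leading == "anodic") {
      state$F_a <- state$F_a + params$facilitation_decrement
    } else {
      state$F_c <- state$F_c + params$facilitation_decrement
    }
    list(spike = FALSE, latency_us = NA_real_,
         spike_time_ms = NA_real_, state = state)
  }
}

#' Simulate a pulse train over a population of fibers
#'
#' Runs the fine-grain schedule over all fibers at once. Because the membrane
#' integrator is linear and fully decays between pulses (12.5 ms spacing
#' versus a sub-millisecond membrane time constant), the per-unit-charge
#' membrane trace is computed once per leading polarity and scaled per fiber
#' by `charge * 10^(-2 d / 20)`; threshold draws, crossing search, critical-
#' period commitment and latency are vectorized over fibers. Refractoriness,
#' adaptation and facilitation state is carried across pulses.
#'
#' @param schedule A [fine_grain_schedule()].
#' @param distances_mm Stimulating-electrode-to-fiber distances, one per
#'   fiber (mm).
#' @param params A [fiber_params()].
#' @param seed Integer seed; runs are reproducible given the seed.
#' @param dt_us Simulation time step in µs.
#' @return A data frame of class `spike_train` with columns `fiber`, `slot`,
#'   `time_ms` (absolute spike time) and `latency_us` (relative to the
#'   pulse onset).
#' @export
simulate_train <- function(schedule, distances_mm, params, seed = 1,
                           dt_us = attr(schedule, "params")$dt_us %||% 1) {
  stopifnot(inherits(schedule, "fine_grain_schedule"),
            inherits(params, "fiber_params"), all(distances_mm >= 0))
  sp <- attr(schedule, "params")
  n <- length(distances_mm)
  set.seed(seed)

  w <- round(params$critical_period_us / dt_us)
  tail_n <- max(w + 1L, round(120 / dt_us))
  unit <- make_biphasic_pulse(pulse_spec(1, sp$phase_duration_us, sp$ipg_us,
                                         "anodic", dt_us))
  v_unit <- integrate_membrane(c(unit, rep(0, tail_n)), params, dt_us)
  basis_pos <- channel_basis(v_unit, w)    # positive excursion of anodic-leading
  basis_neg <- channel_basis(-v_unit, w)   # negative excursion

  atten <- attenuation_factor(distances_mm)
  floor_uv <- params$threshold_floor_frac * params$mean_threshold
  state <- new_fiber_state(n, time_ms = 0)

  res_fiber <- vector("list", nrow(schedule))
  res_time <- vector("list", nrow(schedule))
  res_lat <- vector("list", nrow(schedule))
  for (p in seq_len(nrow(schedule))) {
    onset <- schedule$onset_ms[p]
    q <- schedule$charge_nc[p]
    pol <- schedule$polarity[p]
    state <- decay_state(state, onset, params)
    if (q <= 0) next

    mu_a <- params$mean_threshold + state$R + state$A - state$F_a
    mu_c <- params$mean_threshold + state$R + state$A - state$F_c
    th_a <- draw_thresholds(n, mu_a, params$threshold_sd, floor_uv)
    th_c <- draw_thresholds(n, mu_c, params$threshold_sd, floor_uv)
    s <- q * atten

    # the anodic threshold channel sees the positive membrane excursion;
    # swapping the leading polarity mirrors the trace
    if (pol == "anodic") {
      t_spk <- decide_spikes(s, th_a, th_c, basis_pos, basis_neg, dt_us, params)
    } else {
      t_spk <- decide_spikes(s, th_a, th_c, basis_neg, basis_pos, dt_us, params)
    }
    t_spk[(onset - state$last_spike_ms) < params$abs_refractory_ms] <- NA_real_

    spiked <- !is.na(t_spk)
    if (any(spiked)) {
      state$last_spike_ms[spiked] <- onset + t_spk[spiked] / 1000
      state$R[spiked] <- state$R[spiked] + params$refractory_increment
      state$A[spiked] <- state$A[spiked] + params$adaptation_increment
      res_fiber[[p]] <- which(spiked)
      res_time[[p]] <- onset + t_spk[spiked] / 1000
      res_lat[[p]] <- t_spk[spiked]
    }
    sub <- !spiked & s > 0
    if (pol == "anodic") {
      state$F_a[sub] <- state$F_a[sub] + params$facilitation_decrement
    } else {
      state$F_c[sub] <- state$F_c[sub] + params$facilitation_decrement
    }
  }

  slot_rep <- rep(schedule$slot, vapply(res_fiber, length, 1L))
  out <- data.frame(fiber = unlist(res_fiber) %||% integer(0),
                    slot = slot_rep %||% integer(0),
                    time_ms = unlist(res_time) %||% numeric(0),
                    latency_us = unlist(res_lat) %||% numeric(0))
  class(out) <- c("spike_train", "data.frame")
  out
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Export a spike train as CSV
#'
#' @param spikes A `spike_train` data frame.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_spike_train_csv <- function(spikes, path) {
  utils::write.csv(as.data.frame(spikes), path, row.names = FALSE)
  invisible(path)
}
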