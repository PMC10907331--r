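# Test parameters: dt = 0.5 us keeps the Monte-Carlo loops fast; the mean
# threshold is set near the committable drive of the test pulses so that the
# probability checks straddle the steep part of the psychometric function.
mc_params <- function(...) {
  fiber_params(mean_threshold = 18, ...)
}

test_that("current attenuation follows 2 dB/mm", {
  i <- c(0, 5, -5, 0)
  expect_equal(attenuate_current(i, 0), i)
  expect_equal(attenuate_current(i, 10), i * 0.1)
  expect_equal(attenuate_current(i, 1), i * 10^(-0.1))
  expect_equal(attenuation_factor(c(0, 1, 10)), c(1, 10^(-0.1), 0.1))
})

test_that("membrane integration is a linear first-order low-pass", {
  p <- fiber_params()
  expect_equal(integrate_membrane(rep(0, 100), p), rep(0, 100))

  step <- integrate_membrane(rep(10, 500), p, dt_us = 1)
  expect_true(all(diff(step) > -1e-12))          # monotone saturating rise
  expect_lt(step[500] - step[499], step[2] - step[1])

  x <- sin(seq(0, 5, length.out = 200))
  expect_equal(integrate_membrane(2 * x, p), 2 * integrate_membrane(x, p),
               tolerance = 1e-12)

  # zero input decays exponentially from the initial state
  dec <- integrate_membrane(rep(0, 10), p, dt_us = 1, v0 = 5)
  expect_equal(dec, 5 * exp(-(1:10) / p$membrane_tau_us), tolerance = 1e-12)

  expect_error(integrate_membrane(c(1, NA, 2), p), "non-finite")
})

test_that("zero-amplitude pulses leave the fiber untouched", {
  p <- mc_params()
  st <- new_fiber_state(1)
  r <- simulate_pulse_response(rep(0, 100), p, st)
  expect_false(r$spike)
  expect_equal(r$state$F_a, 0)
  expect_equal(r$state$F_c, 0)
  expect_equal(r$state$A, 0)
})

test_that("far-suprathreshold pulses always spike, subthreshold facilitate", {
  p <- mc_params()
  i <- attenuate_current(make_biphasic_pulse(pulse_spec(60, dt_us = 0.5)), 0)
  set.seed(1)
  spikes <- replicate(1000, simulate_pulse_response(i, p, dt_us = 0.5)$spike)
  expect_equal(mean(spikes), 1)  # drive is far beyond mean + 6 sd

  # clearly subthreshold: no spike, leading-polarity facilitation applied
  i_small <- attenuate_current(make_biphasic_pulse(pulse_spec(0.2, dt_us = 0.5)), 0)
  r <- simulate_pulse_response(i_small, p, dt_us = 0.5)
  expect_false(r$spike)
  expect_equal(r$state$F_a, p$facilitation_decrement)
  expect_equal(r$state$F_c, 0)
})

test_that("spike probability matches the truncated-normal CDF oracle", {
  p <- mc_params()
  w <- round(p$critical_period_us / 0.5)
  floor_uv <- p$threshold_floor_frac * p$mean_threshold
  set.seed(7)
  for (q in c(5, 7.5, 10)) {
    i <- make_biphasic_pulse(pulse_spec(q, dt_us = 0.5))
    v <- integrate_membrane(c(i, rep(0, 240)), p, dt_us = 0.5)
    m_a <- brute_commit_drive(v, w)
    m_c <- brute_commit_drive(-v, w)
    p_th <- 1 -
      (1 - trunc_norm_cdf(m_a, p$mean_threshold, p$threshold_sd, floor_uv)) *
      (1 - trunc_norm_cdf(m_c, p$mean_threshold, p$threshold_sd, floor_uv))
    hits <- replicate(1000, simulate_pulse_response(i, p, dt_us = 0.5)$spike)
    se <- sqrt(max(p_th * (1 - p_th), 1e-4) / 1000)
    expect_lt(abs(mean(hits) - p_th), 3.5 * se + 1e-3)
  }
})

test_that("a longer inter-phase gap raises near-threshold spike probability", {
  p <- mc_params()
  prob <- function(ipg, q) {
    i <- make_biphasic_pulse(pulse_spec(q, ipg_us = ipg, dt_us = 0.5))
    mean(replicate(1000, simulate_pulse_response(i, p, dt_us = 0.5)$spike))
  }
  set.seed(11)
  p_short <- prob(2.1, 7.5)
  p_long <- prob(30, 7.5)
  expect_gt(p_long, p_short)
})

test_that("spike latency is monotone non-increasing in charge", {
  # near-deterministic thresholds isolate the latency map
  p <- mc_params(threshold_sd = 1e-9)
  lat <- vapply(seq(14, 40, by = 1), function(q) {
    i <- make_biphasic_pulse(pulse_spec(q, dt_us = 0.5))
    simulate_pulse_response(i, p, dt_us = 0.5)$latency_us
  }, numeric(1))
  expect_true(all(!is.na(lat)))
  expect_true(all(diff(lat) <= 1e-9))
  expect_gt(lat[1], lat[length(lat)])
})

test_that("no spike can occur during absolute refractoriness", {
  p <- mc_params(threshold_sd = 1e-9)
  i <- make_biphasic_pulse(pulse_spec(30, dt_us = 0.5))
  r1 <- simulate_pulse_response(i, p, dt_us = 0.5, onset_ms = 0)
  expect_true(r1$spike)
  r2 <- simulate_pulse_response(i, p, r1$state, onset_ms = 0.2, dt_us = 0.5)
  expect_false(r2$spike)  # 0.2 ms < 0.5 ms absolute refractory period
  r3 <- simulate_pulse_response(i, p, r2$state, onset_ms = 12.5, dt_us = 0.5)
  expect_true(r3$spike)
  expect_error(simulate_pulse_response(i, p, r3$state, onset_ms = 1),
               "forward in time")
})

test_that("anodic and cathodic leading polarities are statistically identical", {
  p <- mc_params()
  prob <- function(lead) {
    i <- make_biphasic_pulse(pulse_spec(7.5, leading = lead, dt_us = 0.5))
    mean(replicate(1500, simulate_pulse_response(i, p, dt_us = 0.5)$spike))
  }
  set.seed(5)
  pa <- prob("anodic"); pc <- prob("cathodic")
  expect_lt(abs(pa - pc), 3.5 * sqrt(2 * 0.25 / 1500) + 1e-3)
})

test_that("threshold spread scales with the threshold standard deviation", {
  # 10-90% dynamic range of the single-fiber psychometric function roughly
  # doubles when the threshold SD is doubled (normal-CDF oracle prediction)
  dyn_range <- function(sd_uv) {
    p <- mc_params(threshold_sd = sd_uv)
    w <- round(p$critical_period_us / 0.5)
    floor_uv <- p$threshold_floor_frac * p$mean_threshold
    qs <- seq(2, 20, by = 0.25)
    probs <- vapply(qs, function(q) {
      i <- make_biphasic_pulse(pulse_spec(q, dt_us = 0.5))
      v <- integrate_membrane(c(i, rep(0, 240)), p, dt_us = 0.5)
      1 - (1 - trunc_norm_cdf(brute_commit_drive(v, w), p$mean_threshold,
                              p$threshold_sd, floor_uv)) *
        (1 - trunc_norm_cdf(brute_commit_drive(-v, w), p$mean_threshold,
                            p$threshold_sd, floor_uv))
    }, numeric(1))
    diff(approx(probs, qs, xout = c(0.1, 0.9), ties = "ordered")$y)
  }
  r1 <- dyn_range(2.3)
  r2 <- dyn_range(4.6)
  expect_gt(r2 / r1, 1.6)
  expect_lt(r2 / r1, 2.4)
})

test_that("simulate_train is reproducible and matches the single-fiber path", {
  sched <- fine_grain_schedule(max_charge = 30, charge_step = 5, dt_us = 0.5)
  d <- c(0.4, 1.2, 2.5)

  p <- mc_params()
  s1 <- simulate_train(sched, d, p, seed = 3)
  s2 <- simulate_train(sched, d, p, seed = 3)
  expect_identical(s1, s2)

  # all-zero schedule produces no spikes
  s0 <- simulate_train(fine_grain_schedule(max_charge = 0, dt_us = 0.5),
                       d, p, seed = 3)
  expect_equal(nrow(s0), 0)

  # with near-deterministic thresholds the vectorized train must reproduce
  # the per-pulse single-fiber reference, including cross-pulse state
  pd <- mc_params(threshold_sd = 1e-9)
  tr <- simulate_train(sched, d, pd, seed = 1)
  ref <- do.call(rbind, lapply(seq_along(d), function(f) {
    st <- new_fiber_state(1)
    out <- NULL
    for (k in seq_len(nrow(sched))) {
      i <- attenuate_current(
        make_biphasic_pulse(pulse_spec(sched$charge_nc[k],
                                       leading = sched$polarity[k],
                                       dt_us = 0.5)), d[f])
      r <- simulate_pulse_response(i, pd, st, onset_ms = sched$onset_ms[k],
                                   dt_us = 0.5)
      st <- r$state
      if (r$spike) out <- rbind(out, data.frame(fiber = f, slot = sched$slot[k],
                                                time_ms = r$spike_time_ms))
    }
    out
  }))
  ref <- ref[order(ref$slot, ref$fiber), ]
  trs <- tr[order(tr$slot, tr$fiber), ]
  expect_equal(trs$fiber, ref$fiber)
  expect_equal(trs$slot, ref$slot)
  expect_equal(trs$time_ms, ref$time_ms, tolerance = 1e-6)
})

test_that("spike counts grow with the maximum charge", {
  p <- mc_params()
  d <- seq(0.5, 4, length.out = 20)
  counts <- vapply(c(5, 10, 20, 30), function(mx) {
    nrow(simulate_train(fine_grain_schedule(max_charge = mx, charge_step = 1,
                                            dt_us = 0.5), d, p, seed = 9))
  }, numeric(1))
  expect_true(all(diff(counts) > 0))
})

test_that("modified parameters are the documented multiples of the originals", {
  m <- fiber_params(); o <- original_fiber_params()
  expect_equal(m$threshold_sd, 2 * o$threshold_sd)
  # the published modified gains (602.6e-6) are the tripled originals
  # (200.9e-6) to the printed precision of four significant digits
  expect_equal(m$gain_b0, 3 * o$gain_b0, tolerance = 5e-4)
  expect_equal(m$gain_b1, 3 * o$gain_b1, tolerance = 5e-4)
})
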