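#' Specification of a charge-balanced symmetric biphasic pulse
#'
#' @param charge_nc Charge per phase in nC (>= 0).
#' @param phase_duration_us Phase duration in µs (default 40).
#' @param ipg_us Inter-phase gap in µs (default 2.1; the study also uses 30).
#' @param leading Leading polarity, `"anodic"` or `"cathodic"`.
#' @param dt_us Simulation time step in µs (default 0.1, which realizes the
#'   2.1 µs IPG exactly). The IPG is realized to the nearest sample; the
#'   realized value is stored in the pulse.
#' @return An object of class `pulse_spec`.
#' @export
pulse_spec <- function(charge_nc, phase_duration_us = 40, ipg_us = 2.1,
                       leading = c("anodic", "cathodic"), dt_us = 0.1) {
  leading <- match.arg(leading)
  stopifnot(charge_nc >= 0, phase_duration_us > 0, ipg_us >= 0, dt_us > 0)
  if (dt_us > phase_duration_us) stop("dt larger than the phase duration")
  structure(list(charge_nc = charge_nc,
                 phase_duration_us = phase_duration_us,
                 ipg_us = ipg_us, leading = leading, dt_us = dt_us),
            class = "pulse_spec")
}

#' Sample a biphasic current waveform
#'
#' Builds the current waveform of a symmetric charge-balanced biphasic pulse:
#' a first phase of amplitude `charge/phase_duration` with the leading
#' polarity's sign, a zero-current inter-phase gap, and a second phase of
#' equal magnitude and opposite sign. Anodic current is positive. The
#' waveform integrates to zero net charge exactly.
#'
#' @param spec A [pulse_spec()].
#' @return Numeric vector of current samples in µA, one per `dt_us`, with
#'   attributes `dt_us`, `realized_ipg_us` and `duration_us`.
#' @export
make_biphasic_pulse <- function(spec) {
  stopifnot(inherits(spec, "pulse_spec"))
  dt <- spec$dt_us
  n_phase <- max(1L, round(spec$phase_duration_us / dt))
  n_gap <- round(spec$ipg_us / dt)
  amp_ua <- 1000 * spec$charge_nc / (n_phase * dt)   # nC/µs = mA -> µA
  sgn <- if (spec$leading == "anodic") 1 else -1
  i <- c(rep(sgn * amp_ua, n_phase), rep(0, n_gap), rep(-sgn * amp_ua, n_phase))
  attr(i, "dt_us") <- dt
  attr(i, "realized_ipg_us") <- n_gap * dt
  attr(i, "duration_us") <- length(i) * dt
  i
}

#' Fine-grain stimulation schedule with alternating polarity
#'
#' Generates the pulse schedule of the fine-grain AGF paradigm: pulses at
#' `pulse_rate` Hz whose charge ramps from 0 to `max_charge`. At each charge
#' level an anodic-leading and a cathodic-leading pulse are presented in
#' consecutive slots (their eCAP responses are later averaged), so in the
#' default `"pair"` mode the charge increments by `2 * charge_rate /
#' pulse_rate` per polarity pair; a `"slot"` mode increments every slot
#' instead (polarities then differ slightly in charge within a pair). A
#' coarse grid for desk-scale runs is selected by giving `charge_step`
#' explicitly (e.g. 0.25 nC).
#'
#' @param max_charge Maximum charge in nC (default 30).
#' @param charge_rate Charge increase rate in nC/s (default 1.5).
#' @param pulse_rate Pulse rate in Hz (default 80).
#' @param mode `"pair"` (default) or `"slot"` charge incrementation.
#' @param charge_step Optional explicit per-pair charge step in nC (coarse
#'   grid); overrides `charge_rate`.
#' @param phase_duration_us,ipg_us,dt_us Passed to each pulse's [pulse_spec()].
#' @return A data frame of class `fine_grain_schedule` with columns `slot`,
#'   `onset_ms`, `charge_nc`, `polarity`, plus attributes recording the
#'   parameters.
#' @export
fine_grain_schedule <- function(max_charge = 30, charge_rate = 1.5,
                                pulse_rate = 80,
                                mode = c("pair", "slot"),
                                charge_step = NULL,
                                phase_duration_us = 40, ipg_us = 2.1,
                                dt_us = 0.1) {
  mode <- match.arg(mode)
  stopifnot(max_charge >= 0, charge_rate > 0, pulse_rate > 0)
  slot_s <- 1 / pulse_rate
  if (!is.null(charge_step)) {
    stopifnot(charge_step > 0)
    levels <- seq(0, max_charge, by = charge_step)
    if (max(levels) < max_charge) levels <- c(levels, max_charge)
    charge <- rep(levels, each = 2)
  } else if (mode == "pair") {
    step <- 2 * charge_rate / pulse_rate
    levels <- seq(0, max_charge, by = step)
    if (max(levels) < max_charge) levels <- c(levels, max_charge)
    charge <- rep(levels, each = 2)
  } else {
    step <- charge_rate / pulse_rate
    charge <- seq(0, max_charge, by = step)
    if (max(charge) < max_charge) charge <- c(charge, max_charge)
  }
  n <- length(charge)
  polarity <- rep(c("anodic", "cathodic"), length.out = n)
  out <- data.frame(slot = seq_len(n),
                    onset_ms = (seq_len(n) - 1) * slot_s * 1000,
                    charge_nc = pmin(charge, max_charge),
                    polarity = polarity)
  attr(out, "params") <- list(max_charge = max_charge,
                              charge_rate = charge_rate,
                              pulse_rate = pulse_rate, mode = mode,
                              charge_step = charge_step,
                              phase_duration_us = phase_duration_us,
                              ipg_us = ipg_us, dt_us = dt_us)
  class(out) <- c("fine_grain_schedule", "data.frame")
  out
}

#' Recording delay of the eCAP window
#'
#' The eCAP recording window starts `d_R = 145 µs + (i - 2.1 µs)` after pulse
#' onset, where `i` is the inter-phase gap, and has a fixed length of 1.7 ms.
#'
#' @param ipg_us Inter-phase gap in µs.
#' @return Delay from pulse onset in µs.
#' @seealso [recording_window_ms()]
#' @export
recording_delay <- function(ipg_us) {
  stopifnot(all(ipg_us >= 0))
  145 + (ipg_us - 2.1)
}

#' Length of the eCAP recording window
#'
#' @return The fixed window length, 1.7 ms.
#' @export
recording_window_ms <- function() 1.7

#' Export a schedule as CSV
#'
#' @param schedule A [fine_grain_schedule()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_schedule_csv <- function(schedule, path) {
  utils::write.csv(as.data.frame(schedule), path, row.names = FALSE)
  invisible(path)
}
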