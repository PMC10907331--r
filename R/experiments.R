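#' Configuration of the simulation condition grid
#'
#' The default grid crosses neural survival (500/1000/1500/2000 fibers), the
#' two inter-phase gaps (2.1 and 30 µs) and the two electrode-neuron
#' distance profiles, stimulating at contact #6 and recording simultaneously
#' at all other contacts. The default charge grid is the coarse 0.25 nC
#' paradigm (121 levels, each with an anodic- and a cathodic-leading pulse);
#' `schedule_mode = "fine"` selects the full fine-grain ramp
#' (0.0375 nC per polarity pair at 1.5 nC/s, 80 Hz).
#'
#' @param n_fibers Vector of fiber counts.
#' @param ipgs_us Vector of inter-phase gaps in µs.
#' @param profiles Height profiles to simulate.
#' @param stim_electrode Stimulating contact number.
#' @param rec_electrodes Recording contacts (stimulating contact excluded).
#' @param max_charge,charge_rate,pulse_rate See [fine_grain_schedule()].
#' @param schedule_mode `"coarse"` (explicit `charge_step`) or `"fine"`.
#' @param charge_step Charge step of the coarse grid, nC.
#' @param phase_duration_us Phase duration, µs.
#' @param dt_us Fiber-simulation time step, µs (0.1 realizes the 2.1 µs IPG
#'   exactly and sets the membrane scale of the per-sample IIR gains).
#' @param trace_dt_us Sampling step of the recorded eCAP traces, µs (the
#'   unitary response varies on a ms scale, so 1 µs suffices).
#' @param fiber A [fiber_params()].
#' @param geometry_args Extra arguments passed to [geometry_config()]
#'   (e.g. custom height polynomials).
#' @param seed Integer base seed; each condition derives its own sub-seed.
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(n_fibers = c(500, 1000, 1500, 2000),
                              ipgs_us = c(2.1, 30),
                              profiles = c("short", "long"),
                              stim_electrode = 6,
                              rec_electrodes = setdiff(1:12, stim_electrode),
                              max_charge = 30,
                              charge_rate = 1.5,
                              pulse_rate = 80,
                              schedule_mode = c("coarse", "fine"),
                              charge_step = 0.25,
                              phase_duration_us = 40,
                              dt_us = 0.1,
                              trace_dt_us = 1,
                              fiber = fiber_params(),
                              geometry_args = list(),
                              seed = 1) {
  schedule_mode <- match.arg(schedule_mode)
  if (stim_electrode %in% rec_electrodes) {
    stop("stimulating electrode must be excluded from the recording set")
  }
  structure(as.list(environment()), class = "experiment_config")
}

#' Read an experiment configuration from a YAML file
#'
#' Keys mirror the arguments of [experiment_config()]; fiber parameter
#' overrides may be given under a `fiber:` mapping.
#'
#' @param path YAML file path.
#' @return An `experiment_config`.
#' @export
read_experiment_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y)) y <- list()
  if (!is.null(y$fiber)) y$fiber <- do.call(fiber_params, y$fiber)
  do.call(experiment_config, y)
}

condition_seed <- function(base_seed, i) {
  (as.integer(base_seed) * 1009L + 7919L * as.integer(i)) %% 2147483647L
}

#' Simulate one condition of the grid
#'
#' Runs the full pulse schedule for one (n_fibers, profile, IPG) condition:
#' simulates the spike trains of all fibers, assembles the compound eCAP
#' trace at every recording electrode for every pulse, averages each
#' polarity pair and extracts the N1-P2 amplitude, yielding one AGF per
#' recording electrode.
#'
#' @param cfg An [experiment_config()].
#' @param n_fibers,profile,ipg_us The condition.
#' @param seed Seed for this condition's stochastic thresholds.
#' @return Data frame with columns `n_fibers`, `profile`, `ipg_us`,
#'   `electrode`, `charge_nc`, `amplitude_uv`; geometry and schedule
#'   parameters in the `meta` attribute.
#' @export
run_condition <- function(cfg, n_fibers, profile, ipg_us, seed = cfg$seed) {
  gargs <- c(list(n_fibers = n_fibers, height_profile = profile),
             cfg$geometry_args)
  geom <- build_geometry(do.call(geometry_config, gargs))

  sched <- if (cfg$schedule_mode == "coarse") {
    fine_grain_schedule(cfg$max_charge, cfg$charge_rate, cfg$pulse_rate,
                        charge_step = cfg$charge_step,
                        phase_duration_us = cfg$phase_duration_us,
                        ipg_us = ipg_us, dt_us = cfg$dt_us)
  } else {
    fine_grain_schedule(cfg$max_charge, cfg$charge_rate, cfg$pulse_rate,
                        mode = "pair",
                        phase_duration_us = cfg$phase_duration_us,
                        ipg_us = ipg_us, dt_us = cfg$dt_us)
  }

  d_stim <- geom$distances[cfg$stim_electrode, ]
  spikes <- simulate_train(sched, d_stim, cfg$fiber, seed = seed,
                           dt_us = cfg$dt_us)

  d_rec <- geom$distances[cfg$rec_electrodes, , drop = FALSE]
  d_r_us <- recording_delay(ipg_us)
  tdt <- cfg$trace_dt_us
  t_max_ms <- (d_r_us + recording_window_ms() * 1000) / 1000
  win_start <- floor(d_r_us / tdt) + 1L
  win_len <- floor(recording_window_ms() * 1000 / tdt) + 1L

  by_slot <- split(spikes, factor(spikes$slot, levels = sched$slot))
  n_rec <- length(cfg$rec_electrodes)
  urp <- ur_params()

  slot_trace <- function(p) {
    sp <- by_slot[[p]]
    sp$time_ms <- sp$time_ms - sched$onset_ms[p]
    compound_response(sp, d_rec, t_max_ms = t_max_ms, dt_us = tdt,
                      params = urp)
  }

  n_pairs <- nrow(sched) %/% 2L
  out <- vector("list", n_pairs)
  for (k in seq_len(n_pairs)) {
    p1 <- 2L * k - 1L; p2 <- 2L * k
    v <- (slot_trace(p1) + slot_trace(p2)) / 2
    amps <- vapply(seq_len(n_rec), function(e) {
      extract_ecap_amplitude(v[win_start:(win_start + win_len - 1L), e],
                             dt_us = tdt)$amplitude_uv
    }, numeric(1))
    out[[k]] <- data.frame(electrode = cfg$rec_electrodes,
                           charge_nc = sched$charge_nc[p1],
                           amplitude_uv = amps)
  }
  agf <- do.call(rbind, out)
  agf <- data.frame(n_fibers = n_fibers, profile = profile, ipg_us = ipg_us,
                    agf)
  attr(agf, "meta") <- list(
    seed = seed, stim_electrode = cfg$stim_electrode,
    schedule = attr(sched, "params"),
    height_polynomials = geom$config$height_polynomials,
    electrode_x = geom$config$electrode_x,
    n_spikes = nrow(spikes))
  agf
}

#' Run the full condition grid
#'
#' Simulates every (n_fibers, profile, IPG) combination of the
#' configuration. Failures are isolated per condition and reported in the
#' returned object instead of aborting the grid.
#'
#' @param cfg An [experiment_config()].
#' @param verbose Print per-condition progress.
#' @return An object of class `ecap_grid`: `agf` (long data frame over all
#'   conditions and recording electrodes), `errors` (named list of failed
#'   conditions) and `config`.
#' @export
run_grid <- function(cfg, verbose = FALSE) {
  grid <- expand.grid(n_fibers = cfg$n_fibers, profile = cfg$profiles,
                      ipg_us = cfg$ipgs_us, stringsAsFactors = FALSE)
  agfs <- vector("list", nrow(grid))
  errors <- list()
  for (i in seq_len(nrow(grid))) {
    key <- sprintf("n%d_%s_ipg%g", grid$n_fibers[i], grid$profile[i],
                   grid$ipg_us[i])
    if (verbose) message("condition ", key)
    res <- tryCatch(
      run_condition(cfg, grid$n_fibers[i], grid$profile[i], grid$ipg_us[i],
                    seed = condition_seed(cfg$seed, i)),
      error = function(e) e)
    if (inherits(res, "error")) {
      errors[[key]] <- conditionMessage(res)
    } else {
      agfs[[i]] <- res
    }
  }
  structure(list(agf = do.call(rbind, agfs), errors = errors, config = cfg),
            class = "ecap_grid")
}

#' @export
print.ecap_grid <- function(x, ...) {
  n_cond <- nrow(unique(x$agf[c("n_fibers", "profile", "ipg_us")]))
  cat(sprintf("eCAP simulation grid: %d condition(s), %d AGF(s), %d failure(s)\n",
              n_cond,
              nrow(unique(x$agf[c("n_fibers", "profile", "ipg_us", "electrode")])),
              length(x$errors)))
  invisible(x)
}

#' Fit sigmoids to every AGF of a grid
#'
#' @param grid An `ecap_grid` (or its `agf` data frame).
#' @return Data frame with one row per (condition, recording electrode):
#'   fitted parameters, `x0`, `slope`, `threshold` and the `flagged` status.
#' @export
fit_grid <- function(grid) {
  agf <- if (inherits(grid, "ecap_grid")) grid$agf else grid
  keys <- unique(agf[c("n_fibers", "profile", "ipg_us", "electrode")])
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    k <- keys[i, ]
    d <- agf[agf$n_fibers == k$n_fibers & agf$profile == k$profile &
               agf$ipg_us == k$ipg_us & agf$electrode == k$electrode, ]
    f <- fit_sigmoid(d$charge_nc, d$amplitude_uv)
    if (is.null(f$coef)) {
      cbind(k, y0 = NA, B = NA, C = NA, D = NA, z = NA, x0 = NA,
            slope = NA, threshold = NA, flagged = TRUE)
    } else {
      cbind(k, as.data.frame(f$coef), x0 = f$x0, slope = f$slope,
            threshold = f$threshold, flagged = f$flagged)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Electrode-neuron distance difference between the two height profiles
#'
#' Mean, over the electrode contacts, of the difference in distance from the
#' contact to its nearest fiber between the `long` and `short` profiles.
#'
#' @param cfg An [experiment_config()].
#' @param n_fibers Fiber count used to evaluate nearest-fiber distances.
#' @return Mean distance difference in mm.
#' @export
profile_distance_difference <- function(cfg, n_fibers = max(cfg$n_fibers)) {
  g <- function(p) {
    gargs <- c(list(n_fibers = n_fibers, height_profile = p),
               cfg$geometry_args)
    build_geometry(do.call(geometry_config, gargs))
  }
  d_s <- apply(g("short")$distances, 1, min)
  d_l <- apply(g("long")$distances, 1, min)
  mean(d_l - d_s)
}

#' Threshold and slope summary table
#'
#' Long-format table of fitted eCAP thresholds and AGF slopes per condition
#' and recording electrode, together with the mean rate (dB/mm) at which the
#' eCAP threshold grows between the two electrode-neuron distance profiles:
#' the mean over paired (n_fibers, IPG, electrode) cells of
#' `20 log10(threshold_long / threshold_short)` divided by the mean
#' electrode-neuron distance difference between the profiles.
#'
#' @param fits Output of [fit_grid()].
#' @param cfg The [experiment_config()] that produced the fits.
#' @return List with `table` (accepted fits only) and
#'   `threshold_shift_db_per_mm` (NA when only one profile is present).
#' @export
summarize_thresholds_slopes <- function(fits, cfg) {
  tab <- fits[!fits$flagged & !is.na(fits$threshold),
              c("n_fibers", "profile", "ipg_us", "electrode",
                "threshold", "slope")]
  shift <- NA_real_
  if (all(c("short", "long") %in% tab$profile)) {
    s <- tab[tab$profile == "short", ]
    l <- tab[tab$profile == "long", ]
    m <- merge(s, l, by = c("n_fibers", "ipg_us", "electrode"),
               suffixes = c("_short", "_long"))
    m <- m[m$threshold_short > 0 & m$threshold_long > 0, ]
    dd <- profile_distance_difference(cfg)
    shift <- if (dd == 0) 0 else
      mean(20 * log10(m$threshold_long / m$threshold_short)) / dd
  }
  list(table = tab, threshold_shift_db_per_mm = shift)
}

#' IPG-effect summary table
#'
#' For every (n_fibers, profile, recording electrode) with accepted fits for
#' both IPGs, computes the absolute and relative IPG effects from the fitted
#' slopes and the IPG offset from the raw AGFs in log-log scale. Flagged
#' fits propagate as missing values.
#'
#' @param grid An `ecap_grid`.
#' @param fits Output of [fit_grid()] on the same grid.
#' @param offset_range Passed to [ipg_offset()] (`"auto"` or numeric range).
#' @return Data frame with columns `n_fibers`, `profile`, `electrode`,
#'   `absolute`, `relative`, `offset_db`.
#' @export
summarize_ipg_effects <- function(grid, fits, offset_range = "auto") {
  agf <- grid$agf
  ipgs <- sort(unique(fits$ipg_us))
  if (length(ipgs) != 2) stop("need exactly two IPG conditions")
  keys <- unique(fits[c("n_fibers", "profile", "electrode")])
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    k <- keys[i, ]
    pick <- function(df, ipg) {
      df[df$n_fibers == k$n_fibers & df$profile == k$profile &
           df$electrode == k$electrode & df$ipg_us == ipg, ]
    }
    fs <- pick(fits, ipgs[1]); fl <- pick(fits, ipgs[2])
    absolute <- relative <- offset <- NA_real_
    if (nrow(fs) == 1 && nrow(fl) == 1 && !fs$flagged && !fl$flagged) {
      absolute <- fl$slope - fs$slope
      relative <- if (fs$slope > 0) fl$slope / fs$slope else NA_real_
    }
    off <- tryCatch(
      ipg_offset(pick(agf, ipgs[1]), pick(agf, ipgs[2]),
                 range = offset_range),
      error = function(e) NULL)
    if (!is.null(off)) offset <- off$offset_db
    cbind(k, absolute = absolute, relative = relative, offset_db = offset)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Normalized maximum eCAP amplitudes per recording electrode
#'
#' The maximum amplitude of each AGF, normalized by the largest value across
#' recording electrodes within the same (profile, n_fibers, IPG) condition.
#'
#' @param grid An `ecap_grid`.
#' @return Data frame with `n_fibers`, `profile`, `ipg_us`, `electrode`,
#'   `max_amplitude_uv`, `normalized`.
#' @export
summarize_max_amplitudes <- function(grid) {
  agf <- if (inherits(grid, "ecap_grid")) grid$agf else grid
  mx <- stats::aggregate(amplitude_uv ~ n_fibers + profile + ipg_us + electrode,
                         data = agf, FUN = max)
  names(mx)[names(mx) == "amplitude_uv"] <- "max_amplitude_uv"
  grp <- interaction(mx$n_fibers, mx$profile, mx$ipg_us)
  mx$normalized <- mx$max_amplitude_uv / ave(mx$max_amplitude_uv, grp,
                                             FUN = max)
  mx
}

#' Write grid results as CSV with a JSON metadata sidecar
#'
#' @param grid An `ecap_grid`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_grid_csv <- function(grid, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  agf_path <- file.path(dir, "agf.csv")
  utils::write.csv(grid$agf, agf_path, row.names = FALSE)
  meta <- list(seed = grid$config$seed,
               n_fibers = grid$config$n_fibers,
               ipgs_us = grid$config$ipgs_us,
               profiles = grid$config$profiles,
               stim_electrode = grid$config$stim_electrode,
               schedule_mode = grid$config$schedule_mode,
               charge_step = grid$config$charge_step,
               height_polynomials = default_height_polynomials(),
               errors = grid$errors)
  meta_path <- file.path(dir, "agf_meta.yaml")
  yaml::write_yaml(meta, meta_path)
  invisible(c(agf_path, meta_path))
}
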