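#' Default scala-tympani height profiles
#'
#' Two third-order polynomials mapping longitudinal position along the
#' unrolled cochlear duct (mm from the base) to the height of the electrode
#' contact above the neural axis (mm). The `short` profile emulates a 10%
#' quantile of scala-tympani height across temporal bones, the `long` profile
#' a 90% quantile; both stay in the anatomically plausible 0.4--1.4 mm range
#' and the `long` profile lies above the `short` one everywhere. Coefficients
#' are in increasing order (intercept, linear, quadratic, cubic).
#'
#' @return Named list with numeric coefficient vectors `short` and `long`.
#' @export
default_height_polynomials <- function() {
  list(
    short = c(0.75, -0.015, 2.0e-4, -2.0e-6),
    long  = c(1.30, -0.020, 3.0e-4, -3.0e-6)
  )
}

#' Evaluate a cubic height polynomial
#'
#' @param coefs Numeric vector of length 4, increasing powers.
#' @param x Longitudinal positions (mm from the base).
#' @return Heights in mm.
#' @export
eval_height_polynomial <- function(coefs, x) {
  stopifnot(length(coefs) == 4L)
  coefs[1] + coefs[2] * x + coefs[3] * x^2 + coefs[4] * x^3
}

#' Greenwood frequency-position map (human)
#'
#' Maps a position along the cochlea, measured in mm from the base, to its
#' characteristic frequency using Greenwood's function
#' \eqn{F = A (10^{a x} - k)} with \eqn{x} the fractional distance from the
#' apex (A = 165.4 Hz, a = 2.1, k = 0.88).
#'
#' @param position_mm Position from the base, in mm.
#' @param length_mm Cochlear duct length (default 33.9 mm).
#' @param A,a,k Greenwood parameters for the human cochlea.
#' @return Characteristic frequency in Hz.
#' @export
greenwood_frequency <- function(position_mm, length_mm = 33.9,
                                A = 165.4, a = 2.1, k = 0.88) {
  stopifnot(length_mm > 0)
  if (any(position_mm < 0 | position_mm > length_mm)) {
    stop("position must lie in [0, length_mm]")
  }
  x <- (length_mm - position_mm) / length_mm  # fractional distance from apex
  A * (10^(a * x) - k)
}

#' Inverse Greenwood map
#'
#' Converts a characteristic frequency into the corresponding position along
#' the cochlea (mm from the base). Monotonically decreasing in frequency:
#' high frequencies map to the base (0 mm), the lowest audible frequency to
#' the apex (`length_mm`).
#'
#' @param frequency_hz Frequency in Hz, within the human range covered by the
#'   map (about 20 Hz to 20.6 kHz).
#' @inheritParams greenwood_frequency
#' @return Position in mm from the base.
#' @export
inverse_greenwood <- function(frequency_hz, length_mm = 33.9,
                              A = 165.4, a = 2.1, k = 0.88) {
  stopifnot(length_mm > 0)
  f_lo <- A * (1 - k)           # frequency at the apex
  f_hi <- A * (10^a - k)        # frequency at the base
  if (any(frequency_hz < f_lo - 1e-9 | frequency_hz > f_hi + 1e-9)) {
    stop(sprintf("frequency outside the valid range [%.1f, %.1f] Hz",
                 f_lo, f_hi))
  }
  x <- log10(frequency_hz / A + k) / a
  length_mm * (1 - x)
}

#' Geometry configuration for the 2-D implanted cochlea
#'
#' Defines the unrolled 2-D model: cochlear duct length (33.9 mm spanning an
#' angular range of 900 degrees), a lateral-wall array of point-source
#' electrode contacts at fixed longitudinal spacing, the number of equidistant
#' auditory nerve fibers (ANFs) on the neural axis, and the scala-tympani
#' height profile that sets the electrode-neuron distance.
#'
#' Electrode contacts are numbered so that higher numbers are more basal
#' (contact `n_electrodes` sits closest to the base). By default 12 contacts
#' at exactly 2 mm spacing span 4--26 mm from the base so that contact #6
#' lies mid-cochlea. Alternatively, per-contact characteristic frequencies can
#' be supplied and are converted to positions via [inverse_greenwood()].
#'
#' @param cochlear_length Duct length in mm.
#' @param angular_span Angular span of the duct in degrees (bookkeeping only;
#'   the model is unrolled).
#' @param n_electrodes Number of contacts (>= 2).
#' @param electrode_spacing Longitudinal contact spacing in mm.
#' @param n_fibers Number of ANFs, equidistant over the duct.
#' @param height_profile `"short"` or `"long"` electrode-neuron distance
#'   profile.
#' @param height_polynomials List with cubic coefficient vectors `short` and
#'   `long`, see [default_height_polynomials()].
#' @param most_basal_contact_mm Position of the most basal contact (mm from
#'   the base), used when `electrode_cfs` is `NULL`.
#' @param electrode_cfs Optional numeric vector of per-contact characteristic
#'   frequencies (Hz, ordered by contact number); mapped through
#'   [inverse_greenwood()].
#' @return An object of class `geometry_config`.
#' @export
geometry_config <- function(cochlear_length = 33.9,
                            angular_span = 900,
                            n_electrodes = 12,
                            electrode_spacing = 2.0,
                            n_fibers = 2000,
                            height_profile = c("short", "long"),
                            height_polynomials = default_height_polynomials(),
                            most_basal_contact_mm = 4.0,
                            electrode_cfs = NULL) {
  height_profile <- match.arg(height_profile)
  stopifnot(cochlear_length > 0, n_fibers >= 1, n_electrodes >= 2,
            electrode_spacing > 0,
            all(c("short", "long") %in% names(height_polynomials)))

  if (is.null(electrode_cfs)) {
    span <- electrode_spacing * (n_electrodes - 1)
    if (most_basal_contact_mm + span > cochlear_length) {
      stop("electrode array longer than the cochlea")
    }
    # contact k: higher numbers more basal
    x_e <- most_basal_contact_mm + electrode_spacing * (n_electrodes - seq_len(n_electrodes))
  } else {
    stopifnot(length(electrode_cfs) == n_electrodes)
    x_e <- inverse_greenwood(electrode_cfs, length_mm = cochlear_length)
    if (any(x_e < 0 | x_e > cochlear_length)) {
      stop("electrode array longer than the cochlea")
    }
  }

  xs <- seq(0, cochlear_length, length.out = 257)
  h_short <- eval_height_polynomial(height_polynomials$short, xs)
  h_long  <- eval_height_polynomial(height_polynomials$long, xs)
  if (any(h_short <= 0) || any(h_long <= 0)) {
    stop("height polynomials must be strictly positive over the duct")
  }
  h_se <- eval_height_polynomial(height_polynomials$short, x_e)
  h_le <- eval_height_polynomial(height_polynomials$long, x_e)
  if (any(h_le < h_se)) {
    stop("'long' profile must lie at or above 'short' at every contact")
  }

  structure(
    list(cochlear_length = cochlear_length,
         angular_span = angular_span,
         n_electrodes = n_electrodes,
         electrode_spacing = electrode_spacing,
         n_fibers = n_fibers,
         height_profile = height_profile,
         height_polynomials = height_polynomials,
         electrode_x = x_e),
    class = "geometry_config")
}

#' Pairwise Euclidean distances between 2-D point sets
#'
#' @param points_a,points_b Two-column matrices (or data frames) of 2-D
#'   points; rows are points.
#' @return A `nrow(points_a)` x `nrow(points_b)` matrix of distances.
#' @export
euclidean_distances <- function(points_a, points_b) {
  a <- as.matrix(points_a); b <- as.matrix(points_b)
  stopifnot(ncol(a) == 2L, ncol(b) == 2L, nrow(a) >= 1L, nrow(b) >= 1L)
  dx <- outer(a[, 1], b[, 1], "-")
  dy <- outer(a[, 2], b[, 2], "-")
  sqrt(dx^2 + dy^2)
}

#' Build the 2-D cochlear geometry
#'
#' Places the electrode contacts on the selected scala-tympani height profile
#' and `n_fibers` ANFs equidistantly on the neural axis (height 0) over
#' `[0, cochlear_length]`, then computes the Euclidean distance matrix between
#' every contact and every fiber. The same matrix serves as the
#' stimulating-electrode-to-fiber distances (row of the stimulating contact)
#' and the fiber-to-recording-electrode distances (rows of the recording
#' contacts).
#'
#' @param config A [geometry_config()].
#' @return An object of class `cochlear_geometry` with elements
#'   `electrodes` (data frame: electrode, x_mm, height_mm),
#'   `fibers` (data frame: fiber, x_mm),
#'   `distances` (n_electrodes x n_fibers matrix, mm) and `config`.
#' @export
build_geometry <- function(config) {
  stopifnot(inherits(config, "geometry_config"))
  x_e <- config$electrode_x
  h_e <- eval_height_polynomial(config$height_polynomials[[config$height_profile]], x_e)
  x_f <- if (config$n_fibers == 1L) config$cochlear_length / 2 else
    seq(0, config$cochlear_length, length.out = config$n_fibers)

  d <- euclidean_distances(cbind(x_e, h_e), cbind(x_f, 0))
  structure(
    list(
      electrodes = data.frame(electrode = seq_along(x_e), x_mm = x_e,
                              height_mm = h_e),
      fibers = data.frame(fiber = seq_along(x_f), x_mm = x_f),
      distances = d,
      config = config),
    class = "cochlear_geometry")
}

#' @export
print.cochlear_geometry <- function(x, ...) {
  cat("2-D cochlear geometry\n")
  cat(sprintf("  duct length: %.1f mm (%d deg), %d fibers, %d contacts (%s profile)\n",
              x$config$cochlear_length, x$config$angular_span,
              x$config$n_fibers, x$config$n_electrodes,
              x$config$height_profile))
  cat(sprintf("  contacts span %.1f--%.1f mm from base, heights %.2f--%.2f mm\n",
              min(x$electrodes$x_mm), max(x$electrodes$x_mm),
              min(x$electrodes$height_mm), max(x$electrodes$height_mm)))
  invisible(x)
}

#' Export geometry as CSV
#'
#' Writes two CSV files: electrode contacts (electrode, x_mm, height_mm) and
#' fibers (fiber, x_mm).
#'
#' @param geometry A `cochlear_geometry`.
#' @param electrodes_path,fibers_path Output file paths.
#' @return Invisibly, the two paths.
#' @export
write_geometry_csv <- function(geometry, electrodes_path, fibers_path) {
  stopifnot(inherits(geometry, "cochlear_geometry"))
  utils::write.csv(geometry$electrodes, electrodes_path, row.names = FALSE)
  utils::write.csv(geometry$fibers, fibers_path, row.names = FALSE)
  invisible(c(electrodes_path, fibers_path))
}
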