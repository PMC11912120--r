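# Observation model of a frequency-scan transient:
#   S(t) = Sx(t) + N_RF(t) + N_AC(t) + N_w(t)
# where Sx is the noise-free ion signal, N_RF and N_AC are pickup of the
# trap's swept RF drive and auxiliary resonance-ejection AC field, and N_w
# is zero-mean Gaussian white noise. The two interference terms are modelled
# as sinusoids with linear-chirp phases, linearly coupled onto the detector:
#   N_S(t) = beta * A_RF * sin(phi_RF(t)) + gamma * A_AC * sin(phi_AC(t)).

#' Construct a sampled transient
#'
#' Light container for a uniformly sampled 1-D transient with optional mass
#' axis and scan-mode tag.
#'
#' @param intensities Numeric vector, length >= 2.
#' @param sample_rate Sampling rate in Hz (default 1).
#' @param mode Scan-mode tag: `"RF"`, `"AC"` or `"RF+AC"` (or `NA`).
#' @param mass_axis Optional strictly monotone numeric vector (Da), same
#'   length as `intensities`.
#' @param metadata Free-form named list.
#' @return Object of class `ms_spectrum`.
#' @export
ms_spectrum <- function(intensities, sample_rate = 1, mode = NA_character_,
                        mass_axis = NULL, metadata = list()) {
  intensities <- as.numeric(intensities)
  if (length(intensities) < 2L) {
    stop("a spectrum needs at least 2 samples", call. = FALSE)
  }
  if (anyNA(intensities)) stop("intensities contain NA", call. = FALSE)
  if (!is.null(mass_axis)) {
    mass_axis <- as.numeric(mass_axis)
    if (length(mass_axis) != length(intensities)) {
      stop("mass_axis length must match intensities", call. = FALSE)
    }
    dm <- diff(mass_axis)
    if (!(all(dm > 0) || all(dm < 0))) {
      stop("mass_axis must be strictly monotone", call. = FALSE)
    }
  }
  structure(list(intensities = intensities, sample_rate = sample_rate,
                 mode = mode, mass_axis = mass_axis, metadata = metadata),
            class = "ms_spectrum")
}

# Accept either a bare numeric vector or an ms_spectrum.
as_intensities <- function(x) {
  if (inherits(x, "ms_spectrum")) x$intensities else as.numeric(x)
}

# Evaluate expr under a fixed seed without disturbing the caller's RNG state.
.with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' @export
print.ms_spectrum <- function(x, ...) {
  n <- length(x$intensities)
  cat("Transient: ", n, " samples @ ", format(x$sample_rate), " Hz",
      if (!is.na(x$mode)) paste0(", mode ", x$mode) else "", "\n", sep = "")
  if (!is.null(x$mass_axis)) {
    cat("  mass axis ", format(min(x$mass_axis)), " - ",
        format(max(x$mass_axis)), " Da\n", sep = "")
  }
  cat("  intensity range [", format(min(x$intensities)), ", ",
      format(max(x$intensities)), "]\n", sep = "")
  invisible(x)
}

#' @export
length.ms_spectrum <- function(x) length(x$intensities)

#' Define a frequency-scan program
#'
#' Holds the RF/AC sweep endpoints, pickup amplitudes and coupling
#' coefficients that drive interference synthesis. `beta` and `gamma` are
#' the dimensionless coupling coefficients of the RF and AC drive onto the
#' charge detector; `a_rf`, `a_ac` are the drive amplitudes in intensity
#' units at the detector.
#'
#' @param f_rf_initial,f_rf_final RF sweep endpoints, Hz.
#' @param f_ac_initial,f_ac_final AC sweep endpoints, Hz.
#' @param a_rf,a_ac Interference amplitudes (intensity units).
#' @param beta,gamma Dimensionless coupling coefficients.
#' @param duration Scan duration, seconds.
#' @param n_samples Number of samples (>= 2).
#' @param mode `"RF"`, `"AC"` or `"RF+AC"`: which interference terms are
#'   synthesized (the other term is zeroed).
#' @return Object of class `scan_program`.
#' @export
scan_program <- function(f_rf_initial, f_rf_final, f_ac_initial, f_ac_final,
                         a_rf = 1, a_ac = 1, beta = 1, gamma = 1,
                         duration = 1, n_samples = 1000L,
                         mode = c("RF+AC", "RF", "AC")) {
  mode <- match.arg(mode)
  freqs <- c(f_rf_initial, f_rf_final, f_ac_initial, f_ac_final)
  if (any(!is.finite(freqs)) || any(freqs <= 0)) {
    stop("all scan frequencies must be positive", call. = FALSE)
  }
  if (!is.finite(duration) || duration <= 0) {
    stop("duration must be positive", call. = FALSE)
  }
  if (n_samples < 2L) stop("n_samples must be >= 2", call. = FALSE)
  structure(list(f_rf_initial = f_rf_initial, f_rf_final = f_rf_final,
                 f_ac_initial = f_ac_initial, f_ac_final = f_ac_final,
                 a_rf = a_rf, a_ac = a_ac, beta = beta, gamma = gamma,
                 duration = duration, n_samples = as.integer(n_samples),
                 mode = mode),
            class = "scan_program")
}

#' @export
print.scan_program <- function(x, ...) {
  cat("Scan program (", x$mode, "): ", x$n_samples, " samples over ",
      format(x$duration), " s\n", sep = "")
  cat("  RF ", format(x$f_rf_initial), " -> ", format(x$f_rf_final),
      " Hz, coupled amplitude ", format(x$beta * x$a_rf), "\n", sep = "")
  cat("  AC ", format(x$f_ac_initial), " -> ", format(x$f_ac_final),
      " Hz, coupled amplitude ", format(x$gamma * x$a_ac), "\n", sep = "")
  invisible(x)
}

#' Specify a Gaussian ion peak
#'
#' @param center Peak apex, fractional sample index in `[0, n_samples)`.
#' @param width_sigma Gaussian standard deviation, samples (> 0).
#' @param amplitude Apex intensity (>= 0).
#' @param charge_state Positive integer annotation (not used numerically).
#' @return Object of class `peak_spec`.
#' @export
peak_spec <- function(center, width_sigma, amplitude, charge_state = 1L) {
  if (width_sigma <= 0) stop("width_sigma must be > 0", call. = FALSE)
  if (amplitude < 0) stop("amplitude must be >= 0", call. = FALSE)
  if (charge_state < 1) stop("charge_state must be >= 1", call. = FALSE)
  structure(list(center = center, width_sigma = width_sigma,
                 amplitude = amplitude, charge_state = as.integer(charge_state)),
            class = "peak_spec")
}

#' Phase of a linear frequency sweep
#'
#' Phase-continuous chirp phase: the instantaneous frequency runs linearly
#' from `f_initial` to `f_final` over `duration`, and
#' `phi(t) = 2*pi*(f_initial*t + (f_final - f_initial)*t^2/(2*duration))`.
#' A continuous phase scan avoids the jagged waveform edges (periodic
#' baseline spikes) that stepwise frequency programming produces.
#'
#' @param f_initial,f_final Sweep endpoints, Hz (> 0).
#' @param duration Sweep duration, seconds (> 0).
#' @param n_samples Number of samples (>= 2); samples are taken at
#'   `t_k = k*duration/(n_samples-1)`, `k = 0..n_samples-1`.
#' @return Numeric vector of phases in radians, `phi(0) = 0`.
#' @examples
#' phi <- phase_sweep(100, 50, 1, 101)
#' phi[101] / (2 * pi)  # mean frequency x duration = 75
#' @export
phase_sweep <- function(f_initial, f_final, duration, n_samples) {
  if (!is.finite(f_initial) || !is.finite(f_final) ||
      f_initial <= 0 || f_final <= 0) {
    stop("sweep frequencies must be positive", call. = FALSE)
  }
  if (!is.finite(duration) || duration <= 0) {
    stop("duration must be positive", call. = FALSE)
  }
  if (n_samples < 2L) stop("n_samples must be >= 2", call. = FALSE)
  t <- seq(0, duration, length.out = n_samples)
  2 * pi * (f_initial * t + (f_final - f_initial) * t^2 / (2 * duration))
}

#' Synthesize swept RF/AC interference
#'
#' Builds `N_S(t) = beta*A_RF*sin(phi_RF(t)) + gamma*A_AC*sin(phi_AC(t))`
#' with linear-chirp phases over the scan's frequency endpoints. Terms not
#' belonging to the scan mode are zeroed.
#'
#' @param scan A [scan_program()].
#' @return Numeric vector of length `scan$n_samples`.
#' @export
synth_interference <- function(scan) {
  stopifnot(inherits(scan, "scan_program"))
  out <- numeric(scan$n_samples)
  if (scan$mode %in% c("RF", "RF+AC")) {
    phi <- phase_sweep(scan$f_rf_initial, scan$f_rf_final, scan$duration,
                       scan$n_samples)
    out <- out + scan$beta * scan$a_rf * sin(phi)
  }
  if (scan$mode %in% c("AC", "RF+AC")) {
    phi <- phase_sweep(scan$f_ac_initial, scan$f_ac_final, scan$duration,
                       scan$n_samples)
    out <- out + scan$gamma * scan$a_ac * sin(phi)
  }
  out
}

#' Synthesize the noise-free ion signal
#'
#' Sum of Gaussian peaks in sample-index coordinates:
#' `sum_p A_p * exp(-(k - center_p)^2 / (2 * sigma_p^2))`.
#'
#' @param peaks List of [peak_spec()] objects (possibly empty).
#' @param n_samples Signal length.
#' @return Numeric vector of length `n_samples`.
#' @export
synth_clean_signal <- function(peaks, n_samples) {
  if (n_samples < 2L) stop("n_samples must be >= 2", call. = FALSE)
  out <- numeric(n_samples)
  k <- seq_len(n_samples) - 1
  for (p in peaks) {
    stopifnot(inherits(p, "peak_spec"))
    if (p$center < 0 || p$center >= n_samples) {
      stop("peak center ", p$center, " outside [0, ", n_samples, ")",
           call. = FALSE)
    }
    out <- out + p$amplitude * exp(-(k - p$center)^2 / (2 * p$width_sigma^2))
  }
  out
}

#' Simulate a full transient with known truth
#'
#' Composes clean signal, chirped interference and seeded white noise into
#' one transient, retaining every component so that denoising performance
#' can be measured against ground truth.
#'
#' @param peaks List of [peak_spec()] objects.
#' @param scan A [scan_program()]; its `n_samples` fixes the length.
#' @param noise_sigma White-noise standard deviation (>= 0).
#' @param seed Integer RNG seed; identical seeds give bit-identical output.
#' @param mass_range Optional length-2 vector (Da); when supplied, a linear
#'   index-to-mass axis is attached to the spectrum.
#' @return List with `spectrum` (an [ms_spectrum]) and `truth` (class
#'   `simulation_truth`: `clean`, `interference`, `noise`, `noise_sigma`,
#'   `seed`, `peaks`, `scan`).
#' @export
simulate_spectrum <- function(peaks, scan, noise_sigma, seed,
                              mass_range = NULL) {
  stopifnot(inherits(scan, "scan_program"))
  if (!is.finite(noise_sigma) || noise_sigma < 0) {
    stop("noise_sigma must be >= 0", call. = FALSE)
  }
  n <- scan$n_samples
  clean <- synth_clean_signal(peaks, n)
  interference <- synth_interference(scan)
  noise <- .with_seed(as.integer(seed), stats::rnorm(n, 0, noise_sigma))
  mass_axis <- if (!is.null(mass_range)) {
    seq(mass_range[1], mass_range[2], length.out = n)
  }
  spec <- ms_spectrum(clean + interference + noise,
                      sample_rate = (n - 1) / scan$duration,
                      mode = scan$mode, mass_axis = mass_axis,
                      metadata = list(seed = as.integer(seed),
                                      noise_sigma = noise_sigma))
  truth <- structure(list(clean = clean, interference = interference,
                          noise = noise, noise_sigma = noise_sigma,
                          seed = as.integer(seed), peaks = peaks,
                          scan = scan),
                     class = "simulation_truth")
  list(spectrum = spec, truth = truth)
}

#' Default transient profile
#'
#' The study conditions used throughout testing: a 200,000-point RF+AC
#' frequency-scan transient digitized at 2 MHz (0.1 s), carrying a
#' 25--200 kDa linear mass annotation and five Gaussian ion peaks for
#' charge states +1..+5 with decreasing amplitude, positioned where a
#' 150 kDa protein's charge states fall on the mass axis. RF interference
#' sweeps 480 -> 60 kHz ("hundreds to tens of kHz"); the resonance-ejection
#' AC tracks it at half the RF frequency, 240 -> 30 kHz. Coupled
#' interference amplitudes are 0.4 (RF) and 0.15 (AC) intensity units
#' against a unit singly-charged peak, with white noise of sigma 0.05,
#' putting the raw single-charge S/N in the low single digits -- the regime
#' the method targets. The noise window sits in a peak-free stretch of the
#' scan where the RF instantaneous frequency lies in band cD2 and the AC in
#' cD3; the peak window brackets the singly-charged peak.
#'
#' @param n_samples Transient length (default 200000).
#' @return List with `peaks`, `scan`, `noise_sigma`, `mass_range`, and the
#'   default S/N `peak_window`/`noise_window` index ranges.
#' @export
default_profile <- function(n_samples = 200000L) {
  n <- as.integer(n_samples)
  duration <- 0.1 * n / 200000
  # charge states +5..+1 of a 150 kDa analyte on the 25-200 kDa axis
  masses <- 150000 / (5:1)
  centers <- (masses - 25000) / (200000 - 25000) * n
  amps <- c(0.3, 0.45, 0.6, 0.8, 1.0)  # +5 .. +1
  widths <- rep(0.0015 * n, 5)
  peaks <- lapply(1:5, function(i) {
    peak_spec(center = centers[i], width_sigma = widths[i],
              amplitude = amps[i], charge_state = 6L - i)
  })
  scan <- scan_program(f_rf_initial = 4.8e5, f_rf_final = 6e4,
                       f_ac_initial = 2.4e5, f_ac_final = 3e4,
                       a_rf = 1, a_ac = 1, beta = 0.4, gamma = 0.15,
                       duration = duration, n_samples = n, mode = "RF+AC")
  list(peaks = peaks, scan = scan, noise_sigma = 0.05,
       mass_range = c(25000, 200000),
       peak_window = c(floor(0.70 * n), ceiling(0.73 * n)),
       noise_window = c(floor(0.32 * n), ceiling(0.45 * n)))
}
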