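#' Acquisition parameters for dynamic 13C spectroscopy
#'
#' Bundles the RF sampling scheme shared by the simulator, the spectral
#' processor and the kinetic fitter: one low-flip-angle excitation every
#' `tr_s` seconds, `n_transients` transients in total, each transient read
#' out as an FID of `n_points` complex points.
#'
#' Defaults correspond to a slab-selective dynamic acquisition on a 7 T
#' small-animal system: 90 transients, TR 2 s (3 min total), 12 degree
#' excitation, 2048 complex points.
#'
#' @param tr_s Repetition time between transients, seconds.
#' @param flip_deg Excitation flip angle, degrees; must lie in (0, 90).
#' @param n_transients Number of transients (>= 2).
#' @param n_points Complex points per FID (>= 64).
#' @param spectral_width_hz Spectral width (receiver bandwidth), Hz.
#' @param carrier_ppm Transmitter offset in ppm.
#' @param field_mhz_13c Spectrometer 13C frequency in MHz; sets the
#'   Hz-per-ppm conversion (75.4 MHz for a 7 T magnet).
#' @return An object of class `acq_params`.
#' @examples
#' acq <- acq_params()
#' acq$tr_s * (acq$n_transients - 1)  # time-axis span, 178 s
#' @export
acq_params <- function(tr_s = 2, flip_deg = 12, n_transients = 90,
                       n_points = 2048, spectral_width_hz = 4000,
                       carrier_ppm = 173, field_mhz_13c = 75.4) {
  stopifnot(is.numeric(tr_s), length(tr_s) == 1L)
  if (tr_s <= 0) stop("tr_s must be positive")
  if (flip_deg <= 0 || flip_deg >= 90) stop("flip_deg must be in (0, 90)")
  if (n_transients < 2) stop("n_transients must be >= 2")
  if (n_points < 64) stop("n_points must be >= 64")
  if (spectral_width_hz <= 0) stop("spectral_width_hz must be positive")
  structure(list(tr_s = tr_s, flip_deg = flip_deg,
                 n_transients = as.integer(n_transients),
                 n_points = as.integer(n_points),
                 spectral_width_hz = spectral_width_hz,
                 carrier_ppm = carrier_ppm,
                 field_mhz_13c = field_mhz_13c),
            class = "acq_params")
}

#' @export
print.acq_params <- function(x, ...) {
  cat("Dynamic 13C acquisition:\n")
  cat(sprintf("  %d transients, TR %.3g s, flip %.3g deg\n",
              x$n_transients, x$tr_s, x$flip_deg))
  cat(sprintf("  %d points, sw %.5g Hz, carrier %.5g ppm at %.5g MHz\n",
              x$n_points, x$spectral_width_hz, x$carrier_ppm,
              x$field_mhz_13c))
  invisible(x)
}

#' Kinetic parameters of the unidirectional three-pool model
#'
#' Generative truth and estimand of the precursor-product model: pyruvate
#' converts irreversibly to lactate (rate `k_pl_per_s`, LDH-mediated) and to
#' alanine (rate `k_pa_per_s`, ALT-mediated); each pool additionally loses
#' longitudinal magnetization at an effective rate `r1*_eff_per_s` that
#' excludes both conversion and RF loss (RF loss is accounted for
#' separately from the flip angle and TR).
#'
#' @param k_pl_per_s Pyruvate-to-lactate apparent rate constant, 1/s.
#' @param k_pa_per_s Pyruvate-to-alanine apparent rate constant, 1/s.
#' @param r1p_eff_per_s,r1l_eff_per_s,r1a_eff_per_s Effective longitudinal
#'   decay rates of pyruvate / lactate / alanine, 1/s. Defaults assume
#'   T1 of about 40 s for pyruvate and 30 s for the products at 7 T.
#' @param p0 Initial pyruvate z-magnetization amplitude, arbitrary units.
#' @param t0_s Bolus arrival time relative to the first transient, s.
#' @return An object of class `kinetic_params`.
#' @export
kinetic_params <- function(k_pl_per_s, k_pa_per_s,
                           r1p_eff_per_s = 1 / 40,
                           r1l_eff_per_s = 1 / 30,
                           r1a_eff_per_s = 1 / 30,
                           p0 = 1, t0_s = 0) {
  rates <- c(k_pl_per_s, k_pa_per_s, r1p_eff_per_s, r1l_eff_per_s,
             r1a_eff_per_s)
  if (any(!is.finite(rates)) || any(rates < 0))
    stop("all rates must be finite and >= 0")
  if (p0 <= 0) stop("p0 must be positive")
  if (k_pl_per_s + k_pa_per_s >= 1)
    stop("k_pl_per_s + k_pa_per_s must be < 1 /s for this regime")
  structure(list(k_pl_per_s = k_pl_per_s, k_pa_per_s = k_pa_per_s,
                 r1p_eff_per_s = r1p_eff_per_s,
                 r1l_eff_per_s = r1l_eff_per_s,
                 r1a_eff_per_s = r1a_eff_per_s,
                 p0 = p0, t0_s = t0_s),
            class = "kinetic_params")
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat(sprintf("kPL %.4g /s, kPA %.4g /s; R1eff (P,L,A) = (%.4g, %.4g, %.4g) /s; p0 %.4g, t0 %.4g s\n",
              x$k_pl_per_s, x$k_pa_per_s, x$r1p_eff_per_s,
              x$r1l_eff_per_s, x$r1a_eff_per_s, x$p0, x$t0_s))
  invisible(x)
}

#' Metabolite amplitude time series
#'
#' Per-transient signal amplitudes of pyruvate, lactate and alanine on a
#' common time axis and common (arbitrary) amplitude scale. The fitter's
#' input and the forward model's output.
#'
#' @param times_s Strictly increasing sampling times, s.
#' @param pyruvate,lactate,alanine Amplitude vectors, same length as
#'   `times_s` (length >= 4).
#' @return A `data.frame` with class `metabolite_series`.
#' @export
metabolite_series <- function(times_s, pyruvate, lactate, alanine) {
  n <- length(times_s)
  if (n < 4) stop("a series needs at least 4 time points")
  if (length(pyruvate) != n || length(lactate) != n || length(alanine) != n)
    stop("channel lengths must match times_s")
  if (any(diff(times_s) <= 0)) stop("times_s must be strictly increasing")
  structure(data.frame(time_s = times_s, pyruvate = pyruvate,
                       lactate = lactate, alanine = alanine),
            class = c("metabolite_series", "data.frame"))
}

is_metabolite_series <- function(x) {
  is.data.frame(x) &&
    all(c("time_s", "pyruvate", "lactate", "alanine") %in% names(x))
}

as_metabolite_series <- function(x) {
  if (!is_metabolite_series(x))
    stop("need columns time_s, pyruvate, lactate, alanine")
  metabolite_series(x$time_s, x$pyruvate, x$lactate, x$alanine)
}

deg2rad <- function(deg) deg * pi / 180
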