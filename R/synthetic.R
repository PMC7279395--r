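#' Spectral peak model
#'
#' Per-resonance description used by the synthesizers: chemical shift,
#' Lorentzian linewidth, multiplet pattern and the number of equivalent
#' nuclei contributing to the line (quantification scaling).
#'
#' @param label Metabolite / reference name.
#' @param shift_ppm Center chemical shift, ppm.
#' @param lw_hz Lorentzian full width at half maximum, Hz (> 0).
#' @param multiplet `"singlet"` or `"doublet"`.
#' @param j_hz Scalar coupling for doublets, Hz.
#' @param n_nuclei Equivalent nuclei count (protons for 1H work, 1 for the
#'   13C carbonyl lines).
#' @return Object of class `peak_model`.
#' @export
peak_model <- function(label, shift_ppm, lw_hz,
                       multiplet = c("singlet", "doublet"),
                       j_hz = 0, n_nuclei = 1) {
  multiplet <- match.arg(multiplet)
  if (lw_hz <= 0) stop("lw_hz must be positive")
  if (multiplet == "doublet" && j_hz <= 0)
    stop("doublet requires j_hz > 0")
  structure(list(label = label, shift_ppm = shift_ppm, lw_hz = lw_hz,
                 multiplet = multiplet, j_hz = j_hz,
                 n_nuclei = n_nuclei), class = "peak_model")
}

# component offsets (Hz) and fractional intensities (sum to 1)
.peak_lines <- function(peak) {
  if (peak$multiplet == "singlet")
    list(offset_hz = 0, frac = 1)
  else
    list(offset_hz = c(-peak$j_hz / 2, peak$j_hz / 2), frac = c(0.5, 0.5))
}

#' Default 13C peak table
#'
#' Carbonyl singlets at literature-standard shifts: pyruvate C1 171.0,
#' lactate C1 183.2, alanine C1 176.5 ppm, plus the urea referencing
#' phantom at 163.5 ppm.
#'
#' @param lw_hz Natural linewidth of every line, Hz.
#' @return Named list of [peak_model()]s.
#' @export
default_peaks_13c <- function(lw_hz = 5) {
  list(pyruvate = peak_model("pyruvate", 171.0, lw_hz),
       lactate = peak_model("lactate", 183.2, lw_hz),
       alanine = peak_model("alanine", 176.5, lw_hz),
       urea = peak_model("urea", 163.5, lw_hz))
}

#' Default 1H peak table for ex vivo extracts
#'
#' TMSP reference singlet at 0 ppm (9 equivalent protons) and the methyl
#' doublets of lactate (1.33 ppm) and alanine (1.48 ppm), both J = 7 Hz,
#' 3 protons each.
#'
#' @param lw_hz Linewidth of every line, Hz.
#' @return Named list of [peak_model()]s.
#' @export
default_peaks_1h <- function(lw_hz = 1.5) {
  list(tmsp = peak_model("tmsp", 0.00, lw_hz, n_nuclei = 9),
       lactate = peak_model("lactate", 1.33, lw_hz, "doublet", j_hz = 7,
                            n_nuclei = 3),
       alanine = peak_model("alanine", 1.48, lw_hz, "doublet", j_hz = 7,
                            n_nuclei = 3))
}

#' Synthesize per-transient 13C FIDs from a metabolite series
#'
#' Each transient's FID is a sum of exponentially decaying complex
#' sinusoids — one multiplet per metabolite with total initial amplitude
#' equal to that transient's series value, plus a constant-amplitude urea
#' reference line — with optional i.i.d. circular complex Gaussian noise.
#'
#' @param series A [metabolite_series()]; channel names must match peak
#'   labels.
#' @param acq An [acq_params()]; `n_transients` must equal `nrow(series)`.
#' @param peaks Named list of [peak_model()]s (default
#'   [default_peaks_13c()]); a `urea` entry provides the reference line.
#' @param noise_sd Standard deviation of the complex Gaussian noise added
#'   to each FID point (per real/imaginary component), absolute units of
#'   the series amplitudes.
#' @param urea_amplitude Constant amplitude of the urea line.
#' @param phase0_deg Zero-order phase applied to every transient
#'   (exercises the automatic phasing downstream).
#' @param seed Optional integer seed for the noise stream.
#' @return List of [nmr_fid()], one per transient.
#' @export
synthesize_13c_fids <- function(series, acq, peaks = default_peaks_13c(),
                                noise_sd = 0, urea_amplitude = 0.2,
                                phase0_deg = 0, seed = NULL) {
  series <- as_metabolite_series(series)
  stopifnot(inherits(acq, "acq_params"))
  if (nrow(series) != acq$n_transients)
    stop("series length must equal acq$n_transients")
  if (!is.null(seed)) set.seed(seed)

  dwell <- 1 / acq$spectral_width_hz
  t <- (seq_len(acq$n_points) - 1) * dwell
  half_sw_ppm <- acq$spectral_width_hz / 2 / acq$field_mhz_13c
  for (p in peaks) {
    if (abs(p$shift_ppm - acq$carrier_ppm) > half_sw_ppm)
      stop(sprintf("peak '%s' at %.4g ppm is outside the spectral window",
                   p$label, p$shift_ppm))
  }

  # per-peak complex basis signal of unit amplitude
  basis <- lapply(peaks, function(p) {
    lines <- .peak_lines(p)
    f0 <- (p$shift_ppm - acq$carrier_ppm) * acq$field_mhz_13c
    sig <- 0
    for (j in seq_along(lines$offset_hz)) {
      f <- f0 + lines$offset_hz[j]
      sig <- sig + lines$frac[j] * exp(2i * pi * f * t)
    }
    sig * exp(-pi * p$lw_hz * t)
  })

  ph <- exp(1i * deg2rad(phase0_deg))
  met <- intersect(names(peaks), c("pyruvate", "lactate", "alanine"))
  lapply(seq_len(nrow(series)), function(i) {
    sig <- 0
    for (m in met) sig <- sig + series[[m]][i] * basis[[m]]
    if ("urea" %in% names(peaks))
      sig <- sig + urea_amplitude * basis[["urea"]]
    sig <- sig * ph
    if (noise_sd > 0)
      sig <- sig + complex(real = stats::rnorm(length(t), 0, noise_sd),
                           imaginary = stats::rnorm(length(t), 0, noise_sd))
    nmr_fid(sig, dwell, index = i)
  })
}

#' Synthesize an ex vivo 1H spectrum
#'
#' Analytic absorption-mode Lorentzian construction on a ppm grid:
#' alanine and lactate methyl doublets with areas proportional to
#' concentration times proton count, and a TMSP reference singlet of fixed
#' area (reference concentration 1).
#'
#' @param ala_conc,lac_conc Relative concentrations (>= 0).
#' @param peaks Named list of [peak_model()]s (default
#'   [default_peaks_1h()]).
#' @param noise_sd Gaussian noise SD added per intensity point.
#' @param seed Optional integer seed.
#' @param field_mhz_1h Spectrometer 1H frequency, MHz (500 for the ex vivo
#'   system emulated).
#' @param ppm_range Axis limits.
#' @param n_points Grid points.
#' @return A real-intensity [nmr_spectrum()], referenced to TMSP.
#' @export
synthesize_1h_spectrum <- function(ala_conc, lac_conc,
                                   peaks = default_peaks_1h(),
                                   noise_sd = 0, seed = NULL,
                                   field_mhz_1h = 500,
                                   ppm_range = c(-0.5, 2.5),
                                   n_points = 4096) {
  if (ala_conc < 0 || lac_conc < 0)
    stop("concentrations must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  conc <- c(tmsp = 1, lactate = lac_conc, alanine = ala_conc)

  ppm <- seq(ppm_range[2], ppm_range[1], length.out = n_points)  # decreasing
  y <- numeric(n_points)
  for (nm in names(peaks)) {
    p <- peaks[[nm]]
    if (!nm %in% names(conc)) next
    area <- conc[[nm]] * p$n_nuclei        # total area, ppm-axis units
    lines <- .peak_lines(p)
    hwhm_ppm <- (p$lw_hz / 2) / field_mhz_1h
    for (j in seq_along(lines$offset_hz)) {
      c_ppm <- p$shift_ppm + lines$offset_hz[j] / field_mhz_1h
      # unit-area Lorentzian in ppm units
      y <- y + area * lines$frac[j] *
        (hwhm_ppm / pi) / ((ppm - c_ppm)^2 + hwhm_ppm^2)
    }
  }
  if (noise_sd > 0) y <- y + stats::rnorm(n_points, 0, noise_sd)
  nmr_spectrum(ppm, y, referenced = "tmsp")
}
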