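acq <- acq_params()
grid_hz <- acq$spectral_width_hz / acq$n_points

test_that("apodization is the identity at lb = 0 and rejects negative lb", {
  set.seed(1)
  fid <- nmr_fid(complex(real = rnorm(2048), imaginary = rnorm(2048)),
                 dwell_s = 1 / 4000)
  expect_identical(apodize(fid, 0)$samples, fid$samples)
  expect_error(apodize(fid, -1), "lb_hz")
})

test_that("apodizing a constant FID gives a Lorentzian of FWHM lb_hz", {
  fid <- nmr_fid(rep(1 + 0i, acq$n_points), 1 / acq$spectral_width_hz)
  sp <- to_spectrum(apodize(fid, 10), acq)
  fw <- measure_fwhm_hz(nmr_spectrum(sp$ppm, Re(sp$intensity)),
                        acq$field_mhz_13c)
  expect_lt(abs(fw - 10), grid_hz)
})

test_that("apodization reduces spectral noise", {
  set.seed(2)
  noise <- complex(real = rnorm(acq$n_points),
                   imaginary = rnorm(acq$n_points))
  fid <- nmr_fid(noise, 1 / acq$spectral_width_hz)
  sd0 <- sd(Re(to_spectrum(fid, acq)$intensity))
  sd12 <- sd(Re(to_spectrum(apodize(fid, 12), acq)$intensity))
  expect_lt(sd12, sd0)
})

test_that("to_spectrum places frequencies at carrier + f/field and satisfies Parseval", {
  dwell <- 1 / acq$spectral_width_hz
  t <- (seq_len(acq$n_points) - 1) * dwell
  on_res <- nmr_fid(exp(-pi * 10 * t), dwell)
  sp <- to_spectrum(on_res, acq)
  expect_lt(abs(sp$ppm[which.max(Re(sp$intensity))] - acq$carrier_ppm),
            grid_hz / acq$field_mhz_13c)

  f <- 500
  shifted <- nmr_fid(exp(2i * pi * f * t) * exp(-pi * 10 * t), dwell)
  sp2 <- to_spectrum(shifted, acq)
  expect_lt(abs(sp2$ppm[which.max(Re(sp2$intensity))] -
                  (acq$carrier_ppm + f / acq$field_mhz_13c)),
            1.5 * grid_hz / acq$field_mhz_13c)

  # Parseval with the package normalization (2*dwell, half first point)
  x <- shifted$samples
  x[1] <- x[1] / 2
  lhs <- sum(Mod(x)^2)
  rhs <- sum(Mod(sp2$intensity)^2) / (acq$n_points * (2 * dwell)^2)
  expect_equal(lhs, rhs, tolerance = 1e-10)
})

test_that("auto_phase recovers a known zero-order phase within one degree", {
  s <- forward_model(kinetic_params(0.02, 0.008), acq)
  for (phi in c(-170, -37, 0.5, 37, 121)) {
    fid <- synthesize_13c_fids(s, acq, phase0_deg = phi)[[5]]
    ph <- auto_phase(to_spectrum(apodize(fid, 10), acq), phi1 = FALSE)
    expect_lt(abs(ph$phi0_deg - phi), 1)
  }
})

test_that("auto_phase is idempotent and recovers absorption area under mixed phases", {
  s <- forward_model(kinetic_params(0.02, 0.008), acq)
  fid0 <- synthesize_13c_fids(s, acq, phase0_deg = 0)[[5]]
  sp0 <- to_spectrum(apodize(fid0, 10), acq)
  total0 <- sum(Re(sp0$intensity))

  absorption <- auto_phase(sp0)$spectrum     # already-phased real spectrum
  again <- auto_phase(nmr_spectrum(absorption$ppm,
                                   absorption$intensity + 0i),
                      phi1 = TRUE)
  expect_lt(abs(again$phi0_deg), 1)
  expect_lt(abs(again$phi1_deg), 1)

  # mixed zero/first order dephasing of the absorption spectrum
  n <- length(sp0$intensity)
  ramp <- (seq_len(n) - n / 2) / n
  mixed <- nmr_spectrum(sp0$ppm,
                        absorption$intensity *
                          exp(1i * (25 + 40 * ramp) * pi / 180))
  cor <- auto_phase(mixed, phi1 = TRUE)
  expect_gte(sum(cor$spectrum$intensity) / total0, 0.99)
})

test_that("auto_phase refuses an empty spectrum", {
  ppm <- seq(10, -10, length.out = 128)
  expect_error(auto_phase(nmr_spectrum(ppm, complex(128))), "no signal")
})

test_that("ppm referencing removes a known axis shift", {
  s <- forward_model(kinetic_params(0.02, 0.008), acq)
  fid <- synthesize_13c_fids(s, acq)[[3]]
  sp <- auto_phase(to_spectrum(apodize(fid, 10), acq))$spectrum
  step <- grid_hz / acq$field_mhz_13c

  shifted <- nmr_spectrum(sp$ppm + 0.3, sp$intensity)
  cal <- reference_ppm(shifted, "urea", 163.5)
  expect_lt(abs(cal$ppm[which.max(Re(cal$intensity) *
                                    (abs(cal$ppm - 163.5) < 1))] - 163.5),
            step)
  # already calibrated: shift below one grid step
  cal2 <- reference_ppm(cal, "urea", 163.5)
  expect_lt(max(abs(cal2$ppm - cal$ppm)), step)
  expect_error(reference_ppm(sp, "urea", 168), "reference")
})

test_that("referencing stays within 0.05 ppm on noisy spectra", {
  s <- forward_model(kinetic_params(0.02, 0.008), acq)
  set.seed(31)
  errs <- replicate(10, {
    fid <- synthesize_13c_fids(s, acq, noise_sd = 0.002)[[3]]
    sp <- auto_phase(to_spectrum(apodize(fid, 10), acq))$spectrum
    shifted <- nmr_spectrum(sp$ppm + 0.21, sp$intensity)
    cal <- reference_ppm(shifted, "urea", 163.5)
    abs(cal$ppm[1] - sp$ppm[1])
  })
  expect_lt(max(errs), 0.05)
})

test_that("window integration matches the closed-form Lorentzian tail integral", {
  sp <- unit_lorentzian_spectrum(center_ppm = 0, hwhm_ppm = 0.01)
  w <- integration_window("line", -16 * 0.01, 16 * 0.01)
  expect_equal(integrate_window(sp, w), (2 / pi) * atan(16),
               tolerance = 1e-3)
  flat <- nmr_spectrum(sp$ppm, rep(0, length(sp$ppm)))
  expect_equal(integrate_window(flat, w), 0)
  expect_error(integrate_window(sp, integration_window("out", 5, 6)),
               "outside")
})

test_that("integration is linear and additive over disjoint peaks", {
  ppm <- seq(2, -2, length.out = 16384)
  lor <- function(c0) (0.01 / pi) / ((ppm - c0)^2 + 0.01^2)
  w1 <- integration_window("a", -0.7, -0.3)
  w2 <- integration_window("b", 0.3, 0.7)
  s1 <- nmr_spectrum(ppm, lor(-0.5))
  s2 <- nmr_spectrum(ppm, lor(0.5))
  both <- nmr_spectrum(ppm, 2 * lor(-0.5) + lor(0.5))
  for (w in list(w1, w2))
    expect_equal(integrate_window(both, w),
                 2 * integrate_window(s1, w) + integrate_window(s2, w),
                 tolerance = 1e-9)
})

test_that("window areas are insensitive to line broadening for wide windows", {
  wide <- acq_params(spectral_width_hz = 8000, n_points = 8192,
                     carrier_ppm = 170)
  dwell <- 1 / wide$spectral_width_hz
  t <- (seq_len(wide$n_points) - 1) * dwell
  fid <- nmr_fid(exp(-pi * 2 * t), dwell)     # 2 Hz natural width
  # 20 broadened half-widths at the largest lb tested
  w_hz <- 20 * (2 + 12) / 2
  w <- integration_window("line", 170 - w_hz / wide$field_mhz_13c,
                          170 + w_hz / wide$field_mhz_13c)
  areas <- vapply(c(10, 12), function(lb)
    integrate_window(to_spectrum(apodize(fid, lb), wide) |>
                       (\(s) nmr_spectrum(s$ppm, Re(s$intensity)))(), w), 0)
  expect_lt(abs(areas[2] / areas[1] - 1), 0.005)
})

test_that("windows must be disjoint and well formed", {
  expect_error(integration_window("x", 2, 1), "ppm_lo")
  expect_error(default_windows_13c(half_ppm = 4), "overlap")
})
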