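test_that("cohort generation is deterministic under a fixed seed", {
  cfg <- default_cohort_config(n_per_group = 3)
  a <- generate_cohort(cfg, acq_params())
  b <- generate_cohort(cfg, acq_params())
  expect_identical(a, b)

  d1 <- file.path(tempdir(), "coh_a")
  d2 <- file.path(tempdir(), "coh_b")
  write_cohort(a, d1)
  write_cohort(b, d2)
  f1 <- list.files(d1, recursive = TRUE)
  expect_identical(f1, list.files(d2, recursive = TRUE))
  for (f in f1)
    expect_identical(readBin(file.path(d1, f), "raw", 1e7),
                     readBin(file.path(d2, f), "raw", 1e7))
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("zero variance and zero noise reproduce the group-mean model exactly", {
  cfg <- default_cohort_config(n_per_group = 3, noise_sd = 0)
  for (g in names(cfg$groups)) cfg$groups[[g]]$sd[] <- 0
  acq <- acq_params()
  coh <- generate_cohort(cfg, acq)
  for (s in coh$subjects) {
    ref <- forward_model(cfg$groups[[s$group]]$mean, acq)
    expect_equal(s$series$pyruvate, ref$pyruvate, tolerance = 1e-12)
    expect_equal(s$series$lactate, ref$lactate, tolerance = 1e-12)
  }
})

test_that("no generated rate constant is negative and extreme SDs warn", {
  cfg <- default_cohort_config(n_per_group = 5)
  cfg$groups$control$sd["k_pa_per_s"] <- 0.004   # mean 0.0098: mild
  coh <- generate_cohort(cfg, acq_params())
  tru <- coh$manifest$truth
  expect_true(all(tru$k_pl_per_s >= 0 & tru$k_pa_per_s >= 0))

  cfg2 <- default_cohort_config(n_per_group = 1)
  cfg2$groups$control$mean$k_pa_per_s <- 0       # half the mass truncates
  cfg2$groups$control$sd["k_pa_per_s"] <- 0.01
  expect_warning(generate_cohort(cfg2, acq_params()), "truncation")
})

test_that("sampled KC-30 rate constants match the generating group mean", {
  coh <- generate_cohort(default_cohort_config(), acq_params())
  tru <- coh$manifest$truth
  kpl <- tru$k_pl_per_s[tru$group == "kc30"]
  sem <- 4e-4 / sqrt(length(kpl))
  expect_lt(abs(mean(kpl) - 0.0296), 2 * sem)
})

test_that("FID synthesis leaves only the urea line when amplitudes vanish", {
  acq <- acq_params(n_transients = 4)
  s <- metabolite_series(c(0, 2, 4, 6), rep(0, 4), rep(0, 4), rep(0, 4))
  fids <- synthesize_13c_fids(s, acq, noise_sd = 0, urea_amplitude = 0.3)
  sp <- to_spectrum(fids[[1]], acq)
  w <- default_windows_13c()
  # the +/-0.8 ppm window captures (2/pi)atan(2W/lw) ~ 97% of the line
  expect_equal(integrate_window(nmr_spectrum(sp$ppm, Re(sp$intensity)),
                                w$urea) * acq$field_mhz_13c,
               0.3, tolerance = 0.05)
  for (m in c("pyruvate", "lactate", "alanine"))
    expect_lt(abs(integrate_window(nmr_spectrum(sp$ppm, Re(sp$intensity)),
                                   w[[m]])) * acq$field_mhz_13c, 1e-3)
})

test_that("FID noise is reproducible under a seed and peaks must be in-window", {
  acq <- acq_params(n_transients = 4)
  s <- metabolite_series(c(0, 2, 4, 6), 1:4 / 4, 1:4 / 8, 1:4 / 16)
  a <- synthesize_13c_fids(s, acq, noise_sd = 0.01, seed = 9)
  b <- synthesize_13c_fids(s, acq, noise_sd = 0.01, seed = 9)
  expect_identical(a, b)
  bad <- default_peaks_13c()
  bad$lactate <- peak_model("lactate", 260, 5)
  expect_error(synthesize_13c_fids(s, acq, peaks = bad), "lactate")
})

test_that("1H synthesis respects concentrations", {
  sp <- synthesize_1h_spectrum(1.2, 1.2)
  wa <- integration_window("ala", 1.41, 1.55)
  wl <- integration_window("lac", 1.26, 1.40)
  aa <- integrate_window(sp, wa)
  al <- integrate_window(sp, wl)
  expect_equal(aa / al, 1, tolerance = 1e-3)

  sp0 <- synthesize_1h_spectrum(1.0, 0)
  # residual lactate-window signal is alanine tail leakage only (< 0.5%)
  expect_lt(abs(integrate_window(sp0, wl)),
            5e-3 * integrate_window(sp0, wa))
  expect_error(synthesize_1h_spectrum(-1, 1), "concentrations")
})

test_that("cohort directories round-trip through write and read", {
  cfg <- default_cohort_config(n_per_group = 2)
  coh <- generate_cohort(cfg, acq_params())
  d <- file.path(tempdir(), "coh_rt")
  write_cohort(coh, d)
  back <- read_cohort(d)
  expect_equal(length(back$subjects), 6)
  expect_equal(back$subjects[[1]]$series$pyruvate,
               coh$subjects[[1]]$series$pyruvate, tolerance = 1e-12)
  expect_equal(back$manifest$truth$k_pl_per_s,
               coh$manifest$truth$k_pl_per_s, tolerance = 1e-12)
  unlink(d, recursive = TRUE)
})
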