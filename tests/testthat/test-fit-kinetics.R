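acq <- acq_params()

test_that("noiseless series are recovered for all published parameter sets", {
  for (nm in names(table1_sets)) {
    tru <- table1_sets[[nm]]
    s <- forward_model(kinetic_params(tru["k_pl"], tru["k_pa"]), acq)
    f <- fit_kinetics(s, acq)
    expect_true(f$converged)
    expect_equal(unname(f$estimates["k_pl_per_s"]), unname(tru["k_pl"]),
                 tolerance = 1e-6)
    expect_equal(unname(f$estimates["k_pa_per_s"]), unname(tru["k_pa"]),
                 tolerance = 1e-6)
  }
})

test_that("joint and freed-decay modes also recover noiseless truth", {
  s <- forward_model(kinetic_params(0.0224, 0.0076), acq)
  fj <- fit_kinetics(s, acq, mode = "joint")
  expect_equal(unname(fj$estimates["k_pl_per_s"]), 0.0224,
               tolerance = 1e-4)
  expect_equal(unname(fj$estimates["k_pa_per_s"]), 0.0076,
               tolerance = 1e-4)
  ff <- fit_kinetics(s, acq, free_decays = TRUE)
  expect_equal(unname(ff$estimates["k_pl_per_s"]), 0.0224,
               tolerance = 1e-3)
  expect_equal(unname(ff$estimates["r1l_eff_per_s"]), 1 / 30,
               tolerance = 1e-2)
})

test_that("empty product channels give zero rate constants", {
  s <- forward_model(kinetic_params(0, 0), acq)
  f <- fit_kinetics(s, acq)
  expect_equal(unname(f$estimates["k_pl_per_s"]), 0)
  expect_equal(unname(f$estimates["k_pa_per_s"]), 0)
})

test_that("scaling a product channel scales its rate constant (signal units cancel only through p0)", {
  s <- forward_model(kinetic_params(0.02, 0.008), acq)
  f1 <- fit_kinetics(s, acq)
  s$lactate <- s$lactate * 3
  f2 <- fit_kinetics(s, acq)
  expect_equal(unname(f2$estimates["k_pl_per_s"]),
               3 * unname(f1$estimates["k_pl_per_s"]), tolerance = 1e-6)
  expect_equal(unname(f2$estimates["k_pa_per_s"]),
               unname(f1$estimates["k_pa_per_s"]), tolerance = 1e-6)
})

test_that("fitted k_PL increases strictly with generating k_PL", {
  grid <- seq(0.005, 0.04, by = 0.005)
  fitted <- vapply(grid, function(k) {
    s <- forward_model(kinetic_params(k, 0.008), acq)
    unname(fit_kinetics(s, acq)$estimates["k_pl_per_s"])
  }, 0)
  expect_true(all(diff(fitted) > 0))
})

test_that("noisy replicates are unbiased with calibrated intervals at SNR 50", {
  theta <- 12 * pi / 180
  tru <- kinetic_params(0.0125, 0.0098)
  clean <- forward_model(tru, acq)
  set.seed(421)
  res <- t(replicate(100, {
    s <- clean
    for (ch in c("pyruvate", "lactate", "alanine"))
      s[[ch]] <- s[[ch]] + rnorm(nrow(s), 0, 0.02 * sin(theta))
    f <- fit_kinetics(s, acq)
    c(f$estimates[c("k_pl_per_s", "k_pa_per_s")],
      f$se[c("k_pl_per_s", "k_pa_per_s")])
  }))
  expect_lt(abs(median(res[, 1]) / 0.0125 - 1), 0.05)
  expect_lt(abs(median(res[, 2]) / 0.0098 - 1), 0.05)
  expect_gte(mean(abs(res[, 1] - 0.0125) <= 1.96 * res[, 3]), 0.90)
  expect_gte(mean(abs(res[, 2] - 0.0098) <= 1.96 * res[, 4]), 0.90)
})

test_that("degenerate inputs abort with diagnostics", {
  s <- forward_model(kinetic_params(0.02, 0.008), acq)
  s$pyruvate <- rev(sort(s$pyruvate))           # max first: fine
  expect_s3_class(fit_kinetics(s, acq), "kinetic_fit")
  s$pyruvate <- sort(s$pyruvate)                # max at last transient
  expect_error(fit_kinetics(s, acq), "last transient")
  s$pyruvate <- rep(0, nrow(s))
  expect_error(fit_kinetics(s, acq), "no positive signal")
})
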