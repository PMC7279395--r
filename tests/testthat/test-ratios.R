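mk_series <- function(pyr, lac, ala) {
  n <- length(pyr)
  metabolite_series(seq(0, by = 2, length.out = n), pyr, lac, ala)
}

test_that("ratio_over_sum handles symmetric, empty and anchored inputs", {
  s <- mk_series(rep(1, 5), rep(1, 5), rep(0.5, 5))
  r <- ratio_over_sum(s)
  expect_equal(r$lac_pyr, 0.5)

  s0 <- mk_series(rep(1, 5), rep(0, 5), rep(0, 5))
  r0 <- ratio_over_sum(s0)
  expect_equal(r0$lac_pyr, 0)
  expect_equal(r0$ala_pyr, 0)

  # AUC split 26.1 / 73.9 over five transients
  s1 <- mk_series(rep(73.9 / 5, 5), rep(26.1 / 5, 5), rep(0, 5))
  expect_equal(ratio_over_sum(s1)$lac_pyr, 0.261, tolerance = 1e-12)

  expect_error(ratio_over_sum(mk_series(rep(0, 5), rep(0, 5), rep(0, 5))),
               "zero total")
})

test_that("ratios are scale invariant and respond monotonically", {
  s <- mk_series(c(5, 4, 3, 2), c(1, 2, 2, 1), c(.5, .6, .4, .2))
  r <- ratio_over_sum(s)
  s_scaled <- mk_series(s$pyruvate * 7.3, s$lactate * 7.3, s$alanine * 7.3)
  r2 <- ratio_over_sum(s_scaled)
  expect_equal(r2$lac_pyr, r$lac_pyr, tolerance = 1e-12)
  expect_equal(r2$ala_pyr, r$ala_pyr, tolerance = 1e-12)

  more_lac <- mk_series(s$pyruvate, s$lactate + 0.5, s$alanine)
  expect_gt(ratio_over_sum(more_lac)$lac_pyr, r$lac_pyr)
  more_pyr <- mk_series(s$pyruvate + 1, s$lactate, s$alanine)
  expect_lt(ratio_over_sum(more_pyr)$lac_pyr, r$lac_pyr)
})

test_that("negative noise excursions are clipped before summation", {
  s <- mk_series(c(2, 2, 2, 2), c(1, -0.4, 1, 0), c(0, 0, 0, 0))
  r <- ratio_over_sum(s)
  expect_equal(r$auc_lac, 2)           # -0.4 clipped, not subtracted
  expect_gte(r$lac_pyr, 0)
  expect_lte(r$lac_pyr, 1)
})

test_that("ex vivo quantification inverts constructed concentration ratios", {
  eq <- quantify_ex_vivo(synthesize_1h_spectrum(1.5, 1.5))
  expect_equal(eq$ala_lac, 1, tolerance = 0.01)

  two <- quantify_ex_vivo(synthesize_1h_spectrum(2, 1))
  expect_equal(two$ala_lac, 2, tolerance = 0.04)

  none <- quantify_ex_vivo(synthesize_1h_spectrum(1, 0))
  expect_true(is.na(none$ala_lac))
})

test_that("proton-count correction scales TMSP-normalized integrals", {
  sp <- synthesize_1h_spectrum(1, 1)
  corr <- quantify_ex_vivo(sp, proton_correction = TRUE)
  raw <- quantify_ex_vivo(sp, proton_correction = FALSE)
  expect_equal(corr$quants$concentration / raw$quants$concentration,
               rep(3, 2), tolerance = 1e-9)   # 9 TMSP protons / 3 methyl
})

test_that("group-mean Ala/Lac declines across the default cohort", {
  coh <- generate_cohort(default_cohort_config(n_per_group = 4),
                         acq_params())
  means <- vapply(c("control", "kc20", "kc30"), function(g) {
    vals <- vapply(Filter(function(s) s$group == g, coh$subjects),
                   function(s) quantify_ex_vivo(s$h1_spectrum)$ala_lac, 0)
    mean(vals)
  }, 0)
  expect_true(all(diff(means) < 0))
})
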