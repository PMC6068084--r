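test_that("Gibbs energy from Kd follows RT ln Kd", {
  expect_equal(gibbs_from_kd(1, 298.15), 0)
  # published wild-type and R5 Kd values
  expect_equal(gibbs_from_kd(2.22e-10, 298.15) / 1e3, -55.1,
               tolerance = 1e-3)
  expect_equal(gibbs_from_kd(2.03e-12, 293.15) / 1e3, -65.6,
               tolerance = 1e-3)
  expect_error(gibbs_from_kd(0, 298.15), "positive")
  expect_error(gibbs_from_kd(-1e-9, 298.15), "positive")
  # strictly increasing in kd at fixed T
  kd <- 10^seq(-12, -6, 0.5)
  expect_true(all(diff(gibbs_from_kd(kd, 298.15)) > 0))
})

test_that("predict_gibbs reduces to dH - T dS at the reference temperature", {
  tp <- thermo_params(-30e3, 80, -1.5e3)
  expect_equal(predict_gibbs(tp, 293.15), -30e3 - 293.15 * 80)
  # dCp = 0 -> linear in T
  lin <- thermo_params(-40e3, 50, 0)
  Tv <- seq(283.15, 303.15, 5)
  dG <- predict_gibbs(lin, Tv)
  expect_equal(diff(dG, differences = 2), rep(0, 3), tolerance = 1e-10)
  # independent hand evaluation at 303.15 K
  T1 <- 303.15
  hand <- -30e3 - T1 * 80 + (-1.5e3) * (T1 - 293.15) -
    (-1.5e3) * T1 * log(T1 / 293.15)
  expect_equal(predict_gibbs(tp, T1), hand)
})

test_that("van't Hoff fit recovers generating parameters", {
  Tv <- seq(283.15, 303.15, by = 5)
  # noiseless linear case (dCp = 0)
  lin <- thermo_params(-40e3, 50, 0)
  f1 <- vant_hoff_fit(Tv, predict_gibbs(lin, Tv))
  expect_lt(rel_err(f1$dH, -40e3), 1e-8)
  expect_lt(rel_err(f1$dS, 50), 1e-8)
  expect_lt(abs(f1$dCp), 1e-6)
  # curved case
  tp <- thermo_params(-30e3, 80, -1.5e3)
  f2 <- vant_hoff_fit(Tv, predict_gibbs(tp, Tv))
  expect_lt(rel_err(f2$dH, tp$dH), 1e-6)
  expect_lt(rel_err(f2$dS, tp$dS), 1e-6)
  expect_lt(rel_err(f2$dCp, tp$dCp), 1e-6)
  # exactly 3 points interpolate with zero residuals
  f3 <- vant_hoff_fit(Tv[c(1, 3, 5)], predict_gibbs(tp, Tv[c(1, 3, 5)]))
  expect_lt(attr(f3, "rss"), 1e-12)
  expect_error(vant_hoff_fit(Tv[1:2], predict_gibbs(tp, Tv[1:2])),
               "under-determined")
})

test_that("van't Hoff round trip holds over random parameter draws", {
  Tv <- c(283.15, 288.15, 293.15, 298.15, 303.15)
  set.seed(21)
  for (i in 1:20) {
    tp <- thermo_params(runif(1, -80e3, 40e3), runif(1, -100, 300),
                        runif(1, -4e3, 1e3))
    fit <- vant_hoff_fit(Tv, predict_gibbs(tp, Tv))
    expect_lt(rel_err(fit$dH, tp$dH), 1e-6)
    expect_lt(rel_err(fit$dS, tp$dS), 1e-6)
    expect_lt(rel_err(fit$dCp, tp$dCp), 1e-6)
    expect_equal(predict_gibbs(fit, Tv), predict_gibbs(tp, Tv),
                 tolerance = 1e-9)
  }
})

test_that("Eyring fit inverts the Eyring relation", {
  Tv <- c(283.15, 288.15, 293.15, 298.15, 303.15)
  # zero activation enthalpy -> zero slope of ln(kon/T) vs 1/T
  ap0 <- activation_params(0, -60)
  f0 <- eyring_fit(Tv, eyring_kon(ap0, Tv))
  expect_lt(abs(f0$dH_act), 1e-6)
  # exact recovery of a generated pair
  ap <- activation_params(40e3, -60)
  f1 <- eyring_fit(Tv, eyring_kon(ap, Tv))
  expect_lt(rel_err(f1$dH_act, 40e3), 1e-9)
  expect_lt(rel_err(f1$dS_act, -60), 1e-9)
  # kon doubling over the 283.15-303.15 K span pins dH_act near 22.3 kJ/mol
  f2 <- eyring_fit(c(283.15, 303.15), c(1e6, 2e6))
  expect_equal(f2$dH_act / 1e3, 22.3, tolerance = 1e-3)
  expect_error(eyring_fit(298.15, 1e6), "2 distinct")
  expect_error(eyring_fit(Tv, c(-1, 1, 1, 1, 1) * 1e6), "positive")
})

test_that("Eyring round trip holds over random parameter draws", {
  Tv <- c(283.15, 288.15, 293.15, 298.15, 303.15)
  set.seed(22)
  for (i in 1:20) {
    ap <- activation_params(runif(1, -20e3, 80e3), runif(1, -150, 50))
    fit <- eyring_fit(Tv, eyring_kon(ap, Tv))
    expect_lt(abs(fit$dH_act - ap$dH_act), 1e-6 * max(1, abs(ap$dH_act)))
    expect_lt(abs(fit$dS_act - ap$dS_act), 1e-6 * max(1, abs(ap$dS_act)))
  }
})

test_that("fold changes reproduce the published ratios at print precision", {
  kin <- published_kinetics()
  k <- function(v, col) kin[kin$variant == v, col]
  expect_equal(format_fold_change(fold_change(k("K5", "kon"),
                                              k("wild_type", "kon"))), 22)
  expect_equal(format_fold_change(fold_change(k("R5", "kon"),
                                              k("wild_type", "kon"))), 2.9)
  expect_equal(format_fold_change(fold_change(k("D5", "kon"),
                                              k("wild_type", "kon"))), 0.31)
  expect_equal(format_fold_change(fold_change(k("E5", "kon"),
                                              k("wild_type", "kon"))), 0.11)
  expect_equal(format_fold_change(fold_change(k("R5", "koff"),
                                              k("wild_type", "koff"))), 0.03)
  expect_equal(fold_change(3.3, 3.3), 1)
  expect_error(fold_change(1, 0), "positive")
})

test_that("thermodynamic signatures classify by sign with a neutral band", {
  both <- classify_signature(-20e3, 120, 298.15)    # basic-mutant pattern
  expect_equal(both, list(enthalpy = "favorable", entropy = "favorable"))
  wt <- classify_signature(15e3, 200, 298.15)       # wild-type pattern
  expect_equal(wt$enthalpy, "unfavorable")
  expect_equal(wt$entropy, "favorable")
  expect_equal(classify_signature(0, 120)$enthalpy, "neutral")
  expect_equal(classify_signature(-20e3, 1e-5)$entropy, "neutral")
  # tolerance boundary: |T dS| just under 0.1 kJ/mol is neutral
  expect_equal(classify_signature(-20e3, 99 / 298.15, 298.15)$entropy,
               "neutral")
})

test_that("Tm extraction finds the peak of a two-state thermogram", {
  dsc <- generate_dsc_thermogram(tm = 76.8)
  tm <- tm_from_thermogram(dsc$temp_C, dsc$excess_cp)
  expect_lt(abs(tm - 76.8), 0.1)
  expect_false(attr(tm, "edge_warning"))
  # flat baseline -> no-peak error
  expect_error(tm_from_thermogram(seq(30, 90, 1), rep(2, 61)), "no peak")
  # peak at the grid edge -> warning and flag
  ramp <- c(rep(0, 59), 5, 10)
  expect_warning(tm_edge <- tm_from_thermogram(seq(30, 90, 1), ramp),
                 "boundary")
  expect_true(attr(tm_edge, "edge_warning"))
  expect_error(tm_from_thermogram(1:3, c(0, 1, 0)), ">= 5")
})
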