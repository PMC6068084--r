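test_that("blank subtraction removes a constant blank exactly", {
  tr <- simulate_sensorgram(wt_params(),
                            injection_protocol(concentration = 5e-9))
  zero <- sensorgram_trace(tr$times, rep(0, length(tr$times)),
                           0, tr$temperature, tr$t_assoc_start,
                           tr$t_assoc_end)
  expect_equal(blank_subtract(tr, tr)$responses,
               rep(0, length(tr$times)))
  expect_equal(blank_subtract(tr, zero)$responses, tr$responses)
  # known offset b on every point, constant blank b -> original trace
  b <- 3.7
  shifted <- sensorgram_trace(tr$times, tr$responses + b, tr$concentration,
                              tr$temperature, tr$t_assoc_start, tr$t_assoc_end)
  blank <- sensorgram_trace(tr$times, rep(b, length(tr$times)), 0,
                            tr$temperature, tr$t_assoc_start, tr$t_assoc_end)
  out <- blank_subtract(shifted, blank)
  expect_equal(out$responses, tr$responses)
  expect_equal(out$concentration, tr$concentration)  # metadata from sample
  # grid mismatch is an error, never an interpolation
  short <- sensorgram_trace(tr$times[-1], tr$responses[-1], 0,
                            tr$temperature, tr$t_assoc_start, tr$t_assoc_end)
  expect_error(blank_subtract(tr, short), "time grid")
})

test_that("global fit recovers published-rate ground truth from noiseless data", {
  p <- wt_params()
  fit <- global_fit(make_traces(p))
  expect_true(fit$converged)
  expect_lt(rel_err(fit$params$kon, p$kon), 1e-6)
  expect_lt(rel_err(fit$params$koff, p$koff), 1e-6)
  expect_lt(rel_err(fit$params$rmax, p$rmax), 1e-6)
  expect_equal(fit$params$kd, fit$params$koff / fit$params$kon)
  expect_true(all(fit$standard_errors >= 0 | is.na(fit$standard_errors)))
  expect_gte(fit$residual_sum_of_squares, 0)
})

test_that("global fit rejects non-identifiable inputs", {
  p <- wt_params()
  blank_only <- make_traces(p, conc = c(0, 0))
  expect_error(global_fit(blank_only), "concentration > 0")
  tr <- make_traces(p, conc = c(5e-9, 1e-8))
  zeroed <- lapply(tr, function(x) {
    x$responses[] <- 0; x
  })
  expect_error(global_fit(zeroed), "non-identifiable")
  mixed_T <- list(make_traces(wt_params(283.15), conc = 5e-9)[[1]],
                  make_traces(wt_params(298.15), conc = 5e-9)[[1]])
  expect_error(global_fit(mixed_T), "temperature")
})

test_that("global fit warns when the dissociation tail barely decays", {
  slow <- kinetic_params(1e6, 1e-6, 100)   # koff * 600 s = 6e-4 < 1e-3
  expect_warning(fit <- global_fit(make_traces(slow, conc = c(5e-9, 1e-8))),
                 "poorly determined")
  expect_true(fit$koff_poorly_determined)
})

test_that("parameter recovery holds across random rate regimes", {
  set.seed(11)
  for (i in 1:20) {
    p <- kinetic_params(10^runif(1, 5, 8), 10^runif(1, -5, -2),
                        rmax = runif(1, 50, 200))
    # an informative design: concentrations bracketing Kd, phase durations
    # spanning a few binding/unbinding time constants of the draw
    conc <- p$kd * c(0.5, 1, 2, 4)
    t_assoc <- 3 / (p$kon * min(conc) + p$koff)
    traces <- lapply(conc, function(C) {
      prot <- injection_protocol(
        t_assoc_start = 0, t_assoc_end = t_assoc,
        t_end = t_assoc + 3 / p$koff,
        concentration = C, sample_interval = t_assoc / 400)
      simulate_sensorgram(p, prot)
    })
    fit <- global_fit(traces)
    expect_lt(rel_err(fit$params$kon, p$kon), 1e-6)
    expect_lt(rel_err(fit$params$koff, p$koff), 1e-6)
    expect_lt(rel_err(fit$params$rmax, p$rmax), 1e-6)
  }
})

test_that("fit is invariant to trace ordering", {
  traces <- make_traces(wt_params(), noise_sd = 1, seed = 5)
  f1 <- global_fit(traces)
  f2 <- global_fit(rev(traces))
  expect_equal(f1$params$kon, f2$params$kon, tolerance = 1e-9)
  expect_equal(f1$params$koff, f2$params$koff, tolerance = 1e-9)
  expect_equal(f1$residual_sum_of_squares, f2$residual_sum_of_squares,
               tolerance = 1e-9)
})

test_that("standard errors shrink when replicates are added", {
  p <- wt_params()
  med_se <- function(n_rep) {
    ses <- vapply(1:7, function(r) {
      traces <- unlist(lapply(seq_len(n_rep), function(k)
        make_traces(p, noise_sd = 1, seed = 1000 * r + 10 * k)),
        recursive = FALSE)
      global_fit(traces)$standard_errors[["kon"]]
    }, numeric(1))
    median(ses)
  }
  expect_lt(med_se(2), med_se(1))
})

test_that("fit_report rounds to 3 significant figures, Kd as rate ratio", {
  row <- fit_report(kinetic_params(2.48e6, 5.49e-4, 100), "wild_type")
  expect_equal(row$kd_M, 2.21e-10)     # ratio of the rounded rates
  expect_equal(row$kon_M1s1, 2.48e6)
  expect_false("rmax" %in% names(row))
  r5 <- fit_report(kinetic_params(7.19e6, 1.46e-5, 100), "R5")
  expect_equal(r5$kd_M, 2.03e-12)      # matches the published R5 Kd
})
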