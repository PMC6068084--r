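test_that("kinetic_params enforces positivity and derives Kd", {
  p <- kinetic_params(1e6, 1e-3, 100)
  expect_equal(p$kd, 1e-9)
  expect_error(kinetic_params(-1, 1e-3, 100), "kon")
  expect_error(kinetic_params(1e6, 0, 100), "koff")
  expect_error(kinetic_params(1e6, 1e-3, 100, temperature = -1), "temperature")
})

test_that("association closed form has the Langmuir plateau and rate", {
  p <- kinetic_params(1e6, 1e-3, rmax = 100)
  # C = Kd halves the plateau
  prot <- injection_protocol(t_assoc_end = 1e5, t_end = 1e5 + 1,
                             concentration = p$kd)
  r <- simulate_association(p, prot, t = c(0, 1e5))
  expect_equal(r[1], 0)
  expect_equal(r[2], 50, tolerance = 1e-8)
  # kobs = kon C + koff
  prot10 <- injection_protocol(concentration = 1e-8)
  kobs <- 1e6 * 1e-8 + 1e-3
  expect_equal(kobs, 0.011)
  req <- 100 * 1e-8 / (1e-8 + p$kd)
  r2 <- simulate_association(p, prot10, t = 60)
  expect_equal(r2, req * (1 - exp(-kobs * 60)))
  # monotone increasing for C > 0, asymptote below rmax
  rr <- simulate_association(p, prot10, t = 0:120)
  expect_true(all(diff(rr) > 0))
  expect_lt(max(rr), 100)
  expect_error(
    simulate_association(p, injection_protocol(concentration = 5e-9),
                         t = 500),
    "association phase")
})

test_that("dissociation closed form decays with half-life ln2/koff", {
  p <- kinetic_params(1e6, 1.46e-5, 100)   # slowest published koff
  expect_equal(simulate_dissociation(p, r0 = 0, t = 0:600),
               rep(0, 601))
  r600 <- simulate_dissociation(p, r0 = 100, t = 600, t0 = 0)
  expect_equal(r600, 100 * exp(-8.76e-3), tolerance = 1e-12)
  expect_equal(round(r600, 2), 99.13)
  thalf <- log(2) / p$koff
  expect_equal(simulate_dissociation(p, 80, thalf, t0 = 0), 40)
  rr <- simulate_dissociation(p, 100, t = 0:600)
  expect_true(all(diff(rr) < 0))
  expect_error(simulate_dissociation(p, r0 = -1, t = 0), "r0")
})

test_that("closed form matches the ODE oracle to 1e-8 * rmax", {
  grids <- list(seq(0, 720, by = 1), seq(0, 720, by = 0.1)[1:2000])
  cases <- list(
    list(p = wt_params(), C = 5e-9),
    list(p = kinetic_params(5.44e7, 4.37e-4, 80), C = 1.25e-9),
    list(p = kinetic_params(2.79e5, 4.24e-4, 150), C = 1e-8),
    list(p = kinetic_params(7.19e6, 1.46e-5, 100), C = 0))
  for (cs in cases) {
    prot <- injection_protocol(concentration = cs$C)
    for (t in grids) {
      closed <- fabkin:::langmuir_response(cs$p, prot, t)
      ode <- simulate_ode(cs$p, prot, t)
      expect_lt(max(abs(closed - ode)), 1e-8 * cs$p$rmax)
    }
  }
})

test_that("ODE oracle fixed points: zero at C = 0, Req at equilibrium", {
  p <- wt_params()
  prot0 <- injection_protocol(concentration = 0)
  expect_equal(simulate_ode(p, prot0, t = seq(0, 720, 10)),
               rep(0, 73))
  # long association approaches Req
  prot <- injection_protocol(t_assoc_end = 2e5, t_end = 2e5 + 10,
                             concentration = 5e-9)
  req <- p$rmax * 5e-9 / (5e-9 + p$kd)
  expect_equal(simulate_ode(p, prot, t = c(0, 2e5))[2], req,
               tolerance = 1e-7)
})

test_that("Req is increasing in C and approaches rmax", {
  p <- wt_params()
  req <- function(C) p$rmax * C / (C + p$kd)
  C <- 10^seq(-11, -5, 0.5)
  expect_true(all(diff(req(C)) > 0))
  expect_equal(req(1), p$rmax, tolerance = 1e-6)
})

test_that("simulate_sensorgram is continuous, reproducible and calibrated", {
  p <- wt_params()
  prot <- injection_protocol(concentration = 5e-9)
  clean <- simulate_sensorgram(p, prot, noise_sd = 0)
  # continuity at the phase boundary
  i <- which(clean$times == prot$t_assoc_end)
  expect_lt(abs(clean$responses[i + 1] - clean$responses[i]),
            abs(clean$responses[i] - clean$responses[i - 1]) + 1e-6)
  # C = 0, no noise -> flat zero
  flat <- simulate_sensorgram(p, injection_protocol(concentration = 0))
  expect_equal(flat$responses, rep(0, length(flat$times)))
  # seed contract
  a <- simulate_sensorgram(p, prot, noise_sd = 1, seed = 42)
  b <- simulate_sensorgram(p, prot, noise_sd = 1, seed = 42)
  expect_identical(a, b)
  c2 <- simulate_sensorgram(p, prot, noise_sd = 1, seed = 43)
  expect_false(identical(a, c2))
  # noise calibration: residual SD within 10% at n = 1000
  prot_long <- injection_protocol(t_assoc_end = 120, t_end = 1000,
                                  concentration = 5e-9)
  noisy <- simulate_sensorgram(p, prot_long, noise_sd = 1, seed = 7)
  ref <- simulate_sensorgram(p, prot_long, noise_sd = 0)
  s <- sd(noisy$responses - ref$responses)
  expect_gt(s, 0.9); expect_lt(s, 1.1)
})

test_that("simulate_sensorgram leaves the caller's RNG state alone", {
  set.seed(1); before <- .Random.seed
  invisible(simulate_sensorgram(wt_params(),
                                injection_protocol(concentration = 5e-9),
                                noise_sd = 1, seed = 99))
  expect_identical(.Random.seed, before)
})
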