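# Numerical integration of the circuit equations: agreement with the
# closed form, linearity, convergence, edge shaping, trains and noise.

test_that("ideal-step simulation matches the analytic solution pointwise", {
  p <- ref_circuit()
  pr <- step_protocol(tau_p = 0)
  tr <- simulate_step(p, pr)
  post <- tr$t_ms >= pr$t_pre
  ana <- analytic_step_response(p, pr, t_ms = tr$t_ms[post] - pr$t_pre)
  expect_lt(max(abs(tr$J[post] - ana$J)), 1e-6)
  expect_lt(max(abs(tr$U_s[post] - ana$U_s)), 1e-6)
  expect_lt(max(abs(tr$U_t[post] - ana$U_t)), 1e-6)
})

test_that("edge shaping keeps the peak below the ideal instantaneous jump", {
  p <- ref_circuit()
  tr <- simulate_step(p, step_protocol(tau_p = 0.05))
  base <- measure_baseline(tr)
  expect_lt(max(tr$J) - base, 5 / 12.5)
  # steep rise to a maximum after the onset, then slow decay
  i_peak <- which.max(tr$J)
  expect_gt(tr$t_ms[i_peak], 2)
  expect_lt(tr$t_ms[i_peak], 2.5)
})

test_that("zero-amplitude step stays at the holding steady state", {
  tr <- simulate_step(ref_circuit(),
                      step_protocol(U_1 = -80, U_2 = -80, tau_p = 0.05))
  expect_lt(diff(range(tr$J)), 1e-9)
})

test_that("response is linear in the step amplitude", {
  p <- ref_circuit()
  t1 <- simulate_step(p, step_protocol(U_2 = -75, tau_p = 0))
  t2 <- simulate_step(p, step_protocol(U_2 = -70, tau_p = 0))
  base1 <- analytic_step_response(p, step_protocol(tau_p = 0), t_ms = 0)$J_inf_1
  expect_equal(t2$J - base1, 2 * (t1$J - base1), tolerance = 1e-6)
})

test_that("halving the step size changes the solution negligibly", {
  p <- ref_circuit()
  pr <- step_protocol(tau_p = 0.05)
  tr1 <- simulate_step(p, pr, dt_ms = 0.02)
  tr2 <- simulate_step(p, pr, dt_ms = 0.01)
  on_grid <- match(round(tr1$t_ms, 6), round(tr2$t_ms, 6))
  expect_lt(max(abs(tr1$J - tr2$J[on_grid])), 1e-6)
})

test_that("a too-coarse grid is flagged in the metadata", {
  tr <- simulate_step(ref_circuit(), step_protocol(tau_p = 0), dt_ms = 0.2)
  expect_match(tr$meta$warning, "coarse")
})

test_that("noiseless train sweeps are periodic and identical to their mean", {
  p <- ref_circuit()
  tr <- train_protocol(n_pulses = 6, n_average = 3)
  sim <- simulate_train(p, tr, tau_p_ms = 0.05, noise_sigma = 0,
                        dt_ms = 0.02)
  expect_length(sim$sweeps, 3)
  expect_equal(sim$sweeps[[1]]$J, sim$sweeps[[3]]$J, tolerance = 1e-8)
  expect_equal(sim$average$J, sim$sweeps[[2]]$J, tolerance = 1e-8)
})

test_that("sweep averaging suppresses recording noise as 1/sqrt(n)", {
  p <- ref_circuit()
  tr <- train_protocol(n_pulses = 26, n_average = 25)
  s <- 0.02
  clean <- simulate_train(p, tr, tau_p_ms = 0.05, noise_sigma = 0,
                          dt_ms = 0.05)$average$J
  noisy <- simulate_train(p, tr, tau_p_ms = 0.05, noise_sigma = s,
                          seed = 11, dt_ms = 0.05)$average$J
  resid_sd <- sd(noisy - clean)
  expect_lt(abs(resid_sd - s / sqrt(25)) / (s / sqrt(25)), 0.25)
})

test_that("noisy traces are reproducible from the seed", {
  p <- ref_circuit()
  tr <- train_protocol(n_pulses = 3, n_average = 2)
  a <- simulate_train(p, tr, noise_sigma = 0.01, seed = 5, dt_ms = 0.05)
  b <- simulate_train(p, tr, noise_sigma = 0.01, seed = 5, dt_ms = 0.05)
  c <- simulate_train(p, tr, noise_sigma = 0.01, seed = 6, dt_ms = 0.05)
  expect_identical(a$average$J, b$average$J)
  expect_false(identical(a$average$J, c$average$J))
})

test_that("train protocol validation rejects impossible settings", {
  expect_error(train_protocol(duration_ms = 50, rate_hz = 25), "period")
  expect_error(train_protocol(n_pulses = 10, n_average = 20), "n_average")
})
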