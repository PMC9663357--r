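# Windowing, baseline measurement and exponential decomposition.

test_that("decay window starts at the onset for an ideal step", {
  tr <- simulate_step(ref_circuit(), step_protocol(tau_p = 0))
  win <- extract_decay_window(tr, delay_ms = 0)
  expect_equal(win$t_ms[1], 2, tolerance = 0.011)  # onset at t_pre = 2 ms
  expect_equal(max(win$t_ms), 22, tolerance = 1e-9)
})

test_that("default delay excludes the shaped rising edge", {
  tr <- simulate_step(ref_circuit(), step_protocol(tau_p = 0.05))
  win <- extract_decay_window(tr)
  expect_gte(win$t_ms[1], 2 + 4 * 0.05 - 1e-9)
})

test_that("a trace without a step is rejected", {
  flat <- current_trace(seq(0, 10, 0.01), rep(0.5, 1001),
                        meta = list(onset_ms = 2))
  expect_error(extract_decay_window(flat), "no voltage-step transient")
})

test_that("baseline equals the closed-form holding current on clean traces", {
  p <- ref_circuit()
  tr <- simulate_step(p, step_protocol(tau_p = 0.05))
  truth <- analytic_biexp_params(p)$J_inf_1
  expect_equal(measure_baseline(tr), truth, tolerance = 1e-9)
  expect_error(measure_baseline(tr, onset_ms = 0), "pre-step")
})

test_that("baseline on a noisy trace is within the expected standard error", {
  set.seed(3)
  t_ms <- seq(0, 5, 0.01)
  for (i in 1:20) {
    J <- 0.7 + rnorm(length(t_ms), 0, 0.01)
    tr <- current_trace(t_ms, J, meta = list(onset_ms = 5))
    # 1 ms window at dt = 0.01 ms -> 100 samples, SEM = sigma/10
    expect_lt(abs(measure_baseline(tr, tail_ms = 1) - 0.7), 3 * 0.01 / 10)
  }
})

test_that("noiseless fits recover the closed-form transient parameters", {
  set.seed(19)
  for (i in 1:5) {
    p <- random_circuit()
    truth <- analytic_biexp_params(p)
    tr <- simulate_step(p, step_protocol(tau_p = 0.05))
    win <- extract_decay_window(tr)
    fit <- fit_biexponential(win, J_inf_1 = measure_baseline(tr))
    expect_lt(rel_err(fit$J_1, truth$J_1), 1e-3)
    expect_lt(rel_err(fit$J_2, truth$J_2), 1e-3)
    expect_lt(rel_err(fit$tau_1, truth$tau_1), 1e-3)
    expect_lt(rel_err(fit$tau_2, truth$tau_2), 1e-3)
    expect_lt(rel_err(fit$J_inf_2, truth$J_inf_2), 1e-3)
  }
})

test_that("back-extrapolated amplitudes are window-start invariant", {
  p <- ref_circuit()
  tr <- simulate_step(p, step_protocol(tau_p = 0.05))
  J0 <- measure_baseline(tr)
  f1 <- fit_biexponential(extract_decay_window(tr), J_inf_1 = J0)
  f2 <- fit_biexponential(extract_decay_window(tr, delay_ms = 0.7),
                          J_inf_1 = J0)
  expect_lt(rel_err(f2$J_1, f1$J_1), 1e-3)
  expect_lt(rel_err(f2$J_2, f1$J_2), 1e-3)
})

test_that("component relabelling enforces tau_1 as the longer constant", {
  bx <- biexp_params(J_1 = 0.1, J_2 = 0.3, tau_1 = 300, tau_2 = 1500,
                     J_inf_1 = 0.7, J_inf_2 = 0.8)
  expect_equal(bx$tau_1, 1500)
  expect_equal(bx$J_1, 0.3)
  expect_equal(bx$J_2, 0.1)
})

test_that("a mono-exponential input raises the degenerate flag", {
  t_ms <- seq(0, 20, 0.01)
  J <- 0.4 * exp(-t_ms / 1.5) + 0.8
  tr <- current_trace(c(seq(-1, -0.01, 0.01), t_ms), c(rep(0.8, 100), J),
                      meta = list(onset_ms = 0))
  win <- extract_decay_window(tr, delay_ms = 0)
  fit <- fit_biexponential(win, J_inf_1 = 0.8)
  expect_true(fit$diagnostics$degenerate)
})

test_that("mono-exponential fit recovers a pure exponential exactly", {
  t_ms <- seq(0, 20, 0.01)
  J <- 0.4 * exp(-t_ms / 1.5) + 0.8
  tr <- current_trace(c(seq(-1, -0.01, 0.01), t_ms), c(rep(0.8, 100), J),
                      meta = list(onset_ms = 0, tau_p_ms = 0))
  win <- extract_decay_window(tr, delay_ms = 0)
  m <- fit_monoexponential(win)
  expect_equal(m$amplitude, 0.4, tolerance = 1e-6)
  expect_equal(m$tau_us, 1500, tolerance = 1e-6)
  expect_equal(m$offset, 0.8, tolerance = 1e-6)
})

test_that("charge-based total capacitance is recovered in the Tyrode regime", {
  p <- reference_circuit(R_t = 0.001)
  pr <- step_protocol(tau_p = 0)
  tr <- simulate_step(p, pr)
  win <- extract_decay_window(tr, delay_ms = 0.05)
  m <- fit_monoexponential(win, J_inf_1 = measure_baseline(tr), dU_mV = 5)
  expect_lt(rel_err(m$C_total_pF, 120), 0.02)
})

test_that("mono-exponential description of a sucrose-regime trace is flagged", {
  tr <- simulate_step(ref_circuit(), step_protocol(tau_p = 0.05))
  win <- extract_decay_window(tr)
  m <- fit_monoexponential(win, J_inf_1 = measure_baseline(tr), dU_mV = 5)
  expect_true(m$poor_fit)
})
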