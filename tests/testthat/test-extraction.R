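# Element recovery from the six-parameter transient summary.  Closed-form
# ("analytic") summaries isolate the algebra from curve fitting.

tbl2_biexp <- analytic_biexp_params(reference_circuit())
tbl2_gamma <- true_gamma(reference_circuit())

test_that("access resistance is recovered exactly from analytic summaries", {
  expect_equal(access_resistance(tbl2_biexp, -80, -75), 12.5,
               tolerance = 1e-10)
})

test_that("access resistance scales inversely with the current parameters", {
  p2 <- biexp_params(2 * tbl2_biexp$J_1, 2 * tbl2_biexp$J_2,
                     tbl2_biexp$tau_1, tbl2_biexp$tau_2,
                     2 * tbl2_biexp$J_inf_1, 2 * tbl2_biexp$J_inf_2)
  expect_equal(access_resistance(p2, -80, -75), 12.5 / 2, tolerance = 1e-10)
})

test_that("inconsistent current jump is rejected", {
  bad <- biexp_params(-0.3, -0.1, 1500, 300, 0.7, 0.6)
  expect_error(access_resistance(bad, -80, -75), "invalid fit")
})

test_that("surface capacitance and tau_s are recovered exactly", {
  sc <- surface_capacitance(tbl2_biexp, 12.5)
  expect_equal(sc[["C_s"]], 74, tolerance = 1e-10)
  expect_equal(sc[["tau_s"]], 925, tolerance = 1e-10)
})

test_that("combined resistances equal the parallel-resistor identities", {
  cr <- combined_resistances(tbl2_biexp, 12.5, 925, -80, -75)
  expect_equal(cr$R_1, 150 * 15 / 165, tolerance = 1e-10)
  expect_equal(cr$R_2, 150 * 256 / 406, tolerance = 1e-10)
  expect_gt(cr$a, 0); expect_lt(cr$a, 1); expect_gt(cr$b, 1)
  expect_lt(cr$R_1, cr$R_2)
})

test_that("combined resistances round-trip on random analytic circuits", {
  set.seed(23)
  for (i in 1:25) {
    p <- random_circuit()
    bx <- analytic_biexp_params(p)
    R_a <- access_resistance(bx, -80, -75)
    sc <- surface_capacitance(bx, R_a)
    cr <- combined_resistances(bx, R_a, sc[["tau_s"]], -80, -75)
    expect_lt(rel_err(cr$R_1, p$R_ms * p$R_t / (p$R_ms + p$R_t)), 1e-6)
    expect_lt(rel_err(cr$R_2, p$R_ms * (p$R_t + p$R_mt) /
                              (p$R_ms + p$R_t + p$R_mt)), 1e-6)
  }
})

test_that("the k solver finds the curve intersection for the reference circuit", {
  cr <- combined_resistances(tbl2_biexp, 12.5, 925, -80, -75)
  sol <- solve_k_rms(cr, tbl2_gamma)
  expect_equal(sol$k, 46 / 74, tolerance = 1e-8)
  expect_equal(sol$R_ms, 150, tolerance = 1e-8)
  expect_lt(sol$residual, 1e-8 * sol$R_ms^2)
  expect_false(sol$ambiguous)
})

test_that("the k solver agrees with a brute-force curve-intersection scan", {
  set.seed(31)
  for (i in 1:3) {
    p <- random_circuit()
    bx <- analytic_biexp_params(p)
    R_a <- access_resistance(bx, -80, -75)
    sc <- surface_capacitance(bx, R_a)
    cr <- combined_resistances(bx, R_a, sc[["tau_s"]], -80, -75)
    g <- true_gamma(p)
    sol <- solve_k_rms(cr, g)
    # oracle: evaluate both R_ms(k) curves (written out independently
    # here) on a dense k grid and take the point of closest approach,
    # refining around it; the pole of the second curve is excluded
    curve_gap <- function(k) {
      s <- cr$R_1 + cr$R_2 + (cr$R_2 - cr$R_1) * g * k
      rms_a <- (s + sqrt(s^2 - 4 * cr$R_1 * cr$R_2)) / 2
      rms_b <- (g * k - 1) * cr$R_1 * cr$R_12 / (k * cr$R_1 - cr$R_12)
      abs(rms_a - rms_b)
    }
    k_pole <- cr$R_12 / cr$R_1
    ks <- seq(0.05, 3, length.out = 4000)
    ks <- ks[abs(ks - k_pole) > 5e-3 * k_pole]
    k_best <- NA_real_
    for (pass in 1:3) {
      gap <- vapply(ks, curve_gap, numeric(1))
      k_best <- ks[which.min(gap)]
      dk <- ks[2] - ks[1]
      ks <- seq(k_best - dk, k_best + dk, length.out = 4000)
      ks <- ks[ks > 0 & abs(ks - k_pole) > 1e-9 * k_pole]
    }
    expect_lt(rel_err(sol$k, k_best), 5e-4)  # 4 significant digits
  }
})

test_that("all elements are recovered from the reference analytic summary", {
  res <- extract_circuit(tbl2_biexp, -80, -75, gamma_expected = tbl2_gamma)
  expect_lt(rel_err(res$C_t, 46), 1e-8)
  expect_lt(rel_err(res$R_t, 15), 1e-8)
  expect_lt(rel_err(res$R_mt, 241), 1e-8)
  expect_lt(rel_err(res$R_ms, 150), 1e-8)
  expect_equal(res$C_m, res$C_s + res$C_t)
  expect_equal(res$f_t, res$k / (1 + res$k))
})

test_that("tubular fraction is monotone in k and bounded", {
  cr <- combined_resistances(tbl2_biexp, 12.5, 925, -80, -75)
  ks <- seq(0.05, 5, length.out = 30)
  f <- vapply(ks, function(k)
    circuit_elements(k, 150, 74, cr, 1)$f_t, numeric(1))
  expect_true(all(diff(f) > 0))
  expect_true(all(f > 0 & f < 1))
})

test_that("simplified estimator approximates C_t and scales linearly in k_c", {
  cr <- combined_resistances(tbl2_biexp, 12.5, 925, -80, -75)
  ct1 <- tubular_capacitance_simplified(tbl2_biexp, cr$R_1, k_c = 1)
  expect_lt(rel_err(ct1, 46), 0.05)
  ct97 <- tubular_capacitance_simplified(tbl2_biexp, cr$R_1, k_c = 0.97)
  expect_equal(ct97 / ct1, 0.97, tolerance = 1e-12)
  # with the true (inaccessible) R_mt||R_t the same expression is exact
  rmt_rt <- 241 * 15 / (241 + 15)
  ct_exact <- tubular_capacitance_simplified(tbl2_biexp, rmt_rt, k_c = 1)
  expect_lt(rel_err(ct_exact, 46), 1e-8)
})

test_that("reversal voltage is recovered and capacitances ignore it", {
  res <- extract_circuit(tbl2_biexp, -80, -75, gamma_expected = tbl2_gamma)
  expect_lt(rel_err(res$U_rev, -160), 0.01)
  expect_lt(abs(res$diagnostics$U_rev_detail$discrepancy), 1e-6)

  # distinct reversal voltages: estimate becomes a mixture of the two but
  # stays internally consistent, and the capacitances do not move
  p2 <- reference_circuit(U_ms = -150, U_mt = -170)
  bx2 <- analytic_biexp_params(p2)
  res2 <- extract_circuit(bx2, -80, -75, gamma_expected = true_gamma(p2))
  expect_lt(abs(res2$diagnostics$U_rev_detail$discrepancy), 1e-6)
  expect_gt(res2$U_rev, -170); expect_lt(res2$U_rev, -150)
  expect_lt(rel_err(res2$C_s, 74), 1e-8)
  expect_lt(rel_err(res2$C_t, 46), 1e-8)
})

test_that("zero holding current places the reversal voltage at the holding voltage", {
  p <- reference_circuit(U_ms = -80, U_mt = -80)
  bx <- analytic_biexp_params(p)
  R_a <- access_resistance(bx, -80, -75)
  sc <- surface_capacitance(bx, R_a)
  cr <- combined_resistances(bx, R_a, sc[["tau_s"]], -80, -75)
  rev <- reversal_voltage_estimate(bx, R_a, cr$a, -80, -75)
  expect_equal(rev$from_U1, -80, tolerance = 1e-9)
})

test_that("gamma sweep: C_s constant, C_t/f_t errors bounded, exact at true gamma", {
  # mismatch configuration: R_mt = 345 MOhm makes the true gamma ~0.7
  p <- reference_circuit(R_mt = 345)
  bx <- analytic_biexp_params(p)
  tab <- gamma_sensitivity_sweep(bx, seq(0.4, 1.25, by = 0.05),
                                 reference = list(C_t = 46, f_t = 46 / 120))
  expect_false(any(tab$failed))
  expect_lt(diff(range(tab$C_s)) / mean(tab$C_s), 1e-12)
  expect_lte(attr(tab, "max_err_C_t"), 0.04)
  expect_lte(attr(tab, "max_err_f_t"), 0.04)
  at_07 <- which(abs(tab$gamma - 0.7) < 1e-9)
  expect_lt(abs(tab$err_C_t[at_07]), 0.005)
})

test_that("gamma sweep errors vanish when the conductance tie holds at each gamma", {
  for (g in seq(0.4, 1.25, by = 0.17)) {
    p <- reference_circuit(R_mt = (150 / g) * (74 / 46))
    bx <- analytic_biexp_params(p)
    res <- extract_circuit(bx, -80, -75, gamma_expected = g)
    expect_lt(rel_err(res$C_t, 46), 0.005)
    expect_lt(rel_err(res$f_t, 46 / 120), 0.005)
  }
})

test_that("full analytic round trip recovers every element on random circuits", {
  set.seed(101)
  for (i in 1:25) {
    p <- random_circuit()
    bx <- analytic_biexp_params(p)
    res <- extract_circuit(bx, -80, -75, gamma_expected = true_gamma(p))
    for (el in c("R_a", "R_t", "R_ms", "R_mt", "C_s", "C_t"))
      expect_lt(rel_err(res[[el]], p[[el]]), 1e-6)
    expect_lt(res$diagnostics$k_solver$residual, 1e-8 * res$R_ms^2)
  }
})
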