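# Shared fixtures for the test suite: the reference verification circuit
# and a generator of random circuits in the physical (sucrose) regime,
# where the tubular membrane resistance is tied to the surface one through
# a gamma coefficient so that R_mt >> R_t and R_ms >> R_t hold.

ref_circuit <- function(...) reference_circuit(...)

random_circuit <- function() {
  R_a <- runif(1, 5, 25)
  R_t <- runif(1, 10, 80)
  R_ms <- runif(1, 75, 300)
  C_s <- runif(1, 40, 120)
  C_t <- runif(1, 20, 80)
  gamma <- runif(1, 0.5, 1.3)
  R_mt <- (R_ms / gamma) * (C_s / C_t)
  U <- runif(1, -170, -120)
  circuit_params(R_a = R_a, R_t = R_t, R_ms = R_ms, R_mt = R_mt,
                 C_s = C_s, C_t = C_t, U_ms = U, U_mt = U)
}

# independent oracle for the characteristic time constants: polynomial
# root finder on the rate polynomial, no shared code with the package
oracle_time_constants <- function(params) {
  co <- derive_coeffs(params)
  s <- co$k_t / co$tau_t + co$k_st / co$tau_s
  pr <- (co$k_st * co$k_t - co$k_at) / (co$tau_s * co$tau_t)
  lam <- Re(polyroot(c(pr, -s, 1)))
  sort(1 / lam, decreasing = TRUE)
}

# full simulate -> fit -> extract round trip at expected gamma = true gamma
round_trip <- function(params, tau_p = 0.05, dt_ms = 0.01,
                       gamma_expected = true_gamma(params),
                       protocol = step_protocol(tau_p = tau_p)) {
  tr <- simulate_step(params, protocol, dt_ms = dt_ms)
  J0 <- measure_baseline(tr)
  win <- extract_decay_window(tr)
  fit <- fit_biexponential(win, J_inf_1 = J0)
  extract_circuit(fit, U_1 = protocol$U_1, U_2 = protocol$U_2,
                  gamma_expected = gamma_expected)
}

rel_err <- function(est, truth) abs(est - truth) / abs(truth)
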