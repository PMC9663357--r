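# Lumped two-compartment equivalent circuit of a tubulated cardiomyocyte.
#
# Canonical internal units throughout the package: mV, MOhm, pF, nA, us.
# These are mutually consistent (mV/MOhm = nA, MOhm*pF = us), which keeps
# the characteristic polynomial well scaled.  Trace time axes are in ms at
# the user/file boundary; conversions happen exactly once per boundary.

.us_per_ms <- 1000

#' Equivalent-circuit parameters of a tubulated cell
#'
#' Constructs and validates the eight-element lumped equivalent circuit of a
#' cardiomyocyte under whole-cell voltage clamp: the surface membrane
#' (\code{R_ms}, \code{C_s}, reversal voltage \code{U_ms}) and the tubular
#' membrane (\code{R_mt}, \code{C_t}, \code{U_mt}) are coupled through the
#' resistance of the tubule lumens \code{R_t}, and the whole cell is reached
#' through the access resistance \code{R_a} (pipette plus bath path).
#'
#' @param R_a access resistance [MOhm]
#' @param R_t tubular lumen resistance [MOhm]
#' @param R_ms surface membrane resistance [MOhm]
#' @param R_mt tubular membrane resistance [MOhm]
#' @param C_s surface membrane capacitance [pF]
#' @param C_t tubular membrane capacitance [pF]
#' @param U_ms surface membrane reversal voltage [mV]
#' @param U_mt tubular membrane reversal voltage [mV]
#'
#' @return An object of class \code{circuit_params} (a named list of the
#'   eight element values).
#' @examples
#' p <- circuit_params(R_a = 12.5, R_t = 15, R_ms = 150, R_mt = 241,
#'                     C_s = 74, C_t = 46, U_ms = -160, U_mt = -160)
#' derive_coeffs(p)
#' @export
circuit_params <- function(R_a, R_t, R_ms, R_mt, C_s, C_t,
                           U_ms = -160, U_mt = -160) {
  p <- list(R_a = R_a, R_t = R_t, R_ms = R_ms, R_mt = R_mt,
            C_s = C_s, C_t = C_t, U_ms = U_ms, U_mt = U_mt)
  for (nm in c("R_a", "R_t", "R_ms", "R_mt", "C_s", "C_t")) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("circuit element '", nm, "' must be a single positive finite number",
           call. = FALSE)
  }
  for (nm in c("U_ms", "U_mt")) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("reversal voltage '", nm, "' must be a single finite number",
           call. = FALSE)
  }
  structure(p, class = "circuit_params")
}

#' @export
print.circuit_params <- function(x, ...) {
  cat("Equivalent-circuit parameters:\n")
  cat(sprintf("  R_a  = %8.3f MOhm   R_t  = %8.3f MOhm\n", x$R_a, x$R_t))
  cat(sprintf("  R_ms = %8.3f MOhm   R_mt = %8.3f MOhm\n", x$R_ms, x$R_mt))
  cat(sprintf("  C_s  = %8.3f pF     C_t  = %8.3f pF\n", x$C_s, x$C_t))
  cat(sprintf("  U_ms = %8.2f mV     U_mt = %8.2f mV\n", x$U_ms, x$U_mt))
  invisible(x)
}

#' True gamma coefficient of a circuit
#'
#' The proportionality coefficient between the membrane conductance ratio
#' and the capacitance ratio, gamma = (G_mt/G_ms)/(C_t/C_s)
#' = (R_ms/R_mt)*(C_s/C_t).  Extraction of the full circuit from a fitted
#' transient assumes a value for gamma; for a simulated circuit the true
#' value is known and is computed here.
#'
#' @param params a \code{\link{circuit_params}} object
#' @return the dimensionless gamma value
#' @export
true_gamma <- function(params) {
  stopifnot(inherits(params, "circuit_params"))
  (params$R_ms / params$R_mt) * (params$C_s / params$C_t)
}

#' Derived coefficients of the circuit state equations
#'
#' Transforms the eight element values into the coefficients of the two
#' coupled first-order state equations for the surface and tubular membrane
#' voltages: the tubular and surface charging time constants
#' \code{tau_t = R_t*C_t} and \code{tau_s = R_a*C_s} [us], the dimensionless
#' couplings \code{k_t = 1 + R_t/R_mt}, \code{k_st = 1 + R_a/R_ms + R_a/R_t},
#' \code{k_at = R_a/R_t}, and the reversal-voltage drives
#' \code{k_Ut = U_mt*R_t/R_mt}, \code{k_Us = U_ms*R_a/R_ms} [mV].
#'
#' @param params a \code{\link{circuit_params}} object
#' @return An object of class \code{circuit_coeffs}.
#' @export
derive_coeffs <- function(params) {
  stopifnot(inherits(params, "circuit_params"))
  co <- list(
    tau_t = params$R_t * params$C_t,
    tau_s = params$R_a * params$C_s,
    k_t   = 1 + params$R_t / params$R_mt,
    k_st  = 1 + params$R_a / params$R_ms + params$R_a / params$R_t,
    k_at  = params$R_a / params$R_t,
    k_Ut  = params$U_mt * params$R_t / params$R_mt,
    k_Us  = params$U_ms * params$R_a / params$R_ms
  )
  structure(co, class = "circuit_coeffs")
}

#' Characteristic time constants of the circuit
#'
#' Solves the characteristic equation of the two-compartment system,
#' lambda^2 - (k_t/tau_t + k_st/tau_s) lambda
#'          + (k_st k_t - k_at)/(tau_s tau_t) = 0,
#' whose roots are the reciprocals of the two relaxation time constants of
#' any small-step response.  By convention \code{tau_1} is the longer
#' constant.
#'
#' @param coeffs a \code{circuit_coeffs} object from \code{\link{derive_coeffs}}
#' @return named numeric vector \code{c(tau_1 =, tau_2 =)} in us,
#'   with \code{tau_1 >= tau_2}.
#' @export
characteristic_time_constants <- function(coeffs) {
  stopifnot(inherits(coeffs, "circuit_coeffs"))
  if (coeffs$tau_t <= 0 || coeffs$tau_s <= 0)
    stop("degenerate circuit: tau_t and tau_s must be positive", call. = FALSE)
  s <- coeffs$k_t / coeffs$tau_t + coeffs$k_st / coeffs$tau_s
  p <- (coeffs$k_st * coeffs$k_t - coeffs$k_at) / (coeffs$tau_s * coeffs$tau_t)
  disc <- s^2 - 4 * p
  if (disc < 0)
    stop("characteristic equation has non-real roots; ",
         "input coefficients are not physical", call. = FALSE)
  # quadratic solved in the numerically stable form (avoid cancellation)
  r <- sqrt(disc)
  lam_big <- (s + r) / 2
  lam_small <- p / lam_big
  c(tau_1 = 1 / lam_small, tau_2 = 1 / lam_big)
}

# steady-state membrane voltages at a constant command voltage U.
# Re-derived from the state equations (set both derivatives to zero):
#   U_t_inf = (k_Us + k_st*k_Ut + U) / (k_st*k_t - k_at)
#   U_s_inf = k_t*U_t_inf - k_Ut
#           = (k_t*k_Us + k_at*k_Ut + k_t*U) / (k_st*k_t - k_at)
steady_state_voltages <- function(coeffs, U) {
  D <- coeffs$k_st * coeffs$k_t - coeffs$k_at
  U_t <- (coeffs$k_Us + coeffs$k_st * coeffs$k_Ut + U) / D
  U_s <- coeffs$k_t * U_t - coeffs$k_Ut
  list(U_s = U_s, U_t = U_t)
}

#' Rectangular step stimulus descriptor
#'
#' Describes one voltage-clamp step from \code{U_1} to \code{U_2} with an
#' optional first-order lag on the edges (the command voltage follows
#' \code{dU/dt = (U_target - U)/tau_p}), mimicking the finite rise time of
#' an experimental pulse.  \code{tau_p = 0} denotes an ideal step.
#'
#' @param U_1 pre-step (holding) voltage [mV]
#' @param U_2 step voltage [mV]
#' @param t_pre duration of the pre-step segment [ms]
#' @param t_step duration of the step [ms]
#' @param tau_p edge time constant [ms]; 0 = ideal edges
#' @return An object of class \code{step_protocol}.
#' @export
step_protocol <- function(U_1 = -80, U_2 = -75, t_pre = 2, t_step = 20,
                          tau_p = 0.05) {
  if (t_pre <= 0 || t_step <= 0) stop("durations must be positive", call. = FALSE)
  if (tau_p < 0) stop("tau_p must be >= 0", call. = FALSE)
  structure(list(U_1 = U_1, U_2 = U_2, t_pre = t_pre, t_step = t_step,
                 tau_p = tau_p),
            class = "step_protocol")
}

#' Analytic response to an ideal voltage step
#'
#' Closed-form solution of the circuit state equations for an ideal
#' (\code{tau_p = 0}) step from \code{U_1} to \code{U_2}, starting from the
#' steady state at \code{U_1}.  The surface voltage relaxes as
#' \code{U_s(t) = c_1 exp(-t/tau_1) + c_2 exp(-t/tau_2) + U_s_inf}, the
#' measured current is \code{J = (U_2 - U_s)/R_a}, i.e. a bi-exponential
#' decay \code{J = J_1 exp(-t/tau_1) + J_2 exp(-t/tau_2) + J_inf_2} with
#' amplitudes \code{J_i = -c_i/R_a} referenced to the step onset.
#'
#' @param params a \code{\link{circuit_params}} object
#' @param protocol a \code{\link{step_protocol}} with \code{tau_p = 0}
#'   (post-step timing only is used; the returned trajectories start at the
#'   step onset, t = 0)
#' @param t_ms sample times after the onset [ms]; default covers
#'   \code{t_step}
#' @param dt_ms sample interval for the default grid [ms]
#' @return A list of class \code{analytic_step_response} with the sampled
#'   trajectories (\code{t_ms}, \code{U_s}, \code{U_t}, \code{J}) and the
#'   closed-form constants (\code{c_1}, \code{c_2}, \code{tau_1},
#'   \code{tau_2} [us], \code{J_1}, \code{J_2}, \code{J_inf_1},
#'   \code{J_inf_2}).
#' @export
analytic_step_response <- function(params, protocol = step_protocol(tau_p = 0),
                                   t_ms = NULL, dt_ms = 0.01) {
  stopifnot(inherits(params, "circuit_params"),
            inherits(protocol, "step_protocol"))
  if (protocol$tau_p != 0)
    stop("analytic_step_response requires an ideal step (tau_p = 0); ",
         "use simulate_step() for shaped edges", call. = FALSE)
  co <- derive_coeffs(params)
  tau <- characteristic_time_constants(co)
  tau_1 <- tau[["tau_1"]]; tau_2 <- tau[["tau_2"]]
  if (tau_1 == tau_2)
    stop("components indistinguishable: degenerate double root", call. = FALSE)
  if (is.null(t_ms)) t_ms <- seq(0, protocol$t_step, by = dt_ms)
  D <- co$k_st * co$k_t - co$k_at
  dU <- protocol$U_1 - protocol$U_2
  c_1 <- dU / D * (tau_1 * co$k_t - co$tau_t) / (tau_1 - tau_2)
  c_2 <- dU / D * (co$tau_t - tau_2 * co$k_t) / (tau_1 - tau_2)
  ss2 <- steady_state_voltages(co, protocol$U_2)
  ss1 <- steady_state_voltages(co, protocol$U_1)
  t_us <- t_ms * .us_per_ms
  e1 <- exp(-t_us / tau_1); e2 <- exp(-t_us / tau_2)
  U_s <- c_1 * e1 + c_2 * e2 + ss2$U_s
  U_t <- c_1 / (co$k_t - co$tau_t / tau_1) * e1 +
         c_2 / (co$k_t - co$tau_t / tau_2) * e2 + ss2$U_t
  J <- (protocol$U_2 - U_s) / params$R_a
  J_inf_1 <- (protocol$U_1 - ss1$U_s) / params$R_a
  J_inf_2 <- (protocol$U_2 - ss2$U_s) / params$R_a
  structure(list(
    t_ms = t_ms, U_s = U_s, U_t = U_t, J = J,
    c_1 = c_1, c_2 = c_2, tau_1 = tau_1, tau_2 = tau_2,
    J_1 = -c_1 / params$R_a, J_2 = -c_2 / params$R_a,
    J_inf_1 = J_inf_1, J_inf_2 = J_inf_2,
    protocol = protocol
  ), class = "analytic_step_response")
}

#' Exact bi-exponential summary of a circuit's step response
#'
#' Convenience wrapper returning the six transient parameters
#' (J_1, J_2, J_inf_1, J_inf_2, tau_1, tau_2) of the ideal-step response in
#' closed form, as a \code{\link{biexp_params}} object.  This is the exact
#' counterpart of what \code{\link{fit_biexponential}} estimates from a
#' sampled trace, and the natural input for testing the element-recovery
#' formulas in isolation from curve fitting.
#'
#' @inheritParams analytic_step_response
#' @param U_1,U_2 step voltages [mV]
#' @return a \code{\link{biexp_params}} object
#' @export
analytic_biexp_params <- function(params, U_1 = -80, U_2 = -75) {
  r <- analytic_step_response(params,
                              step_protocol(U_1 = U_1, U_2 = U_2, tau_p = 0),
                              t_ms = 0)
  biexp_params(J_1 = r$J_1, J_2 = r$J_2, tau_1 = r$tau_1, tau_2 = r$tau_2,
               J_inf_1 = r$J_inf_1, J_inf_2 = r$J_inf_2)
}
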