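# Numerical voltage-clamp simulator: stiff integration of the circuit state
# equations with first-order shaped pulse edges, pulse trains, additive
# recording noise, and sweep averaging.

# derivative of (U_t, U_s[, U]) on a ms time base; coefficients carry us
# time constants, hence the .us_per_ms factor.
.circuit_rhs <- function(co, tau_p_ms) {
  if (tau_p_ms > 0) {
    function(t, y, parms) {
      U_t <- y[1]; U_s <- y[2]; U <- y[3]
      dUt <- (U_s - co$k_t * U_t + co$k_Ut) / co$tau_t
      dUs <- (-co$k_st * U_s + co$k_at * U_t + co$k_Us + U) / co$tau_s
      dU  <- (parms[["U_target"]] - U) / (tau_p_ms * .us_per_ms)
      list(c(dUt, dUs, dU) * .us_per_ms)
    }
  } else {
    function(t, y, parms) {
      U_t <- y[1]; U_s <- y[2]
      U <- parms[["U_target"]]
      dUt <- (U_s - co$k_t * U_t + co$k_Ut) / co$tau_t
      dUs <- (-co$k_st * U_s + co$k_at * U_t + co$k_Us + U) / co$tau_s
      list(c(dUt, dUs) * .us_per_ms)
    }
  }
}

# integrate one constant-target segment on a given grid (ms), returning the
# state matrix at the grid points.  y0 = c(U_t, U_s[, U]).
.integrate_segment <- function(rhs, y0, times, U_target, rtol, atol) {
  if (length(times) == 1L) return(matrix(y0, nrow = 1))
  out <- deSolve::ode(y = y0, times = times, func = rhs,
                      parms = list(U_target = U_target),
                      method = "lsoda", rtol = rtol, atol = atol)
  unname(as.matrix(out[, -1, drop = FALSE]))
}

#' Simulate the voltage-clamp response to a single rectangular step
#'
#' Integrates the circuit state equations for a step from \code{U_1} to
#' \code{U_2}.  With \code{tau_p > 0} the command voltage is shaped by a
#' first-order lag, \code{dU/dt = (U_target - U)/tau_p}, solved jointly with
#' the membrane equations, reproducing the finite rise/fall edges of real
#' stimulators; the simulated current then rises steeply to a maximum and
#' decays bi-exponentially, as observed experimentally under sucrose
#' superfusion.  The pre-step segment holds the exact steady state at
#' \code{U_1}.
#'
#' @param params a \code{\link{circuit_params}} object
#' @param protocol a \code{\link{step_protocol}}
#' @param dt_ms sample interval [ms]; default 0.01 ms (10 us), which
#'   resolves the fast component under sucrose-regime parameters
#' @param rtol,atol solver tolerances (stiff-capable lsoda)
#' @return a \code{\link{current_trace}} with columns \code{U}, \code{U_s},
#'   \code{U_t} and metadata recording the onset time and protocol
#' @export
simulate_step <- function(params, protocol = step_protocol(),
                          dt_ms = 0.01, rtol = 1e-10, atol = 1e-12) {
  stopifnot(inherits(params, "circuit_params"),
            inherits(protocol, "step_protocol"))
  co <- derive_coeffs(params)
  tau <- characteristic_time_constants(co)
  meta <- list(onset_ms = protocol$t_pre, protocol = unclass(protocol),
               tau_p_ms = protocol$tau_p)
  if (dt_ms * .us_per_ms > tau[["tau_2"]] / 10)
    meta$warning <- sprintf(
      "dt = %g ms is coarse for the fast component (tau_2 = %.1f us)",
      dt_ms, tau[["tau_2"]])

  n_pre <- round(protocol$t_pre / dt_ms)
  n_step <- round(protocol$t_step / dt_ms)
  t_all <- seq(0, by = dt_ms, length.out = n_pre + n_step + 1L)

  ss1 <- steady_state_voltages(co, protocol$U_1)
  rhs <- .circuit_rhs(co, protocol$tau_p)
  y0 <- c(ss1$U_t, ss1$U_s)
  if (protocol$tau_p > 0) y0 <- c(y0, protocol$U_1)

  t_seg <- seq(0, by = dt_ms, length.out = n_step + 1L)
  st <- .integrate_segment(rhs, y0, t_seg, protocol$U_2, rtol, atol)

  U_t <- c(rep(ss1$U_t, n_pre), st[, 1])
  U_s <- c(rep(ss1$U_s, n_pre), st[, 2])
  U_cmd <- if (protocol$tau_p > 0) {
    c(rep(protocol$U_1, n_pre), st[, 3])
  } else {
    c(rep(protocol$U_1, n_pre), rep(protocol$U_2, n_step + 1L))
  }
  J <- (U_cmd - U_s) / params$R_a
  current_trace(t_all, J, U = U_cmd, U_s = U_s, U_t = U_t, meta = meta)
}

#' Pulse-train stimulus descriptor
#'
#' A train of identical rectangular steps from the holding voltage, applied
#' at a fixed repetition rate; the last \code{n_average} steady-state sweeps
#' are averaged to suppress recording noise.  Defaults follow the
#' experimental protocol used with sucrose superfusion: 300 pulses of 20 ms
#' and 5 mV from -80 mV holding at 25 Hz, last 50 sweeps averaged.
#'
#' @param holding_mV holding voltage [mV]
#' @param step_mV step amplitude [mV] (added to holding)
#' @param duration_ms pulse duration [ms]
#' @param rate_hz repetition rate [Hz]
#' @param n_pulses number of pulses in the train
#' @param n_average number of final sweeps to average
#' @return An object of class \code{train_protocol}.
#' @export
train_protocol <- function(holding_mV = -80, step_mV = 5, duration_ms = 20,
                           rate_hz = 25, n_pulses = 300, n_average = 50) {
  period <- 1000 / rate_hz
  if (duration_ms >= period)
    stop("pulse duration must be shorter than the train period", call. = FALSE)
  if (n_average > n_pulses)
    stop("n_average cannot exceed n_pulses", call. = FALSE)
  structure(list(holding_mV = holding_mV, step_mV = step_mV,
                 duration_ms = duration_ms, rate_hz = rate_hz,
                 period_ms = period, n_pulses = n_pulses,
                 n_average = n_average),
            class = "train_protocol")
}

#' Simulate a pulse train and average the final sweeps
#'
#' Integrates the circuit continuously across the whole train (state is
#' carried from sweep to sweep, so the stored sweeps are periodic
#' steady-state responses), adds optional Gaussian recording noise to the
#' current of each stored sweep, and averages the last \code{n_average}
#' sweeps sample-wise.  Each stored sweep spans one train period with the
#' pulse onset at \code{pre_ms}, so a pre-step baseline segment (tail of the
#' inter-pulse interval) is available for baseline measurement.
#'
#' @param params a \code{\link{circuit_params}} object
#' @param train a \code{\link{train_protocol}}
#' @param tau_p_ms edge time constant [ms]
#' @param noise_sigma standard deviation of additive Gaussian recording
#'   noise [nA]; 0 disables noise
#' @param seed integer seed making the noise reproducible
#' @param dt_ms sample interval [ms]
#' @param pre_ms portion of the inter-pulse interval shown before the pulse
#'   onset in each stored sweep [ms]
#' @param rtol,atol solver tolerances
#' @return list with \code{sweeps} (list of the last \code{n_average}
#'   \code{\link{current_trace}} objects, noise included) and
#'   \code{average} (their sample-wise mean trace)
#' @export
simulate_train <- function(params, train = train_protocol(), tau_p_ms = 0.05,
                           noise_sigma = 0.01, seed = 1L, dt_ms = 0.01,
                           pre_ms = 2, rtol = 1e-10, atol = 1e-12) {
  stopifnot(inherits(params, "circuit_params"),
            inherits(train, "train_protocol"))
  if (pre_ms + train$duration_ms >= train$period_ms)
    stop("pre_ms leaves no room in the inter-pulse interval", call. = FALSE)
  co <- derive_coeffs(params)
  rhs <- .circuit_rhs(co, tau_p_ms)
  U_hold <- train$holding_mV
  U_step <- train$holding_mV + train$step_mV

  n_on <- round(train$duration_ms / dt_ms)
  n_off <- round((train$period_ms - train$duration_ms) / dt_ms)
  t_on <- seq(0, by = dt_ms, length.out = n_on + 1L)
  t_off <- seq(0, by = dt_ms, length.out = n_off + 1L)

  ss <- steady_state_voltages(co, U_hold)
  y <- c(ss$U_t, ss$U_s)
  if (tau_p_ms > 0) y <- c(y, U_hold)

  keep_from <- train$n_pulses - train$n_average + 1L
  kept <- vector("list", train$n_average)
  n_pre <- round(pre_ms / dt_ms)

  # per-period state matrices (on + off segments, shared boundary sample)
  prev_off_tail <- NULL
  for (i in seq_len(train$n_pulses)) {
    st_on <- .integrate_segment(rhs, y, t_on, U_step, rtol, atol)
    y <- st_on[nrow(st_on), ]
    st_off <- .integrate_segment(rhs, y, t_off, U_hold, rtol, atol)
    y <- st_off[nrow(st_off), ]
    if (i >= keep_from && !is.null(prev_off_tail)) {
      # sweep = last pre_ms of previous off segment + pulse + start of off
      n_post <- n_off - n_pre
      st <- rbind(prev_off_tail[seq_len(n_pre), , drop = FALSE],
                  st_on,
                  st_off[2:(n_post + 1L), , drop = FALSE])
      t_sw <- seq(0, by = dt_ms, length.out = nrow(st))
      U_cmd <- if (tau_p_ms > 0) st[, 3] else
        c(rep(U_hold, n_pre), rep(U_step, n_on + 1L), rep(U_hold, n_post))
      J <- (U_cmd - st[, 2]) / params$R_a
      kept[[i - keep_from + 1L]] <- list(t = t_sw, J = J, U = U_cmd,
                                         U_s = st[, 2], U_t = st[, 1])
    }
    prev_off_tail <- st_off[(nrow(st_off) - n_pre):nrow(st_off), , drop = FALSE]
  }
  if (is.null(kept[[1]]))
    stop("n_average too large: first kept sweep lacks a preceding baseline",
         call. = FALSE)

  set.seed(seed)
  meta0 <- list(onset_ms = pre_ms, train = unclass(train),
                tau_p_ms = tau_p_ms, noise_sigma = noise_sigma, seed = seed)
  sweeps <- lapply(kept, function(s) {
    J <- s$J
    if (noise_sigma > 0) J <- J + stats::rnorm(length(J), 0, noise_sigma)
    current_trace(s$t, J, U = s$U, U_s = s$U_s, U_t = s$U_t, meta = meta0)
  })
  Jbar <- Reduce(`+`, lapply(sweeps, `[[`, "J")) / length(sweeps)
  avg <- current_trace(sweeps[[1]]$t_ms, Jbar, U = sweeps[[1]]$U,
                       meta = c(meta0, list(n_averaged = length(sweeps))))
  list(sweeps = sweeps, average = avg)
}
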