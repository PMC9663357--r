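# Bi-exponential decomposition of the capacitive transient.
#
# Under sucrose superfusion the decaying phase of the capacitive current is
# the sum of two exponentials plus a steady level,
#   J(t) = J_1 exp(-t/tau_1) + J_2 exp(-t/tau_2) + J_inf_2,
# and the six quantities (J_1, J_2, J_inf_1, J_inf_2, tau_1, tau_2) carry
# all the information needed to recover the circuit elements.

#' Six-parameter bi-exponential transient summary
#'
#' @param J_1,J_2 component amplitudes referenced to the step onset [nA]
#' @param tau_1,tau_2 time constants [us]; relabelled so tau_1 >= tau_2
#' @param J_inf_1 steady current at the pre-step voltage (baseline) [nA]
#' @param J_inf_2 steady current at the step voltage [nA]
#' @param diagnostics optional list of fit diagnostics (RSS, window,
#'   degenerate-fit flag, raw windowed amplitudes, ...)
#' @return An object of class \code{biexp_params}.
#' @export
biexp_params <- function(J_1, J_2, tau_1, tau_2, J_inf_1, J_inf_2,
                         diagnostics = list()) {
  if (!is.finite(tau_1) || !is.finite(tau_2) || tau_1 <= 0 || tau_2 <= 0)
    stop("time constants must be positive and finite", call. = FALSE)
  if (tau_1 < tau_2) {  # convention: tau_1 is the longer constant
    tmp <- tau_1; tau_1 <- tau_2; tau_2 <- tmp
    tmp <- J_1; J_1 <- J_2; J_2 <- tmp
  }
  structure(list(J_1 = J_1, J_2 = J_2, tau_1 = tau_1, tau_2 = tau_2,
                 J_inf_1 = J_inf_1, J_inf_2 = J_inf_2,
                 diagnostics = diagnostics),
            class = "biexp_params")
}

#' @export
print.biexp_params <- function(x, ...) {
  cat("Bi-exponential transient parameters (onset-referenced):\n")
  cat(sprintf("  J_1 = %.5f nA  tau_1 = %.2f us\n", x$J_1, x$tau_1))
  cat(sprintf("  J_2 = %.5f nA  tau_2 = %.2f us\n", x$J_2, x$tau_2))
  cat(sprintf("  J_inf_1 = %.5f nA  J_inf_2 = %.5f nA\n",
              x$J_inf_1, x$J_inf_2))
  if (isTRUE(x$diagnostics$degenerate))
    cat("  [flag] components indistinguishable (near mono-exponential)\n")
  invisible(x)
}

#' Measure the pre-step baseline current
#'
#' Mean current over the tail of the pre-step segment, used as the steady
#' current level \code{J_inf_1} at the holding voltage.
#'
#' @param trace a \code{\link{current_trace}}
#' @param onset_ms step onset time [ms]; defaults to the trace metadata
#' @param tail_ms length of the averaging window ending at the onset [ms]
#' @return baseline current [nA]
#' @export
measure_baseline <- function(trace, onset_ms = NULL, tail_ms = 1) {
  stopifnot(inherits(trace, "current_trace"))
  if (is.null(onset_ms)) onset_ms <- trace$meta$onset_ms
  if (is.null(onset_ms))
    stop("step onset unknown: supply onset_ms", call. = FALSE)
  pre <- trace$t_ms < onset_ms - 1e-9
  if (!any(pre))
    stop("trace has no pre-step segment before the onset", call. = FALSE)
  sel <- pre & trace$t_ms >= onset_ms - tail_ms - 1e-9
  mean(trace$J[sel])
}

#' Select the decaying phase of a capacitive transient
#'
#' Returns the fitting window: it starts at the later of the peak-current
#' sample and \code{onset + delay} and ends at the end of the pulse.  The
#' default delay, 4 edge time constants, excludes the portion distorted by
#' the shaped rising edge while keeping the early fast-component samples.
#'
#' @param trace a \code{\link{current_trace}}
#' @param onset_ms step onset [ms]; defaults to trace metadata
#' @param delay_ms delay after the onset [ms]; default \code{4 * tau_p}
#'   when the edge time constant is known from metadata, else 0
#' @param end_ms window end [ms]; defaults to onset + pulse duration when
#'   known, else the end of the trace
#' @return a \code{current_trace} restricted to the window, with window
#'   bounds and onset recorded in its metadata
#' @export
extract_decay_window <- function(trace, onset_ms = NULL, delay_ms = NULL,
                                 end_ms = NULL) {
  stopifnot(inherits(trace, "current_trace"))
  if (is.null(onset_ms)) onset_ms <- trace$meta$onset_ms
  if (is.null(onset_ms))
    stop("step onset unknown: supply onset_ms", call. = FALSE)
  if (is.null(delay_ms)) {
    tau_p <- trace$meta$tau_p_ms
    delay_ms <- if (is.null(tau_p)) 0 else 4 * tau_p
  }
  if (is.null(end_ms)) {
    dur <- trace$meta$protocol$t_step
    if (is.null(dur)) dur <- trace$meta$train$duration_ms
    end_ms <- if (is.null(dur)) max(trace$t_ms) else onset_ms + dur
  }
  post <- trace$t_ms >= onset_ms - 1e-9 & trace$t_ms <= end_ms + 1e-9
  if (!any(post)) stop("onset lies outside the trace", call. = FALSE)

  # require a detectable transient relative to the pre-step level
  base <- if (any(trace$t_ms < onset_ms - 1e-9))
    mean(trace$J[trace$t_ms < onset_ms - 1e-9]) else trace$J[1]
  dev <- abs(trace$J[post] - base)
  spread <- stats::sd(trace$J[trace$t_ms < onset_ms - 1e-9])
  if (is.na(spread)) spread <- 0
  if (max(dev) <= 3 * spread + 1e-9)
    stop("no voltage-step transient detected in the trace", call. = FALSE)

  t_peak <- trace$t_ms[post][which.max(dev)]
  t_start <- max(t_peak, onset_ms + delay_ms)
  sel <- trace$t_ms >= t_start - 1e-9 & trace$t_ms <= end_ms + 1e-9
  if (sum(sel) < 10L)
    stop("fitting window shorter than 10 samples", call. = FALSE)
  meta <- trace$meta
  meta$window <- c(start_ms = t_start, end_ms = end_ms)
  meta$onset_ms <- onset_ms
  current_trace(trace$t_ms[sel], trace$J[sel],
                U = if (!is.null(trace$U)) trace$U[sel],
                meta = meta)
}

# deterministic initial guesses: offset from the tail; a rough decay scale
# from the e-fold crossing time of the transient; the slow tau from the
# log-slope over [1.5, 4] decay scales and the fast tau over the first
# half-scale (regions tied to the signal, not the window length, so a long
# noise-dominated tail cannot corrupt them); amplitudes by linear least
# squares given the taus.
.biexp_init <- function(t, y, tau_p = 0) {
  n <- length(t)
  off <- mean(y[max(1L, n - max(10L, n %/% 10L)):n])
  z <- y - off
  sgn <- sign(z[which.max(abs(z))])
  z <- z * sgn
  span <- t[n] - t[1]
  i_e <- which(z < z[1] / exp(1))
  t_e <- if (length(i_e)) t[i_e[1]] - t[1] else span / 3
  if (t_e <= 0) t_e <- span / 3
  logslope <- function(idx) {
    ok <- idx[z[idx] > 0]
    if (length(ok) < 3L) return(NA_real_)
    fit <- stats::lm.fit(cbind(1, t[ok]), log(z[ok]))
    -1 / unname(fit$coefficients[2])
  }
  rel <- t - t[1]
  tau_slow <- logslope(which(rel >= 1.5 * t_e & rel <= 4 * t_e))
  tau_fast <- logslope(which(rel <= 0.5 * t_e))
  if (!is.finite(tau_slow) || tau_slow <= 0) tau_slow <- t_e
  if (!is.finite(tau_fast) || tau_fast <= 0) tau_fast <- tau_slow / 5
  if (tau_fast >= tau_slow) tau_fast <- tau_slow / 5
  X <- cbind(exp(-(t - t[1]) / tau_slow), exp(-(t - t[1]) / tau_fast))
  if (tau_p > 0) X <- cbind(X, exp(-(t - t[1]) / tau_p))
  amp <- tryCatch(stats::lm.fit(X, y - off)$coefficients,
                  error = function(e) rep(sgn * diff(range(y)) / 2, ncol(X)))
  amp[!is.finite(amp)] <- 0
  list(A1 = unname(amp[1]), A2 = unname(amp[2]),
       th1 = tau_slow, th2 = tau_fast, C = off,
       Ap = if (tau_p > 0) unname(amp[3]) else 0)
}

#' Fit a bi-exponential to the decaying capacitive transient
#'
#' Least-squares fit of \code{J = A_1 exp(-(t-t_w)/tau_1) +
#' A_2 exp(-(t-t_w)/tau_2) + J_inf_2} over a fitting window starting at
#' \code{t_w} (from \code{\link{extract_decay_window}}).  The amplitudes are
#' back-extrapolated to the step onset, so they correspond to the
#' closed-form amplitudes of the ideal step response.
#'
#' When the command edges were shaped by a known first-order lag
#' \code{tau_p}, the trace carries a third relaxation mode
#' \code{exp(-t/tau_p)} (the lag-driven linear system has exactly three
#' modes).  Two exact corrections are applied in that case: a term
#' \code{A_p exp(-t/tau_p)} with fixed \code{tau_p} is added to the fit
#' model whenever the window still overlaps the edge mode (start within
#' \code{12 tau_p} of the onset), and each back-extrapolated amplitude is
#' multiplied by \code{(tau_i - tau_p)/tau_i}, undoing the exact
#' \code{tau_i/(tau_i - tau_p)} scaling a first-order lag imposes on every
#' relaxation mode.  Together these restore the ideal-step amplitudes that
#' the element-recovery formulas assume.
#'
#' @param window a windowed \code{\link{current_trace}} from
#'   \code{\link{extract_decay_window}}
#' @param J_inf_1 pre-step baseline current [nA] (from
#'   \code{\link{measure_baseline}}); stored in the result
#' @param onset_ms step onset for back-extrapolation [ms]; defaults to
#'   window metadata
#' @param tau_p_ms edge time constant used for the exact amplitude
#'   de-lagging [ms]; defaults to window metadata, 0 disables
#' @param degenerate_ratio tau_1/tau_2 below which the two components are
#'   flagged indistinguishable (mono-exponential regime, as in Tyrode
#'   solution)
#' @return a \code{\link{biexp_params}} object; diagnostics carry the RSS,
#'   window bounds, raw windowed amplitudes and the degenerate flag
#' @export
fit_biexponential <- function(window, J_inf_1 = NA_real_, onset_ms = NULL,
                              tau_p_ms = NULL, degenerate_ratio = 1.05) {
  stopifnot(inherits(window, "current_trace"))
  if (is.null(onset_ms)) onset_ms <- window$meta$onset_ms
  if (is.null(onset_ms))
    stop("step onset unknown: supply onset_ms", call. = FALSE)
  if (is.null(tau_p_ms)) tau_p_ms <- window$meta$tau_p_ms
  if (is.null(tau_p_ms)) tau_p_ms <- 0

  t <- window$t_ms - window$t_ms[1]  # ms, relative to window start
  y <- window$J
  span <- max(t)
  dt <- window$meta$dt_ms
  t_back <- window$t_ms[1] - onset_ms
  with_edge <- tau_p_ms > 0 && t_back < 12 * tau_p_ms
  init <- .biexp_init(t, y, tau_p = if (with_edge) tau_p_ms else 0)
  init$th1 <- min(max(init$th1, dt), 10 * span)
  init$th2 <- min(max(init$th2, dt), 10 * span)
  if (with_edge) {
    # the fast membrane component must stay slower than the stimulus edge,
    # otherwise it is collinear with the fixed edge mode
    th2_min <- max(dt, 2 * tau_p_ms)
    init$th2 <- max(init$th2, th2_min)
    model <- y ~ A1 * exp(-t / th1) + A2 * exp(-t / th2) +
      Ap * exp(-t / tau_p) + C
    start <- c(init[c("A1", "A2", "th1", "th2", "Ap")], C = init$C)
    lo <- c(A1 = -Inf, A2 = -Inf, th1 = dt, th2 = th2_min,
            Ap = -Inf, C = -Inf)
    hi <- c(A1 = Inf, A2 = Inf, th1 = 10 * span, th2 = 10 * span,
            Ap = Inf, C = Inf)
    dat <- list(t = t, y = y, tau_p = tau_p_ms)
  } else {
    model <- y ~ A1 * exp(-t / th1) + A2 * exp(-t / th2) + C
    start <- init[c("A1", "A2", "th1", "th2", "C")]
    lo <- c(A1 = -Inf, A2 = -Inf, th1 = dt, th2 = dt, C = -Inf)
    hi <- c(A1 = Inf, A2 = Inf, th1 = 10 * span, th2 = 10 * span, C = Inf)
    dat <- list(t = t, y = y)
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(
      model, data = dat, start = start, lower = lo, upper = hi,
      control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-15,
                                           ptol = 1e-15)),
    error = function(e) stop("bi-exponential fit did not converge: ",
                             conditionMessage(e), call. = FALSE))
  cf <- stats::coef(fit)
  rss <- sum(stats::resid(fit)^2)

  # relabel so component 1 is the slower one
  if (cf[["th1"]] < cf[["th2"]]) {
    cf[c("A1", "A2", "th1", "th2")] <-
      cf[c("A2", "A1", "th2", "th1")]
  }
  # near-equal time constants or a vanishing component both mean the
  # two-exponential description is not identifiable (Tyrode regime)
  amp_ratio <- min(abs(cf[["A1"]]), abs(cf[["A2"]])) /
    max(abs(cf[["A1"]]), abs(cf[["A2"]]))
  degenerate <- cf[["th1"]] / cf[["th2"]] < degenerate_ratio ||
    amp_ratio < 1e-3

  # back-extrapolate amplitudes from the window start to the step onset,
  # then remove the exact first-order edge-lag scaling
  J_1 <- cf[["A1"]] * exp(t_back / cf[["th1"]])
  J_2 <- cf[["A2"]] * exp(t_back / cf[["th2"]])
  if (tau_p_ms > 0) {
    J_1 <- J_1 * (cf[["th1"]] - tau_p_ms) / cf[["th1"]]
    J_2 <- J_2 * (cf[["th2"]] - tau_p_ms) / cf[["th2"]]
  }
  biexp_params(
    J_1 = J_1, J_2 = J_2,
    tau_1 = cf[["th1"]] * .us_per_ms, tau_2 = cf[["th2"]] * .us_per_ms,
    J_inf_1 = J_inf_1, J_inf_2 = cf[["C"]],
    diagnostics = list(
      rss = rss, degenerate = degenerate,
      window = window$meta$window, onset_ms = onset_ms,
      tau_p_ms = tau_p_ms,
      raw_amplitudes = c(A1 = unname(cf[["A1"]]), A2 = unname(cf[["A2"]])),
      edge_amplitude = if (with_edge) unname(cf[["Ap"]]) else NULL,
      n_samples = length(y)))
}

#' Fit a mono-exponential to the transient (physiological-solution analysis)
#'
#' The conventional single-exponential analysis used in normal-conductivity
#' (Tyrode) solution, where the tubular coupling resistance is too small
#' for the two components to be distinguishable.  Estimates the total
#' membrane capacitance from the transferred charge
#' \code{Q = J_1 * tau} (the integral of the fitted transient above the
#' steady level).  Two corrections make this exact for the single-RC cell:
#' the capacitor sees only the membrane-voltage step
#' \code{dU_m = dU - R_a dJ_inf} (command step minus the drop across
#' \code{R_a}), and a fraction \code{R_a/(R_a + R_m)} of the transient
#' integral is ionic rather than capacitive, giving
#' \code{C_total = Q dU / dU_m^2}.
#'
#' @inheritParams fit_biexponential
#' @param dU_mV voltage-step amplitude [mV]; needed for \code{C_total}
#' @param rss_ratio mono/bi-exponential residual-sum-of-squares ratio above
#'   which the mono-exponential description is flagged inadequate
#' @return list with \code{amplitude} [nA, onset-referenced], \code{tau_us},
#'   \code{offset} [nA], \code{C_total_pF} (NA when \code{dU_mV} or the
#'   baseline is missing), \code{rss}, and \code{poor_fit} flag
#' @export
fit_monoexponential <- function(window, J_inf_1 = NA_real_, dU_mV = NULL,
                                onset_ms = NULL, tau_p_ms = NULL,
                                rss_ratio = 10) {
  stopifnot(inherits(window, "current_trace"))
  if (is.null(onset_ms)) onset_ms <- window$meta$onset_ms
  if (is.null(onset_ms))
    stop("step onset unknown: supply onset_ms", call. = FALSE)
  if (is.null(tau_p_ms)) tau_p_ms <- window$meta$tau_p_ms
  if (is.null(tau_p_ms)) tau_p_ms <- 0
  t <- window$t_ms - window$t_ms[1]
  y <- window$J
  init <- .biexp_init(t, y)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ A * exp(-t / th) + C,
      data = list(t = t, y = y),
      start = list(A = init$A1 + init$A2, th = init$th1, C = init$C),
      lower = c(A = -Inf, th = window$meta$dt_ms, C = -Inf),
      upper = c(A = Inf, th = 10 * max(t), C = Inf),
      control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-15,
                                           ptol = 1e-15)),
    error = function(e) stop("mono-exponential fit did not converge: ",
                             conditionMessage(e), call. = FALSE))
  cf <- stats::coef(fit)
  rss <- sum(stats::resid(fit)^2)
  # adequacy check against the two-component description
  rss_bi <- tryCatch(
    fit_biexponential(window, J_inf_1, onset_ms, tau_p_ms)$diagnostics$rss,
    error = function(e) NA_real_)
  poor <- is.finite(rss_bi) && rss_bi > 0 && rss / rss_bi > rss_ratio

  A_onset <- cf[["A"]] * exp((window$t_ms[1] - onset_ms) / cf[["th"]])
  if (tau_p_ms > 0) A_onset <- A_onset * (cf[["th"]] - tau_p_ms) / cf[["th"]]
  C_total <- NA_real_
  if (!is.null(dU_mV) && is.finite(J_inf_1)) {
    dJ <- cf[["C"]] - J_inf_1
    R_a <- dU_mV / (A_onset + dJ)     # instantaneous-jump identity
    Q <- A_onset * cf[["th"]] * .us_per_ms        # nA*us = fC
    C_total <- Q * dU_mV / (dU_mV - R_a * dJ)^2   # fC/mV = pF
  }
  list(amplitude = unname(A_onset), tau_us = unname(cf[["th"]]) * .us_per_ms,
       offset = unname(cf[["C"]]), C_total_pF = unname(C_total),
       rss = rss, rss_biexp = rss_bi, poor_fit = poor)
}
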