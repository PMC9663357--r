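# Uniformly sampled voltage-clamp records.

#' Current trace container
#'
#' A uniformly sampled record of membrane current under voltage clamp,
#' optionally carrying the imposed command voltage and (for simulated
#' traces) the internal surface/tubular membrane voltages.
#'
#' @param t_ms sample times [ms], strictly increasing, uniform grid
#' @param J membrane current [nA]
#' @param U optional imposed command voltage [mV]
#' @param U_s,U_t optional surface/tubular membrane voltages [mV]
#' @param meta named list of metadata (step onset, protocol, noise sigma,
#'   seed, solution label, ...)
#' @return An object of class \code{current_trace}.
#' @export
current_trace <- function(t_ms, J, U = NULL, U_s = NULL, U_t = NULL,
                          meta = list()) {
  t_ms <- as.numeric(t_ms); J <- as.numeric(J)
  n <- length(t_ms)
  if (n < 2L) stop("trace needs at least two samples", call. = FALSE)
  if (length(J) != n) stop("t and J lengths differ", call. = FALSE)
  dt <- diff(t_ms)
  if (any(dt <= 0)) stop("time axis must be strictly increasing", call. = FALSE)
  if (max(dt) - min(dt) > 1e-3 * stats::median(dt))
    stop("time axis is not a uniform grid (tolerance 0.1% of dt)",
         call. = FALSE)
  for (nm in c("U", "U_s", "U_t")) {
    v <- get(nm)
    if (!is.null(v) && length(v) != n)
      stop("column '", nm, "' length differs from t", call. = FALSE)
  }
  meta$dt_ms <- stats::median(dt)
  structure(list(t_ms = t_ms, J = J, U = U, U_s = U_s, U_t = U_t,
                 meta = meta),
            class = "current_trace")
}

#' @export
print.current_trace <- function(x, ...) {
  cat(sprintf("Current trace: %d samples, dt = %g ms, span %.3f-%.3f ms\n",
              length(x$t_ms), x$meta$dt_ms, x$t_ms[1],
              x$t_ms[length(x$t_ms)]))
  extras <- c("U", "U_s", "U_t")[!vapply(x[c("U", "U_s", "U_t")], is.null,
                                         logical(1))]
  if (length(extras)) cat("  voltage columns:", paste(extras, collapse = ", "), "\n")
  if (!is.null(x$meta$onset_ms))
    cat(sprintf("  step onset at %g ms\n", x$meta$onset_ms))
  invisible(x)
}

#' @export
as.data.frame.current_trace <- function(x, ...) {
  d <- data.frame(time_ms = x$t_ms, current_nA = x$J)
  if (!is.null(x$U))   d$voltage_mV <- x$U
  if (!is.null(x$U_s)) d$Us_mV <- x$U_s
  if (!is.null(x$U_t)) d$Ut_mV <- x$U_t
  d
}
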