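# Acceptance criteria for a sucrose-solution measurement.
#
# Incomplete sucrose wash-in (cell lying on the chamber bottom, jet pipe
# misaligned) leaves the tubular lumen resistance too low: the two current
# components then fail to separate and the extraction is unreliable.  Five
# empirical criteria decide whether a measurement is analyzable.

#' Evaluate wash-in / analyzability criteria
#'
#' The five criteria, all strict inequalities:
#' \itemize{
#'   \item \code{R_2 > 20} MOhm
#'   \item \code{R_1/R_2 > 0.08}
#'   \item \code{R_a_suc - R_a_Tyr > 3} MOhm (access-resistance rise on
#'     switching to sucrose)
#'   \item \code{J_1/J_2 > 0.16}
#'   \item \code{tau_1/tau_2 < 10} (tau_1 the longer constant)
#' }
#' When the Tyrode-solution access resistance is unavailable (extraction-only
#' workflows), the shift criterion is marked indeterminate and excluded from
#' the conjunction; the verdict is then a "conditional pass" at best.
#'
#' @param res an \code{\link{extraction_result}}
#' @param p the \code{\link{biexp_params}} behind it (defaults to the copy
#'   stored in the result's diagnostics)
#' @param R_a_Tyr access resistance measured in Tyrode solution [MOhm], or
#'   NA if not available
#' @param thresholds named list overriding the default thresholds
#'   (\code{r2_min}, \code{r1_r2_ratio}, \code{ra_shift}, \code{amp_ratio},
#'   \code{tau_ratio})
#' @return object of class \code{qc_result}: per-criterion logical flags,
#'   the evaluated values, the thresholds and the overall verdict
#' @export
evaluate_qc <- function(res, p = NULL, R_a_Tyr = NA_real_,
                        thresholds = list()) {
  stopifnot(inherits(res, "extraction_result"))
  if (is.null(p)) p <- res$diagnostics$biexp
  stopifnot(inherits(p, "biexp_params"))
  th <- utils::modifyList(
    list(r2_min = 20, r1_r2_ratio = 0.08, ra_shift = 3,
         amp_ratio = 0.16, tau_ratio = 10),
    thresholds)
  vals <- list(
    R_2 = res$combined$R_2,
    r1_r2 = res$combined$R_1 / res$combined$R_2,
    ra_shift = res$R_a - R_a_Tyr,
    amp_ratio = p$J_1 / p$J_2,
    tau_ratio = p$tau_1 / p$tau_2)
  flags <- list(
    r2_min = vals$R_2 > th$r2_min,
    r1_r2_ratio = vals$r1_r2 > th$r1_r2_ratio,
    ra_shift = if (is.finite(R_a_Tyr)) vals$ra_shift > th$ra_shift else NA,
    amp_ratio = vals$amp_ratio > th$amp_ratio,
    tau_ratio = vals$tau_ratio < th$tau_ratio)
  evaluable <- !vapply(flags, is.na, logical(1))
  pass_eval <- all(unlist(flags[evaluable]))
  verdict <- if (!pass_eval) "fail"
  else if (all(evaluable)) "pass"
  else "conditional pass (R_a_Tyr unavailable)"
  structure(list(flags = flags, values = vals, thresholds = th,
                 R_a_suc = res$R_a, R_a_Tyr = R_a_Tyr,
                 pass = pass_eval && all(evaluable), verdict = verdict),
            class = "qc_result")
}

#' @export
print.qc_result <- function(x, ...) {
  cat("Sucrose-measurement QC:\n")
  fmt <- function(flag) if (is.na(flag)) "n/a " else if (flag) "pass" else "FAIL"
  cat(sprintf("  R_2 = %.2f MOhm (> %g): %s\n",
              x$values$R_2, x$thresholds$r2_min, fmt(x$flags$r2_min)))
  cat(sprintf("  R_1/R_2 = %.4f (> %g): %s\n",
              x$values$r1_r2, x$thresholds$r1_r2_ratio,
              fmt(x$flags$r1_r2_ratio)))
  cat(sprintf("  R_a shift = %.2f MOhm (> %g): %s\n",
              x$values$ra_shift, x$thresholds$ra_shift, fmt(x$flags$ra_shift)))
  cat(sprintf("  J_1/J_2 = %.4f (> %g): %s\n",
              x$values$amp_ratio, x$thresholds$amp_ratio,
              fmt(x$flags$amp_ratio)))
  cat(sprintf("  tau_1/tau_2 = %.3f (< %g): %s\n",
              x$values$tau_ratio, x$thresholds$tau_ratio,
              fmt(x$flags$tau_ratio)))
  cat("  verdict:", x$verdict, "\n")
  invisible(x)
}
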