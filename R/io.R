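# File formats, configuration, pipeline orchestration and fixtures.
#
# Trace files are plain CSV with optional "# key=value" metadata comment
# lines followed by a header naming the time and current columns with
# units: time_ms or time_s, current_nA or current_pA, optional voltage_mV.

#' Read a current trace from a delimited text file
#'
#' @param path file path
#' @return a \code{\link{current_trace}} in canonical units (ms, nA)
#' @export
read_trace <- function(path) {
  lines <- readLines(path)
  is_meta <- grepl("^\\s*#", lines)
  meta <- list()
  for (ln in lines[is_meta]) {
    kv <- sub("^\\s*#\\s*", "", ln)
    if (grepl("=", kv, fixed = TRUE)) {
      key <- trimws(sub("=.*", "", kv))
      val <- trimws(sub("^[^=]*=", "", kv))
      num <- suppressWarnings(as.numeric(val))
      meta[[key]] <- if (is.na(num)) val else num
    }
  }
  body <- lines[!is_meta & nzchar(trimws(lines))]
  if (length(body) < 2L) stop("no data rows in ", path, call. = FALSE)
  header <- strsplit(body[1], ",", fixed = TRUE)[[1]]
  header <- trimws(header)
  rows <- strsplit(body[-1], ",", fixed = TRUE)
  bad <- which(lengths(rows) != length(header))
  if (length(bad))
    stop("malformed rows (wrong field count) at data line(s): ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  mat <- matrix(suppressWarnings(as.numeric(unlist(rows))),
                ncol = length(header), byrow = TRUE)
  nonnum <- which(rowSums(is.na(mat)) > 0)
  if (length(nonnum))
    stop("non-numeric values at data line(s): ",
         paste(utils::head(nonnum, 5), collapse = ", "), call. = FALSE)
  colnames(mat) <- header

  t_col <- intersect(c("time_ms", "time_s"), header)
  j_col <- intersect(c("current_nA", "current_pA"), header)
  if (length(t_col) != 1L || length(j_col) != 1L)
    stop("header must name one time column (time_ms|time_s) and one ",
         "current column (current_nA|current_pA)", call. = FALSE)
  t_ms <- mat[, t_col] * if (t_col == "time_s") 1000 else 1
  J <- mat[, j_col] * if (j_col == "current_pA") 1e-3 else 1
  U <- if ("voltage_mV" %in% header) mat[, "voltage_mV"] else NULL
  current_trace(t_ms, J, U = U, meta = meta)
}

#' Write a current trace to a delimited text file
#'
#' @param trace a \code{\link{current_trace}}
#' @param path output path
#' @param digits significant digits written
#' @export
write_trace <- function(trace, path, digits = 15) {
  stopifnot(inherits(trace, "current_trace"))
  meta <- trace$meta
  scalars <- meta[vapply(meta, function(v)
    is.atomic(v) && length(v) == 1L, logical(1))]
  hdr <- sprintf("# %s=%s", names(scalars),
                 vapply(scalars, function(v) format(v, digits = digits),
                        character(1)))
  d <- as.data.frame(trace)
  d <- d[, intersect(c("time_ms", "current_nA", "voltage_mV"), names(d)),
         drop = FALSE]
  body <- c(paste(names(d), collapse = ","),
            do.call(paste, c(lapply(d, function(col)
              format(col, digits = digits, trim = TRUE, scientific = FALSE)),
              sep = ",")))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Serialize an extraction result (with optional QC) to JSON
#'
#' @param res an \code{\link{extraction_result}}
#' @param path output path; NULL returns the JSON string
#' @export
write_result_json <- function(res, path = NULL) {
  stopifnot(inherits(res, "extraction_result"))
  out <- unclass(res)
  out$combined <- unclass(out$combined)
  if (!is.null(out$diagnostics$biexp)) {
    bx <- unclass(out$diagnostics$biexp)
    bx$diagnostics <- NULL
    out$biexp <- bx
    out$diagnostics$biexp <- NULL
  }
  if (!is.null(out$qc)) out$qc <- unclass(out$qc)
  js <- jsonlite::toJSON(out, auto_unbox = TRUE, digits = NA, null = "null",
                         na = "null", pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}

#' Read a six-parameter transient summary from a JSON file
#'
#' Expected keys: \code{J_1}, \code{J_2}, \code{tau_1}, \code{tau_2}
#' (us), \code{J_inf_1}, \code{J_inf_2}.
#'
#' @param path JSON file path
#' @return a \code{\link{biexp_params}} object
#' @export
read_biexp_json <- function(path) {
  x <- jsonlite::fromJSON(path)
  need <- c("J_1", "J_2", "tau_1", "tau_2", "J_inf_1", "J_inf_2")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("missing keys in ", path, ": ", paste(miss, collapse = ", "),
         call. = FALSE)
  biexp_params(x$J_1, x$J_2, x$tau_1, x$tau_2, x$J_inf_1, x$J_inf_2)
}

#' Pipeline configuration
#'
#' Exactly one input source must be given: a \code{\link{circuit_params}}
#' object (simulate mode), a trace file path, or a transient-summary JSON
#' path (extraction-only mode).
#'
#' @param params optional \code{\link{circuit_params}} (simulate mode)
#' @param trace_file optional trace CSV path
#' @param biexp_file optional transient-summary JSON path
#' @param protocol a \code{\link{step_protocol}} (simulate mode and for the
#'   step voltages used in extraction)
#' @param train optional \code{\link{train_protocol}}; when given, simulate
#'   mode runs the full pulse train and analyzes the averaged sweep
#' @param gamma_expected assumed gamma for extraction
#' @param k_c correction coefficient for the simplified C_t estimate
#'   (NULL disables)
#' @param noise_sigma,seed recording-noise settings (train simulation)
#' @param delay_ms fitting-window delay override [ms]
#' @param R_a_Tyr Tyrode-solution access resistance for QC [MOhm]
#' @param dt_ms simulation sample interval [ms]
#' @return a \code{run_config} list
#' @export
run_config <- function(params = NULL, trace_file = NULL, biexp_file = NULL,
                       protocol = step_protocol(), train = NULL,
                       gamma_expected = 1.2, k_c = NULL,
                       noise_sigma = 0.01, seed = 1L, delay_ms = NULL,
                       R_a_Tyr = NA_real_, dt_ms = 0.01) {
  n_src <- (!is.null(params)) + (!is.null(trace_file)) + (!is.null(biexp_file))
  if (n_src != 1L)
    stop("exactly one input source (params | trace_file | biexp_file) ",
         "must be supplied", call. = FALSE)
  structure(list(params = params, trace_file = trace_file,
                 biexp_file = biexp_file, protocol = protocol, train = train,
                 gamma_expected = gamma_expected, k_c = k_c,
                 noise_sigma = noise_sigma, seed = seed, delay_ms = delay_ms,
                 R_a_Tyr = R_a_Tyr, dt_ms = dt_ms),
            class = "run_config")
}

#' Run the full analysis pipeline
#'
#' simulate/load -> (average) -> baseline -> window -> bi-exponential fit ->
#' element extraction -> QC.  Deterministic given the config seed.
#'
#' @param config a \code{\link{run_config}}
#' @return an \code{\link{extraction_result}} with a \code{qc} field and,
#'   in simulate mode, the true parameter values in
#'   \code{diagnostics$truth}
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  pr <- config$protocol
  U_1 <- pr$U_1; U_2 <- pr$U_2

  p <- NULL
  if (!is.null(config$biexp_file)) {
    p <- read_biexp_json(config$biexp_file)
  } else {
    if (!is.null(config$params)) {
      if (!is.null(config$train)) {
        tr <- config$train
        U_1 <- tr$holding_mV; U_2 <- tr$holding_mV + tr$step_mV
        sim <- simulate_train(config$params, tr, tau_p_ms = pr$tau_p,
                              noise_sigma = config$noise_sigma,
                              seed = config$seed, dt_ms = config$dt_ms)
        trace <- sim$average
      } else {
        trace <- simulate_step(config$params, pr, dt_ms = config$dt_ms)
      }
    } else {
      trace <- read_trace(config$trace_file)
      if (!is.null(trace$meta$U_1)) U_1 <- trace$meta$U_1
      if (!is.null(trace$meta$U_2)) U_2 <- trace$meta$U_2
    }
    J_inf_1 <- measure_baseline(trace)
    win <- extract_decay_window(trace, delay_ms = config$delay_ms)
    p <- fit_biexponential(win, J_inf_1 = J_inf_1)
  }

  res <- extract_circuit(p, U_1 = U_1, U_2 = U_2,
                         gamma_expected = config$gamma_expected,
                         k_c = config$k_c)
  res$qc <- evaluate_qc(res, p, R_a_Tyr = config$R_a_Tyr)
  if (!is.null(config$params)) {
    res$diagnostics$truth <- unclass(config$params)
    res$diagnostics$truth$gamma <- true_gamma(config$params)
  }
  res
}

#' Reference circuit used throughout verification
#'
#' The element values used for all verification computations: R_a = 12.5,
#' R_t = 15, R_ms = 150, R_mt = 241 MOhm, C_s = 74, C_t = 46 pF,
#' U_ms = U_mt = -160 mV (close to values observed in rat ventricular
#' cardiomyocytes under sucrose superfusion).
#'
#' @param ... overrides passed to \code{\link{circuit_params}}
#' @return a \code{\link{circuit_params}} object
#' @export
reference_circuit <- function(...) {
  over <- list(...)
  base <- list(R_a = 12.5, R_t = 15, R_ms = 150, R_mt = 241,
               C_s = 74, C_t = 46, U_ms = -160, U_mt = -160)
  do.call(circuit_params, utils::modifyList(base, over))
}

#' Generate the packaged verification fixtures
#'
#' Writes, under \code{dir}: the reference-circuit baseline trace; traces
#' with tubular lumen resistance 15, 30 and 80 MOhm; the gamma-mismatch
#' configuration (R_mt = 345 MOhm); a noisy 50-sweep-averaged train trace;
#' and a truth JSON next to each.  Byte-identical on re-run with the same
#' seed.
#'
#' @param dir output directory (created if needed)
#' @param seed noise seed for the train fixture
#' @param dt_ms sample interval [ms]
#' @return invisible character vector of the files written
#' @export
generate_fixtures <- function(dir, seed = 1L, dt_ms = 0.01) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pr <- step_protocol()
  written <- character(0)
  emit <- function(name, params, trace) {
    tp <- file.path(dir, paste0(name, ".csv"))
    trace$meta$U_1 <- pr$U_1; trace$meta$U_2 <- pr$U_2
    write_trace(trace, tp)
    truth <- c(unclass(params), gamma = true_gamma(params))
    jp <- file.path(dir, paste0(name, "_truth.json"))
    writeLines(jsonlite::toJSON(truth, auto_unbox = TRUE, digits = NA,
                                pretty = TRUE), jp)
    written <<- c(written, tp, jp)
  }
  base <- reference_circuit()
  emit("baseline", base, simulate_step(base, pr, dt_ms = dt_ms))
  for (rt in c(15, 30, 80)) {
    pars <- reference_circuit(R_t = rt)
    emit(sprintf("rt_%02d_Mohm", rt), pars,
         simulate_step(pars, pr, dt_ms = dt_ms))
  }
  g_mis <- reference_circuit(R_mt = 345)
  emit("gamma_mismatch", g_mis, simulate_step(g_mis, pr, dt_ms = dt_ms))
  tr <- train_protocol(n_pulses = 60, n_average = 50)
  sim <- simulate_train(base, tr, tau_p_ms = pr$tau_p, noise_sigma = 0.01,
                        seed = seed, dt_ms = dt_ms)
  emit("noisy_train_average", base, sim$average)
  invisible(written)
}
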