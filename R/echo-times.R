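#' Exponentially increasing gradient-echo time schedule
#'
#' Builds the ME-GE echo-time vector with exponentially increasing echo
#' spacing. The spacing of echo `n` (counted from 0) is
#' `dTE_n = dTE_0 * exp(n * rate * dTE_0)`, so the cumulative echo time has
#' the closed form
#' `TE_n = TE_0 + dTE_0 * (exp(n * rate * dTE_0) - 1) / (exp(rate * dTE_0) - 1)`.
#' For `rate = 0` the schedule degenerates to equidistant spacing `dte0`.
#'
#' @param te0 First echo time in ms (> 0).
#' @param dte0 First echo-time increment in ms (> 0).
#' @param rate Spacing increase rate in 1/ms (>= 0).
#' @param n_echoes Number of echoes (>= 1).
#'
#' @return An object of class `mwi_echo_schedule`: a list with fields
#'   `te0`, `dte0`, `rate`, `n_echoes` and the echo-time vector `te` (ms,
#'   `te[1]` corresponds to n = 0).
#'
#' @examples
#' sched <- exponential_echo_times(2, 1.5, 0.02, 32)
#' head(sched$te) # 2.0 3.5 ...
#' @export
exponential_echo_times <- function(te0, dte0, rate, n_echoes) {
  stopifnot(is.numeric(te0), length(te0) == 1, te0 > 0,
            is.numeric(dte0), length(dte0) == 1, dte0 > 0,
            is.numeric(rate), length(rate) == 1, rate >= 0,
            is.numeric(n_echoes), length(n_echoes) == 1, n_echoes >= 1)
  n_echoes <- as.integer(n_echoes)
  n <- seq_len(n_echoes) - 1L
  if (rate == 0) {
    te <- te0 + n * dte0
  } else {
    g <- exp(rate * dte0)
    te <- te0 + dte0 * (g^n - 1) / (g - 1)
  }
  structure(
    list(te0 = te0, dte0 = dte0, rate = rate, n_echoes = n_echoes, te = te),
    class = "mwi_echo_schedule"
  )
}

#' Coerce a schedule or numeric vector to echo times (ms)
#' @param x An `mwi_echo_schedule` or a numeric echo-time vector.
#' @return Numeric vector of echo times in ms.
#' @keywords internal
echo_times <- function(x) {
  if (inherits(x, "mwi_echo_schedule")) return(x$te)
  stopifnot(is.numeric(x), length(x) >= 1, all(is.finite(x)), all(x > 0),
            !is.unsorted(x, strictly = TRUE))
  as.numeric(x)
}

#' Write / read an echo-time schedule JSON sidecar
#'
#' The sidecar stores either the generating parameters
#' (`te0`/`dte0`/`rate`/`n_echoes`) or an explicit `te` list, all in ms.
#'
#' @param sched `mwi_echo_schedule` or numeric echo-time vector.
#' @param path File path for the JSON sidecar.
#' @return `write_echo_schedule()` returns `path` invisibly;
#'   `read_echo_schedule()` returns an `mwi_echo_schedule`.
#' @export
write_echo_schedule <- function(sched, path) {
  if (inherits(sched, "mwi_echo_schedule")) {
    x <- sched[c("te0", "dte0", "rate", "n_echoes")]
    x$te <- sched$te
  } else {
    x <- list(te = echo_times(sched))
  }
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_echo_schedule
#' @export
read_echo_schedule <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(x$te0)) {
    sched <- exponential_echo_times(x$te0, x$dte0, x$rate, x$n_echoes)
    if (!is.null(x$te) && max(abs(sched$te - x$te)) > 1e-6)
      abort("echo-time sidecar is inconsistent with its generating parameters")
    return(sched)
  }
  te <- echo_times(as.numeric(x$te))
  structure(list(te0 = te[1], dte0 = if (length(te) > 1) te[2] - te[1] else NA_real_,
                 rate = NA_real_, n_echoes = length(te), te = te),
            class = "mwi_echo_schedule")
}
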