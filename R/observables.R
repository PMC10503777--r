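#' Observable series container
#'
#' Uniformly sampled (default 10 Hz) series of the five bedside observables:
#' mean arterial pressure `p_a` (mmHg), mean venous pressure `p_v` (mmHg),
#' heart rate `hr` (beats/min), pulse pressure `p_p` (mmHg) and the scaled
#' resistance-compliance product `rc` (s, known only up to the pulse-contour
#' scale).
#'
#' @param x Data frame with columns `t, p_a, p_v, hr, p_p, rc`.
#' @param fs Sampling rate, Hz.
#' @return Object of class `observable_series`.
#' @export
as_observable_series <- function(x, fs = 10) {
  need <- c("t", "p_a", "p_v", "hr", "p_p", "rc")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("missing observable columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  x <- as.data.frame(x)[need]
  if (nrow(x) > 1) {
    dt <- diff(x$t)
    if (max(abs(dt - 1 / fs)) > 1e-6)
      stop("time grid is not uniform at ", fs, " Hz", call. = FALSE)
  }
  structure(x, class = c("observable_series", "data.frame"), fs = fs)
}

#' @export
print.observable_series <- function(x, ...) {
  cat(sprintf("observable series: %d samples at %g Hz (%.1f s)\n",
              nrow(x), attr(x, "fs"), nrow(x) / attr(x, "fs")))
  rng <- function(v) sprintf("%.2f-%.2f", min(v), max(v))
  cat(sprintf("  P_a %s mmHg | P_v %s mmHg | Hr %s bpm | P_p %s mmHg | RC %s s\n",
              rng(x$p_a), rng(x$p_v), rng(x$hr), rng(x$p_p), rng(x$rc)))
  invisible(x)
}

#' Read / write observable series
#'
#' Columnar text interchange for the five-observable series: a CSV with a
#' `# cvstate observables v1` header comment and columns
#' `t, pa, pv, hr, pp, rc`.
#'
#' @param x An `observable_series`.
#' @param path File path.
#' @return `write_observables` returns `path` invisibly; `read_observables`
#'   returns an `observable_series`.
#' @export
write_observables <- function(x, path) {
  stopifnot(inherits(x, "observable_series"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# cvstate observables v1 fs=%g", attr(x, "fs")), con)
  out <- x
  names(out) <- c("t", "pa", "pv", "hr", "pp", "rc")
  utils::write.csv(out, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_observables
#' @export
read_observables <- function(path) {
  header <- readLines(path, n = 1)
  fs <- 10
  if (grepl("^# cvstate observables", header)) {
    m <- regmatches(header, regexpr("fs=[0-9.]+", header))
    if (length(m)) fs <- as.numeric(sub("fs=", "", m))
  }
  x <- utils::read.csv(path, comment.char = "#")
  need <- c("t", "pa", "pv", "hr", "pp", "rc")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("observables file ", path, " lacks column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  names(x)[match(need, names(x))] <- c("t", "p_a", "p_v", "hr", "p_p", "rc")
  as_observable_series(x, fs = fs)
}

#' Write / read a simulation trace
#'
#' Full trace interchange (observables plus hidden states) as CSV with
#' columns `t, Pa, Pv, Hr, Pp, RC, Sb, Stot, Iex, Msvr`.
#'
#' @param trace A `cvs_trace`.
#' @param path File path.
#' @return `write_trace` returns `path` invisibly; `read_trace` a data frame.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "cvs_trace"))
  out <- data.frame(t = trace$t, Pa = trace$p_a, Pv = trace$p_v,
                    Hr = trace$hr, Pp = trace$p_p, RC = trace$rc,
                    Sb = trace$s_b, Stot = trace$s_tot,
                    Iex = trace$i_ex, Msvr = trace$m_svr)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# cvstate trace v1", con)
  utils::write.csv(out, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  x <- utils::read.csv(path, comment.char = "#")
  need <- c("t", "Pa", "Pv", "Hr", "Pp", "RC", "Sb", "Stot", "Iex", "Msvr")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("trace file ", path, " lacks column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  x
}
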