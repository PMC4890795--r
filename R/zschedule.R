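#' Gastric-outflow Z-schedule
#'
#' A piecewise-constant gastric-outflow state on a grid of interval
#' breakpoints. Each interval carries a code in `{0, 1, 2}`: 0 = no outflow,
#' 1 = slow outflow at `k_SP2`, 2 = fast outflow at `k_SP3`. Intervals are
#' half-open `[t_i, t_{i+1})`; lookups beyond the last breakpoint return the
#' last code.
#'
#' @param breakpoints strictly increasing times (min) delimiting the
#'   intervals, starting at 0; length `length(values) + 1`.
#' @param values integer codes in `{0, 1, 2}`, one per interval.
#' @return An object of class `z_schedule`.
#' @examples
#' z <- z_schedule(seq(0, 420, by = 30),
#'                 c(2, 1, 2, 2, 1, 0, 0, 1, 1, 1, 0, 0, 0, 0))
#' z_code_at(z, c(0, 29.9, 30, 1000))
#' @export
z_schedule <- function(breakpoints, values) {
  breakpoints <- as.numeric(breakpoints)
  values <- as.integer(values)
  if (length(breakpoints) != length(values) + 1L)
    stop("need length(breakpoints) == length(values) + 1 (",
         length(breakpoints), " breakpoints for ", length(values),
         " interval codes)")
  if (breakpoints[1] != 0) stop("breakpoints must start at 0")
  if (any(diff(breakpoints) <= 0))
    stop("breakpoints must be strictly increasing")
  bad <- which(!values %in% 0:2)
  if (length(bad))
    stop("invalid Z code ", values[bad[1]], " in interval ", bad[1],
         " (codes must be 0, 1 or 2)")
  structure(list(breakpoints = breakpoints, values = values),
            class = "z_schedule")
}

#' @rdname z_schedule
#' @param z a `z_schedule`.
#' @param t times (min) to look up.
#' @return `z_code_at()` returns the integer code per time.
#' @export
z_code_at <- function(z, t) {
  stopifnot(inherits(z, "z_schedule"))
  i <- findInterval(t, z$breakpoints, rightmost.closed = FALSE)
  i[i < 1L] <- 1L
  i[i > length(z$values)] <- length(z$values)
  z$values[i]
}

#' @export
print.z_schedule <- function(x, ...) {
  cat("<z_schedule> ", length(x$values), " intervals over [",
      x$breakpoints[1], ", ", x$breakpoints[length(x$breakpoints)],
      "] min\n", sep = "")
  cat("  codes: ", paste(x$values, collapse = ","), "\n", sep = "")
  invisible(x)
}

#' Gastric-emptying rate constant for a Z code
#'
#' Maps an outflow code to its first-order rate constant: 0 -> 0,
#' 1 -> `k_SP2` (slow), 2 -> `k_SP3` (fast).
#'
#' @param z_code integer code(s) in `{0, 1, 2}`.
#' @param params a [model_parameters()] object.
#' @return Rate constant(s), 1/min.
#' @export
emptying_rate <- function(z_code, params) {
  bad <- which(!z_code %in% 0:2)
  if (length(bad))
    stop("invalid Z code ", z_code[bad[1]], " in interval ", bad[1],
         " (codes must be 0, 1 or 2)")
  c(0, params$k_SP2, params$k_SP3)[z_code + 1L]
}
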