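#' @keywords internal
"_PACKAGE"

#' @importFrom stats fft mvfft optimize uniroot integrate quantile rnorm runif sd
#' @importFrom utils read.csv write.csv
NULL

# Stop with a classed condition so callers can distinguish failure modes.
stop_dietdx <- function(msg, class, call. = FALSE) {
  cond <- structure(
    class = c(class, "dietdx_error", "error", "condition"),
    list(message = msg, call = if (call.) sys.call(-1) else NULL)
  )
  stop(cond)
}

stop_invalid <- function(msg) stop_dietdx(msg, "dietdx_invalid_spec")

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_invalid(sprintf("`%s` must be a single finite number", name))
  lo_ok <- if (strict_lower) x > lower else x >= lower
  hi_ok <- if (strict_upper) x < upper else x <= upper
  if (!lo_ok || !hi_ok)
    stop_invalid(sprintf(
      "`%s` = %g outside allowed range %s%g, %g%s", name, x,
      if (strict_lower) "(" else "[", lower, upper,
      if (strict_upper) ")" else "]"
    ))
  x
}

check_side <- function(side) {
  if (!is.character(side) || length(side) != 1L || !side %in% c("left", "right"))
    stop_invalid("`side` must be \"left\" or \"right\"")
  side
}

# Run `expr` under a fixed seed without disturbing the caller's RNG state.
with_seed_ <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}

# Derive a reproducible child seed (kept within 32-bit integer range).
child_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(k)) %% 2147483587)
}
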