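# Internal helpers: classed conditions, seed scoping, number formatting.

rtlc_stop <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "rtlc_error")))
}

rtlc_warn <- function(msg, class) {
  warning(warningCondition(msg, class = c(class, "rtlc_warning")))
}

#' @noRd
assert_scalar_number <- function(x, name, min = -Inf, strict_min = FALSE,
                                 allow_null = FALSE) {
  if (is.null(x)) {
    if (allow_null) return(invisible(x))
    rtlc_stop(sprintf("'%s' must not be NULL", name), "rtlc_invalid_parameter")
  }
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    rtlc_stop(sprintf("'%s' must be a single finite number", name),
              "rtlc_invalid_parameter")
  }
  ok <- if (strict_min) x > min else x >= min
  if (!ok) {
    rtlc_stop(sprintf("'%s' must be %s %s (got %g)", name,
                      if (strict_min) ">" else ">=", format(min), x),
              "rtlc_invalid_parameter")
  }
  invisible(x)
}

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# random stream. A NULL seed leaves the global stream untouched.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  assert_scalar_number(seed, "seed")
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Deterministic, locale-independent numeric rendering for metadata values.
fmt_num <- function(x) {
  vapply(x, function(v) sprintf("%.10g", v), character(1))
}
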