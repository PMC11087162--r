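# Classed conditions so callers (and the CLI) can branch on failure stage.

gatelat_abort <- function(message, class, call = sys.call(-1)) {
  stop(errorCondition(message, class = c(paste0("gatelat_", class, "_error"),
                                         "gatelat_error", "error"),
                      call = call))
}

gatelat_warn <- function(message, class) {
  warning(warningCondition(message,
                           class = c(paste0("gatelat_", class, "_warning"),
                                     "gatelat_warning", "warning")))
}

# validate a scalar numeric field, naming the field in the error
check_scalar <- function(x, field, lower = -Inf, upper = Inf,
                         strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    gatelat_abort(sprintf("field '%s' must be a finite numeric scalar", field),
                  "config")
  lo_ok <- if (strict_lower) x > lower else x >= lower
  hi_ok <- if (strict_upper) x < upper else x <= upper
  if (!lo_ok || !hi_ok)
    gatelat_abort(sprintf("field '%s' = %g outside allowed range %s%g, %g%s",
                          field, x,
                          if (strict_lower) "(" else "[", lower, upper,
                          if (strict_upper) ")" else "]"),
                  "config")
  invisible(x)
}
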