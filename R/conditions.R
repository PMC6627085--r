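# Typed condition helpers. Every package error inherits from "ntk_error" plus
# a specific class so callers (and tests) can catch precisely.

ntk_abort <- function(class, message, ..., call = sys.call(-1)) {
  cond <- structure(
    class = c(class, "ntk_error", "error", "condition"),
    list(message = message, call = call, ...)
  )
  stop(cond)
}

ntk_warn <- function(class, message, call = sys.call(-1)) {
  cond <- structure(
    class = c(class, "ntk_warning", "warning", "condition"),
    list(message = message, call = call)
  )
  warning(cond)
}

# Input checking used across modules; raises an "ntk_domain_error".
check_scalar <- function(x, name, positive = FALSE, nonnegative = FALSE,
                         finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    ntk_abort("ntk_domain_error", sprintf("`%s` must be a single number", name))
  }
  if (finite && !is.finite(x)) {
    ntk_abort("ntk_domain_error", sprintf("`%s` must be finite", name))
  }
  if (positive && x <= 0) {
    ntk_abort("ntk_domain_error", sprintf("`%s` must be > 0 (got %g)", name, x))
  }
  if (nonnegative && x < 0) {
    ntk_abort("ntk_domain_error", sprintf("`%s` must be >= 0 (got %g)", name, x))
  }
  invisible(x)
}
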