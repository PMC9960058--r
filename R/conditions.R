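#' @keywords internal
"_PACKAGE"

# Classed conditions so callers (and the command-line wrapper) can map
# failures to exit codes without parsing messages.
ck_stop <- function(msg, class, ..., call = sys.call(-1)) {
  stop(errorCondition(msg, ..., class = c(class, "casekin_error"),
                      call = call))
}

ck_invalid <- function(msg, ...) ck_stop(msg, "casekin_invalid_parameter", ...)
ck_config_error <- function(msg, key = NULL, ...) {
  ck_stop(msg, "casekin_config_error", key = key, ...)
}

ck_warn <- function(msg, class = "casekin_warning") {
  warning(warningCondition(msg, class = class))
}

stopifnot_scalar_number <- function(x, name, positive = FALSE,
                                    nonnegative = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    ck_invalid(sprintf("'%s' must be a single finite number", name))
  if (positive && x <= 0)
    ck_invalid(sprintf("'%s' must be > 0 (got %g)", name, x))
  if (nonnegative && x < 0)
    ck_invalid(sprintf("'%s' must be >= 0 (got %g)", name, x))
  invisible(x)
}
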