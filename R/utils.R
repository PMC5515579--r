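# Internal helpers shared across modules.

# Classed conditions so callers can distinguish bad inputs from bad
# configuration from genuinely missing expression domains.
stop_invalid <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("bcdecode_invalid_input", "bcdecode_error")))
}

stop_config <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("bcdecode_config_error", "bcdecode_error")))
}

stop_domain <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("bcdecode_domain_error", "bcdecode_error")))
}

stop_numerical <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("bcdecode_numerical_error", "bcdecode_error")))
}

stop_fit <- function(msg, ..., last = NULL) {
  stop(errorCondition(sprintf(msg, ...), last_iterate = last,
                      class = c("bcdecode_fit_error", "bcdecode_error")))
}

check_finite <- function(x, what) {
  if (!is.numeric(x) || any(!is.finite(x)))
    stop_invalid("`%s` must be finite numeric", what)
  invisible(x)
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

`%||%` <- function(a, b) if (is.null(a)) b else a
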