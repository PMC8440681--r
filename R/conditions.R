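# Typed error conditions so callers (and the CLI) can distinguish
# user/config problems from runtime failures.

scshift_stop <- function(msg, class, call. = FALSE) {
  stop(errorCondition(msg, class = c(class, "scshift_error", "error")))
}

stop_format     <- function(msg) scshift_stop(msg, "scshift_format_error")
stop_integrity  <- function(msg) scshift_stop(msg, "scshift_integrity_error")
stop_validation <- function(msg) scshift_stop(msg, "scshift_validation_error")
stop_numerical  <- function(msg) scshift_stop(msg, "scshift_numerical_error")
stop_skip       <- function(msg) scshift_stop(msg, "scshift_skip_error")
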