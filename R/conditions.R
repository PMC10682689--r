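# Condition classes shared across the package. Three families map onto the
# CLI exit-code contract: format/usage errors (exit 2), domain violations
# (exit 1), and ordinary success (exit 0).

stop_format <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...), class = c("al_format_error", "al_error")))
}

stop_usage <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...), class = c("al_usage_error", "al_error")))
}

stop_domain <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...), class = c("al_domain_error", "al_error")))
}

# Logging goes to stderr via message() so result streams stay clean.
al_log <- function(msg, ...) {
  message(sprintf(msg, ...))
}
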