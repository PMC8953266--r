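# Structured conditions so callers (and the command-line wrapper) can tell
# input-validation problems apart from fit failures.

stop_validation <- function(msg, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c("lumibind_validation_error", "error"),
                      call = call))
}

stop_fit <- function(msg, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c("lumibind_fit_error", "error"),
                      call = call))
}
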