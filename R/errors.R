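# Structured conditions so callers (and the CLI) can map failures to
# exit codes: capkin_parse_error -> 2, capkin_fit_error -> 3,
# anything else -> 1.

stop_capkin <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "capkin_error"), call = call))
}

stop_invalid <- function(msg) stop_capkin(msg, "capkin_invalid_parameter")
stop_parse   <- function(msg) stop_capkin(msg, "capkin_parse_error")
stop_fit     <- function(msg) stop_capkin(msg, "capkin_fit_error")

`%||%` <- function(a, b) if (is.null(a)) b else a
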