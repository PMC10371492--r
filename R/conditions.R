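# Classed conditions so callers (and the CLI) can distinguish user errors
# from internal ones. All inherit from "kinmatrix_error".

kin_stop <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "kinmatrix_error", "error", "condition"),
                      call = call))
}

stop_format     <- function(msg) kin_stop(msg, "kin_format_error")
stop_validation <- function(msg) kin_stop(msg, "kin_validation_error")
stop_parameter  <- function(msg) kin_stop(msg, "kin_parameter_error")
stop_cycle      <- function(msg) kin_stop(msg, c("kin_cycle_error", "kin_validation_error"))
stop_numeric    <- function(msg) kin_stop(msg, "kin_numeric_error")

# validation-type errors map to CLI exit status 2
is_user_error <- function(cond) {
  inherits(cond, c("kin_format_error", "kin_validation_error",
                   "kin_parameter_error", "kin_cycle_error"))
}
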