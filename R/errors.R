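# Classed conditions so callers (and the CLI) can map failures to causes.

glp_error <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "glp_error", "error")))
}

stop_input <- function(...) glp_error(paste0(...), "glp_input_error")
stop_validation <- function(...) glp_error(paste0(...), "glp_validation_error")
stop_numerical <- function(...) glp_error(paste0(...), "glp_numerical_error")
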