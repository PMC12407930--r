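## Classed conditions shared across the package. The CLI maps these onto
## exit codes (input 2, parameter 3, empty-result 4).

dnds_error <- function(msg, class, call. = FALSE) {
  stop(errorCondition(msg, class = c(class, "dnds_error", "error", "condition")))
}

dnds_input_error <- function(msg) dnds_error(msg, "dnds_input_error")

dnds_parameter_error <- function(msg) dnds_error(msg, "dnds_parameter_error")

dnds_empty_error <- function(msg) dnds_error(msg, "dnds_empty_error")
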