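# Classed error conditions so callers (and tests) can distinguish
# configuration, file-format, input-validation and mathematical-domain
# failures without matching on message text.

stop_config <- function(msg, call. = FALSE) {
  stop(errorCondition(msg, class = c("herdghg_config_error", "herdghg_error")))
}

stop_format <- function(msg) {
  stop(errorCondition(msg, class = c("herdghg_format_error", "herdghg_error")))
}

stop_validation <- function(msg) {
  stop(errorCondition(msg, class = c("herdghg_validation_error", "herdghg_error")))
}

stop_domain <- function(msg) {
  stop(errorCondition(msg, class = c("herdghg_domain_error", "herdghg_error")))
}
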