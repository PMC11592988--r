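# Structured conditions. Every error raised by the package carries a class of
# the form "ffg_<snake_case_code>" plus "ffg_error", so callers (and tests)
# can dispatch on the failure kind rather than on message text.

ffg_stop <- function(code, msg, ...) {
  stop(errorCondition(sprintf(msg, ...), class = c(paste0("ffg_", code), "ffg_error")))
}

ffg_warn <- function(code, msg, ...) {
  warning(warningCondition(sprintf(msg, ...), class = c(paste0("ffg_", code), "ffg_warning")))
}
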