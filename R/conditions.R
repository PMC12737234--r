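# Classed conditions so callers (and the CLI) can distinguish failure modes:
#   apd_format_error   - a file does not conform to its declared format
#   apd_contract_error - two inputs that must agree (e.g. sample sets) do not
#   apd_domain_error   - an argument is outside its mathematical domain
#   apd_lookup_error   - a requested ID does not exist (subclass of contract)

stop_format <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("apd_format_error", "apd_error")))
}

stop_contract <- function(msg, ..., class = character()) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c(class, "apd_contract_error", "apd_error")))
}

stop_lookup <- function(msg, ...) {
  stop_contract(msg, ..., class = "apd_lookup_error")
}

stop_domain <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("apd_domain_error", "apd_error")))
}
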