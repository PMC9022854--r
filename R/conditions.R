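# Classed conditions so callers (and the CLI) can map failures to exit codes:
# config errors, data/validation errors, and degenerate-math errors are
# distinguishable without parsing messages.

qci_abort <- function(message, class) {
  rlang::abort(message, class = c(class, "qcindex_error"))
}

abort_schema <- function(message) qci_abort(message, "qcindex_schema_error")
abort_validation <- function(message) qci_abort(message, "qcindex_validation_error")
abort_config <- function(message) qci_abort(message, "qcindex_config_error")
abort_data <- function(message) qci_abort(message, "qcindex_data_error")
abort_degenerate <- function(message) qci_abort(message, "qcindex_degenerate_error")
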