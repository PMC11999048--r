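# Structured condition classes so callers (and the CLI) can map failures to
# exit codes: config errors, data/format errors, internal errors.

pf_error <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "pf_error"), call = call))
}

#' @noRd
pf_format_error <- function(msg) pf_error(msg, "pf_format_error")

#' @noRd
pf_bounds_error <- function(msg) pf_error(msg, "pf_bounds_error")

#' @noRd
pf_domain_error <- function(msg) pf_error(msg, "pf_domain_error")

#' @noRd
pf_config_error <- function(msg) pf_error(msg, "pf_config_error")

#' @noRd
pf_capacity_error <- function(msg) pf_error(msg, "pf_capacity_error")

#' @noRd
pf_io_error <- function(msg) pf_error(msg, "pf_io_error")
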