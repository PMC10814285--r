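# Classed conditions so callers (and the CLI) can map error kinds to exit
# codes: input errors are problems with the data, config errors with the
# requested settings.

abort_input <- function(msg, ...) {
  abort(msg, class = "fairgibbs_input_error", ...)
}

abort_config <- function(msg, ...) {
  abort(msg, class = "fairgibbs_config_error", ...)
}

abort_internal <- function(msg, ...) {
  abort(msg, class = "fairgibbs_internal_error", ...)
}
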