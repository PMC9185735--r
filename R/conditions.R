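# Classed conditions so callers (and the command-line front end) can map
# failures onto exit codes: validation problems vs. I/O problems.

stop_validation <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("ecoclim_validation_error", "ecoclim_error")))
}

stop_io <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("ecoclim_io_error", "ecoclim_error")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
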