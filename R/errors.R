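# Classed conditions so callers (and the CLI) can distinguish bad inputs,
# bad configuration, unfittable problems and numerical failures.

glocal_error <- function(message, class) {
  stop(structure(
    class = c(class, "glocalsvm_error", "error", "condition"),
    list(message = message, call = sys.call(-1))
  ))
}

stop_input     <- function(message) glocal_error(message, "glocalsvm_input_error")
stop_config    <- function(message) glocal_error(message, "glocalsvm_config_error")
stop_unfittable <- function(message) glocal_error(message, "glocalsvm_unfittable_error")
stop_numerical <- function(message) glocal_error(message, "glocalsvm_numerical_error")
stop_io        <- function(message) glocal_error(message, "glocalsvm_io_error")

# Derive a per-stage seed from a master seed; kept inside 32-bit integer range.
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) %% 2147483647 + 104729 * as.numeric(index)) %% 2147483647)
}
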