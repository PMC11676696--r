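# Condition constructors. All package errors carry a subclass so callers (and
# the CLI) can distinguish bad arguments / malformed files / failed detection.

stop_with <- function(subclass, msg, ...) {
  stop(structure(class = c(subclass, "tricadence_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1), ...)))
}

stop_validation <- function(msg, ...) stop_with("tricadence_validation_error", msg, ...)
stop_format     <- function(msg, ...) stop_with("tricadence_format_error", msg, ...)
stop_io         <- function(msg, ...) stop_with("tricadence_io_error", msg, ...)
stop_argument   <- function(msg, ...) stop_with("tricadence_argument_error", msg, ...)
stop_detection  <- function(msg, ...) stop_with("tricadence_detection_error", msg, ...)
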