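# Condition constructors shared by all modules. Every error raised by the
# package carries class "eegbids_error" plus a specific subclass, so callers
# (and the validator, which must never crash on malformed content) can catch
# selectively with tryCatch(..., eegbids_format_error = ...).

bids_abort <- function(subclass, message, ...) {
  stop(errorCondition(message, ..., class = c(subclass, "eegbids_error")))
}

grammar_error   <- function(message, ...) bids_abort("eegbids_grammar_error", message, ...)
invariant_error <- function(message, ...) bids_abort("eegbids_invariant_error", message, ...)
schema_error    <- function(message, ...) bids_abort("eegbids_schema_error", message, ...)
format_error    <- function(message, ...) bids_abort("eegbids_format_error", message, ...)
range_error     <- function(message, ...) bids_abort("eegbids_range_error", message, ...)
ambiguity_error <- function(message, ...) bids_abort("eegbids_ambiguity_error", message, ...)
collision_error <- function(message, ...) bids_abort("eegbids_collision_error", message, ...)
io_error        <- function(message, ...) bids_abort("eegbids_io_error", message, ...)
unknown_code_error <- function(message, ...) bids_abort("eegbids_unknown_code_error", message, ...)
usage_error     <- function(message, ...) bids_abort("eegbids_usage_error", message, ...)

precision_warning <- function(message) {
  warning(warningCondition(message, class = c("eegbids_precision_warning", "eegbids_warning")))
}
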