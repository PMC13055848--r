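#' @keywords internal
"_PACKAGE"

# Typed condition helpers: every user-facing failure carries a subclass so
# callers (and tests) can distinguish schema, validation and numerical errors.
ep_abort <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "endoprofiler_error")))
}

ep_schema_error <- function(msg) ep_abort(msg, "ep_schema_error")
ep_validation_error <- function(msg) ep_abort(msg, "ep_validation_error")
ep_numerical_error <- function(msg) ep_abort(msg, "ep_numerical_error")
ep_degenerate_error <- function(msg) ep_abort(msg, "ep_degenerate_error")

is_count1 <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x == round(x)
}

# Delimiter from file extension: .csv -> comma, anything else tab.
delim_for <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

stage_log <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, paste0(...)))
}
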