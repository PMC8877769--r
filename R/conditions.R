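# Structured error conditions. Every error raised by the package inherits from
# "fetalhc_error" plus one specific class, so callers can branch on failure
# mode (e.g. treat a fit failure as a skipped prediction, not a crash).

fhc_stop <- function(msg, class, ..., call = sys.call(-1)) {
  stop(errorCondition(msg, ..., class = c(class, "fetalhc_error", "error"),
                      call = call))
}

stop_invalid_parameter <- function(msg, ...) {
  fhc_stop(msg, "fetalhc_invalid_parameter", ...)
}

stop_invalid_input <- function(msg, ...) {
  fhc_stop(msg, "fetalhc_invalid_input", ...)
}

# cause: one of "too_few_points", "degenerate_points", "not_an_ellipse",
# "empty_contour" -- a distinct code per failure mode.
stop_fit_failure <- function(msg, cause, ...) {
  fhc_stop(msg, "fetalhc_fit_failure", cause = cause, ...)
}

stop_empty_mask <- function(msg, ...) {
  fhc_stop(msg, "fetalhc_empty_mask", ...)
}

stop_config_error <- function(msg, ...) {
  fhc_stop(msg, "fetalhc_config_error", ...)
}

stop_insufficient_data <- function(msg, ...) {
  fhc_stop(msg, "fetalhc_insufficient_data", ...)
}

#' Extract the failure cause from a fit-failure condition
#'
#' @param cond A condition object, typically caught from a failed call to
#'   [fit_ellipse()] or [postprocess_to_points()].
#' @return A character scalar (e.g. `"too_few_points"`) or `NA_character_` if
#'   the condition carries no cause.
#' @export
fit_failure_cause <- function(cond) {
  if (!is.null(cond$cause)) cond$cause else NA_character_
}
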