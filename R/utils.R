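# Internal helpers shared across modules.

stop_invalid <- function(...) {
  stop(structure(class = c("ccflow_invalid_argument", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

stop_degenerate <- function(...) {
  stop(structure(class = c("ccflow_degenerate_input", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

stop_format <- function(...) {
  stop(structure(class = c("ccflow_format_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

stop_singular <- function(...) {
  stop(structure(class = c("ccflow_singular_design", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

stop_dependency <- function(...) {
  stop(structure(class = c("ccflow_dependency_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

#' @noRd
check_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_invalid(name, " must be a single finite number")
  if (positive && x <= 0)
    stop_invalid(name, " must be positive (got ", x, ")")
  invisible(x)
}

# Fixed condition order used everywhere downstream.
CC_CONDITIONS <- c("balance", "calculation", "dual")

clip01 <- function(x) pmin(1, pmax(0, x))

# Derive a stage seed from a master seed, staying inside 32-bit integer range.
derive_seed <- function(seed, offset) {
  (as.integer(seed) %% 1000000L) * 2000L + as.integer(offset)
}
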