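# Internal helpers: classed conditions and seed scoping.

#' @importFrom withr with_seed
NULL

nm_stop <- function(msg, class, call. = FALSE) {
  stop(structure(
    class = c(class, "nucleomech_error", "error", "condition"),
    list(message = msg, call = if (call.) sys.call(-1) else NULL)
  ))
}

stop_invalid_parameter  <- function(msg) nm_stop(msg, "invalid_parameter_error")
stop_invalid_geometry   <- function(msg) nm_stop(msg, "invalid_geometry_error")
stop_data               <- function(msg) nm_stop(msg, "data_error")
stop_shape              <- function(msg) nm_stop(msg, "shape_error")
stop_convergence        <- function(msg) nm_stop(msg, "convergence_error")
stop_segmentation       <- function(msg) nm_stop(msg, "segmentation_failure_error")
stop_degenerate         <- function(msg) nm_stop(msg, "degenerate_input_error")
stop_schema             <- function(msg) nm_stop(msg, "schema_error")
stop_io                 <- function(msg) nm_stop(msg, "io_error")

# All generator randomness is scoped to an explicit integer seed; the global
# RNG stream of the calling session is left untouched.
with_nm_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop_invalid_parameter("`seed` must be a single finite integer")
  }
  withr::with_seed(as.integer(seed), code)
}

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
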