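# Registries of node activation and aggregation functions.
#
# Activations are applied to z = bias + response * aggregation(weighted
# inputs).  The logistic is clamped at |z| = 60, far outside double-precision
# saturation, so lesioned networks can never produce NaN via overflow.

.netlesion_registry <- new.env(parent = emptyenv())

.init_registry <- function() {
  .netlesion_registry$activation <- list(
    # plain logistic; saturates cleanly to 0/1 at extreme z (no NaN for
    # finite input), equivalent to clamping z at +/-60 within double
    # precision
    sigmoid  = function(z) 1 / (1 + exp(-z)),
    identity = function(z) z,
    tanh     = function(z) tanh(z),
    relu     = function(z) pmax(z, 0)
  )
  # Aggregations receive a numeric vector of weighted incoming values; the
  # empty set aggregates to 0 ("severed connections pass zero").
  .netlesion_registry$aggregation <- list(
    sum = function(x) if (length(x)) sum(x) else 0,
    max = function(x) if (length(x)) max(x) else 0
  )
}

#' Register a custom activation or aggregation function
#'
#' Networks refer to activation and aggregation functions by name; the
#' registry maps those names to R functions. `sigmoid` (plain logistic,
#' clamped at |z| = 60), `identity`, `tanh` and `relu` activations and `sum`
#' and `max` aggregations are built in. Registering an existing name
#' overwrites it, so alternative sigmoid parameterisations can be swapped in.
#'
#' @param name Character name used by node genes.
#' @param fn For activations, a vectorised function of the pre-activation
#'   `z`; for aggregations, a function of the numeric vector of weighted
#'   incoming values (it must return 0 for `numeric(0)`).
#' @param kind `"activation"` or `"aggregation"`.
#' @return `name`, invisibly.
#' @examples
#' register_net_function("neg", function(z) -z, "activation")
#' @export
register_net_function <- function(name, fn, kind = c("activation", "aggregation")) {
  kind <- match.arg(kind)
  stopifnot(is.character(name), length(name) == 1L, is.function(fn))
  .netlesion_registry[[kind]][[name]] <- fn
  invisible(name)
}

get_activation <- function(name) {
  fn <- .netlesion_registry$activation[[name]]
  if (is.null(fn)) stop("unregistered activation function: '", name, "'", call. = FALSE)
  fn
}

get_aggregation <- function(name) {
  fn <- .netlesion_registry$aggregation[[name]]
  if (is.null(fn)) stop("unregistered aggregation function: '", name, "'", call. = FALSE)
  fn
}

registered_net_functions <- function(kind = c("activation", "aggregation")) {
  names(.netlesion_registry[[match.arg(kind)]])
}
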