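#' Construct a forward-model object
#'
#' A forward model maps a matrix of parameter vectors (rows) to a matrix of
#' outputs plus a validity flag per row. This is the interface consumed by
#' the SMC calibration engine, the range-calibration routine and the
#' refinement pipeline; implementations include the CRN simulator
#' ([crn_forward_model()]) and the closed-form test models
#' ([toy_models()]).
#'
#' @param fn Function taking an `n x d` parameter matrix and returning
#'   `list(y = n x k output matrix, valid = logical(n))`.
#' @param param_names,output_names Dimension names.
#' @param bounds List with named `lower` and `upper` vectors.
#' @param name Short identifier used in provenance records.
#' @param pushforward Optional analytic density of outputs under uniform
#'   parameters (used by tests), a function of an output matrix.
#' @return An object of class `forward_model`.
#' @export
forward_model <- function(fn, param_names, output_names, bounds,
                          name = "forward", pushforward = NULL) {
  stopifnot(is.function(fn),
            length(bounds$lower) == length(param_names),
            length(bounds$upper) == length(param_names))
  if (any(bounds$lower >= bounds$upper))
    stop("each lower bound must be below its upper bound")
  structure(list(fn = fn, param_names = param_names,
                 output_names = output_names, bounds = bounds,
                 name = name, pushforward = pushforward),
            class = "forward_model")
}

#' Evaluate a forward model on a matrix of parameter vectors
#'
#' @param model A [forward_model()].
#' @param theta Numeric matrix (rows = parameter vectors) or a single
#'   vector.
#' @return `list(y, valid)` as documented in [forward_model()].
#' @export
evaluate_forward <- function(model, theta) {
  stopifnot(inherits(model, "forward_model"))
  if (is.null(dim(theta))) theta <- matrix(theta, nrow = 1)
  if (ncol(theta) != length(model$param_names))
    stop("theta has ", ncol(theta), " columns; model expects ",
         length(model$param_names))
  out <- model$fn(theta)
  stopifnot(is.matrix(out$y), length(out$valid) == nrow(theta))
  colnames(out$y) <- model$output_names
  out
}

#' @export
print.forward_model <- function(x, ...) {
  cat(sprintf("Forward model '%s': %d parameters -> %d outputs\n",
              x$name, length(x$param_names), length(x$output_names)))
  invisible(x)
}
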