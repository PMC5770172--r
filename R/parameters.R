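#' Names of the scaled CRN current magnitudes
#'
#' The eleven current magnitudes that are varied when building populations of
#' CRN models: the fast Na+ conductance, five K+ conductances, the L-type
#' Ca2+ conductance, the maximal Na+/K+ pump and Na+/Ca2+ exchanger currents,
#' and the maximal SR uptake and release rates.
#'
#' @return Character vector of length 11.
#' @export
crn_param_names <- function() {
  c("gNa", "gto", "gKur", "gKr", "gKs", "gK1", "gCaL",
    "INaK_max", "INaCa_max", "Iup_max", "krel")
}

#' Construct a CRN parameter vector of dimensionless multipliers
#'
#' Each entry scales the corresponding published CRN magnitude; all ones is
#' the original model. `tau_h_scale` multiplies the time constant of the
#' I_Na h (fast inactivation) gate and defaults to 1 (no change).
#'
#' @param gNa,gto,gKur,gKr,gKs,gK1,gCaL Conductance multipliers (>= 0).
#' @param INaK_max,INaCa_max Pump/exchanger maximal-current multipliers.
#' @param Iup_max,krel SR uptake/release maximal-rate multipliers.
#' @param tau_h_scale Multiplier on the I_Na h-gate time constant.
#' @return Named numeric vector of class `crn_parameters` (length 12).
#' @export
crn_parameters <- function(gNa = 1, gto = 1, gKur = 1, gKr = 1, gKs = 1,
                           gK1 = 1, gCaL = 1, INaK_max = 1, INaCa_max = 1,
                           Iup_max = 1, krel = 1, tau_h_scale = 1) {
  theta <- c(gNa = gNa, gto = gto, gKur = gKur, gKr = gKr, gKs = gKs,
             gK1 = gK1, gCaL = gCaL, INaK_max = INaK_max,
             INaCa_max = INaCa_max, Iup_max = Iup_max, krel = krel,
             tau_h_scale = tau_h_scale)
  validate_parameters(theta)
  structure(theta, class = "crn_parameters")
}

validate_parameters <- function(theta) {
  if (!is.numeric(theta) || anyNA(theta) || any(!is.finite(theta)))
    stop("parameter multipliers must be finite numbers")
  if (any(theta < 0))
    stop("parameter multipliers must be >= 0")
  invisible(theta)
}

#' Coerce a named vector or list to a full 12-entry parameter vector
#'
#' Missing entries default to 1 (the published value); unknown names are an
#' error.
#'
#' @param x Named numeric vector or list.
#' @return A `crn_parameters` vector.
#' @export
as_crn_parameters <- function(x) {
  if (inherits(x, "crn_parameters")) return(x)
  x <- unlist(x)
  full <- c(crn_param_names(), "tau_h_scale")
  bad <- setdiff(names(x), full)
  if (length(bad))
    stop("unknown parameter name(s): ", paste(bad, collapse = ", "))
  theta <- setNames(rep(1, length(full)), full)
  theta[names(x)] <- x
  do.call(crn_parameters, as.list(theta))
}

#' Parameter-space bounds for population construction
#'
#' Defaults to a +/-100% search space, i.e. every multiplier in `[0, 2]`. The
#' gNa upper bound can be widened (e.g. to 4, +300%) and the h-gate time
#' constant scaling can be included as a twelfth searched dimension.
#'
#' @param lower,upper Default per-dimension bounds.
#' @param gNa_upper Optional replacement upper bound for gNa.
#' @param include_tau_h Include `tau_h_scale` as a searched dimension?
#' @return List with numeric vectors `lower` and `upper` (named).
#' @export
crn_bounds <- function(lower = 0, upper = 2, gNa_upper = NULL,
                       include_tau_h = FALSE) {
  nm <- crn_param_names()
  if (include_tau_h) nm <- c(nm, "tau_h_scale")
  lo <- setNames(rep(lower, length(nm)), nm)
  hi <- setNames(rep(upper, length(nm)), nm)
  if (!is.null(gNa_upper)) hi["gNa"] <- gNa_upper
  if (any(lo >= hi)) stop("each lower bound must be below its upper bound")
  list(lower = lo, upper = hi)
}

#' Chronic-AF remodelled baseline parameters
#'
#' Applies the experimentally quantified conductance adjustments associated
#' with chronic atrial fibrillation to a parameter vector: I_to x0.3,
#' I_Kur x0.5, I_Ks x2, I_K1 x2, I_CaL x0.3 and the Na+/Ca2+ exchanger x1.4.
#' Currents for which no consistent quantitative change has been reported
#' are left unchanged.
#'
#' @param theta Parameter vector to remodel (default: baseline, all ones).
#' @return A `crn_parameters` vector.
#' @export
caf_remodelled_parameters <- function(theta = crn_parameters()) {
  theta <- as_crn_parameters(theta)
  adj <- c(gto = 0.3, gKur = 0.5, gKs = 2, gK1 = 2, gCaL = 0.3,
           INaCa_max = 1.4)
  theta[names(adj)] <- theta[names(adj)] * adj
  structure(theta, class = "crn_parameters")
}

#' Apply a fractional block to one scaled current
#'
#' Models drug block of a single channel/pump by scaling the named
#' multiplier by `1 - block_fraction`; all other entries are untouched.
#'
#' @param theta Parameter vector.
#' @param current_name One of [crn_param_names()].
#' @param block_fraction Fraction blocked, in \[0, 1\].
#' @return A `crn_parameters` vector.
#' @export
apply_drug_block <- function(theta, current_name, block_fraction) {
  theta <- as_crn_parameters(theta)
  if (length(current_name) != 1L || !current_name %in% crn_param_names())
    stop("unknown current name: ", current_name)
  if (!is.numeric(block_fraction) || block_fraction < 0 || block_fraction > 1)
    stop("block_fraction must lie in [0, 1]")
  theta[current_name] <- theta[current_name] * (1 - block_fraction)
  theta
}
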