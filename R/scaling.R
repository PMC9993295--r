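#' Allometric scaling model
#'
#' Parameterises the power law \eqn{Y = \alpha \cdot BW^b} used to scale an
#' adult quantity (a maintenance dose in mg, or a clearance) down to a child
#' of known body weight.  With the default exponent \eqn{b = 0.75} the model
#' expresses the standard observation that metabolic quantities -- drug
#' clearance in particular -- scale with the three-quarter power of body
#' weight, so that at steady state the paediatric maintenance dose is
#'
#' \deqn{Dose_{child} = Dose_{adult} \times (W_{child} / W_{ref})^{0.75}}
#'
#' anchored at a reference adult weight (70 kg by convention).
#'
#' @param adult_value Adult value of the scaled quantity; mg for a dose.
#'   Must be positive.
#' @param reference_weight_kg Reference adult body weight in kg
#'   (default 70).  Must be positive.
#' @param exponent Allometric exponent \eqn{b}; must lie in (0, 2].
#'   0.75 for clearance-type quantities, 1 recovers linear per-kg scaling.
#' @return An object of class `scaling_model`.
#' @examples
#' m <- scaling_model(adult_value = 600)
#' power_scale(m, 9.6)      # dose for a 9.6 kg child
#' weight_for_dose(m, 300)  # weight at which half the adult dose is exact
#' @seealso [allometric_dose()], [weight_for_dose()], [build_allometric_bands()]
#' @export
scaling_model <- function(adult_value = 600, reference_weight_kg = 70,
                          exponent = 0.75) {
  stopifnot(is.numeric(adult_value), length(adult_value) == 1L,
            is.numeric(reference_weight_kg), length(reference_weight_kg) == 1L,
            is.numeric(exponent), length(exponent) == 1L)
  if (!is.finite(adult_value) || adult_value <= 0)
    stop("`adult_value` must be a positive number", call. = FALSE)
  if (!is.finite(reference_weight_kg) || reference_weight_kg <= 0)
    stop("`reference_weight_kg` must be a positive number", call. = FALSE)
  if (!is.finite(exponent) || exponent <= 0 || exponent > 2)
    stop("`exponent` must lie in (0, 2]", call. = FALSE)
  structure(
    list(adult_value = as.numeric(adult_value),
         reference_weight_kg = as.numeric(reference_weight_kg),
         exponent = as.numeric(exponent)),
    class = "scaling_model"
  )
}

#' @export
print.scaling_model <- function(x, ...) {
  cat(sprintf(
    "Allometric scaling model: adult value %g at %g kg, exponent %g\n",
    x$adult_value, x$reference_weight_kg, x$exponent))
  invisible(x)
}

check_weight <- function(weight_kg) {
  if (!is.numeric(weight_kg) || length(weight_kg) == 0L)
    stop("`weight_kg` must be numeric", call. = FALSE)
  if (any(!is.finite(weight_kg)) || any(weight_kg <= 0))
    stop("`weight_kg` must be positive and finite", call. = FALSE)
  as.numeric(weight_kg)
}

#' Scale an adult quantity to a body weight
#'
#' Evaluates the power law: `adult_value * (weight / reference_weight)^exponent`.
#' Strictly increasing in weight; returns `adult_value` exactly at the
#' reference weight.  Vectorised over `weight_kg`.
#'
#' @param model A [scaling_model()].
#' @param weight_kg Body weight(s) in kg; positive.
#' @return Numeric vector of scaled values (same units as `adult_value`).
#' @export
power_scale <- function(model, weight_kg) {
  stopifnot(inherits(model, "scaling_model"))
  w <- check_weight(weight_kg)
  model$adult_value * (w / model$reference_weight_kg)^model$exponent
}

#' Paediatric dose by allometric scaling
#'
#' The continuous (unrounded) paediatric dose for a child of the given
#' weight.  With `cap_at_adult = TRUE` (the default) weights above the
#' reference weight receive the adult dose rather than an extrapolated
#' larger one.
#'
#' @inheritParams power_scale
#' @param cap_at_adult Cap the result at `adult_value` for weights above
#'   the reference weight (default `TRUE`).
#' @return Numeric vector of doses in the units of `adult_value` (mg).
#' @export
allometric_dose <- function(model, weight_kg, cap_at_adult = TRUE) {
  d <- power_scale(model, weight_kg)
  if (isTRUE(cap_at_adult)) d <- pmin(d, model$adult_value)
  d
}

#' Body weight at which a paediatric dose is exact
#'
#' Inverts the allometric dose equation:
#' `weight = reference_weight * (dose / adult_value)^(1/exponent)`.
#' This is the construction rule for allometric weight-band edges: the
#' weight returned for a tablet step is the heaviest child for whom that
#' step is not an underdose.
#'
#' @inheritParams power_scale
#' @param dose_mg Paediatric dose(s); must lie in (0, adult dose].
#' @return Numeric vector of weights in kg.
#' @export
weight_for_dose <- function(model, dose_mg) {
  stopifnot(inherits(model, "scaling_model"))
  if (!is.numeric(dose_mg) || length(dose_mg) == 0L)
    stop("`dose_mg` must be numeric", call. = FALSE)
  if (any(!is.finite(dose_mg)) || any(dose_mg <= 0))
    stop("`dose_mg` must be positive and finite", call. = FALSE)
  if (any(dose_mg > model$adult_value))
    stop("`dose_mg` must not exceed the adult dose (",
         model$adult_value, ")", call. = FALSE)
  model$reference_weight_kg * (dose_mg / model$adult_value)^(1 / model$exponent)
}

#' Read / write a scaling model as JSON
#'
#' The on-disk form is a flat JSON object, e.g.
#' `{"adult_dose_mg": 600, "reference_weight_kg": 70, "exponent": 0.75}`.
#' `adult_value` is accepted as an alias for `adult_dose_mg`.
#'
#' @param path File path.
#' @return `read_scaling_model()` returns a [scaling_model()];
#'   `write_scaling_model()` returns `path` invisibly.
#' @export
read_scaling_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  adult <- x$adult_dose_mg %||% x$adult_value
  if (is.null(adult))
    stop("scaling model JSON needs `adult_dose_mg` (or `adult_value`): ",
         path, call. = FALSE)
  scaling_model(adult_value = adult,
                reference_weight_kg = x$reference_weight_kg %||% 70,
                exponent = x$exponent %||% 0.75)
}

#' @rdname read_scaling_model
#' @param model A [scaling_model()].
#' @export
write_scaling_model <- function(model, path) {
  stopifnot(inherits(model, "scaling_model"))
  jsonlite::write_json(
    list(adult_dose_mg = model$adult_value,
         reference_weight_kg = model$reference_weight_kg,
         exponent = model$exponent),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
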