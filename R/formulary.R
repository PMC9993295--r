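#' Tablet formulary
#'
#' The ordered list of dispensable dose steps for one drug, expressed in mg
#' of the index component.  For a fixed-dose combination the co-formulated
#' component follows the tablet ratio and need not be carried separately:
#' the default abacavir/lamivudine (ABC/3TC) formulary is stated in mg ABC,
#' with 3TC at half the ABC dose (2:1 FDC ratio).
#'
#' @param steps Numeric vector of dose steps in mg, strictly increasing.
#' @param labels Character vector of tablet-count labels, one per step
#'   (e.g. `"1.5"`, `"adult"`).
#' @param unit_strength_mg Strength of one paediatric tablet unit in mg of
#'   the index drug (120 for the ABC/3TC 120/60 dispersible tablet).
#' @param drug_label Display name of the drug.
#' @param adult_dose_mg Adult dose; must equal the largest step
#'   (default: the largest step).
#' @return An object of class `formulary`.
#' @examples
#' f <- abc3tc_formulary()
#' round_to_formulary(277.2, f)
#' @export
formulary <- function(steps, labels = as.character(steps),
                      unit_strength_mg = steps[1],
                      drug_label = "drug",
                      adult_dose_mg = max(steps)) {
  if (!is.numeric(steps) || length(steps) == 0L)
    stop("`steps` must be a non-empty numeric vector", call. = FALSE)
  if (any(!is.finite(steps)) || any(steps <= 0))
    stop("formulary steps must be positive and finite", call. = FALSE)
  if (any(diff(steps) <= 0))
    stop("formulary steps must be strictly increasing with no duplicates",
         call. = FALSE)
  if (length(labels) != length(steps))
    stop("`labels` must have one entry per step", call. = FALSE)
  if (!isTRUE(all.equal(adult_dose_mg, max(steps))))
    stop("`adult_dose_mg` must equal the largest step", call. = FALSE)
  if (!is.finite(unit_strength_mg) || unit_strength_mg <= 0)
    stop("`unit_strength_mg` must be positive", call. = FALSE)
  structure(
    list(drug_label = as.character(drug_label),
         unit_strength_mg = as.numeric(unit_strength_mg),
         steps = data.frame(dose_mg = as.numeric(steps),
                            label = as.character(labels),
                            stringsAsFactors = FALSE),
         adult_dose_mg = as.numeric(adult_dose_mg)),
    class = "formulary"
  )
}

#' @export
print.formulary <- function(x, ...) {
  cat(sprintf("Formulary for %s (unit tablet %g mg, adult dose %g mg)\n",
              x$drug_label, x$unit_strength_mg, x$adult_dose_mg))
  print(x$steps, row.names = FALSE)
  invisible(x)
}

#' Default ABC/3TC dispersible-tablet formulary
#'
#' Dose steps available from the paediatric 120/60 mg ABC/3TC dispersible
#' tablet in half-tablet increments, topped by the 600/300 mg adult tablet:
#' 120, 180, 240, 300, 360 and 600 mg ABC, labelled by tablet count
#' ("1" ... "3", "adult").
#'
#' @return A [formulary()].
#' @export
abc3tc_formulary <- function() {
  formulary(steps  = c(120, 180, 240, 300, 360, 600),
            labels = c("1", "1.5", "2", "2.5", "3", "adult"),
            unit_strength_mg = 120,
            drug_label = "ABC/3TC")
}

#' Rounding policy for formulary conversion
#'
#' How a continuous dose is mapped onto the discrete formulary steps.
#' `nearest` picks the closest step (the "closest equivalent dose"
#' convention for per-patient conversion); `ceil` picks the smallest step
#' at or above the dose (the convention under which weight-band tables are
#' built, so no band underdoses its heaviest child); `floor` is symmetric.
#'
#' @param mode One of `"nearest"`, `"ceil"`, `"floor"`.
#' @param tie_rule For `nearest` at an exact midpoint: `"lower"`
#'   (conservative dosing; default) or `"higher"`.
#' @param cap_at_adult Never return a step above the adult dose
#'   (default `TRUE`; with steps capped at the adult dose this also governs
#'   `ceil` when the dose exceeds every step).
#' @return An object of class `rounding_policy`.
#' @export
rounding_policy <- function(mode = c("nearest", "ceil", "floor"),
                            tie_rule = c("lower", "higher"),
                            cap_at_adult = TRUE) {
  mode <- match.arg(mode)
  tie_rule <- match.arg(tie_rule)
  structure(list(mode = mode, tie_rule = tie_rule,
                 cap_at_adult = isTRUE(cap_at_adult)),
            class = "rounding_policy")
}

#' Round a continuous dose to a dispensable formulary step
#'
#' Vectorised over `dose_mg`.  `nearest` minimises the absolute distance to
#' a step, breaking exact midpoints by `policy$tie_rule`; `ceil` returns the
#' smallest step at or above the dose (the largest step when the dose
#' exceeds all of them); `floor` the largest step at or below (the smallest
#' step when the dose is below all of them).
#'
#' @param dose_mg Positive continuous dose(s) in mg.
#' @param formulary A [formulary()].
#' @param policy A [rounding_policy()].
#' @return A data.frame with columns `dose_mg` (the chosen step) and
#'   `label`.
#' @export
round_to_formulary <- function(dose_mg, formulary,
                               policy = rounding_policy()) {
  stopifnot(inherits(formulary, "formulary"),
            inherits(policy, "rounding_policy"))
  if (nrow(formulary$steps) == 0L)
    stop("formulary has no steps", call. = FALSE)
  if (!is.numeric(dose_mg) || any(!is.finite(dose_mg)) || any(dose_mg <= 0))
    stop("`dose_mg` must be positive and finite", call. = FALSE)
  steps <- formulary$steps$dose_mg
  idx <- vapply(dose_mg, function(d) {
    switch(policy$mode,
      nearest = {
        dist <- abs(steps - d)
        best <- which(dist <= min(dist) + 1e-9 * max(1, d))
        # a midpoint leaves two candidates; tie_rule picks one
        if (length(best) > 1L)
          best <- if (policy$tie_rule == "lower") min(best) else max(best)
        best
      },
      ceil = {
        at_or_above <- which(steps >= d - 1e-9 * max(1, d))
        if (length(at_or_above)) min(at_or_above) else length(steps)
      },
      floor = {
        at_or_below <- which(steps <= d + 1e-9 * max(1, d))
        if (length(at_or_below)) max(at_or_below) else 1L
      })
  }, integer(1))
  out <- formulary$steps[idx, , drop = FALSE]
  if (policy$cap_at_adult) {
    over <- out$dose_mg > formulary$adult_dose_mg
    if (any(over)) {
      k <- which(steps == formulary$adult_dose_mg)[1]
      out[over, ] <- formulary$steps[k, ]
    }
  }
  rownames(out) <- NULL
  out
}

#' Read / write a formulary as JSON
#'
#' On-disk form:
#' `{"drug_label": "ABC/3TC", "unit_strength_mg": 120,
#'   "adult_dose_mg": 600, "steps": [[120,"1"], [180,"1.5"], ...]}`.
#'
#' @param path File path.
#' @return `read_formulary()` returns a [formulary()];
#'   `write_formulary()` returns `path` invisibly.
#' @export
read_formulary <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(x$steps) || !length(x$steps))
    stop("formulary JSON needs a non-empty `steps` array: ", path,
         call. = FALSE)
  doses <- vapply(x$steps, function(s) as.numeric(s[[1]]), numeric(1))
  labels <- vapply(x$steps, function(s) as.character(s[[2]]), character(1))
  formulary(steps = doses, labels = labels,
            unit_strength_mg = x$unit_strength_mg %||% doses[1],
            drug_label = x$drug_label %||% "drug",
            adult_dose_mg = x$adult_dose_mg %||% max(doses))
}

#' @rdname read_formulary
#' @param formulary A [formulary()].
#' @export
write_formulary <- function(formulary, path) {
  stopifnot(inherits(formulary, "formulary"))
  jsonlite::write_json(
    list(drug_label = formulary$drug_label,
         unit_strength_mg = formulary$unit_strength_mg,
         adult_dose_mg = formulary$adult_dose_mg,
         steps = mapply(function(d, l) list(d, l),
                        formulary$steps$dose_mg, formulary$steps$label,
                        SIMPLIFY = FALSE, USE.NAMES = FALSE)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Co-formulated component dose in a fixed-ratio FDC
#'
#' For display: the dose of the second component of a fixed-dose
#' combination given the index-drug dose and the tablet ratio (ABC:3TC is
#' 2:1, so `ratio = 2` gives 3TC = ABC / 2).
#'
#' @param index_dose_mg Dose of the index drug in mg.
#' @param ratio Index-to-companion mg ratio in one tablet (default 2).
#' @return Companion-component dose in mg.
#' @export
companion_dose <- function(index_dose_mg, ratio = 2) {
  stopifnot(is.numeric(index_dose_mg), is.numeric(ratio), ratio > 0)
  index_dose_mg / ratio
}
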