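#' Dosing strategies
#'
#' A dosing strategy maps a patient's body weight to a dispensed dose.
#' `band_strategy()` looks the weight up in a [weight_band_table()] (the
#' WHO chart or an allometric band table); `allometric_strategy()`
#' computes the continuous allometric dose and rounds it to the formulary
#' under a [rounding_policy()] (`nearest` by default, the
#' closest-equivalent-dose convention for per-patient conversion).
#'
#' @param table A [weight_band_table()].
#' @param formulary A [formulary()]; supplies the tablet unit strength
#'   used to express assigned doses as tablet counts.
#' @param name Strategy name used in reports.
#' @return An object of class `dosing_strategy`.
#' @seealso [assign_doses()], [run_comparison()]
#' @export
band_strategy <- function(table, formulary = abc3tc_formulary(),
                          name = attr(table, "source")) {
  stopifnot(inherits(table, "weight_band_table"),
            inherits(formulary, "formulary"))
  structure(list(type = "band", table = table, formulary = formulary,
                 name = as.character(name)),
            class = "dosing_strategy")
}

#' @rdname band_strategy
#' @param model A [scaling_model()].
#' @param policy A [rounding_policy()].
#' @export
allometric_strategy <- function(model = scaling_model(),
                                formulary = abc3tc_formulary(),
                                policy = rounding_policy("nearest"),
                                name = "allometric") {
  stopifnot(inherits(model, "scaling_model"),
            inherits(formulary, "formulary"),
            inherits(policy, "rounding_policy"))
  structure(list(type = "allometric", model = model, formulary = formulary,
                 policy = policy, name = as.character(name)),
            class = "dosing_strategy")
}

#' Assign doses to every patient under a strategy
#'
#' One assignment per patient, deterministically.  Tablet counts are the
#' assigned dose divided by the formulary's unit tablet strength, so the
#' adult 600 mg step counts as 5 units of the 120 mg paediatric tablet --
#' the only mg-proportional way to place the adult tablet on the same
#' scale as the fractional paediatric counts.
#'
#' @param cohort A cohort data.frame (`id`, `age_years`, `weight_kg`,
#'   `sex`).
#' @param strategy A [band_strategy()] or [allometric_strategy()].
#' @return A data.frame with columns `patient_id`, `strategy`,
#'   `exact_dose_mg` (`NA` for table lookup), `assigned_dose_mg`,
#'   `tablet_label`, `tablets`.
#' @export
assign_doses <- function(cohort, strategy) {
  stopifnot(inherits(strategy, "dosing_strategy"))
  if (!is.data.frame(cohort) || nrow(cohort) == 0L)
    stop("`cohort` must be a non-empty cohort data.frame", call. = FALSE)
  w <- check_weight(cohort$weight_kg)
  if (strategy$type == "band") {
    hit <- lookup_dose(strategy$table, w)
    exact <- rep(NA_real_, nrow(cohort))
    assigned <- hit$dose_mg
    label <- hit$label
  } else {
    exact <- allometric_dose(strategy$model, w,
                             cap_at_adult = strategy$policy$cap_at_adult)
    rounded <- round_to_formulary(exact, strategy$formulary,
                                  strategy$policy)
    assigned <- rounded$dose_mg
    label <- rounded$label
  }
  data.frame(patient_id = as.character(cohort$id),
             strategy = strategy$name,
             exact_dose_mg = exact,
             assigned_dose_mg = assigned,
             tablet_label = label,
             tablets = assigned / strategy$formulary$unit_strength_mg,
             stringsAsFactors = FALSE)
}

#' Dose distribution per strategy
#'
#' Histogram of assigned doses over tablet labels, and the fraction of
#' patients on the adult dose, per strategy.
#'
#' @param assignments Assignments from [assign_doses()] (rows from one or
#'   more strategies may be stacked with `rbind`).
#' @param adult_dose_mg Dose counted as the adult dose (default 600).
#' @return A list with `histogram` (data.frame `strategy`,
#'   `tablet_label`, `assigned_dose_mg`, `count`) and `adult_fraction`
#'   (data.frame `strategy`, `n`, `n_adult`, `pct_adult` -- percent to
#'   1 decimal).
#' @export
dose_distribution <- function(assignments, adult_dose_mg = 600) {
  stopifnot(is.data.frame(assignments), nrow(assignments) > 0L)
  hist <- stats::aggregate(count ~ strategy + assigned_dose_mg + tablet_label,
                           data = transform(assignments, count = 1L),
                           FUN = sum)
  hist <- hist[order(hist$strategy, hist$assigned_dose_mg),
               c("strategy", "tablet_label", "assigned_dose_mg", "count")]
  rownames(hist) <- NULL
  adult <- do.call(rbind, lapply(split(assignments, assignments$strategy),
    function(a) {
      n_adult <- sum(a$assigned_dose_mg == adult_dose_mg)
      data.frame(strategy = a$strategy[1], n = nrow(a), n_adult = n_adult,
                 pct_adult = round(100 * n_adult / nrow(a), 1),
                 stringsAsFactors = FALSE)
    }))
  rownames(adult) <- NULL
  list(histogram = hist, adult_fraction = adult)
}

#' Mann-Whitney (Wilcoxon rank-sum) two-sample test
#'
#' The rank-sum statistic from midranks (ties averaged), with the exact
#' permutation distribution enumerated when the groups are small enough
#' and a normal approximation -- tie-corrected variance and 0.5 continuity
#' correction -- otherwise.  Two-sided p values throughout: the exact p is
#' `min(1, 2 * min(P(U <= u), P(U >= u)))` over all equally likely
#' assignments of the pooled midranks to the two groups.
#'
#' @param x,y Numeric samples, each non-empty.
#' @param method `"auto"` (exact when `min(n)` is at most 10 and the
#'   enumeration is at most `exact_limit` subsets), `"exact"`, or
#'   `"normal"`.
#' @param exact_limit Largest number of subsets enumerated in exact mode.
#' @return An object of class `mw_test`: list with `U` (for `x`),
#'   `U_prime` (`n_x * n_y - U`), `z` (`NA` when the variance is
#'   degenerate), `p_value`, `method`, `n_x`, `n_y`.
#' @examples
#' mann_whitney_u(c(1, 2, 3), c(4, 5, 6))   # exact p = 0.1
#' @export
mann_whitney_u <- function(x, y, method = c("auto", "exact", "normal"),
                           exact_limit = 2e5) {
  method <- match.arg(method)
  if (!is.numeric(x) || !is.numeric(y) || !length(x) || !length(y))
    stop("`x` and `y` must be non-empty numeric vectors", call. = FALSE)
  nx <- length(x); ny <- length(y); N <- nx + ny
  r <- rank(c(x, y))
  u <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  ties <- table(c(x, y))
  v <- nx * ny / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
  degenerate <- v <= 0
  if (method == "auto")
    method <- if (min(nx, ny) <= 10 && choose(N, nx) <= exact_limit)
      "exact" else "normal"
  if (degenerate) {
    warning("all pooled values identical: rank-sum variance is zero, p = 1",
            call. = FALSE)
    p <- 1
    z <- NA_real_
  } else if (method == "exact") {
    if (choose(N, nx) > exact_limit)
      stop("exact enumeration of ", choose(N, nx),
           " subsets exceeds `exact_limit`", call. = FALSE)
    us <- exact_u_distribution(r, nx)
    p <- min(1, 2 * min(mean(us <= u + 1e-9), mean(us >= u - 1e-9)))
    z <- (u - nx * ny / 2 - 0.5 * sign(u - nx * ny / 2)) / sqrt(v)
  } else {
    mu <- nx * ny / 2
    z <- if (u == mu) 0 else (u - mu - 0.5 * sign(u - mu)) / sqrt(v)
    p <- 2 * stats::pnorm(-abs(z))
  }
  structure(list(U = u, U_prime = nx * ny - u, z = z, p_value = p,
                 method = method, n_x = nx, n_y = ny),
            class = "mw_test")
}

# all rank-sum values over the C(N, nx) equally likely group assignments
exact_u_distribution <- function(r, nx) {
  cmb <- utils::combn(length(r), nx)
  colSums(matrix(r[cmb], nrow = nx)) - nx * (nx + 1) / 2
}

#' @export
print.mw_test <- function(x, ...) {
  cat(sprintf("Mann-Whitney rank-sum test (%s): U = %g, n = %d vs %d\n",
              x$method, x$U, x$n_x, x$n_y))
  if (!is.na(x$z)) cat(sprintf("  z = %.4f\n", x$z))
  cat(sprintf("  two-sided p = %.4g\n", x$p_value))
  invisible(x)
}

#' Pearson product-moment correlation
#'
#' @param a,b Numeric vectors of equal length (at least 3), each with
#'   non-zero variance.
#' @return A list with `r` and `r2`.
#' @export
pearson_r <- function(a, b) {
  if (!is.numeric(a) || !is.numeric(b) || length(a) != length(b))
    stop("`a` and `b` must be numeric vectors of equal length",
         call. = FALSE)
  if (length(a) < 3L)
    stop("need at least 3 pairs for a correlation", call. = FALSE)
  da <- a - mean(a); db <- b - mean(b)
  ssa <- sum(da^2); ssb <- sum(db^2)
  if (ssa == 0 || ssb == 0)
    stop("correlation undefined: one input has zero variance",
         call. = FALSE)
  r <- sum(da * db) / sqrt(ssa * ssb)
  list(r = r, r2 = r^2)
}

#' Compare dosing strategies on a cohort
#'
#' Assigns every patient a dose under each strategy, tabulates the dose
#' distributions, and computes summary statistics: per-strategy mean and
#' SD of tablet counts, the fraction on the adult dose, a Mann-Whitney
#' rank-sum test between the first two strategies (on tablet counts by
#' default, mg via `scale = "mg"`), and the Pearson age-weight
#' correlation of the cohort.
#'
#' @param cohort A cohort data.frame.
#' @param strategies A list of two or more [band_strategy()] /
#'   [allometric_strategy()] objects.
#' @param scale `"tablets"` (default) or `"mg"`: the scale on which dose
#'   distributions are compared.
#' @param mw_method Passed to [mann_whitney_u()].
#' @param adult_dose_mg Dose counted as the adult dose (default 600).
#' @return An object of class `strategy_comparison`: list with
#'   `assignments`, `histogram`, `summary` (per-strategy n, mean, sd,
#'   pct_adult), `test` ([mann_whitney_u()] result, `NULL` when the
#'   cohort is too small), `correlation` (`r`, `r2`), `scale`.
#' @examples
#' co <- generate_cohort(default_cohort_spec(), seed = 42)
#' cmp <- run_comparison(co)
#' cmp
#' @export
run_comparison <- function(cohort,
                           strategies = list(
                             band_strategy(who_band_table(), name = "WHO"),
                             allometric_strategy()),
                           scale = c("tablets", "mg"),
                           mw_method = "auto",
                           adult_dose_mg = 600) {
  scale <- match.arg(scale)
  if (length(strategies) < 2L)
    stop("need at least two strategies to compare", call. = FALSE)
  assignments <- do.call(rbind, lapply(strategies, function(s)
    assign_doses(cohort, s)))
  dist <- dose_distribution(assignments, adult_dose_mg = adult_dose_mg)
  values <- function(nm) {
    a <- assignments[assignments$strategy == nm, ]
    if (scale == "tablets") a$tablets else a$assigned_dose_mg
  }
  nms <- vapply(strategies, `[[`, character(1), "name")
  summary <- do.call(rbind, lapply(nms, function(nm) {
    v <- values(nm)
    data.frame(strategy = nm, n = length(v),
               mean = mean(v), sd = stats::sd(v),
               pct_adult = dist$adult_fraction$pct_adult[
                 match(nm, dist$adult_fraction$strategy)],
               stringsAsFactors = FALSE)
  }))
  test <- NULL
  if (nrow(cohort) >= 2L) {
    test <- mann_whitney_u(values(nms[1]), values(nms[2]),
                           method = mw_method)
  } else {
    warning("single-patient cohort: rank-sum test skipped", call. = FALSE)
  }
  correlation <- if (nrow(cohort) >= 3L &&
                     stats::var(cohort$age_years) > 0 &&
                     stats::var(cohort$weight_kg) > 0) {
    pearson_r(cohort$age_years, cohort$weight_kg)
  } else {
    warning("age-weight correlation needs >= 3 patients with variation",
            call. = FALSE)
    list(r = NA_real_, r2 = NA_real_)
  }
  structure(list(assignments = assignments,
                 histogram = dist$histogram,
                 adult_fraction = dist$adult_fraction,
                 summary = summary,
                 test = test,
                 correlation = correlation,
                 scale = scale),
            class = "strategy_comparison")
}

#' @export
print.strategy_comparison <- function(x, ...) {
  cat("Dosing strategy comparison (", x$scale, " scale)\n\n", sep = "")
  s <- x$summary
  s$mean <- round(s$mean, 2); s$sd <- round(s$sd, 2)
  print(s, row.names = FALSE)
  cat("\nDose distribution:\n")
  print(x$histogram, row.names = FALSE)
  if (!is.null(x$test)) {
    cat("\n")
    print(x$test)
  }
  if (!is.na(x$correlation$r))
    cat(sprintf("\nAge-weight correlation: r = %.3f, r2 = %.3f\n",
                x$correlation$r, x$correlation$r2))
  invisible(x)
}

#' Write a strategy comparison as JSON
#'
#' Machine-readable report: per-strategy histograms, means, SDs,
#' adult-dose fractions, the rank-sum test (U, z, p) and the age-weight
#' correlation (r, r2).
#'
#' @param comparison A [run_comparison()] result.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_comparison_json <- function(comparison, path) {
  stopifnot(inherits(comparison, "strategy_comparison"))
  jsonlite::write_json(
    list(scale = comparison$scale,
         summary = comparison$summary,
         histogram = comparison$histogram,
         adult_fraction = comparison$adult_fraction,
         test = if (is.null(comparison$test)) NULL else
           comparison$test[c("U", "U_prime", "z", "p_value", "method",
                             "n_x", "n_y")],
         correlation = comparison$correlation),
    path, auto_unbox = TRUE, digits = NA, null = "null", na = "null")
  invisible(path)
}
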