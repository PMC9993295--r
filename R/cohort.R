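#' Cohort specification for synthetic paediatric cohorts
#'
#' A per-age (stratum) description of a paediatric cohort: how many
#' children of each age, and the mean and range of their body weights.
#' This is the summary a published demographic table provides when the
#' individual records are not deposited; [generate_cohort()] draws
#' synthetic patients consistent with it.
#'
#' @param strata A data.frame with columns `age_years`, `n`, `mean_kg`,
#'   `min_kg`, `max_kg`; one row per age stratum, `min_kg <= mean_kg <=
#'   max_kg`, `n >= 1`.
#' @param sex_ratio_male Probability that a generated patient is male,
#'   in \[0, 1\].
#' @return An object of class `cohort_spec`.
#' @seealso [default_cohort_spec()], [generate_cohort()]
#' @export
cohort_spec <- function(strata, sex_ratio_male = 0.5) {
  need <- c("age_years", "n", "mean_kg", "min_kg", "max_kg")
  if (!is.data.frame(strata) || !all(need %in% names(strata)))
    stop("`strata` must be a data.frame with columns ",
         paste(need, collapse = ", "), call. = FALSE)
  strata <- as.data.frame(strata)[need]
  bad <- which(!(strata$min_kg <= strata$mean_kg &
                 strata$mean_kg <= strata$max_kg))
  if (length(bad))
    stop("strata rows ", paste(bad, collapse = ", "),
         ": need min_kg <= mean_kg <= max_kg", call. = FALSE)
  if (any(strata$n < 1) || any(strata$n != round(strata$n)))
    stop("stratum `n` must be a positive integer", call. = FALSE)
  if (any(strata$min_kg <= 0))
    stop("stratum `min_kg` must be positive", call. = FALSE)
  if (!is.numeric(sex_ratio_male) || sex_ratio_male < 0 ||
      sex_ratio_male > 1)
    stop("`sex_ratio_male` must lie in [0, 1]", call. = FALSE)
  structure(list(strata = strata,
                 sex_ratio_male = as.numeric(sex_ratio_male)),
            class = "cohort_spec")
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf("Cohort spec: %d strata, n = %d, P(male) = %.3f\n",
              nrow(x$strata), sum(x$strata$n), x$sex_ratio_male))
  print(x$strata, row.names = FALSE)
  invisible(x)
}

#' Default cohort specification (Namibian paediatric ART cohort)
#'
#' The per-age counts, mean weights and weight ranges of the 89 children
#' aged 2-12 years on ABC/3TC-based ART whose published demographic
#' summary this package's synthetic cohorts emulate (40 male, 49 female).
#'
#' @param n_scale Integer factor by which every stratum count is
#'   multiplied (1 reproduces the study size of 89; larger values give
#'   proportionally bigger synthetic cohorts for calibration checks).
#' @return A [cohort_spec()].
#' @export
default_cohort_spec <- function(n_scale = 1) {
  stopifnot(is.numeric(n_scale), length(n_scale) == 1L, n_scale >= 1,
            n_scale == round(n_scale))
  strata <- data.frame(
    age_years = 2:12,
    n       = c(4, 4, 2, 3, 4, 9, 11, 9, 11, 15, 17) * n_scale,
    mean_kg = c(12.0, 13.4, 12.9, 16.5, 18.8, 19.8, 24.0, 23.5, 28.3,
                29.4, 31.9),
    min_kg  = c(9.6, 12.3, 11.7, 14.3, 15.1, 15.0, 18.1, 19.8, 22.3,
                21.8, 23.7),
    max_kg  = c(14.5, 14.9, 14.2, 17.6, 23.1, 29.0, 31.3, 28.2, 41.5,
                35.0, 58.8))
  cohort_spec(strata, sex_ratio_male = 40 / 89)
}

# mean of a normal(mu, sd) truncated to [a, b]
truncnorm_mean <- function(mu, sd, a, b) {
  al <- (a - mu) / sd
  be <- (b - mu) / sd
  mu + sd * (stats::dnorm(al) - stats::dnorm(be)) /
    (stats::pnorm(be) - stats::pnorm(al))
}

# location parameter for which the truncated normal's mean equals target;
# an uncalibrated location misses the target badly for skewed ranges
# (e.g. mean 31.9 in range 23.7-58.8 would shift by +2.7 kg).  The mean is
# monotone in mu with limits a and b; far from [a, b] the dnorm/pnorm
# ratio degenerates to 0/0, so the limit value stands in there to keep
# the bracket signs correct.
calibrate_location <- function(target, sd, a, b) {
  if (target <= a || target >= b) return(target)
  f <- function(mu) {
    v <- truncnorm_mean(mu, sd, a, b)
    if (!is.finite(v)) v <- if (mu < (a + b) / 2) a else b
    v - target
  }
  stats::uniroot(f, lower = target - 10 * sd, upper = target + 10 * sd,
                 tol = 1e-10)$root
}

# inverse-CDF draws from normal(mu, sd) truncated to [a, b]
rtruncnorm <- function(n, mu, sd, a, b) {
  lo <- stats::pnorm(a, mu, sd)
  hi <- stats::pnorm(b, mu, sd)
  stats::qnorm(stats::runif(n, lo, hi), mu, sd)
}

#' Generate a synthetic paediatric cohort
#'
#' Draws, for each age stratum, `n` body weights from a truncated normal
#' on `[min_kg, max_kg]` with standard deviation `(max_kg - min_kg) / 4`
#' (so the printed extremes sit near +/- 2 sd) and location calibrated so
#' the truncated distribution's mean equals the stratum's `mean_kg`.
#' Weights are rounded to 0.1 kg, matching clinical recording.  Sex is
#' drawn Bernoulli(`sex_ratio_male`).  The result is a pure function of
#' `(spec, seed)`.
#'
#' @param spec A [cohort_spec()].
#' @param seed Integer seed; all randomness flows from it.
#' @return A `cohort`: a data.frame with columns `id`, `age_years`,
#'   `weight_kg`, `sex`.
#' @examples
#' co <- generate_cohort(default_cohort_spec(), seed = 42)
#' summarize_cohort(co)
#' @export
generate_cohort <- function(spec, seed) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("`seed` must be a single integer", call. = FALSE)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  st <- spec$strata
  weights <- unlist(lapply(seq_len(nrow(st)), function(i) {
    a <- st$min_kg[i]; b <- st$max_kg[i]
    if (a == b) return(rep(a, st$n[i]))
    sd <- (b - a) / 4
    mu <- calibrate_location(st$mean_kg[i], sd, a, b)
    w <- rtruncnorm(st$n[i], mu, sd, a, b)
    pmin(pmax(quantise_weight(w, 0.1), a), b)
  }))
  ages <- rep(st$age_years, st$n)
  n <- length(ages)
  sex <- ifelse(stats::runif(n) < spec$sex_ratio_male, "M", "F")
  as_cohort(data.frame(id = sprintf("P%03d", seq_len(n)),
                       age_years = as.integer(ages),
                       weight_kg = weights,
                       sex = sex,
                       stringsAsFactors = FALSE))
}

as_cohort <- function(df) {
  structure(df, class = c("cohort", "data.frame"))
}

validate_cohort <- function(df, lines = NULL, age_range = c(0, 18)) {
  need <- c("id", "age_years", "weight_kg", "sex")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("cohort is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (is.null(lines)) lines <- seq_len(nrow(df))
  p <- character(0)
  w <- suppressWarnings(as.numeric(df$weight_kg))
  bad <- which(is.na(w) | w <= 2 | w >= 120)
  if (length(bad))
    p <- c(p, paste0("line ", lines[bad], ": weight_kg '", df$weight_kg[bad],
                     "' is not a weight in (2, 120) kg"))
  a <- suppressWarnings(as.numeric(df$age_years))
  bad <- which(is.na(a) | a != round(a) | a < age_range[1] |
               a > age_range[2])
  if (length(bad))
    p <- c(p, paste0("line ", lines[bad], ": age_years '", df$age_years[bad],
                     "' is not an integer age in [", age_range[1], ", ",
                     age_range[2], "]"))
  bad <- which(!df$sex %in% c("M", "F", "unknown"))
  if (length(bad))
    p <- c(p, paste0("line ", lines[bad], ": sex '", df$sex[bad],
                     "' is not one of M, F, unknown"))
  if (length(p))
    stop("invalid cohort:\n  ", paste(p, collapse = "\n  "), call. = FALSE)
  df$weight_kg <- w
  df$age_years <- as.integer(a)
  as_cohort(df[need])
}

#' Read / write a cohort specification as JSON
#'
#' On-disk form: `{"sex_ratio_male": 0.45,
#' "strata": [{"age_years": 2, "n": 4, "mean_kg": 12.0,
#'             "min_kg": 9.6, "max_kg": 14.5}, ...]}`.
#'
#' @param path File path.
#' @return `read_cohort_spec()` returns a [cohort_spec()];
#'   `write_cohort_spec()` returns `path` invisibly.
#' @export
read_cohort_spec <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(x$strata))
    stop("cohort spec JSON needs a `strata` array: ", path, call. = FALSE)
  cohort_spec(as.data.frame(x$strata),
              sex_ratio_male = x$sex_ratio_male %||% 0.5)
}

#' @rdname read_cohort_spec
#' @param spec A [cohort_spec()].
#' @export
write_cohort_spec <- function(spec, path) {
  stopifnot(inherits(spec, "cohort_spec"))
  jsonlite::write_json(
    list(sex_ratio_male = spec$sex_ratio_male, strata = spec$strata),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Summarise a cohort per age stratum
#'
#' Per-age counts with cumulative percentage (2 decimals), mean weight
#' (1 decimal) and weight range, plus the overall median age and weight
#' (standard order-statistic rule: mean of the central pair for even n).
#'
#' @param cohort A cohort data.frame (`id`, `age_years`, `weight_kg`,
#'   `sex`).
#' @return An object of class `cohort_summary`: a list with `per_age`
#'   (data.frame `age_years`, `n`, `cum_pct`, `mean_kg`, `min_kg`,
#'   `max_kg`), `median_age`, `median_weight`, `n`.
#' @export
summarize_cohort <- function(cohort) {
  if (!is.data.frame(cohort) || nrow(cohort) == 0L)
    stop("`cohort` must be a non-empty cohort data.frame", call. = FALSE)
  ages <- sort(unique(cohort$age_years))
  per <- do.call(rbind, lapply(ages, function(a) {
    w <- cohort$weight_kg[cohort$age_years == a]
    data.frame(age_years = a, n = length(w), cum_pct = NA_real_,
               mean_kg = round(mean(w), 1), min_kg = min(w),
               max_kg = max(w))
  }))
  per$cum_pct <- round(cumsum(per$n) / nrow(cohort) * 100, 2)
  structure(list(per_age = per,
                 median_age = stats::median(cohort$age_years),
                 median_weight = stats::median(cohort$weight_kg),
                 n = nrow(cohort)),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("Cohort of %d patients: median age %g years, median weight %g kg\n",
              x$n, x$median_age, x$median_weight))
  per <- x$per_age
  per$range <- sprintf("%.1f-%.1f", per$min_kg, per$max_kg)
  print(per[c("age_years", "n", "cum_pct", "mean_kg", "range")],
        row.names = FALSE)
  invisible(x)
}

#' Read / write a cohort as delimited text
#'
#' Comma-delimited UTF-8 with header `id,age_years,weight_kg,sex`.
#' Reading validates every row and reports malformed rows by file line
#' number; an empty file with only the header yields an empty cohort with
#' a warning.  The write/read round trip is lossless.
#'
#' @param path File path.
#' @return `read_cohort()` returns a cohort data.frame; `write_cohort()`
#'   returns `path` invisibly.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path))
    stop("cohort file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, colClasses = "character",
                        stringsAsFactors = FALSE)
  if (nrow(df) == 0L) {
    warning("cohort file has a header but no rows: ", path, call. = FALSE)
    return(as_cohort(data.frame(id = character(0),
                                age_years = integer(0),
                                weight_kg = numeric(0),
                                sex = character(0),
                                stringsAsFactors = FALSE)))
  }
  validate_cohort(df, lines = seq_len(nrow(df)) + 1L)  # +1 for header
}

#' @rdname read_cohort
#' @param cohort A cohort data.frame.
#' @export
write_cohort <- function(cohort, path) {
  need <- c("id", "age_years", "weight_kg", "sex")
  stopifnot(is.data.frame(cohort), all(need %in% names(cohort)))
  utils::write.csv(as.data.frame(cohort)[need], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
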