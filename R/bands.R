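#' Weight-band dosing table
#'
#' An ordered set of body-weight intervals, each mapped to one formulary
#' dose step.  Band edges are recorded at a fixed weight resolution
#' (0.1 kg by default, matching clinical weight recording): a band's upper
#' edge is inclusive, and the next band starts one resolution step above
#' it, so the printed form reads e.g. `... - 14.1` then `14.2 - ...`.
#' The last band may be unbounded above (`upper_kg = Inf`).
#'
#' @param bands A data.frame with columns `lower_kg`, `upper_kg`,
#'   `dose_mg`, `label`, in increasing weight order.
#' @param resolution_kg Weight resolution in kg (default 0.1).
#' @param source Free-text provenance tag, e.g. `"allometric"` or
#'   `"WHO-2019"`.
#' @return An object of class `weight_band_table` (a data.frame with
#'   attributes `resolution_kg` and `source`).
#' @seealso [build_allometric_bands()], [lookup_dose()], [who_band_table()]
#' @export
weight_band_table <- function(bands, resolution_kg = 0.1,
                              source = "custom") {
  need <- c("lower_kg", "upper_kg", "dose_mg", "label")
  if (!is.data.frame(bands) || !all(need %in% names(bands)))
    stop("`bands` must be a data.frame with columns ",
         paste(need, collapse = ", "), call. = FALSE)
  if (!is.numeric(resolution_kg) || resolution_kg < 0)
    stop("`resolution_kg` must be a non-negative number", call. = FALSE)
  bands <- as.data.frame(bands)[need]
  bands$lower_kg <- as.numeric(bands$lower_kg)
  bands$upper_kg <- as.numeric(bands$upper_kg)
  bands$dose_mg <- as.numeric(bands$dose_mg)
  bands$label <- as.character(bands$label)
  problems <- validate_bands(bands, resolution_kg)
  if (length(problems))
    stop("invalid weight-band table:\n  ",
         paste(problems, collapse = "\n  "), call. = FALSE)
  structure(bands, resolution_kg = as.numeric(resolution_kg),
            source = as.character(source),
            class = c("weight_band_table", "data.frame"))
}

validate_bands <- function(bands, resolution_kg) {
  p <- character(0)
  n <- nrow(bands)
  if (n == 0L) return("table has no bands")
  bad <- which(!(bands$lower_kg < bands$upper_kg))
  if (length(bad))
    p <- c(p, paste0("row ", bad, ": lower_kg must be below upper_kg"))
  if (n > 1L) {
    gap <- bands$lower_kg[-1] - bands$upper_kg[-n]
    tol <- 1e-9
    expected <- if (resolution_kg > 0) resolution_kg else 0
    bad <- which(abs(gap - expected) > tol)
    if (length(bad))
      p <- c(p, paste0("rows ", bad, "-", bad + 1,
                       ": bands must be separated by exactly one ",
                       "resolution step (", expected, " kg), found ",
                       signif(gap[bad], 6)))
    bad <- which(diff(bands$dose_mg) < 0)
    if (length(bad))
      p <- c(p, paste0("rows ", bad, "-", bad + 1,
                       ": dose_mg must be non-decreasing"))
  }
  bad <- which(!is.finite(bands$dose_mg) | bands$dose_mg <= 0)
  if (length(bad))
    p <- c(p, paste0("row ", bad, ": dose_mg must be positive"))
  p
}

#' @export
print.weight_band_table <- function(x, ...) {
  res <- attr(x, "resolution_kg")
  cat(sprintf("Weight-band dosing table (%s, resolution %g kg)\n",
              attr(x, "source"), res))
  rng <- band_range_labels(x)
  out <- data.frame(`body weight (kg)` = rng,
                    `dose (mg)` = x$dose_mg,
                    tablets = x$label,
                    check.names = FALSE)
  print(out, row.names = FALSE)
  invisible(x)
}

band_range_labels <- function(x) {
  n <- nrow(x)
  rng <- sprintf("%g-%g", x$lower_kg, x$upper_kg)
  if (x$lower_kg[1] <= 0) rng[1] <- sprintf("<=%g", x$upper_kg[1])
  if (is.infinite(x$upper_kg[n])) rng[n] <- sprintf(">=%g", x$lower_kg[n])
  rng
}

# half-up quantisation to the table resolution; the epsilon keeps recorded
# decimals like 14.15 (stored as 14.1499...) on the clinical half-up side
quantise_weight <- function(weight_kg, resolution_kg) {
  if (resolution_kg <= 0) return(weight_kg)
  floor(weight_kg / resolution_kg + 0.5 + 1e-9) * resolution_kg
}

#' Build an allometric weight-band dosing table
#'
#' Inverts the scaling model at each formulary step below the adult dose:
#' the upper edge of the band for step \eqn{d_k} is
#' `weight_for_dose(model, d_k)` rounded to the table resolution, so a
#' child at or below that edge needs no more than \eqn{d_k} (round-up,
#' never-underdose convention).  Each following band starts one resolution
#' step higher; weights above the last finite edge map to the adult step.
#'
#' With the default ABC/3TC inputs (600 mg adult dose, 70 kg reference,
#' exponent 0.75, steps 120/180/240/300/360/600 mg) the finite edges fall
#' at 8.2, 14.1, 20.6, 27.8 and 35.4 kg and the adult band starts at
#' 35.5 kg.
#'
#' @param model A [scaling_model()].
#' @param formulary A [formulary()] with at least two steps.
#' @param resolution_kg Edge resolution in kg (default 0.1).
#' @return A [weight_band_table()] with `source = "allometric"`.
#' @export
build_allometric_bands <- function(model, formulary, resolution_kg = 0.1) {
  stopifnot(inherits(model, "scaling_model"),
            inherits(formulary, "formulary"))
  steps <- formulary$steps
  if (nrow(steps) < 2L)
    stop("formulary must have at least two steps to form bands",
         call. = FALSE)
  if (resolution_kg <= 0)
    stop("`resolution_kg` must be positive", call. = FALSE)
  k <- nrow(steps)
  edges <- weight_for_dose(model, steps$dose_mg[-k])
  edges <- round(edges / resolution_kg) * resolution_kg
  lower <- c(0, edges + resolution_kg)
  upper <- c(edges, Inf)
  weight_band_table(
    data.frame(lower_kg = lower, upper_kg = upper,
               dose_mg = steps$dose_mg, label = steps$label,
               stringsAsFactors = FALSE),
    resolution_kg = resolution_kg, source = "allometric")
}

#' Look up the banded dose for a body weight
#'
#' Weights are quantised to the table resolution (half-up) before lookup,
#' so a recorded 14.15 kg falls in the band starting at 14.2.  The lookup
#' is total: weights below the first band's lower edge are assigned the
#' first band and flagged `below_minimum`; an unbounded top band catches
#' all heavier patients.  Vectorised over `weight_kg`.
#'
#' @param table A [weight_band_table()].
#' @param weight_kg Positive body weight(s) in kg.
#' @return A data.frame with columns `weight_kg` (as given), `dose_mg`,
#'   `label`, `below_minimum`.
#' @export
lookup_dose <- function(table, weight_kg) {
  stopifnot(inherits(table, "weight_band_table"))
  w <- check_weight(weight_kg)
  res <- attr(table, "resolution_kg")
  wq <- quantise_weight(w, res)
  # bands are contiguous at the resolution, so the lower edges partition
  # the covered range and findInterval picks the unique band
  idx <- findInterval(wq + 1e-9, table$lower_kg)
  below <- idx == 0L
  idx[below] <- 1L
  over <- wq > table$upper_kg[nrow(table)] + 1e-9
  if (any(over))
    stop("weight ", max(w), " kg above table coverage", call. = FALSE)
  if (any(below))
    warning(sum(below), " weight(s) below the table minimum (",
            table$lower_kg[1], " kg); first band assigned", call. = FALSE)
  data.frame(weight_kg = w,
             dose_mg = table$dose_mg[idx],
             label = table$label[idx],
             below_minimum = below,
             stringsAsFactors = FALSE)
}

#' Read / write a weight-band table as JSON
#'
#' On-disk form:
#' `{"source": ..., "resolution_kg": 0.1,
#'   "bands": [{"lower_kg": 0, "upper_kg": 8.2, "dose_mg": 120,
#'              "label": "1"}, ...]}`
#' with `null` for an unbounded upper edge.  Parsing re-validates every
#' table invariant and reports offending rows; the round trip is lossless.
#'
#' @param path File path.
#' @return `read_band_table()` returns a [weight_band_table()];
#'   `write_band_table()` returns `path` invisibly.
#' @export
read_band_table <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(x$bands) || !length(x$bands))
    stop("band table JSON needs a non-empty `bands` array: ", path,
         call. = FALSE)
  bands <- do.call(rbind, lapply(x$bands, function(b) {
    data.frame(lower_kg = as.numeric(b$lower_kg),
               upper_kg = if (is.null(b$upper_kg)) Inf
                          else as.numeric(b$upper_kg),
               dose_mg = as.numeric(b$dose_mg),
               label = as.character(b$label),
               stringsAsFactors = FALSE)
  }))
  weight_band_table(bands,
                    resolution_kg = x$resolution_kg %||% 0.1,
                    source = x$source %||% "unknown")
}

#' @rdname read_band_table
#' @param table A [weight_band_table()].
#' @export
write_band_table <- function(table, path) {
  stopifnot(inherits(table, "weight_band_table"))
  bands <- lapply(seq_len(nrow(table)), function(i) {
    list(lower_kg = table$lower_kg[i],
         upper_kg = if (is.infinite(table$upper_kg[i])) NULL
                    else table$upper_kg[i],
         dose_mg = table$dose_mg[i],
         label = table$label[i])
  })
  jsonlite::write_json(
    list(source = attr(table, "source"),
         resolution_kg = attr(table, "resolution_kg"),
         bands = bands),
    path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Packaged WHO-style paediatric ABC/3TC weight-band chart
#'
#' The once-daily ABC/3TC column of the WHO paediatric ARV dosing chart
#' (2019 guidelines): 120/60 mg dispersible-tablet counts 1, 1.5, 2, 2.5
#' and 3 for the 3-5.9, 6-9.9, 10-13.9, 14-19.9 and 20-24.9 kg bands, and
#' the 600/300 mg adult tablet from 25 kg upward.
#'
#' @return A [weight_band_table()] with `source = "WHO-2019"`.
#' @export
who_band_table <- function() {
  read_band_table(system.file("extdata", "who_bands.json",
                              package = "allodose", mustWork = TRUE))
}

#' Packaged allometric ABC/3TC reference band table
#'
#' The recommended allometric weight-band dosing table for ABC/3TC, as
#' produced by [build_allometric_bands()] with the default scaling model
#' and formulary; shipped as a fixture so the published recommendation can
#' be compared field-for-field with a fresh construction.
#'
#' @return A [weight_band_table()] with `source = "allometric"`.
#' @export
allometric_reference_table <- function() {
  read_band_table(system.file("extdata", "allometric_bands.json",
                              package = "allodose", mustWork = TRUE))
}
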