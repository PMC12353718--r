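## Demographic nutrient requirement sets: daily recommended intakes (lower
## bounds) and upper limits where defined, their weekly scaling, config I/O,
## and the adequacy audit applied to every diet.

requirement_sexes <- c("female", "male")
requirement_age_groups <- c("19-30", "31-50", "51-69", "70+")

#' Construct a requirement set
#'
#' One demographic stratum's daily nutrient bounds. A lower bound is the
#' recommended dietary intake (RDI); an upper bound is the upper limit (UL),
#' present only where one is defined. Bounds are closed: a supply exactly at
#' a bound is adequate.
#'
#' @param sex `"female"` or `"male"`.
#' @param age_group One of `"19-30"`, `"31-50"`, `"51-69"`, `"70+"`.
#' @param bounds Data frame with columns `nutrient_id`, `daily_lower`,
#'   `daily_upper` (either bound may be `NA`), and optionally `unit`.
#' @return A `requirement_set`.
#' @export
requirement_set <- function(sex, age_group, bounds) {
  sex <- match.arg(sex, requirement_sexes)
  age_group <- match.arg(age_group, requirement_age_groups)
  stopifnot(is.data.frame(bounds),
            all(c("nutrient_id", "daily_lower", "daily_upper") %in%
                  names(bounds)))
  if (anyDuplicated(bounds$nutrient_id))
    stop("duplicate nutrient in requirement set", call. = FALSE)
  both <- !is.na(bounds$daily_lower) & !is.na(bounds$daily_upper)
  if (any(bounds$daily_lower[both] > bounds$daily_upper[both]))
    stop("daily_lower exceeds daily_upper for: ",
         paste(bounds$nutrient_id[both][
           bounds$daily_lower[both] > bounds$daily_upper[both]],
           collapse = ", "), call. = FALSE)
  if (!any(!is.na(bounds$daily_lower)))
    stop("requirement set must contain at least one lower bound",
         call. = FALSE)
  if (is.null(bounds$unit)) bounds$unit <- NA_character_
  rownames(bounds) <- NULL
  structure(list(sex = sex, age_group = age_group,
                 bounds = bounds[, c("nutrient_id", "daily_lower",
                                     "daily_upper", "unit")]),
            class = "requirement_set")
}

#' @export
print.requirement_set <- function(x, ...) {
  cat(sprintf("<requirement_set> %s %s: %d nutrient bound(s)\n",
              x$sex, x$age_group, nrow(x$bounds)))
  invisible(x)
}

demographic_key <- function(sex, age_group) paste(sex, age_group, sep = "_")

#' Scale daily requirement bounds to a weekly basis
#'
#' Diets are optimised per week, so each present daily bound is multiplied
#' by 7; absent bounds stay absent. The map is linear in the bounds.
#'
#' @param req A `requirement_set`.
#' @return A `weekly_bounds` object: data frame `nutrient_id`,
#'   `weekly_lower`, `weekly_upper`, `unit`.
#' @export
to_weekly <- function(req) {
  stopifnot(inherits(req, "requirement_set"))
  b <- req$bounds
  structure(list(
    sex = req$sex, age_group = req$age_group,
    bounds = data.frame(nutrient_id = b$nutrient_id,
                        weekly_lower = 7 * b$daily_lower,
                        weekly_upper = 7 * b$daily_upper,
                        unit = b$unit, stringsAsFactors = FALSE)
  ), class = "weekly_bounds")
}

#' Audit a weekly nutrient supply against weekly bounds
#'
#' Classifies each bounded nutrient as `below_lower`, `within`, or
#' `above_upper`, using closed bounds with a small numeric tolerance. Every
#' optimiser solution is passed through this audit; baseline diets may
#' legitimately fail it (survey diets are often inadequate).
#'
#' @param supply Named numeric: weekly supply per nutrient id. For protein
#'   and essential amino acids this should be the absorbable supply.
#' @param bounds A `weekly_bounds`.
#' @param tol Absolute tolerance on each bound (default 1e-6).
#' @return An `adequacy_report`: data frame `nutrient_id`, `supply`,
#'   `weekly_lower`, `weekly_upper`, `status`; attribute `n_violations`.
#' @export
audit_diet <- function(supply, bounds, tol = 1e-6) {
  stopifnot(inherits(bounds, "weekly_bounds"))
  b <- bounds$bounds
  miss <- setdiff(b$nutrient_id, names(supply))
  if (length(miss))
    stop("supply is missing bounded nutrient(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  s <- supply[b$nutrient_id]
  status <- rep("within", nrow(b))
  status[!is.na(b$weekly_lower) & s < b$weekly_lower - tol] <- "below_lower"
  status[!is.na(b$weekly_upper) & s > b$weekly_upper + tol] <- "above_upper"
  rep_df <- data.frame(nutrient_id = b$nutrient_id, supply = unname(s),
                       weekly_lower = b$weekly_lower,
                       weekly_upper = b$weekly_upper,
                       status = status, stringsAsFactors = FALSE)
  structure(rep_df, class = c("adequacy_report", "data.frame"),
            n_violations = sum(status != "within"))
}

#' Number of bound violations in an adequacy report
#' @param report An `adequacy_report` from [audit_diet()].
#' @return Integer count of nutrients outside their bounds.
#' @export
n_violations <- function(report) attr(report, "n_violations")

#' Read requirement sets from a JSON config
#'
#' The config mirrors national nutrient-reference-value tables: one block per
#' (sex, age group) with nutrient bounds and units. Units are validated
#' against the database's nutrient definitions when a database is supplied.
#'
#' @param path JSON config path (see [write_requirements()] for the shape).
#' @param db Optional `food_db` for unit/nutrient validation.
#' @return Named list of `requirement_set`, keyed `"<sex>_<age_group>"`.
#' @export
read_requirements <- function(path, db = NULL) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  sets <- doc$sets
  if (is.null(sets) || length(sets) == 0L)
    stop_load("requirement config contains no sets", file = path)
  if (is.data.frame(sets))
    sets <- split(sets, seq_len(nrow(sets)))
  out <- list()
  for (s in sets) {
    b <- if (is.data.frame(s$bounds)) s$bounds else s$bounds[[1]]
    b$daily_lower <- as.numeric(b$daily_lower)
    b$daily_upper <- as.numeric(b$daily_upper)
    if (!is.null(b$unit)) b$unit <- normalise_unit(b$unit)
    if (!is.null(db)) {
      unknown <- setdiff(b$nutrient_id, db$nutrients$nutrient_id)
      if (length(unknown))
        stop_load("requirement set names nutrient(s) absent from database: ",
                  paste(unknown, collapse = ", "), file = path)
      if (!is.null(b$unit)) {
        dbu <- db$nutrients$unit[match(b$nutrient_id,
                                       db$nutrients$nutrient_id)]
        bad <- !is.na(b$unit) & b$unit != dbu
        if (any(bad))
          stop_load("unit mismatch with database for: ",
                    paste(b$nutrient_id[bad], collapse = ", "), file = path)
      }
    }
    rs <- requirement_set(as.character(s$sex), as.character(s$age_group), b)
    out[[demographic_key(rs$sex, rs$age_group)]] <- rs
  }
  out
}

#' Write requirement sets to a JSON config
#' @param sets Named list of `requirement_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_requirements <- function(sets, path) {
  doc <- list(schema_version = 1L, sets = lapply(unname(sets), function(s) {
    list(sex = s$sex, age_group = s$age_group, bounds = s$bounds)
  }))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}
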