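## MILP construction for one scenario: integer weekly serving counts per
## food, L1 deviation auxiliaries, nutrient-bound rows, and optional price /
## emission cap rows. Matrices are dense (instances are small).

#' Per-serving nutrient supply matrix
#'
#' Converts per-100 g compositions into per-serving weekly contributions:
#' `composition[food, nutrient] * serving_size_g / 100`, with protein and
#' essential-amino-acid entries additionally multiplied by the food's
#' bioavailability coefficient when `absorbable = TRUE`.
#'
#' @param db A `food_db`.
#' @param absorbable Apply bioavailability coefficients (default `TRUE`).
#' @return Matrix foods x nutrients: amount supplied by one serving.
#' @export
serving_supply_matrix <- function(db, absorbable = TRUE) {
  m <- db$composition * (db$foods$serving_size_g / 100)
  if (absorbable) {
    bn <- intersect(colnames(m), colnames(db$bioavailability))
    if (length(bn))
      m[, bn] <- m[, bn] * db$bioavailability[, bn, drop = FALSE]
  }
  m
}

#' Weekly nutrient amount supplied by one food
#'
#' @param food Single-row slice of `db$foods`, or a food id with `db` given.
#' @param servings Weekly serving count (>= 0).
#' @param nutrient_id Nutrient identifier.
#' @param db A `food_db`.
#' @param absorbable Use the bioavailability-adjusted amount for protein and
#'   essential amino acids (default `TRUE`).
#' @return Weekly amount in the nutrient's database unit.
#' @export
food_weekly_amount <- function(food, servings, nutrient_id, db,
                               absorbable = TRUE) {
  stopifnot(servings >= 0)
  id <- if (is.character(food)) food else food$food_id
  if (!nutrient_id %in% colnames(db$composition))
    stop("unknown nutrient: ", nutrient_id, call. = FALSE)
  if (!id %in% rownames(db$composition))
    stop("unknown food: ", id, call. = FALSE)
  amt <- serving_supply_matrix(db, absorbable)[id, nutrient_id]
  amt * servings
}

per_serving_price <- function(db) {
  db$foods$price_per_kg * db$foods$serving_size_g / 1000
}

per_serving_ghge <- function(db) {
  db$foods$ghge_per_kg * db$foods$serving_size_g / 1000
}

#' Decision-variable specification
#'
#' Bounds and integrality for the weekly serving-count variables. The default
#' per-food ceiling of 200 servings/week is a modelling guard that keeps
#' price/emission minimisation bounded; relaxing integrality gives the LP
#' relaxation for sensitivity analysis.
#'
#' @param db A `food_db`.
#' @param lower,upper Scalars or per-food vectors (default 0 and 200).
#' @param integer Integer serving counts (default `TRUE`).
#' @return A `decision_spec` (data frame food_id, lower, upper, integer).
#' @export
decision_spec <- function(db, lower = 0, upper = 200, integer = TRUE) {
  n <- n_foods(db)
  sp <- data.frame(food_id = db$foods$food_id,
                   lower = rep_len(lower, n), upper = rep_len(upper, n),
                   integer = rep_len(integer, n), stringsAsFactors = FALSE)
  if (any(sp$lower < 0) || any(sp$lower > sp$upper))
    stop("decision bounds must satisfy 0 <= lower <= upper", call. = FALSE)
  structure(sp, class = c("decision_spec", "data.frame"))
}

objective_kinds <- c("MIN_DEVIATION", "MIN_PRICE", "MIN_GHGE")

baseline_vector <- function(db, baseline) {
  b <- stats::setNames(rep(0, n_foods(db)), db$foods$food_id)
  if (!is.null(baseline)) {
    sv <- baseline$servings
    unknown <- setdiff(names(sv), names(b))
    if (length(unknown))
      stop("baseline names food id(s) absent from the database: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    b[names(sv)] <- sv
  }
  b
}

#' Build the diet MILP for one scenario
#'
#' Variables are integer weekly serving counts `x_i` with [decision_spec()]
#' bounds; excluded foods are fixed at zero. For `MIN_DEVIATION` the model
#' adds continuous auxiliaries `d_i >= x_i - b_i`, `d_i >= b_i - x_i` (b the
#' baseline) and minimises their sum — the L1 serving-count distance from the
#' baseline — over non-excluded foods only: foods removed by scenario policy
#' (alcohol) are forced out, not penalised. `MIN_PRICE` / `MIN_GHGE` minimise
#' the weekly total price / emissions. Every model carries one row per
#' present weekly nutrient bound (absorbable supply for protein and the
#' essential amino acids, gross otherwise), and, when caps are set, rows
#' limiting total price/emissions to `fraction * baseline total`.
#'
#' @param db A `food_db`.
#' @param weekly_bounds A `weekly_bounds` from [to_weekly()].
#' @param objective One of `"MIN_DEVIATION"`, `"MIN_PRICE"`, `"MIN_GHGE"`.
#' @param baseline A `baseline_diet`; required for `MIN_DEVIATION` and for
#'   any cap.
#' @param price_cap_fraction,ghge_cap_fraction Optional cap fractions in
#'   `(0, 1]` of the baseline weekly price / emissions.
#' @param exclusions Food ids forced to zero servings.
#' @param decisions A [decision_spec()] (default `decision_spec(db)`).
#' @return A `diet_model` holding the dense constraint system and metadata.
#' @export
build_model <- function(db, weekly_bounds, objective = "MIN_DEVIATION",
                        baseline = NULL, price_cap_fraction = NULL,
                        ghge_cap_fraction = NULL, exclusions = character(0),
                        decisions = decision_spec(db)) {
  objective <- match.arg(objective, objective_kinds)
  stopifnot(inherits(weekly_bounds, "weekly_bounds"), n_foods(db) > 0L)
  wb <- weekly_bounds$bounds
  if (nrow(wb) == 0L) stop("weekly bounds are empty", call. = FALSE)
  needs_baseline <- objective == "MIN_DEVIATION" ||
    !is.null(price_cap_fraction) || !is.null(ghge_cap_fraction)
  if (needs_baseline && is.null(baseline))
    stop("baseline diet required for MIN_DEVIATION or any cap",
         call. = FALSE)
  for (f in c(price_cap_fraction, ghge_cap_fraction))
    if (!is.null(f) && (f <= 0 || f > 1))
      stop("cap fractions must lie in (0, 1]", call. = FALSE)

  ids <- db$foods$food_id
  nf <- length(ids)
  unknown <- setdiff(exclusions, ids)
  if (length(unknown))
    stop("exclusion names unknown food id(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  excl <- ids %in% exclusions

  b <- if (needs_baseline) baseline_vector(db, baseline) else
    stats::setNames(rep(0, nf), ids)

  lb <- decisions$lower
  ub <- decisions$upper
  ub[excl] <- 0
  lb[excl] <- 0

  S <- serving_supply_matrix(db, absorbable = TRUE)
  unknown <- setdiff(wb$nutrient_id, colnames(S))
  if (length(unknown))
    stop("bounds name nutrient(s) absent from database: ",
         paste(unknown, collapse = ", "), call. = FALSE)

  dev_idx <- if (objective == "MIN_DEVIATION") which(!excl) else integer(0)
  nd <- length(dev_idx)
  nv <- nf + nd

  cost <- numeric(nv)
  if (objective == "MIN_PRICE") cost[seq_len(nf)] <- per_serving_price(db)
  if (objective == "MIN_GHGE") cost[seq_len(nf)] <- per_serving_ghge(db)
  if (nd) cost[nf + seq_len(nd)] <- 1

  rows <- list(); row_lb <- c(); row_ub <- c(); row_meta <- list()
  add_row <- function(coef, lo, hi, meta) {
    rows[[length(rows) + 1L]] <<- coef
    row_lb <<- c(row_lb, lo); row_ub <<- c(row_ub, hi)
    row_meta[[length(row_meta) + 1L]] <<- meta
  }

  for (k in seq_len(nrow(wb))) {
    coef <- numeric(nv)
    coef[seq_len(nf)] <- S[, wb$nutrient_id[k]]
    lo <- if (is.na(wb$weekly_lower[k])) -Inf else wb$weekly_lower[k]
    hi <- if (is.na(wb$weekly_upper[k])) Inf else wb$weekly_upper[k]
    add_row(coef, lo, hi,
            list(type = "nutrient", nutrient_id = wb$nutrient_id[k]))
  }

  baseline_price <- sum(per_serving_price(db) * b)
  baseline_ghge <- sum(per_serving_ghge(db) * b)
  if (!is.null(price_cap_fraction)) {
    coef <- numeric(nv); coef[seq_len(nf)] <- per_serving_price(db)
    add_row(coef, -Inf, price_cap_fraction * baseline_price,
            list(type = "price_cap"))
  }
  if (!is.null(ghge_cap_fraction)) {
    coef <- numeric(nv); coef[seq_len(nf)] <- per_serving_ghge(db)
    add_row(coef, -Inf, ghge_cap_fraction * baseline_ghge,
            list(type = "ghge_cap"))
  }
  ## deviation linearisation: d_j - x_j >= -b_j  and  d_j + x_j >= b_j
  for (j in seq_along(dev_idx)) {
    i <- dev_idx[j]
    coef <- numeric(nv); coef[i] <- -1; coef[nf + j] <- 1
    add_row(coef, -b[i], Inf, list(type = "dev_pos", food_id = ids[i]))
    coef <- numeric(nv); coef[i] <- 1; coef[nf + j] <- 1
    add_row(coef, b[i], Inf, list(type = "dev_neg", food_id = ids[i]))
  }

  A <- do.call(rbind, rows)
  var_lb <- c(lb, rep(0, nd))
  var_ub <- c(ub, rep(Inf, nd))
  integrality <- c(as.integer(decisions$integer), rep(0L, nd))

  structure(list(
    db = db, objective = objective, food_ids = ids, n_foods = nf,
    n_dev = nd, dev_idx = dev_idx, baseline = b,
    baseline_price = baseline_price, baseline_ghge = baseline_ghge,
    price_cap_fraction = price_cap_fraction,
    ghge_cap_fraction = ghge_cap_fraction,
    exclusions = ids[excl], weekly_bounds = weekly_bounds,
    cost = cost, A = A, row_lb = row_lb, row_ub = row_ub,
    row_meta = row_meta, var_lb = var_lb, var_ub = var_ub,
    integrality = integrality
  ), class = "diet_model")
}

#' @export
print.diet_model <- function(x, ...) {
  cat(sprintf(
    "<diet_model> %s: %d integer + %d continuous vars, %d rows (%d nutrient, %d cap)\n",
    x$objective, x$n_foods, x$n_dev, nrow(x$A),
    sum(vapply(x$row_meta, function(m) m$type == "nutrient", logical(1))),
    sum(vapply(x$row_meta, function(m) m$type %in% c("price_cap", "ghge_cap"),
               logical(1)))))
  invisible(x)
}

#' Export a model in LP file format
#'
#' Writes a CPLEX-LP-format rendering of the model for inspection with any
#' external solver.
#'
#' @param model A `diet_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_lp <- function(model, path) {
  nv <- length(model$cost)
  vn <- c(paste0("x_", model$food_ids),
          if (model$n_dev) paste0("d_", model$food_ids[model$dev_idx]))
  term <- function(coef) {
    nz <- which(coef != 0)
    if (!length(nz)) return("0 x_dummy")
    paste(sprintf("%+.12g %s", coef[nz], vn[nz]), collapse = " ")
  }
  con <- character(0)
  for (r in seq_len(nrow(model$A))) {
    lhs <- term(model$A[r, ])
    if (is.finite(model$row_lb[r]))
      con <- c(con, sprintf(" c%d_l: %s >= %.12g", r, lhs, model$row_lb[r]))
    if (is.finite(model$row_ub[r]))
      con <- c(con, sprintf(" c%d_u: %s <= %.12g", r, lhs, model$row_ub[r]))
  }
  bounds <- sprintf(" %.12g <= %s <= %s", model$var_lb, vn,
                    ifelse(is.finite(model$var_ub),
                           sprintf("%.12g", model$var_ub), "+inf"))
  ints <- vn[model$integrality == 1L]
  writeLines(c("Minimize", paste(" obj:", term(model$cost)),
               "Subject To", con, "Bounds", bounds,
               if (length(ints)) c("General", paste("", ints)),
               "End"), path)
  invisible(path)
}

#' Evaluate a diet's weekly totals
#'
#' Computes, from serving counts alone, the weekly price, greenhouse-gas
#' emissions, per-nutrient supply (absorbable and gross), and the per-group
#' decompositions of grams, price and emissions. Group decompositions
#' partition the totals exactly.
#'
#' @param db A `food_db`.
#' @param servings Named numeric of weekly serving counts (foods absent from
#'   the vector count as zero).
#' @return A `diet_totals` list: `price`, `ghge`, `supply` (absorbable, named
#'   by nutrient), `supply_gross`, `group_grams`, `group_price`,
#'   `group_ghge` (named by food group, all groups present).
#' @export
evaluate_diet <- function(db, servings) {
  x <- stats::setNames(rep(0, n_foods(db)), db$foods$food_id)
  if (length(servings)) {
    unknown <- setdiff(names(servings), names(x))
    if (length(unknown))
      stop("unknown food id(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    x[names(servings)] <- servings
  }
  grp <- factor(db$foods$group, levels = food_groups())
  by_group <- function(v) {
    out <- tapply(v, grp, sum, default = 0)
    stats::setNames(as.numeric(out), levels(grp))
  }
  grams <- x * db$foods$serving_size_g
  price_i <- x * per_serving_price(db)
  ghge_i <- x * per_serving_ghge(db)
  structure(list(
    price = sum(price_i),
    ghge = sum(ghge_i),
    supply = drop(x %*% serving_supply_matrix(db, TRUE)),
    supply_gross = drop(x %*% serving_supply_matrix(db, FALSE)),
    group_grams = by_group(grams),
    group_price = by_group(price_i),
    group_ghge = by_group(ghge_i),
    servings = x
  ), class = "diet_totals")
}

## objective value recomputed from a serving vector, independent of solver
objective_from_servings <- function(model, x) {
  switch(model$objective,
         MIN_DEVIATION = sum(abs(x[model$dev_idx] -
                                   model$baseline[model$dev_idx])),
         MIN_PRICE = sum(per_serving_price(model$db) * x),
         MIN_GHGE = sum(per_serving_ghge(model$db) * x))
}

## feasibility of a serving vector against the model's rows, tolerance tol
check_feasibility <- function(model, x, tol = 1e-6) {
  totals <- evaluate_diet(model$db, stats::setNames(x, model$food_ids))
  wb <- model$weekly_bounds$bounds
  s <- totals$supply[wb$nutrient_id]
  viol <- character(0)
  low_bad <- !is.na(wb$weekly_lower) & s < wb$weekly_lower - tol
  up_bad <- !is.na(wb$weekly_upper) & s > wb$weekly_upper + tol
  viol <- c(viol,
            if (any(low_bad)) paste0("below lower: ",
                                     paste(wb$nutrient_id[low_bad],
                                           collapse = ",")),
            if (any(up_bad)) paste0("above upper: ",
                                    paste(wb$nutrient_id[up_bad],
                                          collapse = ",")))
  if (!is.null(model$price_cap_fraction) &&
      totals$price > model$price_cap_fraction * model$baseline_price + tol)
    viol <- c(viol, "price cap exceeded")
  if (!is.null(model$ghge_cap_fraction) &&
      totals$ghge > model$ghge_cap_fraction * model$baseline_ghge + tol)
    viol <- c(viol, "ghge cap exceeded")
  if (any(x < model$var_lb[seq_len(model$n_foods)] - tol) ||
      any(x > model$var_ub[seq_len(model$n_foods)] + tol))
    viol <- c(viol, "serving bounds violated")
  list(feasible = length(viol) == 0L, violations = viol, totals = totals)
}
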