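## Exhaustive-enumeration oracle: the independent route against which the
## MILP path is verified on small instances. Pure R, shares no code with the
## solver backend.

#' Exact optimum by exhaustive enumeration
#'
#' Enumerates every integer serving vector with entries in
#' `0..min(max_servings, upper bound)` per food, filters by feasibility
#' (nutrient bounds, caps, exclusions) and returns the exact optimum and the
#' complete argmin set (ties included). Intended as a testing oracle for
#' instances of a few foods; refuses instances beyond `budget` candidates.
#'
#' @inheritParams build_model
#' @param max_servings Per-food enumeration ceiling.
#' @param budget Maximum number of candidate vectors (default 1e7).
#' @return List: `status` (`"optimal"` or `"infeasible"`), `objective`,
#'   `argmin` (matrix, one row per tied optimum, columns = foods),
#'   `n_candidates`.
#' @export
brute_force_optimum <- function(db, weekly_bounds,
                                objective = "MIN_DEVIATION",
                                baseline = NULL, price_cap_fraction = NULL,
                                ghge_cap_fraction = NULL,
                                exclusions = character(0),
                                max_servings = 4, budget = 1e7) {
  objective <- match.arg(objective, objective_kinds)
  ids <- db$foods$food_id
  nf <- length(ids)
  ub <- rep(max_servings, nf)
  ub[ids %in% exclusions] <- 0
  n_cand <- prod(ub + 1)
  if (n_cand > budget)
    stop(sprintf(
      "enumeration budget exceeded: %.3g candidates for %d foods (budget %.3g)",
      n_cand, nf, budget), call. = FALSE)

  X <- as.matrix(expand.grid(lapply(ub, function(u) 0:u),
                             KEEP.OUT.ATTRS = FALSE))
  colnames(X) <- ids

  S <- serving_supply_matrix(db, absorbable = TRUE)
  wb <- weekly_bounds$bounds
  supply <- X %*% S[, wb$nutrient_id, drop = FALSE]
  feas <- rep(TRUE, nrow(X))
  for (k in seq_len(nrow(wb))) {
    if (!is.na(wb$weekly_lower[k]))
      feas <- feas & supply[, k] >= wb$weekly_lower[k] - 1e-9
    if (!is.na(wb$weekly_upper[k]))
      feas <- feas & supply[, k] <= wb$weekly_upper[k] + 1e-9
  }
  price <- drop(X %*% per_serving_price(db))
  ghge <- drop(X %*% per_serving_ghge(db))
  b <- if (!is.null(baseline)) baseline_vector(db, baseline) else
    stats::setNames(rep(0, nf), ids)
  if (!is.null(price_cap_fraction))
    feas <- feas & price <= price_cap_fraction * sum(per_serving_price(db) * b) + 1e-9
  if (!is.null(ghge_cap_fraction))
    feas <- feas & ghge <= ghge_cap_fraction * sum(per_serving_ghge(db) * b) + 1e-9

  if (!any(feas))
    return(list(status = "infeasible", objective = NA_real_,
                argmin = NULL, n_candidates = nrow(X)))

  obj <- switch(objective,
                MIN_DEVIATION = {
                  free <- !(ids %in% exclusions)
                  rowSums(abs(sweep(X[, free, drop = FALSE], 2L, b[free])))
                },
                MIN_PRICE = price,
                MIN_GHGE = ghge)
  obj[!feas] <- Inf
  best <- min(obj)
  list(status = "optimal", objective = best,
       argmin = X[obj <= best + 1e-12, , drop = FALSE],
       n_candidates = nrow(X))
}
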