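## Solving: models built by build_model() are handed to the HiGHS
## branch-and-bound via scipy.optimize.milp in a Python subprocess. Calls are
## batched (one interpreter start per batch) and every returned solution is
## audited by independent re-evaluation in R before being accepted.

INF_SENTINEL <- 1e30

encode_inf <- function(v) {
  v[v == Inf] <- INF_SENTINEL
  v[v == -Inf] <- -INF_SENTINEL
  v
}

python_binary <- function() {
  Sys.getenv("DIETOPT_PYTHON", unset = "python")
}

solver_script <- function() {
  p <- system.file("python", "milp_solve.py", package = "dietopt")
  if (!nzchar(p)) stop("solver script not found in installed package",
                       call. = FALSE)
  p
}

## one subprocess call solving a list of raw model payloads
run_solver_backend <- function(payloads) {
  fin <- tempfile(fileext = ".json")
  fout <- tempfile(fileext = ".json")
  on.exit(unlink(c(fin, fout)), add = TRUE)
  jsonlite::write_json(list(models = payloads), fin, auto_unbox = TRUE,
                       digits = NA)
  status <- system2(python_binary(), c(solver_script(), fin, fout),
                    stdout = TRUE, stderr = TRUE)
  code <- attr(status, "status") %||% 0L
  if (code != 0L || !file.exists(fout))
    stop("MILP backend failed (exit ", code, "): ",
         paste(status, collapse = "\n"), call. = FALSE)
  jsonlite::read_json(fout, simplifyVector = TRUE, simplifyDataFrame = FALSE)
}

model_payload <- function(model, time_limit) {
  list(c = model$cost, A = as.vector(t(model$A)),
       row_lb = encode_inf(model$row_lb), row_ub = encode_inf(model$row_ub),
       lb = encode_inf(model$var_lb), ub = encode_inf(model$var_ub),
       integrality = model$integrality, time_limit = time_limit)
}

#' Solve several diet models in one solver invocation
#'
#' Identical to calling [solve_model()] on each element, but starts the
#' solver backend once; scenario batteries and property tests use this to
#' amortise interpreter startup.
#'
#' @param models List of `diet_model`.
#' @param seed Integer recorded in each solution's log (the branch-and-bound
#'   itself is deterministic; the seed governs fixture generation upstream).
#' @param time_limit Per-model wall limit, seconds.
#' @param diagnose On infeasibility, re-solve with elastic slack on nutrient
#'   rows and report the minimal-violation nutrients (default `TRUE`).
#' @return List of `diet_solution`.
#' @export
solve_models <- function(models, seed = NULL, time_limit = 60,
                         diagnose = TRUE) {
  stopifnot(all(vapply(models, inherits, logical(1), "diet_model")))
  if (length(models) == 0L) return(list())
  raw <- run_solver_backend(lapply(models, model_payload, time_limit))
  sols <- Map(finalise_solution, models, raw,
              MoreArgs = list(seed = seed))
  ## elastic diagnosis pass, batched as well
  infeas <- which(vapply(sols, function(s) s$status == "infeasible",
                         logical(1)))
  if (diagnose && length(infeas)) {
    el_models <- lapply(models[infeas], elastic_model)
    el_raw <- run_solver_backend(lapply(el_models, model_payload,
                                        time_limit))
    for (k in seq_along(infeas)) {
      sols[[infeas[k]]]$diagnosis <-
        elastic_diagnosis(models[[infeas[k]]], el_models[[k]], el_raw[[k]])
    }
  }
  sols
}

#' Solve a diet MILP
#'
#' Hands the model to HiGHS (proven-optimal termination, zero relative MIP
#' gap), rounds the integer variables, and audits the result by independent
#' re-evaluation in R: constraint residuals above `1e-6` raise an internal
#' consistency error rather than returning a bad solution. The stored
#' objective value is recomputed from the rounded serving vector, never
#' copied from the solver.
#'
#' @param model A `diet_model` from [build_model()].
#' @inheritParams solve_models
#' @return A `diet_solution`: `status` (`"optimal"`, `"infeasible"`,
#'   `"time_limit"`, `"error"`), `servings` (named weekly counts),
#'   `objective_value`, `totals` (a `diet_totals`), `deviation_l1`, and on
#'   infeasibility an elastic-slack `diagnosis` naming violated nutrients.
#' @export
solve_model <- function(model, seed = NULL, time_limit = 60,
                        diagnose = TRUE) {
  solve_models(list(model), seed = seed, time_limit = time_limit,
               diagnose = diagnose)[[1]]
}

finalise_solution <- function(model, raw, seed = NULL, audit_tol = 1e-6) {
  base <- list(status = raw$status, servings = NULL, objective_value = NA_real_,
               totals = NULL, deviation_l1 = NA_real_, gap = raw$gap %||% NA,
               message = raw$message %||% "", seed = seed)
  if (!identical(raw$status, "optimal")) {
    if (identical(raw$status, "unbounded")) base$status <- "unbounded_guard"
    if (identical(raw$status, "time_limit") && !is.null(raw$x))
      base$incumbent <- stats::setNames(unlist(raw$x)[seq_len(model$n_foods)],
                                        model$food_ids)
    return(structure(base, class = "diet_solution"))
  }
  x_raw <- unlist(raw$x)[seq_len(model$n_foods)]
  is_int <- model$integrality[seq_len(model$n_foods)] == 1L
  x <- x_raw
  x[is_int] <- round(x_raw[is_int])
  if (any(abs(x[is_int] - x_raw[is_int]) > 1e-5))
    stop("solver returned non-integral integer variables", call. = FALSE)
  x[abs(x) < 1e-9] <- 0
  chk <- check_feasibility(model, x, tol = audit_tol)
  if (!chk$feasible)
    stop("solution failed the independent constraint audit: ",
         paste(chk$violations, collapse = "; "), call. = FALSE)
  obj <- objective_from_servings(model, x)
  sol <- structure(list(
    status = "optimal",
    servings = stats::setNames(x, model$food_ids),
    objective_value = obj,
    totals = chk$totals,
    deviation_l1 = sum(abs(x[model$dev_idx] - model$baseline[model$dev_idx])),
    gap = raw$gap %||% 0,
    message = raw$message %||% "",
    seed = seed
  ), class = "diet_solution")
  sol
}

## elastic reformulation: one slack variable per finite nutrient bound,
## objective = total slack; exposes which requirements make a model infeasible
elastic_model <- function(model) {
  nut_rows <- which(vapply(model$row_meta,
                           function(m) m$type == "nutrient", logical(1)))
  ## one slack per finite bound side: +s relaxes a lower bound, -s an upper
  sides <- do.call(rbind, lapply(nut_rows, function(r) {
    rbind(if (is.finite(model$row_lb[r])) c(r, 1),
          if (is.finite(model$row_ub[r])) c(r, -1))
  }))
  nv <- length(model$cost)
  ns <- nrow(sides)
  A <- cbind(model$A, matrix(0, nrow(model$A), ns))
  for (k in seq_len(ns)) A[sides[k, 1L], nv + k] <- sides[k, 2L]
  em <- model
  em$cost <- c(numeric(nv), rep(1, ns))
  em$A <- A
  em$var_lb <- c(model$var_lb, rep(0, ns))
  em$var_ub <- c(model$var_ub, rep(Inf, ns))
  em$integrality <- c(model$integrality, rep(0L, ns))
  em$elastic_rows <- sides[, 1L]
  em
}

elastic_diagnosis <- function(model, em, raw, tol = 1e-6) {
  if (!identical(raw$status, "optimal"))
    return(list(available = FALSE, message = raw$message %||% "elastic solve failed"))
  nv_orig <- length(model$cost)
  slack <- unlist(raw$x)[-seq_len(nv_orig)]
  hit <- which(slack > tol)
  nut <- vapply(model$row_meta[em$elastic_rows[hit]],
                function(m) m$nutrient_id, character(1))
  list(available = TRUE, total_violation = sum(slack),
       nutrients = data.frame(nutrient_id = nut, violation = slack[hit],
                              stringsAsFactors = FALSE))
}

#' @export
print.diet_solution <- function(x, ...) {
  cat(sprintf("<diet_solution> status=%s", x$status))
  if (identical(x$status, "optimal"))
    cat(sprintf(" objective=%.6g price=%.2f ghge=%.3f deviation=%.6g foods=%d",
                x$objective_value, x$totals$price, x$totals$ghge,
                x$deviation_l1, sum(x$servings > 0)))
  cat("\n")
  if (!is.null(x$diagnosis) && isTRUE(x$diagnosis$available) &&
      nrow(x$diagnosis$nutrients))
    cat("  infeasible on:",
        paste(x$diagnosis$nutrients$nutrient_id, collapse = ", "), "\n")
  invisible(x)
}

#' Count distinct foods used by a solution
#' @param solution A `diet_solution`.
#' @return Number of foods with servings > 0 (NA unless optimal).
#' @export
n_distinct_foods <- function(solution) {
  if (!identical(solution$status, "optimal")) return(NA_integer_)
  sum(solution$servings > 0)
}
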