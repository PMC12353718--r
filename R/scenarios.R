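## Scenario battery: the nine per-sex scenarios (baseline evaluation plus
## eight optimisations), the runner, and the report tables (food-group
## intakes, nutrient contributions, price/emission decompositions, percent
## changes versus baseline).

#' Construct a scenario
#'
#' @param label Unique scenario label, e.g. `"F.NAD_P"`.
#' @param sex `"female"` or `"male"`.
#' @param age_group Requirement-set age group (`"19-30"` unless stated).
#' @param objective `"BASELINE"` (evaluate only) or an optimisation kind
#'   (`"MIN_DEVIATION"`, `"MIN_PRICE"`, `"MIN_GHGE"`).
#' @param price_cap_fraction,ghge_cap_fraction Optional caps in `(0, 1]` as
#'   fractions of the baseline weekly total.
#' @param exclude_groups Food groups forced to zero servings (default:
#'   alcoholic beverages, which are never recommended upward).
#' @param deviation_constrained `FALSE` for pure minimum-price/-emission
#'   scenarios: no constraint ties them to the baseline.
#' @return A `scenario`.
#' @export
scenario <- function(label, sex, age_group = "19-30",
                     objective = "MIN_DEVIATION",
                     price_cap_fraction = NULL, ghge_cap_fraction = NULL,
                     exclude_groups = "alcoholic_beverages",
                     deviation_constrained = objective == "MIN_DEVIATION") {
  objective <- match.arg(objective, c("BASELINE", objective_kinds))
  sex <- match.arg(sex, requirement_sexes)
  age_group <- match.arg(age_group, requirement_age_groups)
  for (f in c(price_cap_fraction, ghge_cap_fraction))
    if (!is.null(f) && (f <= 0 || f > 1))
      stop("cap fractions must lie in (0, 1]", call. = FALSE)
  stopifnot(all(exclude_groups %in% food_groups()))
  structure(list(label = label, sex = sex, age_group = age_group,
                 objective = objective,
                 price_cap_fraction = price_cap_fraction,
                 ghge_cap_fraction = ghge_cap_fraction,
                 exclude_groups = exclude_groups,
                 deviation_constrained = deviation_constrained),
            class = "scenario")
}

#' The default nine-scenario battery for one or both sexes
#'
#' Per sex: the baseline evaluation; minimum-deviation nutrient-adequate
#' diets for the four adult age groups (NAD, NAD_35, NAD_55, NAD_75); NAD_P
#' and NAD_E with a 70% price / emission cap; and the unconstrained minimum
#' emission (Min_E) and minimum price (Min_P) diets. Alcoholic beverages are
#' excluded from every optimised scenario. Labels carry the sex prefix
#' (`F.` / `M.`); an unsuffixed NAD label means ages 19-30.
#'
#' @param sexes Which sexes to include (default both).
#' @param cap_fraction Cap used by NAD_P / NAD_E (default 0.7).
#' @return List of 9 `scenario` per sex (18 for both).
#' @export
default_battery <- function(sexes = c("female", "male"), cap_fraction = 0.7) {
  out <- list()
  for (sex in match.arg(sexes, several.ok = TRUE)) {
    p <- if (sex == "female") "F" else "M"
    lab <- function(s) paste0(p, ".", s)
    sc <- list(
      scenario(lab("Base"), sex, "19-30", "BASELINE",
               exclude_groups = character(0)),
      scenario(lab("NAD"), sex, "19-30", "MIN_DEVIATION"),
      scenario(lab("NAD_35"), sex, "31-50", "MIN_DEVIATION"),
      scenario(lab("NAD_55"), sex, "51-69", "MIN_DEVIATION"),
      scenario(lab("NAD_75"), sex, "70+", "MIN_DEVIATION"),
      scenario(lab("NAD_P"), sex, "19-30", "MIN_DEVIATION",
               price_cap_fraction = cap_fraction),
      scenario(lab("NAD_E"), sex, "19-30", "MIN_DEVIATION",
               ghge_cap_fraction = cap_fraction),
      scenario(lab("Min_E"), sex, "19-30", "MIN_GHGE",
               deviation_constrained = FALSE),
      scenario(lab("Min_P"), sex, "19-30", "MIN_PRICE",
               deviation_constrained = FALSE)
    )
    out <- c(out, sc)
  }
  names(out) <- vapply(out, `[[`, character(1), "label")
  out
}

scenario_exclusions <- function(db, sc) {
  db$foods$food_id[db$foods$group %in% sc$exclude_groups]
}

build_scenario_model <- function(db, sc, baseline, req_sets,
                                 decisions = decision_spec(db)) {
  key <- demographic_key(sc$sex, sc$age_group)
  req <- req_sets[[key]]
  if (is.null(req))
    stop("no requirement set for demographic '", key, "' (scenario ",
         sc$label, ")", call. = FALSE)
  build_model(db, to_weekly(req), objective = sc$objective,
              baseline = baseline,
              price_cap_fraction = sc$price_cap_fraction,
              ghge_cap_fraction = sc$ghge_cap_fraction,
              exclusions = scenario_exclusions(db, sc),
              decisions = decisions)
}

#' Run a scenario battery
#'
#' Evaluates baseline scenarios directly and batch-solves all optimisation
#' scenarios in a single solver invocation. Failures are isolated: an
#' infeasible or errored scenario yields a report with that status and does
#' not abort the battery. Each optimal solution is cross-checked with
#' [audit_diet()] against its own requirement set.
#'
#' @param db A `food_db`.
#' @param baselines Named list of `baseline_diet`, keyed `"female"`/`"male"`.
#' @param requirement_sets Named list from [read_requirements()] or
#'   [synth_generate()], keyed `"<sex>_<age_group>"`.
#' @param battery List of `scenario` (default [default_battery()]).
#' @param seed Integer seed recorded in the run log.
#' @param decisions Optional [decision_spec()].
#' @param time_limit Per-scenario solver wall limit, seconds.
#' @return A `battery_result`: named list of `scenario_report` (fields
#'   `scenario`, `status`, `solution`, `totals`, `adequacy`,
#'   `group_grams`, `group_price`, `group_ghge`) plus a `log` data frame.
#' @export
run_battery <- function(db, baselines, requirement_sets,
                        battery = default_battery(), seed = NULL,
                        decisions = decision_spec(db), time_limit = 60) {
  labs <- vapply(battery, `[[`, character(1), "label")
  if (anyDuplicated(labs))
    stop("duplicate scenario labels in battery", call. = FALSE)
  for (sc in battery) {
    if (is.null(baselines[[sc$sex]]))
      stop("no baseline diet for sex '", sc$sex, "' (scenario ", sc$label,
           ")", call. = FALSE)
  }

  opt_idx <- which(vapply(battery, function(s) s$objective != "BASELINE",
                          logical(1)))
  models <- vector("list", length(battery))
  build_err <- rep(NA_character_, length(battery))
  for (i in opt_idx) {
    sc <- battery[[i]]
    models[[i]] <- tryCatch(
      build_scenario_model(db, sc, baselines[[sc$sex]], requirement_sets,
                           decisions),
      error = function(e) {build_err[i] <<- conditionMessage(e); NULL})
  }
  solve_idx <- opt_idx[!vapply(models[opt_idx], is.null, logical(1))]
  sols <- solve_models(models[solve_idx], seed = seed,
                       time_limit = time_limit)

  reports <- vector("list", length(battery))
  t0 <- Sys.time()
  for (i in seq_along(battery)) {
    sc <- battery[[i]]
    if (sc$objective == "BASELINE") {
      totals <- evaluate_diet(db, baselines[[sc$sex]]$servings)
      req <- requirement_sets[[demographic_key(sc$sex, sc$age_group)]]
      adequacy <- if (!is.null(req))
        audit_diet(totals$supply, to_weekly(req)) else NULL
      reports[[i]] <- scenario_report(sc, status = "baseline",
                                      solution = NULL, totals = totals,
                                      adequacy = adequacy)
    } else if (!is.na(build_err[i])) {
      reports[[i]] <- scenario_report(sc, status = "error", solution = NULL,
                                      totals = NULL, adequacy = NULL,
                                      message = build_err[i])
    } else {
      sol <- sols[[match(i, solve_idx)]]
      totals <- if (identical(sol$status, "optimal")) sol$totals else NULL
      adequacy <- NULL
      if (identical(sol$status, "optimal")) {
        req <- requirement_sets[[demographic_key(sc$sex, sc$age_group)]]
        adequacy <- audit_diet(totals$supply, to_weekly(req))
        if (n_violations(adequacy) > 0L)
          stop("internal consistency failure: optimal scenario ", sc$label,
               " violates its requirement set", call. = FALSE)
      }
      reports[[i]] <- scenario_report(sc, status = sol$status,
                                      solution = sol, totals = totals,
                                      adequacy = adequacy,
                                      message = sol$message)
    }
  }
  names(reports) <- labs
  log <- data.frame(
    label = labs,
    status = vapply(reports, `[[`, character(1), "status"),
    objective = vapply(battery, `[[`, character(1), "objective"),
    seed = if (is.null(seed)) NA_integer_ else seed,
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")),
    stringsAsFactors = FALSE
  )
  rownames(log) <- NULL
  structure(list(reports = reports, log = log), class = "battery_result")
}

scenario_report <- function(sc, status, solution, totals, adequacy,
                            message = "") {
  structure(list(
    scenario = sc, status = status, solution = solution, totals = totals,
    adequacy = adequacy, message = message,
    group_grams = if (!is.null(totals)) totals$group_grams,
    group_price = if (!is.null(totals)) totals$group_price,
    group_ghge = if (!is.null(totals)) totals$group_ghge
  ), class = "scenario_report")
}

#' @export
print.battery_result <- function(x, ...) {
  cat("<battery_result>\n")
  print(x$log[, c("label", "status", "objective")], row.names = FALSE)
  invisible(x)
}

#' Signed percent change versus baseline
#'
#' `100 * (scenario - baseline) / baseline`. A quantity appearing only in the
#' optimised diet (baseline 0, scenario > 0) has no defined percent and is
#' flagged `"new"`; 0 to 0 is a 0% change. Vectorised; the `status`
#' attribute carries `"ok"`/`"new"` per element.
#'
#' @param baseline_value,scenario_value Non-negative numerics.
#' @return Numeric percent (NA where `"new"`), with attribute `status`.
#' @export
percent_change <- function(baseline_value, scenario_value) {
  if (any(baseline_value < 0) || any(scenario_value < 0))
    stop("percent_change requires non-negative inputs", call. = FALSE)
  n <- max(length(baseline_value), length(scenario_value))
  b <- rep_len(baseline_value, n)
  s <- rep_len(scenario_value, n)
  pct <- ifelse(b > 0, 100 * (s - b) / b, ifelse(s > 0, NA_real_, 0))
  status <- ifelse(b == 0 & s > 0, "new", "ok")
  structure(pct, status = status)
}

#' Weekly grams per food group for a solved or baseline scenario
#'
#' @param report A `scenario_report` with totals (baseline or optimal).
#' @return Named numeric: weekly grams per food group (all groups present,
#'   zero where no food of the group is eaten).
#' @export
group_intake_table <- function(report) {
  stopifnot(inherits(report, "scenario_report"))
  if (is.null(report$totals))
    stop("scenario '", report$scenario$label, "' has no totals (status ",
         report$status, ")", call. = FALSE)
  report$totals$group_grams
}

#' Per-group weekly contribution to one nutrient's supply
#'
#' Splits the diet's total (absorbable) weekly supply of a nutrient across
#' food groups; the contributions sum exactly to the total supply.
#'
#' @param report A `scenario_report` with totals.
#' @param nutrient_id Nutrient identifier.
#' @param db The `food_db` the scenario was run against.
#' @return Named numeric: weekly contribution per food group.
#' @export
nutrient_contribution_table <- function(report, nutrient_id, db) {
  stopifnot(inherits(report, "scenario_report"))
  if (is.null(report$totals))
    stop("scenario '", report$scenario$label, "' has no totals", call. = FALSE)
  if (!nutrient_id %in% colnames(db$composition))
    stop("unknown nutrient: ", nutrient_id, call. = FALSE)
  x <- report$totals$servings
  contrib <- x * serving_supply_matrix(db, TRUE)[, nutrient_id]
  out <- tapply(contrib, factor(db$foods$group, levels = food_groups()),
                sum, default = 0)
  stats::setNames(as.numeric(out), food_groups())
}

#' Tidy export of a battery result
#'
#' One row per (scenario, measure, item): weekly group grams, group price
#' and emission decompositions, nutrient supplies, and headline totals —
#' the tables a stacked-bar figure of weekly intakes, emissions or prices
#' would consume.
#'
#' @param result A `battery_result`.
#' @return Data frame with columns `label`, `status`, `measure`, `item`,
#'   `value`.
#' @export
tidy_battery <- function(result) {
  stopifnot(inherits(result, "battery_result"))
  rows <- list()
  for (rep in result$reports) {
    if (is.null(rep$totals)) {
      rows[[length(rows) + 1L]] <- data.frame(
        label = rep$scenario$label, status = rep$status,
        measure = "status", item = "status", value = NA_real_,
        stringsAsFactors = FALSE)
      next
    }
    t <- rep$totals
    mk <- function(measure, v) data.frame(
      label = rep$scenario$label, status = rep$status, measure = measure,
      item = names(v) %||% measure, value = as.numeric(v),
      stringsAsFactors = FALSE)
    rows[[length(rows) + 1L]] <- rbind(
      mk("total", c(price = t$price, ghge = t$ghge)),
      mk("group_grams", t$group_grams),
      mk("group_price", t$group_price),
      mk("group_ghge", t$group_ghge),
      mk("nutrient_supply", t$supply))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
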