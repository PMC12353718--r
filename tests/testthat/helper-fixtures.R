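# Fixtures are built in code: a hand-computable miniature database, a
# writer for its CSV renderings, and a seeded generator of tiny random
# instances for the solver-vs-enumeration property tests.

# Assemble a food_db directly (bypasses the CSV loader on purpose: loader
# tests compare against these in-memory objects).
make_db <- function(foods, composition, bioavailability = NULL,
                    nutrients = NULL) {
  ids <- foods$food_id
  rownames(composition) <- ids
  bn <- dietopt::bioavailable_nutrients()
  bio <- matrix(1, length(ids), length(bn), dimnames = list(ids, bn))
  if (!is.null(bioavailability))
    bio[rownames(bioavailability), colnames(bioavailability)] <-
      bioavailability
  if (is.null(nutrients))
    nutrients <- data.frame(nutrient_id = colnames(composition),
                            display_name = colnames(composition),
                            unit = "g", bound_kind = "both",
                            stringsAsFactors = FALSE)
  structure(list(schema_version = 1L, currency = "NZD", foods = foods,
                 composition = composition, bioavailability = bio,
                 nutrients = nutrients,
                 validation = list(dropped = data.frame(
                   food_id = character(0), reason = character(0),
                   stringsAsFactors = FALSE))),
            class = "food_db")
}

# Four foods, integer-friendly numbers. Per serving (100 g unless noted):
#   oat (grain, 100 g):   protein 10, calcium 40,  iron 4, price/kg 3, ghge 1
#   milk (dairy, 200 g):  protein 7/100g -> 14,    calcium 120 -> 240, iron 0
#   bean (legume, 100 g): protein 8, calcium 50, iron 2
#   beer (alcohol, 100g): protein 1, calcium 5, iron 0.1
tiny_db <- function() {
  foods <- data.frame(
    food_id = c("oat", "milk", "bean", "beer"),
    name = c("rolled oats", "whole milk", "kidney beans", "lager"),
    group = c("grain_foods", "dairy", "legumes_nuts_seeds",
              "alcoholic_beverages"),
    subgroup = c("breakfast_cereals", "milk", "pulses", "beer"),
    serving_size_g = c(100, 200, 100, 100),
    ghge_per_kg = c(1, 2, 1.5, 1),
    price_per_kg = c(3, 2, 6, 4),
    stringsAsFactors = FALSE
  )
  comp <- matrix(c(
    # protein, calcium, iron
    10, 40, 4,
    7, 120, 0,
    8, 50, 2,
    1, 5, 0.1
  ), nrow = 4, byrow = TRUE,
  dimnames = list(NULL, c("protein", "calcium", "iron")))
  nutrients <- data.frame(
    nutrient_id = c("protein", "calcium", "iron"),
    display_name = c("Protein", "Calcium", "Iron"),
    unit = c("g", "mg", "mg"),
    bound_kind = c("lower", "both", "lower"),
    stringsAsFactors = FALSE
  )
  make_db(foods, comp, nutrients = nutrients)
}

tiny_weekly_bounds <- function(lower = c(protein = 140, calcium = 2000,
                                         iron = 20),
                               upper = c(calcium = 20000)) {
  nut <- union(names(lower), names(upper))
  rs <- dietopt::requirement_set("female", "19-30", data.frame(
    nutrient_id = nut,
    daily_lower = unname(lower[nut]) / 7,
    daily_upper = unname(upper[nut]) / 7,
    stringsAsFactors = FALSE))
  dietopt::to_weekly(rs)
}

# CSV rendering of tiny_db for loader tests; returns the directory
write_tiny_csvs <- function(dir = NULL) {
  if (is.null(dir)) {
    dir <- tempfile("tinydb")
    dir.create(dir)
  }
  db <- tiny_db()
  p <- function(f) file.path(dir, f)
  write.csv(data.frame(food_id = db$foods$food_id, name = db$foods$name,
                       db$composition, check.names = FALSE),
            p("compositions.csv"), row.names = FALSE)
  write.csv(data.frame(food_id = rep(db$foods$food_id, each = 2),
                       store_label = rep(c("a", "b"), 4),
                       price = rep(db$foods$price_per_kg, each = 2),
                       package_mass_g = 1000),
            p("prices.csv"), row.names = FALSE)
  write.csv(data.frame(food_id = db$foods$food_id,
                       kg_co2e_per_kg = db$foods$ghge_per_kg),
            p("ghge.csv"), row.names = FALSE)
  write.csv(db$foods[, c("food_id", "serving_size_g", "group", "subgroup")],
            p("servings.csv"), row.names = FALSE)
  write.csv(db$nutrients, p("nutrients.csv"), row.names = FALSE)
  dir
}

# Random tiny instance for oracle-vs-solver checks: <= 5 foods, <= 6 bound
# nutrients, serving ceiling 4. Objectives and caps cycle deterministically
# with the seed so every combination is exercised. Bounds are drawn around
# the supply of a random reference vector, so both feasible and infeasible
# instances occur.
random_small_instance <- function(seed) {
  set.seed(seed)
  nf <- sample(3:5, 1)
  nn <- sample(3:6, 1)
  groups <- sample(dietopt::food_groups(), nf, replace = TRUE)
  foods <- data.frame(
    food_id = paste0("f", seq_len(nf)), name = paste0("food ", seq_len(nf)),
    group = groups, subgroup = groups,
    serving_size_g = sample(c(50, 100, 200), nf, replace = TRUE),
    ghge_per_kg = round(runif(nf, 0.5, 12), 2),
    price_per_kg = round(runif(nf, 1, 15), 2),
    stringsAsFactors = FALSE
  )
  comp <- matrix(round(runif(nf * nn, 0, 20), 1), nf,
                 dimnames = list(foods$food_id, paste0("n", seq_len(nn))))
  db <- make_db(foods, comp)
  ref <- sample(0:3, nf, replace = TRUE)
  supply <- drop(ref %*% dietopt::serving_supply_matrix(db))
  lo <- supply * runif(nn, 0.5, 1.15)      # sometimes unattainable
  hi <- ifelse(runif(nn) < 0.3, supply * runif(nn, 1.1, 2), NA_real_)
  hi <- pmax(hi, lo * 1.05)
  rs <- dietopt::requirement_set("female", "19-30", data.frame(
    nutrient_id = colnames(comp), daily_lower = lo / 7, daily_upper = hi / 7,
    stringsAsFactors = FALSE))
  objective <- dietopt:::objective_kinds[seed %% 3 + 1]
  with_cap <- seed %% 2 == 0
  baseline <- dietopt::baseline_diet(
    setNames(pmin(ref + sample(0:1, nf, TRUE), 4), foods$food_id), "ref", db)
  list(db = db, bounds = dietopt::to_weekly(rs), objective = objective,
       baseline = baseline,
       price_cap = if (with_cap && objective != "MIN_PRICE") 0.9 else NULL,
       ghge_cap = if (with_cap && objective == "MIN_PRICE") 0.9 else NULL)
}

# Solver-vs-oracle comparison on a batch of seeds; returns data.frame
compare_solver_oracle <- function(seeds, max_servings = 4) {
  insts <- lapply(seeds, random_small_instance)
  models <- lapply(insts, function(it)
    dietopt::build_model(it$db, it$bounds, it$objective, it$baseline,
                         price_cap_fraction = it$price_cap,
                         ghge_cap_fraction = it$ghge_cap,
                         decisions = dietopt::decision_spec(
                           it$db, upper = max_servings)))
  sols <- dietopt::solve_models(models, diagnose = FALSE)
  oracle <- lapply(insts, function(it)
    dietopt::brute_force_optimum(it$db, it$bounds, it$objective, it$baseline,
                                 price_cap_fraction = it$price_cap,
                                 ghge_cap_fraction = it$ghge_cap,
                                 max_servings = max_servings))
  data.frame(
    seed = seeds,
    milp_status = vapply(sols, `[[`, character(1), "status"),
    oracle_status = vapply(oracle, `[[`, character(1), "status"),
    milp_obj = vapply(sols, function(s)
      if (identical(s$status, "optimal")) s$objective_value else NA_real_,
      numeric(1)),
    oracle_obj = vapply(oracle, function(o) o$objective %||% NA_real_,
                        numeric(1))
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
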