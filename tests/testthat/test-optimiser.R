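# Model construction, solving, evaluation, and the enumeration oracle.

test_that("food_weekly_amount links composition, serving size and counts", {
  db <- tiny_db()
  # milk: calcium 120 mg/100 g, serving 200 g, 7 servings -> 1680 mg
  expect_equal(food_weekly_amount("milk", 7, "calcium", db), 1680)
  expect_equal(food_weekly_amount("oat", 0, "calcium", db), 0)
  # absorbable protein respects the coefficient
  db$bioavailability["oat", "protein"] <- 0.9
  expect_equal(food_weekly_amount("oat", 1, "protein", db), 9)
  expect_equal(food_weekly_amount("oat", 1, "protein", db,
                                  absorbable = FALSE), 10)
  expect_error(food_weekly_amount("oat", 1, "unobtainium", db), "unknown")
})

test_that("build_model lays out variables, rows and caps as specified", {
  db <- tiny_db()
  wb <- tiny_weekly_bounds()
  base <- baseline_diet(c(oat = 7, milk = 7, bean = 2, beer = 3), "f", db)
  m <- build_model(db, wb, "MIN_DEVIATION", base,
                   exclusions = "beer")
  # 4 integer serving variables + 3 deviation auxiliaries (excluded food
  # carries no deviation term)
  expect_equal(m$n_foods, 4)
  expect_equal(m$n_dev, 3)
  expect_equal(sum(m$integrality), 4)
  n_nut <- sum(vapply(m$row_meta, function(x) x$type == "nutrient",
                      logical(1)))
  n_dev_rows <- sum(vapply(m$row_meta, function(x)
    x$type %in% c("dev_pos", "dev_neg"), logical(1)))
  expect_equal(n_nut, 3)
  expect_equal(n_dev_rows, 2 * 3)
  # excluded food variable fixed at zero
  expect_equal(m$var_ub[match("beer", m$food_ids)], 0)

  # price cap right-hand side is fraction x baseline weekly price
  mp <- build_model(db, wb, "MIN_DEVIATION", base, price_cap_fraction = 0.7)
  cap_row <- which(vapply(mp$row_meta, function(x) x$type == "price_cap",
                          logical(1)))
  base_price <- evaluate_diet(db, base$servings)$price
  expect_equal(mp$row_ub[cap_row], 0.7 * base_price)
  # cap without baseline is a config error
  expect_error(build_model(db, wb, "MIN_PRICE", baseline = NULL,
                           price_cap_fraction = 0.7), "baseline")
})

test_that("a one-food instance solves to the hand-derived optimum", {
  foods <- data.frame(food_id = "omni", name = "omnifood",
                      group = "miscellaneous", subgroup = "x",
                      serving_size_g = 100, ghge_per_kg = 2,
                      price_per_kg = 10, stringsAsFactors = FALSE)
  comp <- matrix(c(20, 100), 1, dimnames = list("omni", c("protein",
                                                          "calcium")))
  db <- make_db(foods, comp)
  # lower bounds reachable at exactly 3 servings: protein 60, calcium 300
  rs <- requirement_set("female", "19-30", data.frame(
    nutrient_id = c("protein", "calcium"),
    daily_lower = c(41, 220) / 7, daily_upper = NA_real_))
  sol <- solve_model(build_model(db, to_weekly(rs), "MIN_PRICE"))
  expect_equal(sol$status, "optimal")
  expect_equal(unname(sol$servings["omni"]), 3)
  # price: 3 servings x 100 g x 10 /kg = 3 NZD
  expect_equal(sol$objective_value, 3)
  expect_equal(sol$totals$price, 3)
})

test_that("contradictory bounds are reported infeasible with diagnosis", {
  db <- tiny_db()
  # calcium lower bound above what its upper limit permits elsewhere:
  # require huge iron but cap calcium so tightly no diet can deliver both
  rs <- requirement_set("female", "19-30", data.frame(
    nutrient_id = c("iron", "calcium"),
    daily_lower = c(5000, NA), daily_upper = c(NA, 10),
    stringsAsFactors = FALSE))
  sol <- solve_model(build_model(db, to_weekly(rs), "MIN_PRICE"))
  expect_equal(sol$status, "infeasible")
  expect_true(sol$diagnosis$available)
  expect_true(all(c("iron") %in% sol$diagnosis$nutrients$nutrient_id))
  # oracle agrees
  bf <- brute_force_optimum(db, to_weekly(rs), "MIN_PRICE")
  expect_equal(bf$status, "infeasible")
})

test_that("MILP objective equals exhaustive enumeration on random instances", {
  cmp <- compare_solver_oracle(seeds = 1:25)
  expect_identical(cmp$milp_status, cmp$oracle_status)
  ok <- cmp$milp_status == "optimal"
  expect_true(any(ok) && any(!ok))  # the draw exercises both verdicts
  expect_equal(cmp$milp_obj[ok], cmp$oracle_obj[ok], tolerance = 1e-9)
})

test_that("brute force enumerates the full candidate grid and exposes ties", {
  db <- local({
    d <- tiny_db()
    d$foods <- d$foods[1:3, ]
    d$composition <- d$composition[1:3, , drop = FALSE]
    d$bioavailability <- d$bioavailability[1:3, , drop = FALSE]
    d
  })
  wb <- tiny_weekly_bounds(lower = c(protein = 10, calcium = 100, iron = 1),
                           upper = c(calcium = 1e6))
  bf <- brute_force_optimum(db, wb, "MIN_PRICE", max_servings = 4)
  expect_equal(bf$n_candidates, 125)  # 5^3
  expect_true(nrow(bf$argmin) >= 1)
  expect_error(brute_force_optimum(db, wb, "MIN_PRICE", max_servings = 4,
                                   budget = 100), "budget")
})

test_that("evaluate_diet totals are exact sums and groups partition them", {
  db <- tiny_db()
  # 2 servings x 100 g at 5 kg CO2-eq/kg -> 1.0 kg/week
  db$foods$ghge_per_kg[1] <- 5
  t1 <- evaluate_diet(db, c(oat = 2))
  expect_equal(t1$ghge, 1.0)
  t0 <- evaluate_diet(db, c())
  expect_equal(t0$price, 0)
  expect_true(all(t0$supply == 0))
  set.seed(21)
  x <- setNames(sample(0:5, 4, TRUE), db$foods$food_id)
  tt <- evaluate_diet(db, x)
  expect_equal(sum(tt$group_ghge), tt$ghge, tolerance = 1e-9)
  expect_equal(sum(tt$group_price), tt$price, tolerance = 1e-9)
  expect_equal(sum(tt$group_grams), sum(x * db$foods$serving_size_g))
  expect_error(evaluate_diet(db, c(ghost = 1)), "unknown food")
})

test_that("zero-deviation identity: adequate baseline is returned unchanged", {
  db <- tiny_db()
  base_srv <- c(oat = 7, milk = 7, bean = 3)
  supply <- evaluate_diet(db, base_srv)$supply
  rs <- requirement_set("female", "19-30", data.frame(
    nutrient_id = names(supply), daily_lower = unname(supply) * 0.8 / 7,
    daily_upper = unname(supply) * 2 / 7, stringsAsFactors = FALSE))
  base <- baseline_diet(base_srv, "f", db)
  sol <- solve_model(build_model(db, to_weekly(rs), "MIN_DEVIATION", base,
                                 exclusions = "beer"))
  expect_equal(sol$status, "optimal")
  expect_equal(sol$objective_value, 0)
  expect_equal(sol$servings[names(base_srv)], base_srv)
})

test_that("exclusions are honoured and scale invariance holds for price", {
  db <- tiny_db()
  wb <- tiny_weekly_bounds()
  base <- baseline_diet(c(oat = 7, milk = 7, bean = 3, beer = 4), "f", db)
  sol <- solve_model(build_model(db, wb, "MIN_DEVIATION", base,
                                 exclusions = "beer"))
  expect_equal(unname(sol$servings["beer"]), 0)

  m1 <- build_model(db, wb, "MIN_PRICE")
  s1 <- solve_model(m1)
  db2 <- db; db2$foods$price_per_kg <- db$foods$price_per_kg * 3.5
  s2 <- solve_model(build_model(db2, wb, "MIN_PRICE"))
  expect_equal(s2$objective_value, 3.5 * s1$objective_value,
               tolerance = 1e-9)
})

test_that("cap monotonicity: deviation optimum never worsens as caps loosen", {
  gen <- synth_generate(synth_spec(seed = 404, n_foods_per_group = c(
    fruits_vegetables = 2, grain_foods = 2, legumes_nuts_seeds = 1,
    mspe = 2, dairy = 2, fats_oils = 1, miscellaneous = 1,
    non_alcoholic_beverages = 1, alcoholic_beverages = 1)))
  wb <- to_weekly(gen$requirement_sets[["female_19-30"]])
  excl <- gen$db$foods$food_id[gen$db$foods$group == "alcoholic_beverages"]
  grid <- c(0.5, 0.6, 0.7, 0.8, 0.9, 1.0)
  models <- lapply(grid, function(f)
    build_model(gen$db, wb, "MIN_DEVIATION", gen$baselines$female,
                price_cap_fraction = f, exclusions = excl))
  sols <- solve_models(models, diagnose = FALSE)
  obj <- vapply(sols, function(s)
    if (identical(s$status, "optimal")) s$objective_value else Inf,
    numeric(1))
  expect_true(all(diff(obj) <= 1e-9))
  # a price cap at or above MIN_PRICE's own optimum does not change it
  mp0 <- solve_model(build_model(gen$db, wb, "MIN_PRICE",
                                 exclusions = excl), diagnose = FALSE)
  mp1 <- solve_model(build_model(gen$db, wb, "MIN_PRICE",
                                 gen$baselines$female,
                                 price_cap_fraction = 1.0,
                                 exclusions = excl), diagnose = FALSE)
  expect_equal(mp1$objective_value, mp0$objective_value, tolerance = 1e-9)
})

test_that("audited solutions satisfy every bound on re-evaluation", {
  gen <- synth_generate(synth_spec(seed = 77))
  wb <- to_weekly(gen$requirement_sets[["male_51-69"]])
  excl <- gen$db$foods$food_id[gen$db$foods$group == "alcoholic_beverages"]
  for (obj in c("MIN_DEVIATION", "MIN_PRICE", "MIN_GHGE")) {
    sol <- solve_model(build_model(gen$db, wb, obj, gen$baselines$male,
                                   exclusions = excl))
    expect_equal(sol$status, "optimal")
    expect_equal(n_violations(audit_diet(sol$totals$supply, wb)), 0L)
  }
})

test_that("LP export writes a parseable model rendering", {
  db <- tiny_db()
  m <- build_model(db, tiny_weekly_bounds(), "MIN_PRICE")
  path <- withr::local_tempfile(fileext = ".lp")
  write_lp(m, path)
  txt <- readLines(path)
  expect_true(any(grepl("^Minimize$", txt)))
  expect_true(any(grepl("x_oat", txt)))
  expect_true(any(grepl("^General$", txt)))
})
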