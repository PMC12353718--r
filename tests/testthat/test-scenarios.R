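# Scenario battery contents, the runner, and the report tables.

test_that("default battery matches the nine-per-sex design", {
  bat <- default_battery()
  expect_length(bat, 18)
  expect_true("M.NAD_75" %in% names(bat))
  expect_equal(bat[["M.NAD_75"]]$age_group, "70+")
  # Min_P: price objective, unconstrained by deviation
  expect_equal(bat[["M.Min_P"]]$objective, "MIN_PRICE")
  expect_false(bat[["M.Min_P"]]$deviation_constrained)
  expect_equal(bat[["F.Min_E"]]$objective, "MIN_GHGE")
  # all optimised scenarios exclude alcoholic beverages; baseline does not
  opt <- Filter(function(s) s$objective != "BASELINE", bat)
  expect_true(all(vapply(opt, function(s)
    "alcoholic_beverages" %in% s$exclude_groups, logical(1))))
  expect_length(bat[["F.Base"]]$exclude_groups, 0)
  # NAD_P / NAD_E carry the 70% cap on the right resource
  expect_equal(bat[["F.NAD_P"]]$price_cap_fraction, 0.7)
  expect_null(bat[["F.NAD_P"]]$ghge_cap_fraction)
  expect_equal(bat[["F.NAD_E"]]$ghge_cap_fraction, 0.7)
  one_sex <- default_battery("female")
  expect_length(one_sex, 9)
})

test_that("run_battery produces 18 reports, all optimal on a feasible world", {
  gen <- synth_generate(synth_spec(seed = 42))
  res <- run_battery(gen$db, gen$baselines, gen$requirement_sets, seed = 42)
  expect_length(res$reports, 18)
  st <- vapply(res$reports, `[[`, character(1), "status")
  expect_equal(unname(st[grepl("Base", names(st))]), rep("baseline", 2))
  expect_true(all(st[!grepl("Base", names(st))] == "optimal"))
  # cap scenarios respect their caps against the baseline totals
  for (sex in c("female", "male")) {
    p <- if (sex == "female") "F" else "M"
    base <- res$reports[[paste0(p, ".Base")]]$totals
    expect_lte(res$reports[[paste0(p, ".NAD_P")]]$totals$price,
               0.7 * base$price + 1e-6)
    expect_lte(res$reports[[paste0(p, ".NAD_E")]]$totals$ghge,
               0.7 * base$ghge + 1e-6)
    # qualitative emission ordering
    expect_lte(res$reports[[paste0(p, ".Min_E")]]$totals$ghge,
               res$reports[[paste0(p, ".NAD_E")]]$totals$ghge + 1e-9)
    expect_lte(res$reports[[paste0(p, ".NAD_E")]]$totals$ghge,
               base$ghge + 1e-9)
  }
  # excluded alcohol group is zero in every optimised scenario
  for (lab in names(res$reports)[!grepl("Base", names(res$reports))])
    expect_equal(
      unname(group_intake_table(res$reports[[lab]])["alcoholic_beverages"]),
      0)
})

test_that("an unattainable bound isolates to its scenarios only", {
  gen <- synth_generate(synth_spec(seed = 9, feasibility = "infeasible_on",
                                   infeasible_nutrient = "iodine"))
  res <- run_battery(gen$db, gen$baselines, gen$requirement_sets,
                     battery = default_battery("female"), seed = 9)
  st <- vapply(res$reports, `[[`, character(1), "status")
  expect_equal(unname(st["F.Base"]), "baseline")
  expect_true(all(st[!names(st) %in% "F.Base"] == "infeasible"))
  diag <- res$reports[["F.NAD"]]$solution$diagnosis
  expect_true(diag$available)
  expect_true("iodine" %in% diag$nutrients$nutrient_id)
})

test_that("repeated runs with the same seed give identical objectives", {
  gen <- synth_generate(synth_spec(seed = 13))
  bat <- default_battery("male")
  r1 <- run_battery(gen$db, gen$baselines, gen$requirement_sets, bat,
                    seed = 13)
  r2 <- run_battery(gen$db, gen$baselines, gen$requirement_sets, bat,
                    seed = 13)
  o <- function(r) vapply(r$reports, function(x)
    if (!is.null(x$solution)) x$solution$objective_value else NA_real_,
    numeric(1))
  expect_identical(o(r1), o(r2))
})

test_that("percent_change follows the zero-baseline reporting policy", {
  expect_equal(as.numeric(percent_change(98, 573)), 484.6939,
               tolerance = 1e-4)
  expect_equal(as.numeric(percent_change(100, 0)), -100)
  pc <- percent_change(0, 50)
  expect_true(is.na(as.numeric(pc)))
  expect_equal(attr(pc, "status"), "new")
  expect_equal(as.numeric(percent_change(0, 0)), 0)
  expect_error(percent_change(-1, 5), "non-negative")
  v <- percent_change(c(100, 0, 50), c(110, 3, 50))
  expect_equal(attr(v, "status"), c("ok", "new", "ok"))
  expect_equal(as.numeric(v)[c(1, 3)], c(10, 0))
})

test_that("group and nutrient tables partition the diet totals", {
  db <- tiny_db()
  sc <- scenario("X.Base", "female", objective = "BASELINE",
                 exclude_groups = character(0))
  totals <- evaluate_diet(db, c(milk = 7))
  rpt <- dietopt:::scenario_report(sc, "baseline", NULL, totals, NULL)
  git <- group_intake_table(rpt)
  expect_equal(unname(git["dairy"]), 1400)  # 7 x 200 g
  expect_equal(sum(git), 1400)              # all other groups zero
  expect_equal(sort(names(git)), sort(food_groups()))
  nct <- nutrient_contribution_table(rpt, "calcium", db)
  expect_equal(sum(nct), unname(totals$supply["calcium"]))
  expect_equal(unname(nct["grain_foods"]), 0)
  expect_error(nutrient_contribution_table(rpt, "selenium", db), "unknown")

  # a sole fortified iodine source puts 100% of iodine on its group
  gen <- synth_generate(synth_spec(seed = 3, fortified_fraction = 0))
  db2 <- gen$db
  db2$composition[, "iodine"] <- 0
  db2 <- plant_fortified_food(db2, "iodine", 1)  # still zero everywhere
  cereal <- db2$foods$food_id[db2$foods$group == "grain_foods"][1]
  db2$composition[cereal, "iodine"] <- 50
  x <- setNames(rep(1, n_foods(db2)), db2$foods$food_id)
  totals2 <- evaluate_diet(db2, x)
  rep2 <- dietopt:::scenario_report(sc, "baseline", NULL, totals2, NULL)
  nct2 <- nutrient_contribution_table(rep2, "iodine", db2)
  expect_gt(nct2[["grain_foods"]], 0)
  expect_equal(sum(nct2[names(nct2) != "grain_foods"]), 0)
})

test_that("tidy export is a pure function of the result", {
  gen <- synth_generate(synth_spec(seed = 5))
  res <- run_battery(gen$db, gen$baselines, gen$requirement_sets,
                     battery = default_battery("female")[c("F.Base",
                                                           "F.NAD")],
                     seed = 5)
  t1 <- tidy_battery(res)
  t2 <- tidy_battery(res)
  expect_identical(t1, t2)
  expect_setequal(unique(t1$label), c("F.Base", "F.NAD"))
  # decompositions in the tidy table sum to the stored totals
  for (lab in unique(t1$label)) {
    sub <- t1[t1$label == lab, ]
    expect_equal(sum(sub$value[sub$measure == "group_price"]),
                 sub$value[sub$measure == "total" & sub$item == "price"],
                 tolerance = 1e-9)
  }
})
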