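# Compilation arithmetic and the CSV loader.

test_that("average_compositions takes nutrient-wise means with cap and retention", {
  rec <- function(p, ca = NA, must = FALSE)
    list(source_id = paste0("s", p), nutrient_amounts = c(protein = p, calcium = ca),
         protein_per_100g = p, must_retain = must)
  # plain mean over three records
  out <- average_compositions(list(rec(10), rec(12), rec(14)))
  expect_equal(out$nutrient_amounts[["protein"]], 12)
  # single record is returned unchanged (identity on values)
  one <- average_compositions(list(rec(9, ca = 3)))
  expect_equal(one$nutrient_amounts[["protein"]], 9)
  expect_equal(one$nutrient_amounts[["calcium"]], 3)
  expect_equal(one$n_averaged, 1L)
  # cap honoured: 4th unflagged record ignored
  expect_equal(
    average_compositions(list(rec(10), rec(12), rec(14), rec(100)))$
      nutrient_amounts[["protein"]], 12)
  # grouped item: all four must-retain records enter the mean despite cap = 3
  grouped <- lapply(c(8, 10, 12, 14), rec, must = TRUE)
  out4 <- average_compositions(grouped, cap = 3)
  expect_equal(out4$nutrient_amounts[["protein"]], 11)
  expect_equal(out4$n_averaged, 4L)
  # missing values excluded from that nutrient's mean, not treated as 0
  out_na <- average_compositions(list(rec(10, ca = 6), rec(12, ca = NA)))
  expect_equal(out_na$nutrient_amounts[["calcium"]], 6)
  expect_error(average_compositions(list()), "no composition matches")
})

test_that("average_compositions is permutation-invariant and idempotent", {
  set.seed(11)
  recs <- lapply(1:3, function(i)
    list(nutrient_amounts = c(protein = runif(1, 5, 20),
                              iron = runif(1, 0, 5)),
         protein_per_100g = runif(1, 5, 20)))
  base <- average_compositions(recs)
  for (perm in list(c(2, 1, 3), c(3, 2, 1), c(2, 3, 1)))
    expect_equal(average_compositions(recs[perm])$nutrient_amounts[
      names(base$nutrient_amounts)], base$nutrient_amounts)
  again <- average_compositions(list(base))
  expect_equal(again$nutrient_amounts, base$nutrient_amounts)
})

test_that("amino-acid normalisation divides by protein and round-trips", {
  expect_equal(normalise_amino_acids(c(lysine = 8), 100)[["lysine"]], 0.08)
  norm <- normalise_amino_acids(c(lysine = 2.0, leucine = 3.5), 25.0)
  expect_equal(norm[["lysine"]], 0.08)
  expect_equal(norm * 25.0, c(lysine = 2.0, leucine = 3.5))  # round-trip
  expect_equal(normalise_amino_acids(c(lysine = 0, valine = 0), 10),
               c(lysine = 0, valine = 0))
  expect_length(normalise_amino_acids(c(lysine = 0), 0), 0)
  expect_error(normalise_amino_acids(c(lysine = 1), 0), "inconsistent")
  expect_error(normalise_amino_acids(c(lysine = -1), 10), "non-negative")
})

test_that("bioavailability scaling is bounded by the gross amount", {
  expect_equal(apply_bioavailability(10, 0.8), 8)
  expect_equal(apply_bioavailability(10, 1), 10)
  expect_equal(apply_bioavailability(10, 0), 0)
  expect_error(apply_bioavailability(10, 1.2), "\\[0, 1\\]")
  expect_error(apply_bioavailability(-1, 0.5), "non-negative")
  set.seed(3)
  g <- runif(50, 0, 100); k <- runif(50)
  expect_true(all(apply_bioavailability(g, k) <= g))
})

test_that("price averaging converts to per-kg and round-trips", {
  obs <- data.frame(price = c(4, 6), package_mass_g = c(1000, 1000))
  expect_equal(average_price(obs), 5)
  expect_equal(average_price(data.frame(price = 3, package_mass_g = 500)), 6)
  expect_equal(average_price(data.frame(price = c(2, 4, 9),
                                        package_mass_g = 1000)), 5)
  expect_error(average_price(data.frame(price = numeric(0),
                                        package_mass_g = numeric(0))),
               "unpriced")
  # per-kg price recovers each observed package price
  set.seed(5)
  o <- data.frame(price = runif(20, 0.5, 30),
                  package_mass_g = runif(20, 100, 2000))
  per_kg <- o$price / o$package_mass_g * 1000
  expect_equal(per_kg * o$package_mass_g / 1000, o$price, tolerance = 1e-9)
})

test_that("loader round-trips the fixture database and validates joins", {
  dir <- write_tiny_csvs()
  p <- function(f) file.path(dir, f)
  db <- load_food_database(p("compositions.csv"), p("prices.csv"),
                           p("ghge.csv"), p("servings.csv"),
                           nutrients_path = p("nutrients.csv"))
  ref <- tiny_db()
  expect_equal(n_foods(db), 4)
  expect_equal(nrow(db$validation$dropped), 0)
  expect_equal(db$composition, ref$composition)
  expect_equal(db$foods$price_per_kg, ref$foods$price_per_kg)
  expect_equal(db$nutrients, ref$nutrients)

  # a food with no emission factor is dropped and reported
  ghge2 <- read.csv(p("ghge.csv"))
  write.csv(ghge2[ghge2$food_id != "bean", ], p("ghge2.csv"),
            row.names = FALSE)
  db2 <- load_food_database(p("compositions.csv"), p("prices.csv"),
                            p("ghge2.csv"), p("servings.csv"))
  expect_false("bean" %in% db2$foods$food_id)
  expect_equal(db2$validation$dropped$food_id, "bean")
  expect_match(db2$validation$dropped$reason, "ghge")

  # price row for an unknown food id is a join error naming the id
  pr <- read.csv(p("prices.csv"))
  pr$food_id[1] <- "ghost"
  write.csv(pr, p("prices_bad.csv"), row.names = FALSE)
  expect_error(load_food_database(p("compositions.csv"), p("prices_bad.csv"),
                                  p("ghge.csv"), p("servings.csv")),
               "ghost")

  # negative composition value carries row provenance
  comp <- read.csv(p("compositions.csv"), check.names = FALSE)
  comp$protein[2] <- -1
  write.csv(comp, p("comp_bad.csv"), row.names = FALSE)
  expect_error(load_food_database(p("comp_bad.csv"), p("prices.csv"),
                                  p("ghge.csv"), p("servings.csv")),
               "negative composition.*milk")
})

test_that("database JSON serialisation is deterministic and lossless", {
  dir <- withr::local_tempdir()
  db <- tiny_db()
  f1 <- file.path(dir, "a.json"); f2 <- file.path(dir, "b.json")
  write_food_db(db, f1); write_food_db(db, f2)
  expect_identical(readLines(f1), readLines(f2))  # byte-identical
  back <- read_food_db(f1)
  expect_equal(back$composition, db$composition)
  expect_equal(back$bioavailability, db$bioavailability)
  expect_equal(back$foods$price_per_kg, db$foods$price_per_kg)
  expect_equal(back$currency, db$currency)
})

test_that("remove_items drops named foods and nothing else", {
  d <- baseline_diet(c(oat = 3, milk = 2, oyster = 1), "adult female")
  out <- remove_items(d, c("oyster", "mussel"))
  expect_false("oyster" %in% names(out$servings))
  expect_equal(out$servings[c("oat", "milk")], c(oat = 3, milk = 2))
  expect_equal(remove_items(d, character(0))$servings, d$servings)
  none <- remove_items(d, names(d$servings))
  expect_length(none$servings, 0)
})
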