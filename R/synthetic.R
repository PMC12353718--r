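## Seeded synthetic world: a small food database with realistic group-level
## structure (dairy rich in calcium, meat/seafood emission-heavy, grains
## cheap), per-sex baselines, and requirement sets with controlled
## feasibility. Feasibility is guaranteed by construction: a known integer
## diet is planted first and the bounds are derived from its supply, so a
## feasibility certificate exists for every generated instance.

synth_nutrient_panel <- function() {
  data.frame(
    nutrient_id = c("protein", "lysine", "calcium", "iron", "fibre",
                    "iodine", "zinc", "folate", "vitamin_b12", "vitamin_c",
                    "pufa", "sodium", "energy_kj"),
    display_name = c("Protein", "Lysine", "Calcium", "Iron", "Dietary fibre",
                     "Iodine", "Zinc", "Folate", "Vitamin B12", "Vitamin C",
                     "Polyunsaturated fat", "Sodium", "Energy"),
    unit = c("g", "g", "mg", "mg", "g", "ug", "mg", "ug", "ug", "mg",
             "g", "mg", "kJ"),
    bound_kind = c("lower", "lower", "lower", "lower", "lower", "lower",
                   "lower", "lower", "lower", "lower", "lower", "upper",
                   "none"),
    stringsAsFactors = FALSE
  )
}

## per-100 g density means by group x nutrient; rough nutritional archetypes
synth_density_means <- function(nutrient_ids) {
  g <- food_groups()
  base <- c(protein = 3, lysine = 0.2, calcium = 30, iron = 0.8, fibre = 1.5,
            iodine = 5, zinc = 0.5, folate = 20, vitamin_b12 = 0.1,
            vitamin_c = 5, pufa = 0.5, sodium = 80, energy_kj = 600)
  m <- matrix(rep(base[nutrient_ids], each = length(g)),
              nrow = length(g), dimnames = list(g, nutrient_ids))
  bump <- function(group, nutrient, f) {
    n <- intersect(nutrient, colnames(m))
    m[group, n] <<- m[group, n] * f
  }
  bump("dairy", "calcium", 4); bump("dairy", c("protein", "lysine"), 1.3)
  bump("dairy", "vitamin_b12", 4)
  bump("dairy_alternatives", c("calcium", "iodine", "iron"), 3)
  bump("mspe", c("protein", "lysine"), 6); bump("mspe", "iron", 3)
  bump("mspe", c("vitamin_b12", "zinc"), 8)
  bump("legumes_nuts_seeds", c("protein", "lysine"), 4)
  bump("legumes_nuts_seeds", c("fibre", "folate"), 3)
  bump("grain_foods", "fibre", 3); bump("grain_foods", "iron", 2)
  bump("grain_foods", "folate", 2)
  bump("fruits_vegetables", "vitamin_c", 8)
  bump("fruits_vegetables", c("fibre", "folate"), 2)
  bump("fats_oils", "pufa", 40); bump("fats_oils", "energy_kj", 5)
  bump("fats_oils", c("protein", "lysine"), 0.05)
  bump("discretionary", "energy_kj", 2.5); bump("discretionary", "sodium", 2)
  bump("miscellaneous", "sodium", 8); bump("miscellaneous", "iodine", 6)
  bump("non_alcoholic_beverages",
       setdiff(colnames(m), c("vitamin_c", "sodium")), 0.15)
  bump("non_alcoholic_beverages", "vitamin_c", 2)
  bump("alcoholic_beverages", setdiff(colnames(m), "energy_kj"), 0.05)
  m
}

#' Specification for the synthetic-data generator
#'
#' All distribution parameters of the generated world live here; nothing is
#' hard-coded in [synth_generate()]. Defaults emulate, at reduced size, a
#' national food database: eleven food groups, per-100 g compositions,
#' per-kg prices and cradle-to-retail emission factors with log-normal
#' spread and configurable price-emission correlation.
#'
#' @param n_foods_per_group Named integer vector of foods per group.
#' @param n_nutrients Number of nutrients from the built-in panel (protein
#'   first; >= 3).
#' @param seed Integer seed; fixed seed means byte-identical output.
#' @param feasibility `"guaranteed"` (bounds derived from a planted diet),
#'   `"random"` (bounds drawn around the planted supply, may be
#'   infeasible), or `"infeasible_on"` with `infeasible_nutrient` set.
#' @param infeasible_nutrient Nutrient whose lower bound is pushed above the
#'   maximum attainable supply (only with `feasibility = "infeasible_on"`).
#' @param price_ghge_correlation Correlation of log-price and log-emissions
#'   within a food, in `[-1, 1]`.
#' @param density_sdlog,price_sdlog,ghge_sdlog Log-normal spread of nutrient
#'   densities, prices, emission factors.
#' @param fortified_fraction Fraction of (non-alcohol) foods given a single
#'   fortified nutrient.
#' @param fortified_multiplier Density multiplier for fortified foods.
#' @param planted_nonzero_prob,planted_lambda Sparsity and scale of the
#'   planted weekly diet (servings `1 + Poisson(lambda - 1)` with
#'   probability `planted_nonzero_prob`, else 0).
#' @param lower_frac_range RDI bounds are this fraction (uniform draw) of
#'   the planted supply; upper end must stay < 1 / max age factor so the
#'   planted diet always remains a feasibility certificate.
#' @param upper_margin Upper limits sit at this multiple of the planted
#'   supply.
#' @param baseline_inflation Baseline diets are the planted diet times this
#'   integer factor (plus alcohol servings); at 2 a 70% price or emission
#'   cap is always attainable (the planted diet costs <= 50% of baseline).
#' @param baseline_dropout_share Fraction (by planted price and emission
#'   share, each capped at this value) of planted foods omitted from the
#'   baseline. Mirrors real survey baselines: they miss foods the optimiser
#'   later introduces ("new items") and can under-supply nutrients those
#'   foods carry. Must stay below `1 - 1 / (0.7 * baseline_inflation)` so
#'   that the planted diet still costs at most 70% of the baseline (the
#'   feasibility certificate for capped scenarios); with inflation 2 any
#'   value below 0.285 keeps the guarantee.
#' @return A `synth_spec`.
#' @export
synth_spec <- function(n_foods_per_group = c(
                         fruits_vegetables = 4, grain_foods = 4,
                         legumes_nuts_seeds = 3, mspe = 4, dairy = 3,
                         dairy_alternatives = 2, discretionary = 3,
                         fats_oils = 2, miscellaneous = 2,
                         non_alcoholic_beverages = 3,
                         alcoholic_beverages = 2),
                       n_nutrients = 13, seed = 1L,
                       feasibility = c("guaranteed", "random",
                                       "infeasible_on"),
                       infeasible_nutrient = NULL,
                       price_ghge_correlation = 0.3,
                       density_sdlog = 0.4, price_sdlog = 0.35,
                       ghge_sdlog = 0.45,
                       fortified_fraction = 0.1,
                       fortified_multiplier = 10,
                       planted_nonzero_prob = 0.75, planted_lambda = 3,
                       lower_frac_range = c(0.55, 0.8),
                       upper_margin = 3, baseline_inflation = 2L,
                       baseline_dropout_share = 0.2) {
  feasibility <- match.arg(feasibility)
  if (feasibility == "infeasible_on" && is.null(infeasible_nutrient))
    stop("feasibility = 'infeasible_on' requires infeasible_nutrient",
         call. = FALSE)
  if (feasibility != "infeasible_on" && !is.null(infeasible_nutrient))
    stop("contradictory spec: infeasible_nutrient set but feasibility is '",
         feasibility, "'", call. = FALSE)
  stopifnot(all(n_foods_per_group >= 1),
            all(names(n_foods_per_group) %in% food_groups()),
            n_nutrients >= 3, n_nutrients <= nrow(synth_nutrient_panel()),
            abs(price_ghge_correlation) <= 1,
            fortified_fraction >= 0, fortified_fraction <= 1,
            lower_frac_range[1] > 0, lower_frac_range[2] < 0.95,
            upper_margin > 1, baseline_inflation >= 2L,
            baseline_dropout_share >= 0,
            baseline_dropout_share < 1 - 1 / (0.7 * baseline_inflation))
  structure(as.list(environment()), class = "synth_spec")
}

synth_group_params <- function() {
  list(
    serving_g = c(fruits_vegetables = 120, grain_foods = 75,
                  legumes_nuts_seeds = 50, mspe = 120, dairy = 250,
                  dairy_alternatives = 250, discretionary = 60,
                  fats_oils = 12, miscellaneous = 20,
                  non_alcoholic_beverages = 250, alcoholic_beverages = 330),
    price_kg = c(fruits_vegetables = 5, grain_foods = 3,
                 legumes_nuts_seeds = 9, mspe = 16, dairy = 6,
                 dairy_alternatives = 9, discretionary = 8, fats_oils = 7,
                 miscellaneous = 10, non_alcoholic_beverages = 2,
                 alcoholic_beverages = 6),
    ghge_kg = c(fruits_vegetables = 1, grain_foods = 1.2,
                legumes_nuts_seeds = 1.5, mspe = 14, dairy = 3.5,
                dairy_alternatives = 1.2, discretionary = 2.5,
                fats_oils = 3, miscellaneous = 2,
                non_alcoholic_beverages = 0.5, alcoholic_beverages = 1.5)
  )
}

age_factors <- c("19-30" = 1.0, "31-50" = 0.97, "51-69" = 0.94,
                 "70+" = 1.0)

#' Generate a synthetic database, baselines, and requirement sets
#'
#' See [synth_spec()] for the stated world. Returns in-memory objects whose
#' file renderings ([write_synth_files()]) round-trip through
#' [load_food_database()] with an empty drop list.
#'
#' @param spec A `synth_spec`.
#' @return List: `db` (a `food_db`), `baselines` (per-sex `baseline_diet`),
#'   `requirement_sets` (8 sets keyed `"<sex>_<age_group>"`), `planted`
#'   (per-sex named serving vectors — the feasibility certificates),
#'   `price_observations` (store-level price table), `spec`.
#' @export
synth_generate <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  set.seed(spec$seed)
  panel <- synth_nutrient_panel()[seq_len(spec$n_nutrients), , drop = FALSE]
  gp <- synth_group_params()

  groups <- rep(names(spec$n_foods_per_group), spec$n_foods_per_group)
  nf <- length(groups)
  ids <- paste0(abbreviate(groups, 6), "_", unlist(lapply(
    spec$n_foods_per_group, seq_len)))
  dens_mean <- synth_density_means(panel$nutrient_id)

  comp <- matrix(0, nf, nrow(panel), dimnames = list(ids, panel$nutrient_id))
  for (j in seq_len(nrow(panel)))
    comp[, j] <- dens_mean[groups, j] *
      stats::rlnorm(nf, -spec$density_sdlog^2 / 2, spec$density_sdlog)

  ## correlated log-normal price and emission factors
  z1 <- stats::rnorm(nf)
  z2 <- spec$price_ghge_correlation * z1 +
    sqrt(1 - spec$price_ghge_correlation^2) * stats::rnorm(nf)
  price_kg <- gp$price_kg[groups] * exp(spec$price_sdlog * z1 -
                                          spec$price_sdlog^2 / 2)
  ghge_kg <- gp$ghge_kg[groups] * exp(spec$ghge_sdlog * z2 -
                                        spec$ghge_sdlog^2 / 2)
  serving_g <- round(gp$serving_g[groups] * stats::runif(nf, 0.8, 1.2), 1)

  animal <- groups %in% c("mspe", "dairy")
  bio <- matrix(1, nf, length(bioavailable_nutrients()),
                dimnames = list(ids, bioavailable_nutrients()))
  present_bio <- intersect(colnames(bio), panel$nutrient_id)
  for (n in present_bio)
    bio[, n] <- ifelse(animal, stats::runif(nf, 0.85, 0.95),
                       stats::runif(nf, 0.6, 0.85))

  ## fortification: single-nutrient high densities on a few non-alcohol foods
  fortifiable <- which(groups != "alcoholic_beverages")
  n_fort <- floor(spec$fortified_fraction * nf)
  bound_nuts <- panel$nutrient_id[panel$bound_kind %in% c("lower", "both")]
  if (n_fort > 0 && length(bound_nuts)) {
    fidx <- sample(fortifiable, n_fort)
    fnut <- sample(bound_nuts, n_fort, replace = TRUE)
    comp[cbind(fidx, match(fnut, colnames(comp)))] <-
      comp[cbind(fidx, match(fnut, colnames(comp)))] *
      spec$fortified_multiplier
  }

  foods <- data.frame(food_id = ids, name = gsub("_", " ", ids),
                      group = groups, subgroup = paste0(groups, "_general"),
                      serving_size_g = unname(serving_g),
                      ghge_per_kg = unname(ghge_kg),
                      price_per_kg = unname(price_kg),
                      stringsAsFactors = FALSE)
  db <- structure(list(schema_version = 1L, currency = "NZD", foods = foods,
                       composition = comp, bioavailability = bio,
                       nutrients = panel,
                       validation = list(dropped = data.frame(
                         food_id = character(0), reason = character(0),
                         stringsAsFactors = FALSE))),
                  class = "food_db")

  ## store-level price observations whose per-kg mean is price_per_kg
  spread <- stats::runif(nf, 0, 0.1)
  price_observations <- data.frame(
    food_id = rep(ids, each = 2L),
    store_label = rep(c("store_a", "store_b"), nf),
    price = as.vector(rbind(price_kg * (1 + spread),
                            price_kg * (1 - spread))),
    package_mass_g = 1000,
    stringsAsFactors = FALSE
  )
  ## loader averages the two observations; make the db price match exactly
  db$foods$price_per_kg <- vapply(ids, function(id) {
    average_price(price_observations[price_observations$food_id == id, ])
  }, numeric(1), USE.NAMES = FALSE)

  alcohol <- groups == "alcoholic_beverages"
  plant_one <- function(lambda) {
    s <- stats::setNames(rep(0, nf), ids)
    nz <- !alcohol & stats::runif(nf) < spec$planted_nonzero_prob
    s[nz] <- 1 + stats::rpois(sum(nz), max(lambda - 1, 0))
    if (!any(nz)) s[which(!alcohol)[1]] <- lambda  # degenerate-draw guard
    pmin(s, 10)
  }
  planted <- list(female = plant_one(spec$planted_lambda),
                  male = plant_one(spec$planted_lambda + 1))
  ## baseline = inflated planted diet + alcohol, minus a dropout set of
  ## planted foods whose cumulative price AND emission shares stay below
  ## baseline_dropout_share — the baseline misses foods the optimiser may
  ## later (re)introduce, and can be inadequate in what they carried
  ps <- per_serving_price(db)
  gs <- per_serving_ghge(db)
  S <- serving_supply_matrix(db, TRUE)
  baselines <- lapply(names(planted), function(sex) {
    b <- planted[[sex]] * spec$baseline_inflation
    pl <- planted[[sex]]
    tot_p <- sum(ps * pl); tot_g <- sum(gs * pl)
    ## drop concentrated nutrient sources first (specialty items are what
    ## survey baselines typically miss), jittered so seeds differ
    nut_tot <- drop(pl %*% S)
    share_mat <- (pl * S) / rep(pmax(nut_tot, 1e-12), each = length(pl))
    conc <- apply(share_mat, 1L, max)
    cand <- which(pl > 0)
    cand <- cand[order(conc[cand] * stats::runif(length(cand), 0.6, 1),
                       decreasing = TRUE)]
    drop_p <- 0; drop_g <- 0
    for (i in cand) {
      p_i <- ps[i] * pl[i] / tot_p
      g_i <- gs[i] * pl[i] / tot_g
      if (drop_p + p_i < spec$baseline_dropout_share &&
          drop_g + g_i < spec$baseline_dropout_share) {
        b[i] <- 0
        drop_p <- drop_p + p_i; drop_g <- drop_g + g_i
      }
    }
    b[alcohol] <- 1 + stats::rpois(sum(alcohol), 2)
    baseline_diet(b[b > 0], paste("adult", sex), db)
  })
  names(baselines) <- names(planted)

  bound_panel <- panel[panel$bound_kind != "none", , drop = FALSE]
  max_supply <- colSums(200 * S)  # per-food ceiling of the default spec
  requirement_sets <- list()
  for (sex in names(planted)) {
    supply <- drop(planted[[sex]] %*% S)
    for (ag in requirement_age_groups) {
      lo <- up <- rep(NA_real_, nrow(bound_panel))
      for (k in seq_len(nrow(bound_panel))) {
        n <- bound_panel$nutrient_id[k]
        kind <- bound_panel$bound_kind[k]
        if (kind %in% c("lower", "both")) {
          frac <- switch(spec$feasibility,
                         guaranteed = stats::runif(1, spec$lower_frac_range[1],
                                                   spec$lower_frac_range[2]),
                         random = stats::runif(1, 0.6, 1.3),
                         infeasible_on = stats::runif(1,
                                                      spec$lower_frac_range[1],
                                                      spec$lower_frac_range[2]))
          lo[k] <- supply[n] * frac * age_factors[[ag]] / 7
        }
        if (kind %in% c("upper", "both"))
          up[k] <- supply[n] * spec$upper_margin / 7
      }
      if (spec$feasibility == "infeasible_on") {
        j <- match(spec$infeasible_nutrient, bound_panel$nutrient_id)
        if (is.na(j))
          stop("unknown nutrient for infeasible_on: ",
               spec$infeasible_nutrient, call. = FALSE)
        lo[j] <- 1.5 * max_supply[spec$infeasible_nutrient] / 7
        up[j] <- NA_real_
      }
      rs <- requirement_set(sex, ag, data.frame(
        nutrient_id = bound_panel$nutrient_id, daily_lower = lo,
        daily_upper = up, unit = bound_panel$unit,
        stringsAsFactors = FALSE))
      requirement_sets[[demographic_key(sex, ag)]] <- rs
    }
  }

  list(db = db, baselines = baselines,
       requirement_sets = requirement_sets, planted = planted,
       price_observations = price_observations, spec = spec)
}

#' Multiply one food's density for a nutrient (fortification)
#'
#' Emulates a fortified product (e.g. an iodine-fortified breakfast cereal):
#' one food's per-100 g density for the nutrient is multiplied. By default
#' the grain food with the highest current density is fortified; pass
#' `food_id` to choose. A multiplier of 1 is the identity; 0 removes the
#' food as a source of the nutrient.
#'
#' @param db A `food_db`.
#' @param nutrient_id Nutrient to fortify.
#' @param density_multiplier Non-negative multiplier.
#' @param food_id Optional target food id.
#' @return The modified `food_db`.
#' @export
plant_fortified_food <- function(db, nutrient_id, density_multiplier,
                                 food_id = NULL) {
  if (!nutrient_id %in% colnames(db$composition))
    stop("unknown nutrient: ", nutrient_id, call. = FALSE)
  stopifnot(density_multiplier >= 0)
  if (is.null(food_id)) {
    cand <- db$foods$food_id[db$foods$group == "grain_foods"]
    if (!length(cand)) cand <- db$foods$food_id
    food_id <- cand[which.max(db$composition[cand, nutrient_id])]
  }
  if (!food_id %in% rownames(db$composition))
    stop("unknown food: ", food_id, call. = FALSE)
  db$composition[food_id, nutrient_id] <-
    db$composition[food_id, nutrient_id] * density_multiplier
  db
}

#' Write a generated world as the delimited-text input schemas
#'
#' Emits exactly the files [load_food_database()], [load_baseline()] and
#' [read_requirements()] consume, plus a manifest with the seed and MD5
#' hashes. Output is deterministic for a fixed spec.
#'
#' @param gen Output of [synth_generate()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of written paths, invisibly.
#' @export
write_synth_files <- function(gen, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)
  db <- gen$db
  comp <- data.frame(food_id = db$foods$food_id, name = db$foods$name,
                     db$composition, check.names = FALSE,
                     stringsAsFactors = FALSE)
  utils::write.csv(comp, p("compositions.csv"), row.names = FALSE)
  utils::write.csv(gen$price_observations, p("prices.csv"),
                   row.names = FALSE)
  utils::write.csv(data.frame(food_id = db$foods$food_id,
                              kg_co2e_per_kg = db$foods$ghge_per_kg),
                   p("ghge.csv"), row.names = FALSE)
  utils::write.csv(db$foods[, c("food_id", "serving_size_g", "group",
                                "subgroup")],
                   p("servings.csv"), row.names = FALSE)
  utils::write.csv(db$nutrients, p("nutrients.csv"), row.names = FALSE)
  bn <- intersect(colnames(db$bioavailability), colnames(db$composition))
  bdf <- do.call(rbind, lapply(bn, function(n) data.frame(
    food_id = db$foods$food_id, nutrient_id = n,
    coefficient = db$bioavailability[, n], stringsAsFactors = FALSE)))
  utils::write.csv(bdf, p("bioavailability.csv"), row.names = FALSE)
  for (sex in names(gen$baselines)) {
    sv <- gen$baselines[[sex]]$servings
    utils::write.csv(data.frame(food_id = names(sv), weekly_servings = sv),
                     p(paste0("baseline_", sex, ".csv")), row.names = FALSE)
  }
  write_requirements(gen$requirement_sets, p("requirements.json"))
  files <- c(compositions = "compositions.csv", prices = "prices.csv",
             ghge = "ghge.csv", servings = "servings.csv",
             nutrients = "nutrients.csv",
             bioavailability = "bioavailability.csv",
             baseline_female = "baseline_female.csv",
             baseline_male = "baseline_male.csv",
             requirements = "requirements.json")
  manifest <- list(seed = gen$spec$seed,
                   files = lapply(stats::setNames(nm = names(files)),
                                  function(k) list(
                                    path = files[[k]],
                                    md5 = unname(tools::md5sum(p(files[[k]]))))))
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(stats::setNames(vapply(c(files, manifest = "manifest.json"),
                                   p, character(1)),
                            c(names(files), "manifest")))
}

#' Load a world written by [write_synth_files()]
#' @param dir Directory containing the files.
#' @return List with `db`, `baselines`, `requirement_sets`.
#' @export
load_synth_dir <- function(dir) {
  p <- function(f) file.path(dir, f)
  db <- load_food_database(p("compositions.csv"), p("prices.csv"),
                           p("ghge.csv"), p("servings.csv"),
                           nutrients_path = p("nutrients.csv"),
                           bioavailability_path = p("bioavailability.csv"))
  baselines <- list()
  for (sex in c("female", "male")) {
    f <- p(paste0("baseline_", sex, ".csv"))
    if (file.exists(f))
      baselines[[sex]] <- load_baseline(f, db, paste("adult", sex))
  }
  list(db = db, baselines = baselines,
       requirement_sets = read_requirements(p("requirements.json"), db))
}
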