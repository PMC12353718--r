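## Food-database compilation: composition averaging, amino-acid normalisation,
## bioavailability adjustment, price averaging, cross-file loading into a
## validated `food_db` object, and JSON (de)serialisation.

#' Average matched composition records
#'
#' Compiles one composition from a ranked list of matched records: the
#' nutrient-wise arithmetic mean over the first `min(cap, n)` records plus any
#' records flagged must-retain (grouped items such as "onion/garlic/leeks"
#' keep at least one composition per constituent food, even beyond the cap).
#' Missing (`NA`) nutrient values in a record are excluded from that
#' nutrient's mean rather than treated as zero.
#'
#' @param matches List of composition records (each a list with `source_id`,
#'   `nutrient_amounts` named numeric, optional `protein_per_100g`,
#'   `aa_amounts`, and logical `must_retain`), pre-ranked best match first.
#' @param cap Maximum number of top-ranked records to average (default 3).
#' @return A composition record: `source_id` = "average", `nutrient_amounts`
#'   the per-nutrient means, `protein_per_100g` and `aa_amounts` averaged the
#'   same way, and `n_averaged` the number of records used.
#' @export
average_compositions <- function(matches, cap = 3L) {
  if (length(matches) == 0L)
    stop("no composition matches for food: cannot compile an average",
         call. = FALSE)
  stopifnot(cap >= 1L)
  keep <- seq_len(min(cap, length(matches)))
  retain <- which(vapply(matches, function(m) isTRUE(m$must_retain), logical(1)))
  idx <- sort(unique(c(keep, retain)))
  recs <- matches[idx]

  mean_maps <- function(maps) {
    ids <- unique(unlist(lapply(maps, names)))
    if (length(ids) == 0L) return(stats::setNames(numeric(0), character(0)))
    vapply(ids, function(id) {
      vals <- unlist(lapply(maps, function(m) m[[id]]))
      vals <- vals[!is.na(vals)]
      if (length(vals) == 0L) NA_real_ else mean(vals)
    }, numeric(1))
  }
  amounts <- mean_maps(lapply(recs, `[[`, "nutrient_amounts"))
  if (any(amounts < 0, na.rm = TRUE))
    stop("negative nutrient amount in composition record", call. = FALSE)
  prot <- unlist(lapply(recs, function(r) r$protein_per_100g))
  prot <- prot[!is.na(prot)]
  list(
    source_id = "average",
    source_db = "compiled",
    nutrient_amounts = amounts,
    protein_per_100g = if (length(prot)) mean(prot) else NA_real_,
    aa_amounts = mean_maps(lapply(recs, function(r) r$aa_amounts %||% NULL)),
    n_averaged = length(recs)
  )
}

#' Normalise amino-acid amounts to total protein
#'
#' Converts per-100 g amino-acid amounts into grams per gram of protein, the
#' basis on which amino-acid supply scales with any protein content.
#'
#' @param aa_per_100g Named numeric, g amino acid per 100 g food.
#' @param protein_per_100g Total protein, g per 100 g food.
#' @return Named numeric, g amino acid per g protein. Multiplying back by
#'   `protein_per_100g` reconstructs the input.
#' @export
normalise_amino_acids <- function(aa_per_100g, protein_per_100g) {
  if (any(aa_per_100g < 0, na.rm = TRUE))
    stop("amino-acid amounts must be non-negative", call. = FALSE)
  if (protein_per_100g < 0)
    stop("protein content must be non-negative", call. = FALSE)
  if (protein_per_100g == 0) {
    if (any(aa_per_100g > 0, na.rm = TRUE))
      stop("inconsistent record: zero protein but non-zero amino acids",
           call. = FALSE)
    return(stats::setNames(numeric(0), character(0)))
  }
  aa_per_100g / protein_per_100g
}

#' Apply a bioavailability coefficient
#'
#' Scales a gross nutrient amount by a coefficient in `[0, 1]` to obtain the
#' absorbable amount. Used for protein and the essential amino acids.
#'
#' @param gross_amount Gross amount, same unit in and out; must be >= 0.
#' @param coefficient Fraction absorbed, in `[0, 1]`.
#' @return Absorbable amount (always <= gross).
#' @export
apply_bioavailability <- function(gross_amount, coefficient) {
  if (any(coefficient < 0 | coefficient > 1))
    stop("bioavailability coefficient must lie in [0, 1]", call. = FALSE)
  if (any(gross_amount < 0))
    stop("gross amount must be non-negative", call. = FALSE)
  gross_amount * coefficient
}

#' Average store price observations to a per-kilogram price
#'
#' Converts each observation (package price, package mass) to currency per kg
#' and returns the arithmetic mean, the convention when the same item is
#' priced differently across stores.
#'
#' @param observations Data frame with columns `price` (currency per package,
#'   >= 0) and `package_mass_g` (> 0); or a list of such records.
#' @return Mean price, currency per kg.
#' @export
average_price <- function(observations) {
  if (is.list(observations) && !is.data.frame(observations))
    observations <- do.call(rbind, lapply(observations, as.data.frame))
  if (is.null(observations) || nrow(observations) == 0L)
    stop("no price observations: food is unpriced", call. = FALSE)
  if (any(observations$price < 0))
    stop("negative price observation", call. = FALSE)
  if (any(observations$package_mass_g <= 0))
    stop("package mass must be positive", call. = FALSE)
  mean(observations$price / observations$package_mass_g * 1000)
}

read_csv_checked <- function(path, required, file_label) {
  if (!file.exists(path))
    stop_load("input file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                        fileEncoding = "UTF-8")
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop_load(file_label, " is missing column(s): ",
              paste(miss, collapse = ", "), file = path)
  df
}

#' Load and validate a food database from delimited text
#'
#' Joins four (optionally six) CSV inputs into a single validated `food_db`
#' object: per-100 g compositions (one column per nutrient), store price
#' observations, per-kg greenhouse-gas emission factors, and per-food serving
#' size / group / subgroup. Prices are averaged to per-kg with
#' [average_price()]. Foods missing a price, emission factor or serving entry
#' are dropped and listed in the validation report; rows in auxiliary files
#' that name unknown foods are an error (a join must not silently invent
#' foods).
#'
#' @param composition_path CSV: `food_id`, `name` (optional), then one numeric
#'   column per nutrient id.
#' @param prices_path CSV: `food_id`, `store_label`, `price`,
#'   `package_mass_g`.
#' @param ghge_path CSV: `food_id`, `kg_co2e_per_kg`.
#' @param servings_path CSV: `food_id`, `serving_size_g`, `group`, `subgroup`.
#' @param nutrients_path Optional CSV: `nutrient_id`, `display_name`, `unit`,
#'   `bound_kind`; defaults assign unit `"g"` and bound kind `"both"`.
#' @param bioavailability_path Optional CSV: `food_id`, `nutrient_id`,
#'   `coefficient` for protein/essential-amino-acid coefficients (default 1).
#' @param currency Currency label carried through reports (default `"NZD"`).
#' @return A `food_db` object: `foods` data frame, `composition` matrix
#'   (foods x nutrients, per 100 g), `bioavailability` matrix, `nutrients`
#'   definition table, and `validation` report (`dropped` data frame).
#' @export
load_food_database <- function(composition_path, prices_path, ghge_path,
                               servings_path, nutrients_path = NULL,
                               bioavailability_path = NULL,
                               currency = "NZD") {
  comp <- read_csv_checked(composition_path, "food_id", "composition table")
  if (anyDuplicated(comp$food_id))
    stop_load("duplicate food_id in composition table: ",
              paste(unique(comp$food_id[duplicated(comp$food_id)]),
                    collapse = ", "), file = composition_path)
  nutr_cols <- setdiff(names(comp), c("food_id", "name"))
  if (length(nutr_cols) == 0L)
    stop_load("composition table has no nutrient columns",
              file = composition_path)
  comp_m <- as.matrix(comp[, nutr_cols, drop = FALSE])
  storage.mode(comp_m) <- "double"
  rownames(comp_m) <- comp$food_id
  if (any(comp_m < 0, na.rm = TRUE)) {
    bad <- which(apply(comp_m < 0, 1L, any, na.rm = TRUE))
    stop_load("negative composition value", row = comp$food_id[bad],
              file = composition_path)
  }
  comp_m[is.na(comp_m)] <- 0

  prices <- read_csv_checked(prices_path,
                             c("food_id", "store_label", "price",
                               "package_mass_g"), "price table")
  unknown <- setdiff(prices$food_id, comp$food_id)
  if (length(unknown))
    stop_load("price table names food id(s) absent from compositions: ",
              paste(unique(unknown), collapse = ", "), file = prices_path)
  if (any(prices$price < 0))
    stop_load("negative price", row = prices$food_id[prices$price < 0],
              file = prices_path)
  if (any(prices$package_mass_g <= 0))
    stop_load("non-positive package mass",
              row = prices$food_id[prices$package_mass_g <= 0],
              file = prices_path)

  ghge <- read_csv_checked(ghge_path, c("food_id", "kg_co2e_per_kg"),
                           "emission table")
  unknown <- setdiff(ghge$food_id, comp$food_id)
  if (length(unknown))
    stop_load("emission table names food id(s) absent from compositions: ",
              paste(unique(unknown), collapse = ", "), file = ghge_path)
  if (anyDuplicated(ghge$food_id))
    stop_load("duplicate food_id in emission table", file = ghge_path)
  if (any(ghge$kg_co2e_per_kg < 0))
    stop_load("negative emission factor",
              row = ghge$food_id[ghge$kg_co2e_per_kg < 0], file = ghge_path)

  serv <- read_csv_checked(servings_path,
                           c("food_id", "serving_size_g", "group", "subgroup"),
                           "serving table")
  unknown <- setdiff(serv$food_id, comp$food_id)
  if (length(unknown))
    stop_load("serving table names food id(s) absent from compositions: ",
              paste(unique(unknown), collapse = ", "), file = servings_path)
  if (anyDuplicated(serv$food_id))
    stop_load("duplicate food_id in serving table", file = servings_path)
  if (any(serv$serving_size_g <= 0))
    stop_load("serving size must be positive",
              row = serv$food_id[serv$serving_size_g <= 0],
              file = servings_path)
  badg <- !(serv$group %in% food_groups())
  if (any(badg))
    stop_load("unknown food group(s): ",
              paste(unique(serv$group[badg]), collapse = ", "),
              file = servings_path)

  if (!is.null(nutrients_path)) {
    ndef <- read_csv_checked(nutrients_path,
                             c("nutrient_id", "display_name", "unit",
                               "bound_kind"), "nutrient definition table")
    if (anyDuplicated(ndef$nutrient_id))
      stop_load("duplicate nutrient_id", file = nutrients_path)
    ndef$unit <- normalise_unit(ndef$unit)
    if (!all(ndef$bound_kind %in% c("lower", "upper", "both", "none")))
      stop_load("bound_kind must be one of lower/upper/both/none",
                file = nutrients_path)
    miss <- setdiff(nutr_cols, ndef$nutrient_id)
    if (length(miss))
      stop_load("nutrient definition table missing nutrient(s): ",
                paste(miss, collapse = ", "), file = nutrients_path)
    ndef <- ndef[match(nutr_cols, ndef$nutrient_id), , drop = FALSE]
  } else {
    ndef <- data.frame(nutrient_id = nutr_cols, display_name = nutr_cols,
                       unit = "g", bound_kind = "both",
                       stringsAsFactors = FALSE)
  }
  rownames(ndef) <- NULL

  ## assemble per-food rows, dropping foods with incomplete auxiliary data
  priced_ids <- unique(prices$food_id)
  dropped <- data.frame(food_id = character(0), reason = character(0),
                        stringsAsFactors = FALSE)
  note_drop <- function(ids, why) {
    if (length(ids))
      dropped <<- rbind(dropped, data.frame(food_id = ids, reason = why,
                                            stringsAsFactors = FALSE))
  }
  note_drop(setdiff(comp$food_id, priced_ids), "missing price")
  note_drop(setdiff(comp$food_id, ghge$food_id), "missing ghge")
  note_drop(setdiff(comp$food_id, serv$food_id), "missing serving data")
  keep_ids <- setdiff(comp$food_id, dropped$food_id)
  if (length(keep_ids) == 0L)
    stop_load("no food survives validation: all dropped")

  price_per_kg <- vapply(keep_ids, function(id) {
    average_price(prices[prices$food_id == id, , drop = FALSE])
  }, numeric(1))

  si <- match(keep_ids, serv$food_id)
  gi <- match(keep_ids, ghge$food_id)
  foods <- data.frame(
    food_id = keep_ids,
    name = if ("name" %in% names(comp)) comp$name[match(keep_ids, comp$food_id)] else keep_ids,
    group = serv$group[si],
    subgroup = serv$subgroup[si],
    serving_size_g = serv$serving_size_g[si],
    ghge_per_kg = ghge$kg_co2e_per_kg[gi],
    price_per_kg = unname(price_per_kg),
    stringsAsFactors = FALSE
  )
  rownames(foods) <- NULL

  bio <- matrix(1, nrow = length(keep_ids),
                ncol = length(bioavailable_nutrients()),
                dimnames = list(keep_ids, bioavailable_nutrients()))
  if (!is.null(bioavailability_path)) {
    bdf <- read_csv_checked(bioavailability_path,
                            c("food_id", "nutrient_id", "coefficient"),
                            "bioavailability table")
    unknown <- setdiff(bdf$food_id, comp$food_id)
    if (length(unknown))
      stop_load("bioavailability table names unknown food id(s): ",
                paste(unique(unknown), collapse = ", "),
                file = bioavailability_path)
    badn <- !(bdf$nutrient_id %in% bioavailable_nutrients())
    if (any(badn))
      stop_load("bioavailability applies only to protein/essential amino ",
                "acids; got: ",
                paste(unique(bdf$nutrient_id[badn]), collapse = ", "),
                file = bioavailability_path)
    if (any(bdf$coefficient < 0 | bdf$coefficient > 1))
      stop_load("bioavailability coefficient outside [0, 1]",
                file = bioavailability_path)
    bdf <- bdf[bdf$food_id %in% keep_ids, , drop = FALSE]
    bio[cbind(bdf$food_id, bdf$nutrient_id)] <- bdf$coefficient
  }

  db <- structure(list(
    schema_version = 1L,
    currency = currency,
    foods = foods,
    composition = comp_m[keep_ids, , drop = FALSE],
    bioavailability = bio,
    nutrients = ndef,
    validation = list(dropped = dropped)
  ), class = "food_db")
  db
}

#' @export
print.food_db <- function(x, ...) {
  cat(sprintf("<food_db> %d foods, %d nutrients, %d groups, currency %s\n",
              nrow(x$foods), ncol(x$composition),
              length(unique(x$foods$group)), x$currency))
  if (nrow(x$validation$dropped))
    cat(sprintf("  %d food(s) dropped during validation\n",
                nrow(x$validation$dropped)))
  invisible(x)
}

#' Number of foods in a database
#' @param db A `food_db`.
#' @return Integer count.
#' @export
n_foods <- function(db) nrow(db$foods)

#' Serialise a food database to JSON
#'
#' Writes a schema-versioned JSON document that [read_food_db()] restores
#' exactly. Serialisation is deterministic: identical databases yield
#' byte-identical files.
#'
#' @param db A `food_db`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_food_db <- function(db, path) {
  doc <- list(
    schema_version = db$schema_version,
    currency = db$currency,
    foods = db$foods,
    nutrient_ids = colnames(db$composition),
    composition = apply(db$composition, 1L, function(r) as.list(r),
                        simplify = FALSE),
    bioavailability = apply(db$bioavailability, 1L, function(r) as.list(r),
                            simplify = FALSE),
    nutrients = db$nutrients,
    dropped = db$validation$dropped
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a food database serialised by [write_food_db()]
#' @param path JSON path.
#' @return A `food_db`.
#' @export
read_food_db <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  ids <- doc$foods$food_id
  nut <- doc$nutrient_ids
  comp <- t(vapply(ids, function(id) unlist(doc$composition[[id]])[nut],
                   numeric(length(nut))))
  dimnames(comp) <- list(ids, nut)
  bn <- bioavailable_nutrients()
  bio <- t(vapply(ids, function(id) {
    v <- unlist(doc$bioavailability[[id]])
    out <- stats::setNames(rep(1, length(bn)), bn)
    out[intersect(names(v), bn)] <- v[intersect(names(v), bn)]
    out
  }, numeric(length(bn))))
  dimnames(bio) <- list(ids, bn)
  dropped <- doc$dropped
  if (length(dropped) == 0L)
    dropped <- data.frame(food_id = character(0), reason = character(0),
                          stringsAsFactors = FALSE)
  structure(list(
    schema_version = doc$schema_version,
    currency = doc$currency,
    foods = doc$foods,
    composition = comp,
    bioavailability = bio,
    nutrients = doc$nutrients,
    validation = list(dropped = dropped)
  ), class = "food_db")
}

#' Construct a baseline diet
#'
#' @param servings Named numeric vector: weekly serving counts per food id
#'   (fractional counts are accepted in input data).
#' @param demographic_label Free-text demographic tag, e.g. `"adult female"`.
#' @param db Optional `food_db`; when given, every food id must resolve.
#' @return A `baseline_diet`.
#' @export
baseline_diet <- function(servings, demographic_label = "", db = NULL) {
  if (any(servings < 0))
    stop("baseline serving counts must be non-negative", call. = FALSE)
  if (!is.null(db)) {
    unknown <- setdiff(names(servings), db$foods$food_id)
    if (length(unknown))
      stop("baseline names food id(s) absent from the database: ",
           paste(unknown, collapse = ", "), call. = FALSE)
  }
  structure(list(demographic_label = demographic_label,
                 servings = servings), class = "baseline_diet")
}

#' Load a baseline diet from CSV
#'
#' @param path CSV with columns `food_id`, `weekly_servings`.
#' @param db Optional `food_db` used to validate food ids.
#' @param demographic_label Demographic tag for the returned diet.
#' @return A `baseline_diet`.
#' @export
load_baseline <- function(path, db = NULL, demographic_label = "") {
  df <- read_csv_checked(path, c("food_id", "weekly_servings"),
                         "baseline table")
  if (anyDuplicated(df$food_id))
    stop_load("duplicate food_id in baseline", file = path)
  baseline_diet(stats::setNames(df$weekly_servings, df$food_id),
                demographic_label, db)
}

#' Remove named foods from a baseline diet
#'
#' Used to drop rarely consumed contaminant-monitoring items (shellfish,
#' offal) from survey-derived baselines. Names not present are ignored and
#' reported via a message.
#'
#' @param diet A `baseline_diet`.
#' @param names Character vector of food ids to remove.
#' @return The diet without the named entries.
#' @export
remove_items <- function(diet, names) {
  stopifnot(inherits(diet, "baseline_diet"))
  absent <- setdiff(names, names(diet$servings))
  if (length(absent))
    message("remove_items: not present, ignored: ",
            paste(absent, collapse = ", "))
  diet$servings <- diet$servings[!(names(diet$servings) %in% names)]
  diet
}
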