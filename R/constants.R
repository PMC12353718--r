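#' @keywords internal
"_PACKAGE"

## Closed vocabularies shared across the package. Food groups follow the
## eleven-group taxonomy used for New Zealand-style diet modelling; units are
## the per-100 g basis of composition tables.

#' Food group taxonomy
#'
#' The closed set of food-group identifiers recognised by the database
#' loader and the scenario reports. `mspe` is meat, seafood, poultry and eggs.
#'
#' @return Character vector of the eleven group identifiers.
#' @export
food_groups <- function() {
  c("fruits_vegetables", "grain_foods", "legumes_nuts_seeds", "mspe",
    "dairy", "dairy_alternatives", "discretionary", "fats_oils",
    "miscellaneous", "non_alcoholic_beverages", "alcoholic_beverages")
}

#' Nutrient units
#'
#' Closed set of units for per-100 g nutrient amounts. Micrograms are stored
#' ASCII-safe as `"ug"`; the readers normalise `"µg"` and `"μg"`.
#'
#' @return Character vector of permitted unit labels.
#' @export
nutrient_units <- function() c("g", "mg", "ug", "kJ")

#' Essential amino acid identifiers
#'
#' Identifiers for the nine essential amino acids. Together with `"protein"`
#' these are the nutrients to which bioavailability coefficients apply.
#'
#' @return Character vector of amino-acid identifiers.
#' @export
essential_amino_acids <- function() {
  c("histidine", "isoleucine", "leucine", "lysine", "methionine",
    "phenylalanine", "threonine", "tryptophan", "valine")
}

#' Nutrients subject to bioavailability adjustment
#'
#' Protein and the essential amino acids: for these, the requirement bounds
#' apply to the absorbable (coefficient-adjusted) supply. All other nutrients
#' are constrained on gross amounts.
#'
#' @return Character vector of nutrient identifiers.
#' @export
bioavailable_nutrients <- function() c("protein", essential_amino_acids())

normalise_unit <- function(u) {
  u <- trimws(u)
  u[u %in% c("µg", "μg", "mcg")] <- "ug"
  bad <- !(u %in% nutrient_units())
  if (any(bad)) {
    stop("unknown nutrient unit(s): ", paste(unique(u[bad]), collapse = ", "),
         " (permitted: ", paste(nutrient_units(), collapse = ", "), ")",
         call. = FALSE)
  }
  u
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_load <- function(..., row = NULL, file = NULL) {
  msg <- paste0(...)
  if (!is.null(file)) msg <- paste0(msg, " [file: ", file, "]")
  if (!is.null(row)) msg <- paste0(msg, " [row: ", paste(row, collapse = ","), "]")
  stop(msg, call. = FALSE)
}
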