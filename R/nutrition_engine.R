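nutrients <- function() c("calorie", "carbohydrate", "protein", "fat")

nutrient_unit <- function(nutrient) {
  ifelse(nutrient == "calorie", "Gcal/ha/yr", "kg/ha/yr")
}

gamma_column <- function(nutrient) {
  c(calorie = "gamma_calorie", carbohydrate = "gamma_carb",
    protein = "gamma_protein", fat = "gamma_fat")[nutrient]
}

#' Forage end-use scenarios
#'
#' Crops not directly edible by humans (ley, ryegrass, forage rape, silage
#' maize) reach human nutrition only through an end use. Three scenarios
#' are supported: forage fed to dairy cows (milk), to beef cattle
#' (boneless meat), or used for biofuel / industrial products (no human
#' food output at all). The default conversion rates are 1.05 l of whole
#' milk or 0.047 kg of boneless beef per kg of forage dry-matter intake;
#' the product composition values are replaceable defaults from public
#' food-composition sources.
#'
#' @param name One of `"milk"`, `"beef"`, `"biofuel"`.
#' @param dm_to_product Units of retail product (l milk, kg beef) per kg
#'   of dry-matter intake; `>= 0`.
#' @param product_profile List with `f_h2o`, `f_ref` and `gamma` (named
#'   vector over calorie/carbohydrate/protein/fat, per unit product; Gcal
#'   for calories, kg otherwise). The product quantity is already on the
#'   as-consumed retail basis, so only `f_ref` and `gamma` enter the
#'   output; `f_h2o` is carried for reference.
#' @return An object of class `forage_scenario`.
#' @export
forage_scenario <- function(name, dm_to_product, product_profile) {
  stopifnot(is.character(name), length(name) == 1, dm_to_product >= 0)
  stopifnot(all(c("f_ref", "gamma") %in% names(product_profile)))
  stopifnot(all(nutrients() %in% names(product_profile$gamma)))
  if (name == "biofuel" &&
      (dm_to_product * sum(product_profile$gamma)) != 0) {
    stop("biofuel scenario must yield exactly 0 for all nutrients",
         call. = FALSE)
  }
  structure(list(name = name, dm_to_product = dm_to_product,
                 product_profile = product_profile),
            class = "forage_scenario")
}

#' @rdname forage_scenario
#' @export
default_forage_scenarios <- function() {
  zero_gamma <- c(calorie = 0, carbohydrate = 0, protein = 0, fat = 0)
  list(
    milk = forage_scenario(
      "milk", dm_to_product = 1.05,
      product_profile = list(
        f_h2o = 0.88, f_ref = 1,
        gamma = c(calorie = 0.00063, carbohydrate = 0.047,
                  protein = 0.033, fat = 0.036))),
    beef = forage_scenario(
      "beef", dm_to_product = 0.047,
      product_profile = list(
        f_h2o = 0.62, f_ref = 1,
        gamma = c(calorie = 0.00211, carbohydrate = 0,
                  protein = 0.190, fat = 0.150))),
    biofuel = forage_scenario(
      "biofuel", dm_to_product = 0,
      product_profile = list(f_h2o = 0, f_ref = 1, gamma = zero_gamma))
  )
}

#' Nutritional output of a food crop
#'
#' Food-balance conversion of a crop's dry yield into human-available
#' calories or a macronutrient:
#' \deqn{M = Y \, (1 - f_{H_2O})^{-1} \, \alpha \, f_{ref} \, \gamma_n,}
#' where \eqn{Y} is the dry yield (kg ha-1 yr-1), \eqn{f_{H_2O}} the water
#' fraction of the retail product, \eqn{\alpha} the crop-to-retail factor,
#' \eqn{f_{ref}} the refuse factor and \eqn{\gamma_n} the nutrient
#' conversion rate of the retail product. Calories come out in
#' Gcal ha-1 yr-1, macronutrients in kg ha-1 yr-1.
#'
#' @param yield_dry Dry yield (kg ha-1 yr-1), `>= 0`.
#' @param profile One row of a crop catalog (list or single-row data
#'   frame) for an edible, non-forage crop.
#' @param nutrient One of `"calorie"`, `"carbohydrate"`, `"protein"`,
#'   `"fat"`.
#' @return Output `M` with its unit in attribute `"unit"`.
#' @export
crop_output <- function(yield_dry, profile, nutrient) {
  nutrient <- match.arg(nutrient, nutrients())
  if (isTRUE(profile$forage_only)) {
    stop("crop ", profile$crop_name %||% "<unnamed>",
         " is forage-only; use forage_output() with an end-use scenario",
         call. = FALSE)
  }
  if (!isTRUE(profile$edible)) {
    stop("crop ", profile$crop_name %||% "<unnamed>",
         " is not edible; no direct food conversion is defined", call. = FALSE)
  }
  gamma <- profile[[gamma_column(nutrient)]]
  m <- yield_dry / (1 - profile$f_h2o) * profile$alpha * profile$f_ref * gamma
  structure(m, unit = unname(nutrient_unit(nutrient)))
}

#' Nutritional output of a forage crop under an end-use scenario
#'
#' The crop's dry yield is taken as the dry-matter intake; the scenario
#' converts it into retail product (l milk or kg boneless beef per kg DM)
#' and the product's refuse factor and nutrient rates give the
#' human-available output. The biofuel scenario returns exactly 0.
#'
#' @param yield_dry_dm Forage dry matter (kg ha-1 yr-1).
#' @param scenario A [forage_scenario()].
#' @inheritParams crop_output
#' @return Output `M` with unit attribute, as in [crop_output()].
#' @export
forage_output <- function(yield_dry_dm, scenario, nutrient) {
  nutrient <- match.arg(nutrient, nutrients())
  stopifnot(inherits(scenario, "forage_scenario"))
  product <- yield_dry_dm * scenario$dm_to_product
  m <- product * scenario$product_profile$f_ref *
    scenario$product_profile$gamma[[nutrient]]
  structure(m, unit = unname(nutrient_unit(nutrient)))
}

#' Whole-rotation annual output
#'
#' Area-weighted sum of the per-crop outputs of one site x year x rotation
#' x group cell: \eqn{O_n = \sum_c M_{n,c} F_{A,c}} with
#' \eqn{F_{A,c} = (\mathrm{years\ of\ } c)/(\mathrm{rotation\ length})}.
#' Fallow years contribute zero.
#'
#' @param crop_m Numeric vector of per-crop outputs `M` (one entry per
#'   rotation-year or per distinct crop).
#' @param weights Area fractions, summing to 1.
#' @return The whole-rotation output `O`.
#' @export
rotation_output <- function(crop_m, weights) {
  if (length(crop_m) != length(weights)) {
    stop("crop outputs and weights differ in length", call. = FALSE)
  }
  if (abs(sum(weights) - 1) > 1e-8) {
    stop("area fractions must sum to 1", call. = FALSE)
  }
  sum(crop_m * weights)
}

#' Build the whole-rotation output table
#'
#' Converts a QC'd yield table into one output row per site x calendar
#' year x rotation x group x nutrient for a chosen forage end-use
#' scenario. Records flagged `excluded` drop the whole cell; any other
#' cell missing a crop of its rotation is an error, because the
#' experiments modelled here grow every crop of every rotation in every
#' season. A crop's end use is taken from the rotation catalog's `use`
#' column when given, else from the crop catalog's `forage_only` flag.
#'
#' @param yield_table QC'd yield table (needs `yield_dry` and `qc_flag`;
#'   run [qc_yields()] first, or pass a clean table and it is flagged on
#'   the fly).
#' @param crop_catalog Crop conversion catalog ([read_crop_catalog()]).
#' @param rotation_catalog Rotation catalog ([rotation_catalog()]).
#' @param scenario A [forage_scenario()] or a name in
#'   [default_forage_scenarios()].
#' @param nutrients_wanted Subset of the four nutrients.
#' @return A tibble with columns `site`, `calendar_year`,
#'   `time_since_start`, `rotation_id`, `fr`, `group`, `scenario`,
#'   `nutrient`, `output`, `unit`. Attribute `n_cells_excluded` reports
#'   how many cells QC removed.
#' @export
build_output_table <- function(yield_table, crop_catalog, rotation_catalog,
                               scenario = "milk",
                               nutrients_wanted = nutrients()) {
  if (is.character(scenario)) {
    scenario <- default_forage_scenarios()[[match.arg(scenario,
                                                      c("milk", "beef", "biofuel"))]]
  }
  stopifnot(inherits(scenario, "forage_scenario"))
  nutrients_wanted <- match.arg(nutrients_wanted, nutrients(),
                                several.ok = TRUE)
  tab <- yield_table
  if (!"qc_flag" %in% names(tab)) tab <- initial_flags(tab)
  if (!"yield_dry" %in% names(tab)) {
    tab$yield_dry <- to_dry_weight(tab$yield, tab$water_content)
  }
  unknown <- setdiff(unique(tab$crop), crop_catalog$crop_name)
  if (length(unknown) > 0) {
    stop("unknown crop(s) in yield table: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }

  # rotation structure: occupancy weight and end use per distinct crop
  rot <- validate_rotation_catalog(rotation_catalog, crop_catalog)
  rot_len <- tapply(rot$year_index, rot$rotation_id, length)
  rot_crops <- dplyr::summarise(
    dplyr::group_by(rot, .data$rotation_id, .data$crop_name),
    n_years = dplyr::n(),
    use = {
      u <- unique(.data$use[!is.na(.data$use)])
      if (length(u) > 1) {
        stop("crop ", .data$crop_name[1], " has conflicting uses within rotation ",
             .data$rotation_id[1], call. = FALSE)
      }
      if (length(u) == 1) u else NA_character_
    },
    .groups = "drop"
  )
  rot_crops$weight <- rot_crops$n_years /
    as.numeric(rot_len[rot_crops$rotation_id])

  cat_idx <- match(rot_crops$crop_name, crop_catalog$crop_name)
  rot_crops$functional_type <- crop_catalog$functional_type[cat_idx]
  rot_crops$is_forage <- ifelse(is.na(rot_crops$use),
                                crop_catalog$forage_only[cat_idx],
                                rot_crops$use == "forage")
  rot_crops$is_fallow <- rot_crops$functional_type == "fallow"

  # drop excluded cells, then check completeness of the rest
  cell_key <- paste(tab$site, tab$calendar_year, tab$rotation_id, tab$group,
                    sep = "\r")
  excluded <- unique(cell_key[tab$qc_flag == "excluded"])
  keep <- !(cell_key %in% excluded)
  tab <- tab[keep, , drop = FALSE]

  tab <- dplyr::inner_join(
    tab,
    dplyr::rename(rot_crops, crop = "crop_name"),
    by = c("rotation_id", "crop")
  )
  cell_cols <- c("site", "calendar_year", "time_since_start",
                 "rotation_id", "group")
  if ("fr" %in% names(tab)) cell_cols <- append(cell_cols, "fr", after = 4)
  n_crops_expected <- tapply(rot_crops$crop_name, rot_crops$rotation_id, length)
  counts <- dplyr::summarise(dplyr::group_by(tab, dplyr::across(dplyr::all_of(cell_cols))),
                             n_crops = dplyr::n(), .groups = "drop")
  short <- counts[counts$n_crops <
                    as.numeric(n_crops_expected[counts$rotation_id]), , drop = FALSE]
  if (nrow(short) > 0) {
    ex <- short[1, ]
    stop("rotation ", ex$rotation_id, " at site ", ex$site, ", year ",
         ex$calendar_year, ", group ", ex$group, " is missing ",
         "crop records; every crop of a non-excluded rotation must be ",
         "present every season", call. = FALSE)
  }
  if (any(is.na(tab$yield_dry) & !tab$is_fallow)) {
    stop("missing dry yields in non-excluded cells; run qc_yields() first",
         call. = FALSE)
  }

  out <- lapply(nutrients_wanted, function(n) {
    gam <- crop_catalog[[gamma_column(n)]][match(tab$crop, crop_catalog$crop_name)]
    fh <- crop_catalog$f_h2o[match(tab$crop, crop_catalog$crop_name)]
    al <- crop_catalog$alpha[match(tab$crop, crop_catalog$crop_name)]
    fr_ <- crop_catalog$f_ref[match(tab$crop, crop_catalog$crop_name)]
    m <- ifelse(
      tab$is_fallow, 0,
      ifelse(tab$is_forage,
             tab$yield_dry * scenario$dm_to_product *
               scenario$product_profile$f_ref *
               scenario$product_profile$gamma[[n]],
             tab$yield_dry / (1 - fh) * al * fr_ * gam))
    d <- tab[, cell_cols]
    d$m_weighted <- m * tab$weight
    agg <- dplyr::summarise(dplyr::group_by(d, dplyr::across(dplyr::all_of(cell_cols))),
                            output = sum(.data$m_weighted), .groups = "drop")
    agg$scenario <- scenario$name
    agg$nutrient <- n
    agg$unit <- unname(nutrient_unit(n))
    agg
  })
  res <- dplyr::arrange(dplyr::bind_rows(out), .data$nutrient, .data$site,
                        .data$calendar_year, .data$rotation_id, .data$group)
  attr(res, "n_cells_excluded") <- length(excluded)
  attr(res, "time_scaling") <- max(res$time_since_start)
  res
}
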