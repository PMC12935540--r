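#' Read a crop conversion catalog
#'
#' The crop catalog maps each crop to its functional type and to the
#' food-balance conversion factors used to turn dry yield into
#' human-available calories and macronutrients: the water fraction of the
#' retail product (`f_h2o`), the crop-to-retail factor (`alpha`, kg retail
#' product per kg yield), the refuse factor (`f_ref`, edible fraction of the
#' retail product) and the nutrient conversion rates (`gamma_calorie` in
#' Gcal per kg product, `gamma_carb`/`gamma_protein`/`gamma_fat` in kg per
#' kg product).
#'
#' Forage-only crops (ley, ryegrass, forage rape, silage maize) carry no
#' conversion factors of their own; their output is determined by the
#' forage end-use scenario (see [forage_scenario()]).
#'
#' @param path Path to a CSV file with columns `crop_name`,
#'   `functional_type`, `edible`, `forage_only`, `f_h2o`, `alpha`, `f_ref`,
#'   `gamma_calorie`, `gamma_carb`, `gamma_protein`, `gamma_fat`,
#'   `retail_product`. Defaults to the catalog shipped with the package,
#'   whose factor values are replaceable defaults drawn from public
#'   food-composition sources.
#' @return A tibble with one row per crop, validated.
#' @export
read_crop_catalog <- function(path = system.file("extdata", "crop_catalog_default.csv",
                                                 package = "rotanutri")) {
  if (!file.exists(path)) {
    stop("crop catalog file not found: ", path, call. = FALSE)
  }
  cat_cols <- readr::cols(
    crop_name = readr::col_character(),
    functional_type = readr::col_character(),
    edible = readr::col_logical(),
    forage_only = readr::col_logical(),
    f_h2o = readr::col_double(),
    alpha = readr::col_double(),
    f_ref = readr::col_double(),
    gamma_calorie = readr::col_double(),
    gamma_carb = readr::col_double(),
    gamma_protein = readr::col_double(),
    gamma_fat = readr::col_double(),
    retail_product = readr::col_character()
  )
  catalog <- readr::read_csv(path, col_types = cat_cols, progress = FALSE)
  validate_crop_catalog(catalog, path)
  attr(catalog, "catalog_path") <- path
  catalog
}

functional_types <- function() {
  c("cereal", "annual_legume", "annual_broadleaf", "ley", "fallow")
}

#' @rdname read_crop_catalog
#' @param catalog A data frame to validate against the catalog schema.
#' @param path Label used in error messages.
#' @export
validate_crop_catalog <- function(catalog, path = "<in-memory>") {
  needed <- c("crop_name", "functional_type", "edible", "forage_only",
              "f_h2o", "alpha", "f_ref",
              "gamma_calorie", "gamma_carb", "gamma_protein", "gamma_fat")
  missing_cols <- setdiff(needed, names(catalog))
  if (length(missing_cols) > 0) {
    stop("crop catalog ", path, " lacks columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(catalog$crop_name)) {
    stop("crop catalog ", path, " has duplicated crop names", call. = FALSE)
  }
  bad_type <- setdiff(unique(catalog$functional_type), functional_types())
  if (length(bad_type) > 0) {
    stop("unknown functional type(s) in ", path, ": ",
         paste(bad_type, collapse = ", "), call. = FALSE)
  }
  conv <- catalog[!catalog$forage_only & catalog$edible, , drop = FALSE]
  if (any(conv$f_h2o < 0 | conv$f_h2o >= 1, na.rm = TRUE)) {
    stop("f_h2o must lie in [0, 1) for edible crops (", path, ")", call. = FALSE)
  }
  if (any(conv$alpha < 0, na.rm = TRUE)) {
    stop("alpha must be >= 0 (", path, ")", call. = FALSE)
  }
  if (any(conv$f_ref < 0 | conv$f_ref > 1, na.rm = TRUE)) {
    stop("f_ref must lie in [0, 1] (", path, ")", call. = FALSE)
  }
  gam <- as.matrix(conv[, c("gamma_calorie", "gamma_carb", "gamma_protein", "gamma_fat")])
  if (any(gam < 0, na.rm = TRUE)) {
    stop("nutrient conversion rates must be >= 0 (", path, ")", call. = FALSE)
  }
  invisible(catalog)
}

#' Read a rotation catalog
#'
#' A rotation is a fixed, ordered sequence of crops grown over consecutive
#' years on a plot; in the experiments modelled here, every phase of every
#' rotation is present in every calendar year. The catalog lists one row
#' per rotation-year. An optional `use` column (`food` or `forage`)
#' disambiguates crops grown for forage in some rotations and for direct
#' human consumption in others (e.g. maize); when absent, the crop
#' catalog's `forage_only` flag decides.
#'
#' @param path CSV with columns `rotation_id`, `year_index`, `crop_name`
#'   and optionally `use`.
#' @param crop_catalog Optional crop catalog; when supplied, every crop in
#'   the rotation catalog must be present in it and every rotation must
#'   contain at least one cereal year (the retention rule for the
#'   experiments this package models).
#' @return A tibble of rotation-years ordered by rotation and year index.
#' @export
read_rotation_catalog <- function(path, crop_catalog = NULL) {
  if (!file.exists(path)) {
    stop("rotation catalog file not found: ", path, call. = FALSE)
  }
  rot <- readr::read_csv(path, col_types = readr::cols(), progress = FALSE)
  validate_rotation_catalog(rot, crop_catalog, path)
}

#' @rdname read_rotation_catalog
#' @param rotations Data frame of rotation-years to validate.
#' @export
validate_rotation_catalog <- function(rotations, crop_catalog = NULL,
                                      path = "<in-memory>") {
  needed <- c("rotation_id", "year_index", "crop_name")
  missing_cols <- setdiff(needed, names(rotations))
  if (length(missing_cols) > 0) {
    stop("rotation catalog ", path, " lacks columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!"use" %in% names(rotations)) rotations$use <- NA_character_
  rotations <- dplyr::arrange(tibble::as_tibble(rotations),
                              .data$rotation_id, .data$year_index)
  by_rot <- split(rotations$year_index, rotations$rotation_id)
  for (id in names(by_rot)) {
    yi <- by_rot[[id]]
    if (length(yi) == 0 || any(sort(yi) != seq_along(yi))) {
      stop("rotation ", id, " must have year_index 1..length with no gaps (",
           path, ")", call. = FALSE)
    }
  }
  if (!is.null(crop_catalog)) {
    unknown <- setdiff(unique(rotations$crop_name), crop_catalog$crop_name)
    if (length(unknown) > 0) {
      stop("rotation catalog ", path, " references crops absent from the crop catalog: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    types <- crop_catalog$functional_type[match(rotations$crop_name,
                                                crop_catalog$crop_name)]
    has_cereal <- tapply(types, rotations$rotation_id, function(tt) any(tt == "cereal"))
    if (any(!has_cereal)) {
      stop("rotation(s) without a cereal year: ",
           paste(names(has_cereal)[!has_cereal], collapse = ", "),
           " (every retained rotation must include at least one cereal year)",
           call. = FALSE)
    }
  }
  rotations
}

#' Rotation catalog from a named list of crop sequences
#'
#' Convenience constructor used throughout the simulation interface:
#' `rotation_catalog(list(R1 = c("winter_wheat"), R2 = c("winter_wheat", "pea")))`.
#'
#' @param sequences Named list; each element a character vector of crop
#'   names, one per rotation-year.
#' @param use Optional named list parallel to `sequences` giving per-year
#'   end use (`"food"`/`"forage"`); unnamed entries default to `NA`
#'   (decided by the crop catalog's `forage_only` flag).
#' @param crop_catalog Optional crop catalog for validation.
#' @return Rotation catalog tibble (see [read_rotation_catalog()]).
#' @export
rotation_catalog <- function(sequences, use = NULL, crop_catalog = NULL) {
  stopifnot(is.list(sequences), !is.null(names(sequences)))
  rows <- lapply(names(sequences), function(id) {
    crops <- sequences[[id]]
    u <- if (!is.null(use) && id %in% names(use)) use[[id]] else rep(NA_character_, length(crops))
    if (length(u) != length(crops)) {
      stop("use entry for rotation ", id, " must match its sequence length",
           call. = FALSE)
    }
    tibble::tibble(rotation_id = id, year_index = seq_along(crops),
                   crop_name = crops, use = u)
  })
  validate_rotation_catalog(dplyr::bind_rows(rows), crop_catalog)
}
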