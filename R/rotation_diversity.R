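#' Functional type of a crop
#'
#' Crops are binned into four functional types — annual cereal, annual
#' legume, annual broadleaf and ley — plus fallow for rotation-years with
#' no crop. Root and oil crops both map to annual broadleaf.
#'
#' @param crop_name Crop identifier(s).
#' @param catalog Crop catalog (see [read_crop_catalog()]).
#' @return Character vector of functional types.
#' @export
classify_functional_type <- function(crop_name, catalog) {
  idx <- match(crop_name, catalog$crop_name)
  if (anyNA(idx)) {
    unknown <- unique(crop_name[is.na(idx)])
    stop("unknown crop(s): ", paste(unknown, collapse = ", "),
         " — not present in crop catalog ",
         attr(catalog, "catalog_path") %||% "<in-memory>", call. = FALSE)
  }
  catalog$functional_type[idx]
}

#' Functional richness of a rotation
#'
#' Functional richness (FR) is the number of functionally distinct crop
#' types in a rotation, counted over non-fallow rotation-years. Cereal-only
#' systems are split into monocultures (label `"1M"`: a single cereal
#' species repeated) and cereal-only rotations of several species
#' (`"1C"`). Rotations with two or three functional types are labelled
#' `"2"` and `"3"`. A rotation must contain at least one cereal year;
#' anything else violates the retention rule and is an error.
#'
#' Classification ignores the order of the sequence. A monoculture that
#' also contains fallow years is classified by its non-fallow content
#' (single cereal species -> `"1M"`) and flagged via `has_fallow`.
#'
#' @param crop_sequence Character vector of crop names, one per
#'   rotation-year; `"fallow"`-typed entries are allowed.
#' @param catalog Crop catalog.
#' @return A list of class `fr_level` with fields `label` (one of
#'   `"1M"`, `"1C"`, `"2"`, `"3"`, ...), `n_types`, `n_cereal_species` and
#'   `has_fallow`.
#' @export
functional_richness <- function(crop_sequence, catalog) {
  if (length(crop_sequence) < 1) {
    stop("rotation must have at least one year", call. = FALSE)
  }
  types <- classify_functional_type(crop_sequence, catalog)
  keep <- types != "fallow"
  crops <- crop_sequence[keep]
  types <- types[keep]
  if (!any(types == "cereal")) {
    stop("rotation has no cereal year; retained rotations must include at least one",
         call. = FALSE)
  }
  n_types <- length(unique(types))
  cereal_species <- unique(crops[types == "cereal"])
  label <- if (n_types == 1L) {
    if (length(cereal_species) == 1L) "1M" else "1C"
  } else {
    as.character(n_types)
  }
  structure(
    list(label = label, n_types = n_types,
         n_cereal_species = length(cereal_species),
         has_fallow = any(!keep)),
    class = "fr_level"
  )
}

#' @export
#' @method format fr_level
format.fr_level <- function(x, ...) {
  paste0("FR ", x$label, " (", x$n_types, " functional type",
         if (x$n_types != 1L) "s", if (x$has_fallow) ", incl. fallow years", ")")
}

#' @export
#' @method print fr_level
print.fr_level <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' Area fraction of each rotation-year
#'
#' Outputs of rotations of different lengths are made comparable by
#' weighting each rotation-year by 1/(rotation length): on a notional 1-ha
#' farm every phase of the rotation occupies an equal share of the land
#' each calendar year. Fallow years receive the same weight and contribute
#' zero output downstream.
#'
#' @param crop_sequence Character vector of crop names (one per
#'   rotation-year).
#' @return Numeric vector of weights, one per rotation-year, summing to 1.
#' @export
area_fraction <- function(crop_sequence) {
  n <- length(crop_sequence)
  if (n < 1) stop("rotation must have at least one year", call. = FALSE)
  w <- rep(1 / n, n)
  names(w) <- paste0("year", seq_len(n))
  w
}
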