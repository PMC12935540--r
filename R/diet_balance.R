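#' Calorie shares of the macronutrients
#'
#' Converts macronutrient outputs (any common mass unit) into calorie
#' shares using the Atwater energy densities — 4 kcal per gram for
#' carbohydrates and proteins, 9 kcal per gram for fats — and normalizes.
#' Shares are invariant to rescaling all three inputs, so any consistent
#' mass unit works.
#'
#' @param carb_out,protein_out,fat_out Non-negative macronutrient outputs
#'   in a common mass unit; not all zero.
#' @return An object of class `diet_share`: fractions `carb`, `protein`,
#'   `fat` summing to 1.
#' @export
calorie_shares <- function(carb_out, protein_out, fat_out) {
  vals <- stats::setNames(c(unname(carb_out), unname(protein_out), unname(fat_out)),
                          c("carb", "protein", "fat"))
  if (any(!is.finite(vals)) || any(vals < 0)) {
    stop("macronutrient outputs must be finite and >= 0", call. = FALSE)
  }
  energy <- vals * c(4, 4, 9)
  total <- sum(energy)
  if (total <= 0) {
    stop("all-zero macronutrient outputs: calorie shares undefined",
         call. = FALSE)
  }
  structure(as.list(energy / total), class = "diet_share")
}

#' @export
#' @method print diet_share
print.diet_share <- function(x, ...) {
  cat(sprintf("Calorie shares: %.0f%% carbohydrate, %.0f%% protein, %.0f%% fat\n",
              100 * x$carb, 100 * x$protein, 100 * x$fat))
  invisible(x)
}

#' Recommended macronutrient calorie ranges
#'
#' Dietary guidance for the average adult: 45-65% of calories from
#' carbohydrates, 10-35% from proteins and 20-35% from fats.
#'
#' @return Named list of `c(lower, upper)` fractions.
#' @export
recommended_ranges <- function() {
  list(carb = c(0.45, 0.65), protein = c(0.10, 0.35), fat = c(0.20, 0.35))
}

#' Compare calorie shares with recommended ranges
#'
#' Verdicts use closed intervals: a share exactly on a bound counts as
#' within range.
#'
#' @param share A [calorie_shares()] object.
#' @param ranges Ranges as from [recommended_ranges()].
#' @return Named character vector over carb/protein/fat with values
#'   `"within"`, `"below"` or `"above"`.
#' @export
compare_recommendation <- function(share, ranges = recommended_ranges()) {
  stopifnot(inherits(share, "diet_share"))
  vapply(names(ranges), function(nm) {
    r <- ranges[[nm]]
    if (r[1] > r[2]) stop("range for ", nm, " has lower > upper", call. = FALSE)
    s <- share[[nm]]
    if (s < r[1]) "below" else if (s > r[2]) "above" else "within"
  }, character(1))
}

#' Integer percent change
#'
#' `round(100 * (new - reference) / reference)` with ties rounded half
#' away from zero, the convention used when reporting integer percent
#' changes between model predictions.
#'
#' @param new_value,reference_value Numeric; `reference_value > 0`.
#' @return Integer percent change.
#' @export
percent_change <- function(new_value, reference_value) {
  if (any(reference_value <= 0)) {
    stop("reference_value must be > 0", call. = FALSE)
  }
  pct <- 100 * (new_value - reference_value) / reference_value
  as.integer(sign(pct) * floor(abs(pct) + 0.5))
}
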