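#' Convert fresh yield to dry weight
#'
#' @param yield_raw Yield as reported (kg ha-1), fresh or already dry.
#' @param water_content Water fraction of the reported yield, in `[0, 1)`;
#'   0 means the yield is already a dry weight.
#' @return Dry yield, `yield_raw * (1 - water_content)`.
#' @export
to_dry_weight <- function(yield_raw, water_content) {
  if (any(water_content < 0 | water_content >= 1, na.rm = TRUE)) {
    stop("water_content must lie in [0, 1)", call. = FALSE)
  }
  yield_raw * (1 - water_content)
}

qc_flag_levels <- c("ok", "missing", "unexplained_zero", "explained_zero",
                    "implausible", "gap_filled", "excluded")

# Initial record-level flags from the raw values; existing flags (from a
# previous QC pass) are preserved so that QC is idempotent.
initial_flags <- function(table) {
  if (!"qc_flag" %in% names(table)) {
    table$qc_flag <- NA_character_
  }
  fresh <- is.na(table$qc_flag)
  explained <- !is.na(table$note) & table$note != ""
  table$qc_flag[fresh & is.na(table$yield)] <- "missing"
  zero <- fresh & !is.na(table$yield) & table$yield == 0
  table$qc_flag[zero & explained] <- "explained_zero"
  table$qc_flag[zero & !explained] <- "unexplained_zero"
  table$qc_flag[is.na(table$qc_flag)] <- "ok"
  table
}

#' Flag implausible yields by an interquartile-range screen
#'
#' For each site x crop combination (pooled across years, rotations and
#' groups), non-zero records currently flagged `ok` are screened against
#' the closed interval `[Q1 - 2 IQR, Q3 + 2 IQR]`; values strictly outside
#' it are flagged `implausible` and become candidates for gap filling.
#' Values exactly on a bound are kept, as are zeros and low non-zero
#' yields inside the bounds. Groups with fewer than 4 usable values are
#' skipped with a warning, since quartiles are not meaningful there.
#'
#' @param table Yield table with `yield_dry` (see [qc_yields()], which
#'   computes it) or `yield` + `water_content`.
#' @param quartile_type Quantile convention passed to [stats::quantile()];
#'   the default (type 7, linear interpolation) is a choice, not a law of
#'   nature — flags can differ between conventions at small group sizes.
#' @return The table with `qc_flag` updated.
#' @export
flag_outliers <- function(table, quartile_type = 7) {
  table <- initial_flags(table)
  if (!"yield_dry" %in% names(table)) {
    table$yield_dry <- to_dry_weight(table$yield, table$water_content)
  }
  screen <- table$qc_flag == "ok" & table$yield_dry > 0
  keys <- paste(table$site, table$crop, sep = "\r")
  skipped <- character()
  for (k in unique(keys[screen])) {
    idx <- which(keys == k & screen)
    vals <- table$yield_dry[idx]
    if (length(vals) < 4) {
      skipped <- c(skipped, sub("\r", " / ", k))
      next
    }
    q <- stats::quantile(vals, c(0.25, 0.75), type = quartile_type, names = FALSE)
    iqr <- q[2] - q[1]
    out <- vals < q[1] - 2 * iqr | vals > q[2] + 2 * iqr
    table$qc_flag[idx[out]] <- "implausible"
  }
  if (length(skipped) > 0) {
    warning("outlier screen skipped for site/crop group(s) with < 4 values: ",
            paste(skipped, collapse = "; "), call. = FALSE)
  }
  table
}

#' Gap-fill missing, implausible and unexplained-zero yields
#'
#' Each record needing a fill is replaced by the mean dry yield of its
#' donors: records of the same crop, site, calendar year and rotation in
#' *other* groups (restricted to the same `treatment` when that column is
#' present, so donors differ only in replicate). Explained zeros are never
#' filled and participate as donors. When a record has no donors, the
#' whole site x year x rotation x group combination is excluded from
#' aggregation and listed in the report — never silently dropped.
#'
#' Filling is idempotent: a second pass finds nothing left to fill and
#' changes nothing.
#'
#' @param table Yield table with flags (see [flag_outliers()]).
#' @param keep_unexplained_zeros If `TRUE`, unexplained zeros are kept as
#'   data rather than filled (sensitivity switch).
#' @return A list with `table` (flags/values updated, original flag kept
#'   in `qc_flag_orig`) and `report` (a `qc_report`).
#' @export
gap_fill <- function(table, keep_unexplained_zeros = FALSE) {
  table <- initial_flags(table)
  if (!"yield_dry" %in% names(table)) {
    table$yield_dry <- to_dry_weight(table$yield, table$water_content)
  }
  if (!"qc_flag_orig" %in% names(table)) {
    table$qc_flag_orig <- table$qc_flag
  }
  fill_flags <- c("missing", "implausible",
                  if (!keep_unexplained_zeros) "unexplained_zero")
  needs <- which(table$qc_flag %in% fill_flags)
  donor_ok <- table$qc_flag %in% c("ok", "explained_zero")
  has_treatment <- "treatment" %in% names(table)
  donor_key <- paste(table$site, table$calendar_year, table$rotation_id,
                     table$crop,
                     if (has_treatment) table$treatment else "", sep = "\r")
  donor_sum <- tapply(table$yield_dry[donor_ok], donor_key[donor_ok], sum)
  donor_n <- tapply(table$yield_dry[donor_ok], donor_key[donor_ok], length)
  unfillable <- integer()
  for (i in needs) {
    k <- donor_key[i]
    n <- donor_n[k]
    if (is.na(n) || n == 0) {
      unfillable <- c(unfillable, i)
      next
    }
    fill <- donor_sum[[k]] / n
    table$yield_dry[i] <- fill
    wc <- table$water_content[i]
    table$yield[i] <- if (!is.na(wc) && wc < 1) fill / (1 - wc) else fill
    table$qc_flag_orig[i] <- table$qc_flag[i]
    table$qc_flag[i] <- "gap_filled"
  }
  cell_key <- paste(table$site, table$calendar_year, table$rotation_id,
                    table$group, sep = "\r")
  excluded_cells <- unique(cell_key[unfillable])
  if (length(excluded_cells) > 0) {
    # qc_flag_orig keeps each record's first substantive flag, so records
    # already gap-filled in this pass retain their missing/zero history
    drop <- cell_key %in% excluded_cells
    table$qc_flag[drop] <- "excluded"
  }
  report <- qc_report(table, excluded_cells)
  list(table = table, report = report)
}

qc_report <- function(table, excluded_cells = character()) {
  counts <- table(factor(table$qc_flag, levels = qc_flag_levels))
  n <- nrow(table)
  orig <- if ("qc_flag_orig" %in% names(table)) table$qc_flag_orig else table$qc_flag
  exclusions <- lapply(strsplit(excluded_cells, "\r", fixed = TRUE), function(p) {
    list(site = p[1], calendar_year = as.numeric(p[2]),
         rotation_id = p[3], group = p[4])
  })
  structure(
    list(n_records = n,
         counts = as.list(counts),
         fraction_missing = sum(orig == "missing") / n,
         fraction_unexplained_zero = sum(orig == "unexplained_zero") / n,
         n_gap_filled = sum(table$qc_flag == "gap_filled"),
         n_excluded_cells = length(exclusions),
         exclusions = exclusions),
    class = "qc_report"
  )
}

#' @export
#' @method print qc_report
print.qc_report <- function(x, ...) {
  cat("Yield QC report:", x$n_records, "records\n")
  for (f in names(x$counts)) {
    if (x$counts[[f]] > 0) cat(sprintf("  %-17s %d\n", f, x$counts[[f]]))
  }
  cat(sprintf("  missing fraction: %.4f; unexplained-zero fraction: %.4f\n",
              x$fraction_missing, x$fraction_unexplained_zero))
  cat("  excluded site x year x rotation x group cells:",
      x$n_excluded_cells, "\n")
  invisible(x)
}

#' @rdname gap_fill
#' @param report A `qc_report`.
#' @param path Output JSON path.
#' @export
write_qc_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Run the full yield quality-control chain
#'
#' Computes dry weights, applies the record-level flags (missing,
#' explained/unexplained zero), screens outliers per site x crop, and
#' gap-fills by donor means. The two sensitivity switches reproduce the
#' robustness runs of the analysis this package supports: keeping
#' unexplained zeros as data, and disabling gap filling altogether (in
#' which case implausible values and unexplained zeros are kept as
#' reported and only truly missing records force cell exclusion).
#'
#' @inheritParams flag_outliers
#' @inheritParams gap_fill
#' @param do_gap_fill Master switch for donor-mean filling.
#' @return A list with `table` and `report` (class `qc_result`).
#' @export
qc_yields <- function(table, do_gap_fill = TRUE,
                      keep_unexplained_zeros = FALSE, quartile_type = 7) {
  table <- flag_outliers(table, quartile_type = quartile_type)
  if (do_gap_fill) {
    out <- gap_fill(table, keep_unexplained_zeros = keep_unexplained_zeros)
  } else {
    # keep reported values; only missing records are unusable
    if (!"qc_flag_orig" %in% names(table)) table$qc_flag_orig <- table$qc_flag
    keep <- table$qc_flag %in% c("implausible", "unexplained_zero")
    table$qc_flag[keep] <- "ok"
    cell_key <- paste(table$site, table$calendar_year, table$rotation_id,
                      table$group, sep = "\r")
    excluded_cells <- unique(cell_key[table$qc_flag == "missing"])
    drop <- cell_key %in% excluded_cells
    table$qc_flag[drop] <- "excluded"
    out <- list(table = table, report = qc_report(table, excluded_cells))
  }
  class(out) <- "qc_result"
  out
}
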