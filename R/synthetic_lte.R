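#' Configuration for a synthetic long-term rotation experiment
#'
#' Builds the configuration object consumed by [generate_experiment()].
#' Defaults emulate a network of European long-term experiments: 16 sites
#' of 11-53 years with staggered start years, rotations spanning
#' functional-richness levels 1M, 1C, 2 and 3 (the FR 3 rotations include
#' ley, one rotation includes a fallow year), groups formed by crossing
#' treatments with replicates, and the observed anomaly rates (2.28%
#' missing records, 0.92% unexplained zeros).
#'
#' The data-generating model mirrors the analysis model: for each cell
#' (site x calendar year x rotation x group) a latent value is drawn on
#' the square-root scale of the cell's area-weighted total dry yield,
#' \deqn{s = \sqrt{\bar O_r} + \beta_{t,FR}\,t_s + \beta_{t^2,FR}\,t_s^2 +
#'   b_{site} + b_{year} + b_{group} + \varepsilon,}
#' where \eqn{t_s} is time since the start of the site's experiment divided
#' by the dataset maximum, and \eqn{\bar O_r} is the rotation's deterministic
#' baseline (area-weighted mean of crop baselines times the FR effect).
#' The cell's realised total is \eqn{\max(0, s)^2} and every crop yield in
#' the cell is scaled by a common factor so the aggregate reproduces it
#' exactly. Random intercepts are shared by all crops of a cell: a good
#' year is good for the whole rotation. This makes the square root of the
#' aggregated output follow the analysis model exactly (up to rare
#' truncation at zero), which is what parameter-recovery tests require.
#'
#' @param n_sites Number of sites.
#' @param years_per_site Either a single number of years per site or a
#'   length-2 range from which each site's duration is drawn uniformly.
#' @param rotations Rotation catalog as returned by [rotation_catalog()]
#'   (columns `rotation_id`, `year_index`, `crop_name`, optionally `use`).
#' @param fr_labels Named character vector mapping rotation_id to its FR
#'   label; when `NULL` it is derived from `crop_types`.
#' @param crop_types Named character vector mapping crop name to
#'   functional type (used to derive FR labels and to mark fallow years).
#' @param groups_per_site Number of treatment x replicate groups per site;
#'   every rotation is observed in every group of its site.
#' @param site_sd,year_sd,group_sd,residual_sd Standard deviations of the
#'   random intercepts for site, calendar year (crossed with site),
#'   group-in-site, and of the residual, on the sqrt total-dry-yield scale
#'   (sqrt(kg ha-1)).
#' @param crop_baselines Named numeric vector of mean dry yields
#'   (kg ha-1 yr-1) per crop; fallow needs no entry.
#' @param fr_effects Named numeric vector of multiplicative yield effects
#'   per FR label (1 = no effect).
#' @param time_linear,time_quad Named numeric vectors of per-FR linear and
#'   quadratic trend coefficients on the sqrt scale, per unit of scaled
#'   time (so a coefficient of -6 moves sqrt output by -6 over the full
#'   observed time span).
#' @param missing_rate,zero_rate Fractions of non-fallow records turned
#'   into missing values / unexplained zeros.
#' @param water_content Either a single fresh-yield water fraction applied
#'   to all crops or a named vector per crop; reported yields are fresh,
#'   `yield * (1 - water_content)` recovers the dry yield.
#' @param start_year First possible experiment start year.
#' @param staggered_starts If `TRUE`, site start years are spread over
#'   `start_year + 0..start_spread` to mimic heterogeneous experiment eras.
#' @param start_spread Width (years) of the staggered-start window.
#' @param seed Integer master seed; every stochastic step flows from it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_sites = 16,
                       years_per_site = c(11, 53),
                       rotations = default_sim_rotations(),
                       fr_labels = NULL,
                       crop_types = default_sim_crop_types(),
                       groups_per_site = 6,
                       site_sd = 6, year_sd = 3, group_sd = 2, residual_sd = 4,
                       crop_baselines = default_sim_baselines(),
                       fr_effects = c("1M" = 1, "1C" = 0.95, "2" = 1.0, "3" = 1.05),
                       time_linear = c("1M" = -6, "1C" = 3, "2" = -3, "3" = 5),
                       time_quad = c("1M" = 0, "1C" = 0, "2" = 0, "3" = -2),
                       missing_rate = 0.0228,
                       zero_rate = 0.0092,
                       water_content = 0.14,
                       start_year = 1955,
                       staggered_starts = TRUE,
                       start_spread = 30,
                       seed = 1L) {
  cfg <- list(
    n_sites = n_sites, years_per_site = years_per_site,
    rotations = validate_rotation_catalog(rotations),
    fr_labels = fr_labels, crop_types = crop_types,
    groups_per_site = groups_per_site,
    site_sd = site_sd, year_sd = year_sd, group_sd = group_sd,
    residual_sd = residual_sd,
    crop_baselines = crop_baselines, fr_effects = fr_effects,
    time_linear = time_linear, time_quad = time_quad,
    missing_rate = missing_rate, zero_rate = zero_rate,
    water_content = water_content,
    start_year = start_year, staggered_starts = staggered_starts,
    start_spread = start_spread, seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

#' @rdname sim_config
#' @export
default_sim_rotations <- function() {
  rotation_catalog(list(
    M_wheat  = "winter_wheat",
    M_barley = "spring_barley",
    C_mix    = c("winter_wheat", "spring_barley", "oat"),
    WP       = c("winter_wheat", "pea"),
    WOSR     = c("winter_wheat", "winter_wheat", "oilseed_rape"),
    WPL      = c("winter_wheat", "pea", "ley", "ley"),
    WRL      = c("spring_barley", "oilseed_rape", "ley", "ley", "fallow")
  ))
}

#' @rdname sim_config
#' @export
default_sim_crop_types <- function() {
  c(winter_wheat = "cereal", spring_barley = "cereal", oat = "cereal",
    maize_grain = "cereal", pea = "annual_legume",
    oilseed_rape = "annual_broadleaf", potato = "annual_broadleaf",
    sugar_beet = "annual_broadleaf", ley = "ley", fallow = "fallow")
}

#' @rdname sim_config
#' @export
default_sim_baselines <- function() {
  c(winter_wheat = 6000, spring_barley = 4500, oat = 4000,
    maize_grain = 7500, pea = 3000, oilseed_rape = 2800,
    potato = 9000, sugar_beet = 13000, ley = 8000)
}

#' @rdname sim_config
#' @export
validate_sim_config <- function(cfg) {
  problems <- character()
  chk <- function(ok, msg) if (!isTRUE(ok)) problems <<- c(problems, msg)
  chk(cfg$n_sites >= 1, "n_sites must be >= 1")
  chk(length(cfg$years_per_site) %in% 1:2 && all(cfg$years_per_site >= 2),
      "years_per_site must be a duration >= 2 or a range of them")
  chk(cfg$groups_per_site >= 1, "groups_per_site must be >= 1")
  for (nm in c("site_sd", "year_sd", "group_sd", "residual_sd")) {
    chk(cfg[[nm]] >= 0, paste(nm, "must be >= 0"))
  }
  for (nm in c("missing_rate", "zero_rate")) {
    chk(cfg[[nm]] >= 0 && cfg[[nm]] <= 1, paste(nm, "must lie in [0, 1]"))
  }
  fallow_crops <- names(cfg$crop_types)[cfg$crop_types == "fallow"]
  needed <- setdiff(unique(cfg$rotations$crop_name), fallow_crops)
  missing_base <- setdiff(needed, names(cfg$crop_baselines))
  chk(length(missing_base) == 0,
      paste("rotation crops lack baselines:", paste(missing_base, collapse = ", ")))
  missing_type <- setdiff(unique(cfg$rotations$crop_name), names(cfg$crop_types))
  chk(length(missing_type) == 0,
      paste("rotation crops lack a functional type:",
            paste(missing_type, collapse = ", ")))
  chk(all(cfg$crop_baselines >= 0), "crop baselines must be >= 0")
  if (length(missing_type) == 0) {
    frs <- sim_fr_labels(cfg)
    for (nm in c("fr_effects", "time_linear", "time_quad")) {
      absent <- setdiff(unique(frs), names(cfg[[nm]]))
      chk(length(absent) == 0,
          paste0(nm, " lacks entries for FR level(s): ",
                 paste(absent, collapse = ", ")))
    }
  }
  chk(all(cfg$fr_effects >= 0), "fr_effects must be >= 0")
  wc <- cfg$water_content
  chk(all(wc >= 0 & wc < 1), "water_content must lie in [0, 1)")
  chk(is.finite(cfg$seed) && abs(cfg$seed) < 2^31, "seed must be a 32-bit integer")
  if (length(problems) > 0) {
    stop("invalid sim_config:\n  - ", paste(problems, collapse = "\n  - "),
         call. = FALSE)
  }
  invisible(cfg)
}

# FR label per rotation_id, derived from crop types unless overridden
sim_fr_labels <- function(cfg) {
  ids <- unique(cfg$rotations$rotation_id)
  if (!is.null(cfg$fr_labels)) {
    absent <- setdiff(ids, names(cfg$fr_labels))
    if (length(absent) > 0) {
      stop("fr_labels lacks rotation(s): ", paste(absent, collapse = ", "),
           call. = FALSE)
    }
    return(cfg$fr_labels[ids])
  }
  minimal_catalog <- tibble::tibble(
    crop_name = names(cfg$crop_types),
    functional_type = unname(cfg$crop_types)
  )
  out <- vapply(ids, function(id) {
    seqn <- cfg$rotations$crop_name[cfg$rotations$rotation_id == id]
    functional_richness(seqn, minimal_catalog)$label
  }, character(1))
  names(out) <- ids
  out
}

# deterministic rotation summaries: distinct crops, occupancy weights,
# area-weighted baseline total dry yield per FR-adjusted rotation
sim_rotation_summary <- function(cfg) {
  frs <- sim_fr_labels(cfg)
  fallow_crops <- names(cfg$crop_types)[cfg$crop_types == "fallow"]
  lapply(stats::setNames(nm = unique(cfg$rotations$rotation_id)), function(id) {
    seqn <- cfg$rotations$crop_name[cfg$rotations$rotation_id == id]
    len <- length(seqn)
    occ <- table(seqn)
    crops <- names(occ)
    is_fallow <- crops %in% fallow_crops
    w <- as.numeric(occ) / len
    base <- ifelse(is_fallow, 0, cfg$crop_baselines[crops] * cfg$fr_effects[[frs[[id]]]])
    list(rotation_id = id, fr = frs[[id]], length = len, crops = crops,
         is_fallow = is_fallow, weight = w, crop_mean = unname(base),
         o_bar = sum(w * base))
  })
}

#' Generate a synthetic long-term experiment yield table
#'
#' Produces a long-format yield table with one row per site x calendar
#' year x rotation x group x distinct crop of the rotation (fallow years
#' appear as explained-zero rows), with anomalies injected at the
#' configured rates. Deterministic for a fixed seed. See [sim_config()]
#' for the generating model.
#'
#' @param config A [sim_config()] object.
#' @return A tibble with columns `site`, `calendar_year`,
#'   `time_since_start`, `rotation_id`, `fr`, `group`, `crop`, `yield`
#'   (fresh, kg ha-1), `water_content`, `note` (`"fallow"` for structural
#'   zeros, else `NA`) and `anomaly` (`"none"`, `"injected_missing"` or
#'   `"injected_zero"`). Schema version is recorded in attribute
#'   `yield_table_schema`.
#' @export
generate_experiment <- function(config) {
  validate_sim_config(config)
  cfg <- config
  withr::with_seed(cfg$seed, {
    sites <- sprintf("S%02d", seq_len(cfg$n_sites))
    spans <- if (length(cfg$years_per_site) == 1) {
      rep(cfg$years_per_site, cfg$n_sites)
    } else {
      sample(seq(cfg$years_per_site[1], cfg$years_per_site[2]),
             cfg$n_sites, replace = TRUE)
    }
    starts <- if (cfg$staggered_starts) {
      cfg$start_year + sample(0:cfg$start_spread, cfg$n_sites, replace = TRUE)
    } else {
      rep(cfg$start_year, cfg$n_sites)
    }
    t_max <- max(spans) - 1
    all_years <- seq(min(starts), max(starts + spans - 1))
    b_site <- stats::setNames(stats::rnorm(cfg$n_sites, 0, cfg$site_sd), sites)
    b_year <- stats::setNames(stats::rnorm(length(all_years), 0, cfg$year_sd),
                              all_years)
    groups <- sprintf("g%d", seq_len(cfg$groups_per_site))
    b_group <- stats::setNames(
      stats::rnorm(cfg$n_sites * cfg$groups_per_site, 0, cfg$group_sd),
      as.vector(outer(sites, groups, paste, sep = ":"))
    )
    rots <- sim_rotation_summary(cfg)

    cells <- do.call(rbind, lapply(seq_along(sites), function(i) {
      expand.grid(site = sites[i],
                  calendar_year = seq(starts[i], starts[i] + spans[i] - 1),
                  rotation_id = names(rots), group = groups,
                  stringsAsFactors = FALSE)
    }))
    cells$time_since_start <- cells$calendar_year -
      starts[match(cells$site, sites)]
    t_sc <- cells$time_since_start / t_max
    fr <- vapply(rots, `[[`, character(1), "fr")[cells$rotation_id]
    o_bar <- vapply(rots, `[[`, numeric(1), "o_bar")[cells$rotation_id]
    s <- sqrt(o_bar) +
      cfg$time_linear[fr] * t_sc + cfg$time_quad[fr] * t_sc^2 +
      b_site[cells$site] + b_year[as.character(cells$calendar_year)] +
      b_group[paste(cells$site, cells$group, sep = ":")] +
      stats::rnorm(nrow(cells), 0, cfg$residual_sd)
    scale_fac <- ifelse(o_bar > 0, pmax(0, s)^2 / o_bar, 0)

    wc_of <- function(crop) {
      if (length(cfg$water_content) == 1 && is.null(names(cfg$water_content))) {
        rep(cfg$water_content, length(crop))
      } else {
        ifelse(crop %in% names(cfg$water_content),
               cfg$water_content[crop], 0)
      }
    }
    per_rot <- lapply(rots, function(r) {
      tibble::tibble(rotation_id = r$rotation_id, crop = r$crops,
                     crop_mean = r$crop_mean, is_fallow = r$is_fallow)
    })
    crop_rows <- dplyr::bind_rows(per_rot)
    tab <- dplyr::left_join(
      dplyr::mutate(tibble::as_tibble(cells), fr = fr,
                    .scale = scale_fac),
      crop_rows, by = "rotation_id", relationship = "many-to-many"
    )
    dry <- ifelse(tab$is_fallow, 0, tab$crop_mean * tab$.scale)
    wc <- ifelse(tab$is_fallow, 0, wc_of(tab$crop))
    tab <- dplyr::transmute(
      tab,
      site = .data$site, calendar_year = .data$calendar_year,
      time_since_start = .data$time_since_start,
      rotation_id = .data$rotation_id, fr = .data$fr, group = .data$group,
      crop = .data$crop, yield = dry / (1 - wc), water_content = wc,
      note = ifelse(.data$is_fallow, "fallow", NA_character_),
      anomaly = "none"
    )
    tab <- dplyr::arrange(tab, .data$site, .data$calendar_year,
                          .data$rotation_id, .data$group, .data$crop)
  })
  tab <- inject_anomalies(tab, config$missing_rate, config$zero_rate,
                          seed = config$seed + 1L)
  attr(tab, "out.attrs") <- NULL
  attr(tab, "yield_table_schema") <- yield_table_schema_version
  attr(tab, "time_scaling") <- max(tab$time_since_start)
  tab
}

yield_table_schema_version <- "1.0"

#' Inject missing and unexplained-zero anomalies
#'
#' Randomly selected non-fallow records are set to missing or to an
#' unexplained zero, completely at random, and flagged in the `anomaly`
#' column so downstream QC tests know the ground truth. Structural zeros
#' (fallow years) are never selected. Row count is unchanged.
#'
#' @param table A yield table (see [generate_experiment()]).
#' @param missing_rate,zero_rate Selection probabilities in `[0, 1]`.
#' @param seed Integer seed.
#' @return The table with `yield` and `anomaly` updated.
#' @export
inject_anomalies <- function(table, missing_rate, zero_rate, seed = 1L) {
  stopifnot(missing_rate >= 0, missing_rate <= 1,
            zero_rate >= 0, zero_rate <= 1)
  eligible <- is.na(table$note) | table$note != "fallow"
  withr::with_seed(as.integer(seed), {
    u <- stats::runif(nrow(table))
    to_missing <- eligible & u < missing_rate
    to_zero <- eligible & !to_missing & u >= missing_rate &
      u < missing_rate + zero_rate
  })
  table$yield[to_missing] <- NA_real_
  table$anomaly[to_missing] <- "injected_missing"
  table$yield[to_zero] <- 0
  table$anomaly[to_zero] <- "injected_zero"
  table
}

#' Ground-truth parameters in the analysis-model parameterization
#'
#' Maps the simulation configuration into the parameterization of the
#' fitted model for the aggregate dry-yield output: per-FR intercept
#' offsets on the sqrt scale (reference level 1M), linear and quadratic
#' time coefficients per unit scaled time, and variance components. The
#' multiplicative FR yield effect maps to the sqrt scale as
#' \eqn{\sqrt{\bar O_{FR}} - \sqrt{\bar O_{1M}}}; when several rotations
#' share an FR level with different baseline totals the mapping uses their
#' mean and warns, since the analysis model then has no single truth.
#'
#' These truths are on the sqrt total-dry-yield scale; recovery tests fit
#' the model to outputs built with [dry_matter_catalog()], for which the
#' aggregate output is exactly the area-weighted total dry yield.
#'
#' @param config A [sim_config()].
#' @return A list of class `param_set` with `beta` (named fixed-effect
#'   truths) and `varcomp` (site, group, year, residual variances).
#' @export
true_params <- function(config) {
  validate_sim_config(config)
  rots <- sim_rotation_summary(config)
  fr <- vapply(rots, `[[`, character(1), "fr")
  o_bar <- vapply(rots, `[[`, numeric(1), "o_bar")
  fr_levels <- intersect(c("1M", "1C", "2", "3"), unique(fr))
  sqrt_by_fr <- vapply(fr_levels, function(l) {
    v <- sqrt(o_bar[fr == l])
    if (length(unique(round(v, 10))) > 1) {
      warning("rotations at FR ", l, " differ in baseline total output; ",
              "intercept truth is their mean", call. = FALSE)
    }
    mean(v)
  }, numeric(1))
  if (!"1M" %in% fr_levels) {
    stop("true_params requires an FR 1M rotation as reference", call. = FALSE)
  }
  ref <- "1M"
  beta <- c(intercept = unname(sqrt_by_fr[ref]),
            t = unname(config$time_linear[[ref]]),
            t2 = unname(config$time_quad[[ref]]))
  for (l in setdiff(fr_levels, ref)) {
    beta[paste0("fr", l)] <- sqrt_by_fr[[l]] - sqrt_by_fr[[ref]]
    beta[paste0("fr", l, ":t")] <- config$time_linear[[l]] - config$time_linear[[ref]]
    beta[paste0("fr", l, ":t2")] <- config$time_quad[[l]] - config$time_quad[[ref]]
  }
  structure(
    list(beta = beta,
         varcomp = c(site = config$site_sd^2, group = config$group_sd^2,
                     year = config$year_sd^2, residual = config$residual_sd^2),
         fr_levels = fr_levels),
    class = "param_set"
  )
}

#' Catalog whose output is dry matter itself
#'
#' A conversion catalog with unit factors (`alpha = 1`, `f_ref = 1`,
#' `f_h2o = 0`, all nutrient rates 1), so the "nutrient" output of a
#' rotation is its area-weighted total dry yield (kg ha-1 yr-1). Used for
#' parameter-recovery tests against [true_params()] and for yield-scale
#' sanity checks.
#'
#' @param crop_types Named character vector mapping crop name to
#'   functional type.
#' @return A crop catalog tibble.
#' @export
dry_matter_catalog <- function(crop_types = default_sim_crop_types()) {
  tibble::tibble(
    crop_name = names(crop_types),
    functional_type = unname(crop_types),
    edible = unname(crop_types) != "fallow",
    forage_only = FALSE,
    f_h2o = 0, alpha = 1, f_ref = 1,
    gamma_calorie = 1, gamma_carb = 1, gamma_protein = 1, gamma_fat = 1,
    retail_product = "dry_matter"
  )
}

#' Read/write yield tables and simulation configs
#'
#' Yield tables are written as plain CSV under schema version
#' `r yield_table_schema_version` with columns `site`, `calendar_year`,
#' `time_since_start`, `rotation_id`, `fr`, `group`, `crop`, `yield`,
#' `water_content`, `note`, `anomaly`; simulation configurations round-trip
#' through YAML.
#'
#' @param table Yield table.
#' @param path File path.
#' @export
write_yield_table <- function(table, path) {
  readr::write_csv(table, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_yield_table
#' @export
read_yield_table <- function(path) {
  tab <- readr::read_csv(path, col_types = readr::cols(
    site = readr::col_character(), calendar_year = readr::col_double(),
    time_since_start = readr::col_double(),
    rotation_id = readr::col_character(), fr = readr::col_character(),
    group = readr::col_character(), crop = readr::col_character(),
    yield = readr::col_double(), water_content = readr::col_double(),
    note = readr::col_character(), anomaly = readr::col_character()
  ), progress = FALSE)
  attr(tab, "yield_table_schema") <- yield_table_schema_version
  tab
}

#' @rdname write_yield_table
#' @param config A [sim_config()].
#' @export
write_sim_config <- function(config, path) {
  ser <- unclass(config)
  ser$rotations <- lapply(split(config$rotations, config$rotations$rotation_id),
                          function(d) as.list(d$crop_name[order(d$year_index)]))
  # yaml drops names of atomic vectors; named maps must go through lists
  for (nm in c("crop_types", "crop_baselines", "fr_effects",
               "time_linear", "time_quad", "fr_labels")) {
    if (!is.null(ser[[nm]])) ser[[nm]] <- as.list(ser[[nm]])
  }
  if (!is.null(names(ser$water_content))) {
    ser$water_content <- as.list(ser$water_content)
  }
  yaml::write_yaml(ser, path)
  invisible(path)
}

#' @rdname write_yield_table
#' @export
read_sim_config <- function(path) {
  ser <- yaml::read_yaml(path)
  ser$rotations <- rotation_catalog(ser$rotations)
  for (nm in c("crop_types", "crop_baselines", "fr_effects",
               "time_linear", "time_quad", "water_content")) {
    if (!is.null(ser[[nm]])) ser[[nm]] <- unlist(ser[[nm]])
  }
  if (!is.null(ser$fr_labels)) ser$fr_labels <- unlist(ser$fr_labels)
  do.call(sim_config, ser[setdiff(names(ser), character())])
}
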