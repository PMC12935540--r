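#' Pipeline run configuration
#'
#' Bundles everything one analysis run needs: the input data (a yield
#' table CSV or a simulation configuration), the conversion catalogs, the
#' forage end-use scenarios, QC switches, model options and the output
#' directory. All randomness in a run flows from the single `seed`.
#'
#' @param sim A [sim_config()] to simulate inputs, or `NULL` when
#'   `yield_table` is given.
#' @param yield_table Path to a yield-table CSV (schema of
#'   [write_yield_table()]), or a yield-table data frame.
#' @param crop_catalog Crop catalog tibble or CSV path (default: shipped
#'   catalog).
#' @param rotation_catalog Rotation catalog tibble or CSV path; when
#'   `NULL` and `sim` is given, the simulation's rotations are used.
#' @param scenarios Character subset of `c("milk", "beef", "biofuel")`.
#' @param nutrients_wanted Nutrients to fit (default all four).
#' @param do_gap_fill,keep_unexplained_zeros QC switches ([qc_yields()]).
#' @param time_scaling,include_random Model options ([fit_output_model()],
#'   [predict_outputs()]).
#' @param contrast_times Times (years) for predictions and contrasts.
#' @param diet_time Time (years) at which the dietary balance is assessed.
#' @param diet_scenario Scenario whose outputs feed the dietary-balance
#'   report (default `"milk"`).
#' @param seed Master seed.
#' @param out_dir Output directory (created if needed).
#' @param dry_run If `TRUE`, [run_pipeline()] only validates inputs.
#' @return A list of class `run_config`.
#' @export
run_config <- function(sim = NULL, yield_table = NULL,
                       crop_catalog = NULL, rotation_catalog = NULL,
                       scenarios = "milk",
                       nutrients_wanted = nutrients(),
                       do_gap_fill = TRUE, keep_unexplained_zeros = FALSE,
                       time_scaling = NULL, include_random = TRUE,
                       contrast_times = c(5, 10, 20),
                       diet_time = 20, diet_scenario = "milk",
                       seed = 1L, out_dir = tempfile("rotanutri_run_"),
                       dry_run = FALSE) {
  scenarios <- match.arg(scenarios, c("milk", "beef", "biofuel"),
                         several.ok = TRUE)
  if (is.null(sim) && is.null(yield_table)) {
    stop("run_config needs either `sim` or `yield_table`", call. = FALSE)
  }
  if (is.character(yield_table) && !file.exists(yield_table)) {
    stop("yield table file not found: ", yield_table, call. = FALSE)
  }
  if (is.character(crop_catalog) && !file.exists(crop_catalog)) {
    stop("crop catalog file not found: ", crop_catalog, call. = FALSE)
  }
  structure(
    list(sim = sim, yield_table = yield_table,
         crop_catalog = crop_catalog, rotation_catalog = rotation_catalog,
         scenarios = scenarios, nutrients_wanted = nutrients_wanted,
         do_gap_fill = do_gap_fill,
         keep_unexplained_zeros = keep_unexplained_zeros,
         time_scaling = time_scaling, include_random = include_random,
         contrast_times = contrast_times,
         diet_time = diet_time, diet_scenario = diet_scenario,
         seed = as.integer(seed), out_dir = out_dir, dry_run = dry_run),
    class = "run_config"
  )
}

resolve_catalogs <- function(config) {
  crop_cat <- config$crop_catalog
  if (is.null(crop_cat)) crop_cat <- read_crop_catalog()
  else if (is.character(crop_cat)) crop_cat <- read_crop_catalog(crop_cat)
  else validate_crop_catalog(crop_cat)
  rot_cat <- config$rotation_catalog
  if (is.null(rot_cat) && !is.null(config$sim)) rot_cat <- config$sim$rotations
  if (is.character(rot_cat)) rot_cat <- read_rotation_catalog(rot_cat, crop_cat)
  if (is.null(rot_cat)) {
    stop("no rotation catalog available", call. = FALSE)
  }
  rot_cat <- validate_rotation_catalog(rot_cat, crop_cat)
  list(crop = crop_cat, rotation = rot_cat)
}

#' Run the whole analysis pipeline
#'
#' Orchestrates simulate (or load) -> QC -> nutrient conversion -> model
#' fit -> predictions and contrasts -> dietary-balance report, writing
#' every intermediate table to the run directory together with a manifest
#' (package version, seed, config hash, fitted models per scenario). One
#' mixed model is fitted per nutrient and scenario; with the default four
#' nutrients that is four fits per scenario. Inputs are never mutated in
#' place.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the manifest, QC report, output tables,
#'   fitted models, contrast tables and the diet report. In dry-run mode,
#'   only the validated configuration summary.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  cats <- resolve_catalogs(config)
  if (isTRUE(config$dry_run)) {
    if (!is.null(config$sim)) validate_sim_config(config$sim)
    return(invisible(list(
      valid = TRUE,
      n_crops = nrow(cats$crop),
      n_rotations = length(unique(cats$rotation$rotation_id))
    )))
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  outp <- function(...) file.path(config$out_dir, ...)

  if (!is.null(config$sim)) {
    sim <- config$sim
    sim$seed <- config$seed
    yields <- generate_experiment(sim)
    write_yield_table(yields, outp("yield_table.csv"))
  } else if (is.character(config$yield_table)) {
    yields <- read_yield_table(config$yield_table)
  } else {
    yields <- config$yield_table
  }

  qc <- qc_yields(yields, do_gap_fill = config$do_gap_fill,
                  keep_unexplained_zeros = config$keep_unexplained_zeros)
  write_yield_table(qc$table, outp("yield_table_qc.csv"))
  write_qc_report(qc$report, outp("qc_report.json"))

  models <- list()
  output_tables <- list()
  contrasts <- list()
  for (sc in config$scenarios) {
    outputs <- build_output_table(qc$table, cats$crop, cats$rotation,
                                  scenario = sc,
                                  nutrients_wanted = config$nutrients_wanted)
    output_tables[[sc]] <- outputs
    readr::write_csv(outputs, outp(paste0("rotation_outputs_", sc, ".csv")),
                     progress = FALSE)
    for (n in config$nutrients_wanted) {
      m <- fit_output_model(outputs, nutrient = n,
                            time_scaling = config$time_scaling)
      key <- paste(sc, n, sep = ".")
      models[[key]] <- m
      write_model_json(m, outp(paste0("model_", sc, "_", n, ".json")))
      pred <- predict_outputs(m, fr = m$fr_levels,
                              time = c(0, config$contrast_times),
                              include_random = config$include_random)
      readr::write_csv(pred, outp(paste0("predictions_", sc, "_", n, ".csv")),
                       progress = FALSE)
      if (!m$degenerate_fr) {
        cf <- contrast_fr(m, time = config$contrast_times,
                          seed = config$seed)
        ct <- dplyr::bind_rows(lapply(m$fr_levels, function(l) {
          contrast_time(m, fr = l, times = config$contrast_times,
                        seed = config$seed)
        }))
        contrasts[[key]] <- list(fr = cf, time = ct)
        readr::write_csv(cf, outp(paste0("contrasts_fr_", sc, "_", n, ".csv")),
                         progress = FALSE)
        readr::write_csv(ct, outp(paste0("contrasts_time_", sc, "_", n, ".csv")),
                         progress = FALSE)
      }
    }
  }

  diet <- NULL
  if (config$diet_scenario %in% config$scenarios &&
      all(c("carbohydrate", "protein", "fat") %in% config$nutrients_wanted)) {
    diet <- diet_report(models, scenario = config$diet_scenario,
                        time = config$diet_time)
    jsonlite::write_json(diet, outp("diet_balance.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  manifest <- list(
    package = "rotanutri",
    version = as.character(utils::packageVersion("rotanutri")),
    seed = config$seed,
    config_hash = rlang::hash(config[setdiff(names(config), "out_dir")]),
    scenarios = config$scenarios,
    nutrients = config$nutrients_wanted,
    n_models = length(models),
    models = names(models),
    n_yield_records = nrow(yields),
    n_output_rows = vapply(output_tables, nrow, integer(1)),
    time_scaling = vapply(models, function(m) m$time_scaling, numeric(1))[1]
  )
  jsonlite::write_json(manifest, outp("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(manifest = manifest, qc = qc$report,
                 outputs = output_tables, models = models,
                 contrasts = contrasts, diet = diet,
                 out_dir = config$out_dir))
}

#' Dietary balance of model-predicted outputs
#'
#' Back-transformed carbohydrate, protein and fat predictions at a given
#' time are turned into calorie shares per FR level and compared with the
#' recommended ranges.
#'
#' @param models Named list of `fr_model`s keyed `"<scenario>.<nutrient>"`
#'   (as produced inside [run_pipeline()]).
#' @param scenario Scenario name.
#' @param time Years since start at which to assess the balance.
#' @return A list per FR level with shares and verdicts.
#' @export
diet_report <- function(models, scenario = "milk", time = 20) {
  need <- paste(scenario, c("carbohydrate", "protein", "fat"), sep = ".")
  if (!all(need %in% names(models))) {
    stop("diet report needs carbohydrate, protein and fat models for scenario ",
         scenario, call. = FALSE)
  }
  frs <- models[[need[1]]]$fr_levels
  per_fr <- lapply(stats::setNames(nm = frs), function(l) {
    pred <- vapply(need, function(k) {
      predict_outputs(models[[k]], fr = l, time = time)$predicted
    }, numeric(1))
    sh <- calorie_shares(pred[1], pred[2], pred[3])
    list(outputs_kg_ha_yr = as.list(stats::setNames(unname(pred),
                                                    c("carbohydrate", "protein", "fat"))),
         shares = unclass(sh),
         verdicts = as.list(compare_recommendation(sh)))
  })
  list(scenario = scenario, time = time,
       recommended = recommended_ranges(), by_fr = per_fr)
}

#' Leave-one-site-out sensitivity analysis
#'
#' Refits the output model once per held-out site and summarizes how the
#' FR contrasts change relative to the full fit: sign changes and
#' significance changes (at the 0.05 level on multiplicity-adjusted p
#' values). A refit that loses an entire FR level is reported as
#' degenerate for the affected contrasts, not an error.
#'
#' @param outputs Whole-rotation output table for one nutrient (and
#'   scenario).
#' @param nutrient Nutrient to fit (passed to [fit_output_model()]).
#' @param time Time (years) at which FR contrasts are compared.
#' @param baseline Baseline FR level for the contrasts.
#' @param seed Seed for the multivariate-t adjustment.
#' @param time_scaling Optional fixed time scaling; by default the *full*
#'   data's maximum is reused for every refit so coefficients stay
#'   comparable.
#' @return A list with `full` (the full-fit contrasts) and `summary` (one
#'   row per held-out site and contrast, with estimates, p values,
#'   `sign_flip`, `significance_flip` and `degenerate` flags).
#' @export
leave_one_site_out <- function(outputs, nutrient = NULL, time = 20,
                               baseline = "1M", seed = 1L,
                               time_scaling = NULL) {
  sites <- unique(outputs$site)
  if (length(sites) < 3) {
    stop("leave-one-site-out needs at least 3 sites", call. = FALSE)
  }
  if (is.null(time_scaling)) time_scaling <- max(outputs$time_since_start)
  full <- fit_output_model(outputs, nutrient = nutrient,
                           time_scaling = time_scaling)
  full_con <- contrast_fr(full, time = time, baseline = baseline, seed = seed)
  rows <- lapply(sites, function(s) {
    sub <- outputs[outputs$site != s, , drop = FALSE]
    lost <- setdiff(full$fr_levels, unique(sub$fr))
    fit_ok <- TRUE
    con <- NULL
    m <- tryCatch(fit_output_model(sub, nutrient = nutrient,
                                   time_scaling = time_scaling),
                  error = function(e) {
                    fit_ok <<- FALSE
                    NULL
                  })
    if (fit_ok && !m$degenerate_fr && baseline %in% m$fr_levels) {
      con <- contrast_fr(m, time = time, baseline = baseline, seed = seed)
    }
    out <- lapply(seq_len(nrow(full_con)), function(i) {
      desc <- full_con$description[i]
      level <- sub("^FR (\\S+) vs.*$", "\\1", desc)
      match_row <- if (!is.null(con)) which(con$description == desc) else integer()
      if (level %in% lost || length(match_row) == 0) {
        tibble::tibble(site_removed = s, description = desc,
                       estimate = NA_real_, p_adj = NA_real_,
                       degenerate = TRUE, sign_flip = NA,
                       significance_flip = NA)
      } else {
        est <- con$estimate[match_row]
        p <- con$p_adj[match_row]
        tibble::tibble(
          site_removed = s, description = desc, estimate = est, p_adj = p,
          degenerate = FALSE,
          sign_flip = sign(est) != sign(full_con$estimate[i]),
          significance_flip = (p < 0.05) != (full_con$p_adj[i] < 0.05)
        )
      }
    })
    dplyr::bind_rows(out)
  })
  list(full = full_con, summary = dplyr::bind_rows(rows))
}
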