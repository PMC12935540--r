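# Test-local fixtures. Conversion factors here are arbitrary test values,
# deliberately independent of the shipped default catalog.

toy_crop_catalog <- function() {
  tibble::tibble(
    crop_name = c("winter_wheat", "spring_barley", "maize_grain", "pea",
                  "oilseed_rape", "sugar_beet", "ley", "fallow"),
    functional_type = c("cereal", "cereal", "cereal", "annual_legume",
                        "annual_broadleaf", "annual_broadleaf", "ley", "fallow"),
    edible = c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, FALSE),
    forage_only = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, FALSE),
    f_h2o = c(0.12, 0.10, 0.11, 0.11, 0, 0, NA, NA),
    alpha = c(0.75, 0.65, 0.8, 1, 0.4, 0.6, NA, NA),
    f_ref = c(1, 1, 1, 1, 1, 1, NA, NA),
    gamma_calorie = c(0.0036, 0.0035, 0.0036, 0.0034, 0.0088, 0.0039, NA, NA),
    gamma_carb = c(0.70, 0.77, 0.76, 0.60, 0, 0.99, NA, NA),
    gamma_protein = c(0.10, 0.10, 0.07, 0.25, 0, 0, NA, NA),
    gamma_fat = c(0.01, 0.01, 0.04, 0.01, 1, 0, NA, NA),
    retail_product = c("flour", "flour", "flour", "dried_peas", "oil",
                       "sugar", "forage", "none")
  )
}

# one site, two groups, replicated yield records for QC tests
toy_yield_table <- function(yields, crop = "winter_wheat", site = "S1",
                            rotation = "R1", year = 2000, note = NA) {
  n <- length(yields)
  tibble::tibble(
    site = site, calendar_year = year, time_since_start = year - 2000,
    rotation_id = rotation, fr = "1M", group = paste0("g", seq_len(n)),
    crop = crop, yield = yields, water_content = 0,
    note = rep(note, n)[seq_len(n)], anomaly = "none"
  )
}

small_sim_config <- function(seed = 1, missing_rate = 0.02, zero_rate = 0.01,
                             ...) {
  sim_config(
    n_sites = 4, years_per_site = 10, groups_per_site = 2,
    missing_rate = missing_rate, zero_rate = zero_rate, seed = seed, ...
  )
}

# one rotation per FR level so the ground-truth intercept per level is
# exact (no within-level heterogeneity warning)
recovery_sim_config <- function(seed = 1, n_sites = 30, years_per_site = 30,
                                residual_sd = 4, site_sd = 6, year_sd = 3,
                                group_sd = 2,
                                fr_effects = c("1M" = 1, "1C" = 1, "2" = 1,
                                               "3" = 1.05),
                                time_linear = c("1M" = -6, "1C" = 3,
                                                "2" = -3, "3" = 5),
                                time_quad = c("1M" = 2, "1C" = 0,
                                              "2" = 0, "3" = -2),
                                ...) {
  sim_config(
    n_sites = n_sites, years_per_site = years_per_site, groups_per_site = 2,
    rotations = rotation_catalog(list(
      M  = "winter_wheat",
      C  = c("winter_wheat", "spring_barley", "oat"),
      R2 = c("winter_wheat", "pea"),
      R3 = c("winter_wheat", "pea", "ley", "ley"))),
    crop_baselines = c(winter_wheat = 6000, spring_barley = 6800,
                       oat = 5410, pea = 3000, ley = 8000),
    fr_effects = fr_effects, time_linear = time_linear, time_quad = time_quad,
    missing_rate = 0, zero_rate = 0,
    site_sd = site_sd, year_sd = year_sd, group_sd = group_sd,
    residual_sd = residual_sd, seed = seed, ...
  )
}

# simulate -> aggregate dry-matter outputs -> fit, for recovery tests
fit_recovery_rep <- function(cfg) {
  tab <- generate_experiment(cfg)
  out <- build_output_table(tab, dry_matter_catalog(), cfg$rotations,
                            scenario = "biofuel", nutrients_wanted = "calorie")
  fit_output_model(out)
}

# map between true_params() names and lmer coefficient names
recovery_coef_map <- function() {
  c("(Intercept)" = "intercept", "t_sc" = "t", "I(t_sc^2)" = "t2",
    "fr1C" = "fr1C", "fr2" = "fr2", "fr3" = "fr3",
    "fr1C:t_sc" = "fr1C:t", "fr2:t_sc" = "fr2:t", "fr3:t_sc" = "fr3:t",
    "fr1C:I(t_sc^2)" = "fr1C:t2", "fr2:I(t_sc^2)" = "fr2:t2",
    "fr3:I(t_sc^2)" = "fr3:t2")
}

# two rotations with identical crops but different FR labels: the null
# configuration for contrast calibration tests
null_sim_config <- function(seed, n_sites = 5, years_per_site = 10) {
  sim_config(
    n_sites = n_sites, years_per_site = years_per_site, groups_per_site = 2,
    rotations = rotation_catalog(list(A = "winter_wheat",
                                      B = "winter_wheat")),
    fr_labels = c(A = "1M", B = "3"),
    crop_baselines = c(winter_wheat = 6000),
    fr_effects = c("1M" = 1, "3" = 1),
    time_linear = c("1M" = 0, "3" = 0),
    time_quad = c("1M" = 0, "3" = 0),
    missing_rate = 0, zero_rate = 0,
    site_sd = 3, year_sd = 2, group_sd = 1, residual_sd = 4,
    staggered_starts = FALSE, seed = seed
  )
}
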