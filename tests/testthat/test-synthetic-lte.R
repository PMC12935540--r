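test_that("generation is deterministic per seed and sensitive to it", {
  cfg <- small_sim_config(seed = 42)
  t1 <- generate_experiment(cfg)
  t2 <- generate_experiment(cfg)
  expect_identical(t1, t2)
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_yield_table(t1, f1); write_yield_table(t2, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  t3 <- generate_experiment(small_sim_config(seed = 43))
  expect_false(identical(t1$yield, t3$yield))
})

test_that("noiseless limit reproduces crop baselines times the FR effect", {
  cfg <- recovery_sim_config(seed = 1, n_sites = 2, years_per_site = 5,
                             site_sd = 0, year_sd = 0, group_sd = 0,
                             residual_sd = 0,
                             time_linear = c("1M" = 0, "1C" = 0, "2" = 0, "3" = 0),
                             time_quad = c("1M" = 0, "1C" = 0, "2" = 0, "3" = 0))
  tab <- generate_experiment(cfg)
  dry <- tab$yield * (1 - tab$water_content)
  expected <- cfg$crop_baselines[tab$crop] *
    cfg$fr_effects[tab$fr]
  is_fallow <- tab$crop == "fallow"
  expect_equal(dry[!is_fallow], unname(expected[!is_fallow]), tolerance = 1e-12)
  expect_true(all(dry[is_fallow] == 0))
})

test_that("anomaly injection hits the configured rates within binomial error", {
  n <- 100000
  tab <- tibble::tibble(
    site = "S", calendar_year = 2000, time_since_start = 0,
    rotation_id = "R", fr = "1M", group = "g1", crop = "winter_wheat",
    yield = 5000, water_content = 0, note = NA_character_, anomaly = "none"
  )[rep(1, n), ]
  out <- inject_anomalies(tab, missing_rate = 0.0228, zero_rate = 0.0092,
                          seed = 99)
  p_miss <- mean(is.na(out$yield))
  p_zero <- mean(!is.na(out$yield) & out$yield == 0)
  se_miss <- sqrt(0.0228 * (1 - 0.0228) / n)
  se_zero <- sqrt(0.0092 * (1 - 0.0092) / n)
  expect_lt(abs(p_miss - 0.0228), 3 * se_miss)
  expect_lt(abs(p_zero - 0.0092), 3 * se_zero)
  expect_equal(nrow(out), n)
  expect_true(all(out$anomaly[is.na(out$yield)] == "injected_missing"))
  expect_true(all(out$anomaly[!is.na(out$yield) & out$yield == 0] == "injected_zero"))
})

test_that("injected anomalies are flagged distinctly from structural fallow zeros", {
  cfg <- small_sim_config(seed = 5, zero_rate = 0.05, missing_rate = 0.05)
  tab <- generate_experiment(cfg)
  fallow <- !is.na(tab$note) & tab$note == "fallow"
  expect_true(all(tab$anomaly[fallow] == "none"))
  expect_true(all(tab$yield[fallow] == 0))
  expect_gt(sum(tab$anomaly == "injected_zero"), 0)
  expect_gt(sum(tab$anomaly == "injected_missing"), 0)
  no_zero <- generate_experiment(small_sim_config(seed = 5, zero_rate = 0,
                                                  missing_rate = 0))
  expect_true(all(no_zero$anomaly == "none"))
})

test_that("yields are never negative, even under extreme noise", {
  cfg <- small_sim_config(seed = 8, residual_sd = 60, site_sd = 40)
  tab <- generate_experiment(cfg)
  expect_true(all(tab$yield >= 0, na.rm = TRUE))
})

test_that("ground-truth parameters map the configuration into the model scale", {
  # equal baseline totals across FR levels and unit FR effects -> zero offsets
  cfg0 <- sim_config(
    n_sites = 2, years_per_site = 5, groups_per_site = 1,
    rotations = rotation_catalog(list(M = "winter_wheat",
                                      C = c("spring_barley", "oat"))),
    crop_baselines = c(winter_wheat = 5000, spring_barley = 5000, oat = 5000),
    fr_effects = c("1M" = 1, "1C" = 1),
    time_linear = c("1M" = 0, "1C" = 0), time_quad = c("1M" = 0, "1C" = 0),
    missing_rate = 0, zero_rate = 0, site_sd = 1.5, year_sd = 1,
    group_sd = 0.5, residual_sd = 1, seed = 1)
  tp0 <- true_params(cfg0)
  expect_equal(unname(tp0$beta["fr1C"]), 0)
  expect_equal(unname(tp0$beta[c("fr1C:t", "fr1C:t2")]), c(0, 0))
  expect_equal(unname(tp0$varcomp["site"]), 1.5^2)
  expect_equal(unname(tp0$varcomp["residual"]), 1)

  # multiplicative FR effect -> sqrt-scale offset, checked by simulation
  cfg <- recovery_sim_config(seed = 21, n_sites = 60, years_per_site = 6,
                             site_sd = 0, year_sd = 0, group_sd = 0,
                             residual_sd = 2,
                             time_linear = c("1M" = 0, "1C" = 0, "2" = 0, "3" = 0),
                             time_quad = c("1M" = 0, "1C" = 0, "2" = 0, "3" = 0))
  tp <- true_params(cfg)
  tab <- generate_experiment(cfg)
  out <- build_output_table(tab, dry_matter_catalog(), cfg$rotations,
                            scenario = "biofuel", nutrients_wanted = "calorie")
  m3 <- mean(sqrt(out$output[out$fr == "3"]))
  m1 <- mean(sqrt(out$output[out$fr == "1M"]))
  n_cell <- sum(out$fr == "3")
  # sampling error of the difference in means of two sqrt-scale samples
  tol <- 3 * sqrt(2 * 2^2 / n_cell)
  expect_lt(abs((m3 - m1) - tp$beta[["fr3"]]), tol)
})

test_that("configs and tables round-trip through YAML and CSV", {
  cfg <- small_sim_config(seed = 17)
  f <- tempfile(fileext = ".yaml")
  write_sim_config(cfg, f)
  cfg2 <- read_sim_config(f)
  expect_equal(cfg2$crop_baselines, cfg$crop_baselines)
  expect_equal(cfg2$seed, cfg$seed)
  expect_identical(generate_experiment(cfg2), generate_experiment(cfg))

  tab <- generate_experiment(cfg)
  fcsv <- tempfile(fileext = ".csv")
  write_yield_table(tab, fcsv)
  tab2 <- read_yield_table(fcsv)
  expect_equal(as.data.frame(tab2), as.data.frame(tab), ignore_attr = TRUE)
})

test_that("invalid configurations are rejected with informative messages", {
  expect_error(small_sim_config(site_sd = -1), "site_sd")
  expect_error(small_sim_config(missing_rate = 1.5), "missing_rate")
  expect_error(sim_config(rotations = rotation_catalog(list(M = "unobtainium")),
                          crop_baselines = c(winter_wheat = 5000)),
               "lack")
})
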