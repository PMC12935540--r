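make_small_fit <- function(seed = 13) {
  cfg <- recovery_sim_config(seed = seed, n_sites = 6, years_per_site = 12)
  fit_recovery_rep(cfg)
}

test_that("near-noise-free data on the sqrt-scale model is recovered to tight tolerance", {
  cfg <- recovery_sim_config(seed = 2, n_sites = 3, years_per_site = 8,
                             site_sd = 0, year_sd = 0, group_sd = 0,
                             residual_sd = 1e-6, staggered_starts = FALSE)
  tp <- true_params(cfg)
  m <- suppressMessages(fit_recovery_rep(cfg))
  est <- m$coefficients[names(recovery_coef_map())]
  expect_equal(unname(est), unname(tp$beta[recovery_coef_map()]),
               tolerance = 1e-4)
})

test_that("negative outputs are rejected before the sqrt transform", {
  cfg <- recovery_sim_config(seed = 3, n_sites = 3, years_per_site = 6)
  tab <- generate_experiment(cfg)
  out <- build_output_table(tab, dry_matter_catalog(), cfg$rotations,
                            scenario = "biofuel", nutrients_wanted = "calorie")
  out$output[5] <- -1
  expect_error(fit_output_model(out), "must be finite and >= 0")
})

test_that("row order does not affect the fit", {
  cfg <- recovery_sim_config(seed = 4, n_sites = 4, years_per_site = 8)
  tab <- generate_experiment(cfg)
  out <- build_output_table(tab, dry_matter_catalog(), cfg$rotations,
                            scenario = "biofuel", nutrients_wanted = "calorie")
  m1 <- fit_output_model(out)
  m2 <- fit_output_model(out[sample(nrow(out)), ])
  expect_equal(m1$coefficients, m2$coefficients, tolerance = 1e-6)
  expect_equal(m1$varcomp, m2$varcomp, tolerance = 1e-6)
})

test_that("back-transformed predictions square the linear predictor", {
  m <- make_small_fit()
  # an intercept-only prediction: zero out everything but beta0 = 3.3
  m0 <- m
  m0$coefficients[] <- 0
  m0$coefficients["(Intercept)"] <- 3.3
  m0$vcov[] <- 0
  m0$varcomp[] <- 0
  p <- predict_outputs(m0, fr = "1M", time = c(0, 5, 11))
  expect_equal(p$predicted, rep(3.3^2, 3))
  expect_equal(p$predicted, rep(10.89, 3))
  expect_equal(p$lower, p$upper)

  # real fit: ordering and non-negativity of interval endpoints
  pr <- predict_outputs(m, fr = m$fr_levels, time = c(0, 5))
  expect_true(all(pr$predicted >= 0))
  expect_true(all(pr$lower <= pr$predicted & pr$predicted <= pr$upper))
  # squaring is monotone for the clamped sqrt-scale bounds
  expect_true(all(sqrt(pr$lower) <= pr$mu_sqrt + 1e-12))

  # the FR 1M prediction at time 0 is the squared intercept
  p0 <- predict_outputs(m, fr = "1M", time = 0)
  expect_equal(p0$predicted, unname(m$coefficients["(Intercept)"]^2),
               tolerance = 1e-10)

  # random-component interval is at least as wide as the fixed-only one
  pf <- predict_outputs(m, fr = "1M", time = 5, include_random = FALSE)
  pa <- predict_outputs(m, fr = "1M", time = 5)
  expect_gte(pa$upper - pa$lower, pf$upper - pf$lower)
  expect_warning(predict_outputs(m, fr = "1M", time = 1e4), "extrapolation")
})

test_that("FR contrasts carry Satterthwaite df and ordered adjusted p values", {
  m <- make_small_fit()
  con <- contrast_fr(m, time = c(5, 10), seed = 7)
  expect_equal(nrow(con), 6)
  expect_true(all(con$df > 0))
  expect_true(all(con$p_adj >= con$p_raw - 1e-10))
  expect_true(all(con$p_raw >= 0 & con$p_adj <= 1))
  # deterministic per seed
  con2 <- contrast_fr(m, time = c(5, 10), seed = 7)
  expect_equal(con$p_adj, con2$p_adj)
  expect_error(contrast_fr(m, time = 5, baseline = "9"), "baseline")
})

test_that("a contrast family of one is unaffected by the multiplicity adjustment", {
  cfg <- null_sim_config(seed = 51)
  m <- fit_recovery_rep(cfg)
  con <- contrast_fr(m, time = 5, seed = 3)
  expect_equal(nrow(con), 1)
  expect_equal(con$p_adj, con$p_raw, tolerance = 1e-6)
})

test_that("time contrasts are zero at the baseline and track strong trends", {
  m <- make_small_fit()
  ct <- contrast_time(m, fr = "3", times = c(0, 10, 20), seed = 5)
  expect_equal(ct$estimate[ct$time == 0], 0)
  expect_true(all(ct$df[ct$time > 0] > 0))
  expect_true(all(ct$p_adj >= ct$p_raw - 1e-10))

  # strong generating trend: the sign of the 20y-0y contrast matches it
  signs <- vapply(1:5, function(r) {
    cfg <- recovery_sim_config(seed = 600 + r, n_sites = 6, years_per_site = 21,
                               time_linear = c("1M" = -6, "1C" = 3,
                                               "2" = -3, "3" = 25),
                               time_quad = c("1M" = 0, "1C" = 0,
                                             "2" = 0, "3" = 0))
    mm <- fit_recovery_rep(cfg)
    sign(contrast_time(mm, fr = "3", times = 20, seed = 1)$estimate)
  }, numeric(1))
  expect_true(all(signs == 1))
})

test_that("marginal and conditional R2 partition the variance", {
  m <- make_small_fit()
  r2 <- r2_marginal_conditional(m)
  expect_true(r2["R2m"] >= 0 && r2["R2m"] <= r2["R2c"] && r2["R2c"] <= 1)

  # all random variances zero -> marginal equals conditional
  m0 <- m
  m0$varcomp[c("site", "group", "year")] <- 0
  r20 <- r2_marginal_conditional(m0)
  expect_equal(unname(r20["R2m"]), unname(r20["R2c"]))

  # no fixed variation -> marginal R2 is (numerically) zero
  mflat <- m
  mflat$coefficients[] <- 0
  mflat$coefficients["(Intercept)"] <- 3
  expect_equal(unname(r2_marginal_conditional(mflat)["R2m"]), 0)
})

test_that("variance partition of simulated data is recovered", {
  cfg <- recovery_sim_config(seed = 77)
  tp <- true_params(cfg)
  m <- fit_recovery_rep(cfg)
  # many-level components are tight; the 30-site component is noisier
  expect_lt(abs(m$varcomp[["residual"]] - tp$varcomp[["residual"]]) /
              tp$varcomp[["residual"]], 0.10)
  expect_lt(abs(m$varcomp[["year"]] - tp$varcomp[["year"]]) /
              tp$varcomp[["year"]], 0.35)
  expect_lt(abs(m$varcomp[["site"]] - tp$varcomp[["site"]]) /
              tp$varcomp[["site"]], 0.60)
  r2 <- r2_marginal_conditional(m)
  expect_gt(r2[["R2c"]], r2[["R2m"]])
})

test_that("prediction intervals for new observations attain nominal coverage", {
  hits <- 0L; n_tot <- 0L
  for (r in 1:6) {
    cfg <- recovery_sim_config(seed = 900 + r, n_sites = 10, years_per_site = 12)
    m <- fit_recovery_rep(cfg)
    cfg_new <- cfg
    cfg_new$seed <- as.integer(7000 + r)
    tab_new <- generate_experiment(cfg_new)
    out_new <- build_output_table(tab_new, dry_matter_catalog(), cfg_new$rotations,
                                  scenario = "biofuel",
                                  nutrients_wanted = "calorie")
    pi_ <- predict_outputs(m, fr = unique(out_new$fr),
                           time = unique(out_new$time_since_start),
                           level = 0.90, include_residual = TRUE)
    key <- paste(pi_$fr, pi_$time)
    okey <- paste(out_new$fr, out_new$time_since_start)
    lo <- pi_$lower[match(okey, key)]
    hi <- pi_$upper[match(okey, key)]
    hits <- hits + sum(out_new$output >= lo & out_new$output <= hi)
    n_tot <- n_tot + nrow(out_new)
  }
  cov <- hits / n_tot
  expect_gt(cov, 0.85)
  expect_lt(cov, 0.95)
})

test_that("fitted models serialize to JSON with everything needed to predict", {
  m <- make_small_fit()
  f <- tempfile(fileext = ".json")
  write_model_json(m, f)
  obj <- jsonlite::read_json(f)
  expect_equal(obj$nutrient, m$nutrient)
  expect_equal(obj$time_scaling, m$time_scaling)
  expect_equal(unlist(obj$coefficients), m$coefficients, tolerance = 1e-12)
  expect_equal(length(obj$vcov), length(m$coefficients))
  expect_true(obj$r2_conditional >= obj$r2_marginal)
})
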