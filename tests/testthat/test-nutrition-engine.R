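test_that("food-crop conversion matches hand arithmetic", {
  prof <- list(crop_name = "winter_wheat", edible = TRUE, forage_only = FALSE,
               f_h2o = 0.12, alpha = 0.75, f_ref = 1.0, gamma_carb = 0.70)
  m <- crop_output(1000, prof, "carbohydrate")
  expect_equal(as.numeric(m), 1000 / 0.88 * 0.75 * 0.70, tolerance = 1e-12)
  expect_equal(round(as.numeric(m), 1), 596.6)
  expect_equal(attr(m, "unit"), "kg/ha/yr")

  expect_equal(as.numeric(crop_output(0, prof, "carbohydrate")), 0)
  prof$gamma_fat <- 0
  expect_equal(as.numeric(crop_output(1000, prof, "fat")), 0)

  ley <- list(crop_name = "ley", edible = FALSE, forage_only = TRUE)
  expect_error(crop_output(1000, ley, "calorie"), "forage")
})

test_that("forage scenarios convert dry matter at the stated product rates", {
  sc <- default_forage_scenarios()
  # 1 kg DM -> 1.05 l whole milk / 0.047 kg boneless beef before the
  # product's own nutrient conversion
  expect_equal(sc$milk$dm_to_product, 1.05)
  expect_equal(sc$beef$dm_to_product, 0.047)
  m_prot <- forage_output(1, sc$milk, "protein")
  expect_equal(as.numeric(m_prot),
               1.05 * sc$milk$product_profile$gamma[["protein"]])
  b_fat <- forage_output(1, sc$beef, "fat")
  expect_equal(as.numeric(b_fat),
               0.047 * sc$beef$product_profile$gamma[["fat"]])
  for (n in c("calorie", "carbohydrate", "protein", "fat")) {
    expect_equal(as.numeric(forage_output(12345, sc$biofuel, n)), 0)
  }
  expect_error(forage_scenario("biofuel", 1, sc$milk$product_profile),
               "biofuel")
})

test_that("whole-rotation aggregation is an area-weighted sum", {
  expect_equal(rotation_output(100, 1), 100)
  expect_equal(rotation_output(c(100, 300), c(0.5, 0.5)), 200)
  expect_equal(rotation_output(2 * c(100, 300), c(0.5, 0.5)), 400)
  expect_error(rotation_output(c(1, 2), c(0.6, 0.6)), "sum to 1")
  expect_error(rotation_output(c(1, 2), 1), "length")
})

test_that("output table has one row per cell and nutrient, with units", {
  cat <- toy_crop_catalog()
  rots <- rotation_catalog(list(M = "winter_wheat",
                                WP = c("winter_wheat", "pea")))
  tab <- dplyr::bind_rows(lapply(2000:2001, function(y) {
    tibble::tibble(
      site = "S1", calendar_year = y, time_since_start = y - 2000,
      rotation_id = c("M", "WP", "WP"), fr = c("1M", "2", "2"),
      group = "g1", crop = c("winter_wheat", "winter_wheat", "pea"),
      yield = c(6000, 6200, 3000), water_content = 0,
      note = NA_character_, anomaly = "none")
  }))
  out <- build_output_table(tab, cat, rots, scenario = "milk")
  expect_equal(nrow(out), 2 * 2 * 4)
  expect_setequal(unique(out$unit[out$nutrient == "calorie"]), "Gcal/ha/yr")
  expect_setequal(unique(out$unit[out$nutrient == "protein"]), "kg/ha/yr")
  expect_true(all(out$output >= 0))

  # hand-check one cell: WP carbohydrate in year 2000
  m_w <- 6200 / (1 - 0.12) * 0.75 * 1 * 0.70
  m_p <- 3000 / (1 - 0.11) * 1 * 1 * 0.60
  o <- out$output[out$rotation_id == "WP" & out$calendar_year == 2000 &
                    out$nutrient == "carbohydrate"]
  expect_equal(o, (m_w + m_p) / 2, tolerance = 1e-12)
})

test_that("only forage-bearing rotations respond to the end-use scenario", {
  cat <- toy_crop_catalog()
  rots <- rotation_catalog(list(M = "winter_wheat",
                                WL = c("winter_wheat", "ley")))
  tab <- tibble::tibble(
    site = "S1", calendar_year = 2000, time_since_start = 0,
    rotation_id = c("M", "WL", "WL"), fr = c("1M", "3", "3"), group = "g1",
    crop = c("winter_wheat", "winter_wheat", "ley"),
    yield = c(6000, 6000, 8000), water_content = 0,
    note = NA_character_, anomaly = "none")
  milk <- build_output_table(tab, cat, rots, scenario = "milk")
  biof <- build_output_table(tab, cat, rots, scenario = "biofuel")
  m_m <- milk[milk$rotation_id == "M", ]
  b_m <- biof[biof$rotation_id == "M", ]
  expect_equal(m_m$output, b_m$output)
  m_wl <- milk[milk$rotation_id == "WL", ]
  b_wl <- biof[biof$rotation_id == "WL", ]
  expect_true(all(m_wl$output > b_wl$output))
  # under biofuel the ley year contributes nothing: WL = half the wheat M
  expect_equal(b_wl$output, b_m$output / 2, tolerance = 1e-12)
})

test_that("fallow years carry weight but contribute zero output", {
  cat <- toy_crop_catalog()
  rots <- rotation_catalog(list(WF = c("winter_wheat", "fallow")))
  tab <- tibble::tibble(
    site = "S1", calendar_year = 2000, time_since_start = 0,
    rotation_id = "WF", fr = "1M", group = "g1",
    crop = c("winter_wheat", "fallow"), yield = c(6000, 0),
    water_content = 0, note = c(NA, "fallow"), anomaly = "none")
  out <- build_output_table(tab, cat, rots, scenario = "milk",
                            nutrients_wanted = "calorie")
  expect_equal(out$output, 6000 / 0.88 * 0.75 * 0.0036 / 2, tolerance = 1e-12)
})

test_that("missing crops in a non-excluded cell and unknown crops are errors", {
  cat <- toy_crop_catalog()
  rots <- rotation_catalog(list(WP = c("winter_wheat", "pea")))
  tab <- tibble::tibble(
    site = "S1", calendar_year = 2000, time_since_start = 0,
    rotation_id = "WP", fr = "2", group = "g1", crop = "winter_wheat",
    yield = 6000, water_content = 0, note = NA_character_, anomaly = "none")
  expect_error(build_output_table(tab, cat, rots), "missing")
  tab2 <- tab
  tab2$crop <- "triffid_weed"
  expect_error(build_output_table(tab2, cat, rots), "triffid_weed")
})

test_that("engine equals an independent arithmetic oracle on randomized factor sets", {
  withr::with_seed(2024, {
    for (rep in 1:20) {
      f_h2o <- runif(2, 0, 0.8)
      alpha <- runif(2, 0.2, 1.2)
      f_ref <- runif(2, 0.5, 1)
      gam <- matrix(runif(8, 0, 1), nrow = 2)
      yields <- runif(2, 500, 9000)
      cat <- tibble::tibble(
        crop_name = c("crop_a", "crop_b"),
        functional_type = c("cereal", "annual_legume"),
        edible = TRUE, forage_only = FALSE,
        f_h2o = f_h2o, alpha = alpha, f_ref = f_ref,
        gamma_calorie = gam[, 1], gamma_carb = gam[, 2],
        gamma_protein = gam[, 3], gamma_fat = gam[, 4],
        retail_product = "x")
      rots <- rotation_catalog(list(R = c("crop_a", "crop_b", "crop_b")))
      tab <- tibble::tibble(
        site = "S", calendar_year = 2000, time_since_start = 0,
        rotation_id = "R", fr = "2", group = "g",
        crop = c("crop_a", "crop_b"), yield = yields, water_content = 0,
        note = NA_character_, anomaly = "none")
      out <- build_output_table(tab, cat, rots, scenario = "milk")
      # oracle: per-crop conversion and area weighting written out longhand
      for (j in seq_along(c("calorie", "carbohydrate", "protein", "fat"))) {
        n <- c("calorie", "carbohydrate", "protein", "fat")[j]
        m_a <- yields[1] * (1 / (1 - f_h2o[1])) * alpha[1] * f_ref[1] * gam[1, j]
        m_b <- yields[2] * (1 / (1 - f_h2o[2])) * alpha[2] * f_ref[2] * gam[2, j]
        oracle <- m_a * (1 / 3) + m_b * (2 / 3)
        expect_equal(out$output[out$nutrient == n], oracle, tolerance = 1e-10)
      }
    }
  })
})
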