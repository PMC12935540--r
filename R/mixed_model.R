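#' Fit the whole-rotation output model for one nutrient
#'
#' Fits, by REML, the linear mixed model of square-root-transformed
#' whole-rotation outputs
#' \deqn{\sqrt{O} = \beta_0 + \beta_t t_s + \beta_{t^2} t_s^2 +
#'   \sum_i \beta_{FR_i} FR_i + \sum_i \beta_{FR_i t} FR_i t_s +
#'   \sum_i \beta_{FR_i t^2} FR_i t_s^2 + b_{site} + b_{group(site)} +
#'   b_{year} + \varepsilon,}
#' with random intercepts for site, group nested in site, and calendar
#' year (a categorical factor crossed with the site structure, absorbing
#' year-specific growing conditions, while time since the start of the
#' experiment enters as a continuous fixed effect). FR 1M (cereal
#' monoculture) is the reference level.
#'
#' Time is divided by `time_scaling` before fitting — by default the
#' maximum observed time since start, so `t_s` spans `[0, 1]` and the time
#' coefficients are per full observed span. The divisor is stored in the
#' fitted object and echoed by every report; coefficient values are not
#' comparable across datasets without it.
#'
#' @param outputs Whole-rotation output table ([build_output_table()]);
#'   may contain several nutrients, in which case `nutrient` selects one.
#' @param nutrient Nutrient to fit (defaults to the single one present).
#' @param time_scaling Divisor applied to `time_since_start`; default
#'   `max(time_since_start)`.
#' @param ref_level Reference FR level, default `"1M"`.
#' @return An object of class `fr_model`: the `lmerTest` fit plus
#'   coefficients, coefficient covariance, variance components
#'   (site, group, year, residual), `time_scaling`, `n_obs`, singularity
#'   and convergence diagnostics.
#' @export
fit_output_model <- function(outputs, nutrient = NULL, time_scaling = NULL,
                             ref_level = "1M") {
  if (!is.null(nutrient)) {
    outputs <- outputs[outputs$nutrient == nutrient, , drop = FALSE]
  } else {
    nn <- unique(outputs$nutrient)
    if (length(nn) != 1) {
      stop("outputs contain several nutrients (",
           paste(nn, collapse = ", "), "); pass `nutrient`", call. = FALSE)
    }
    nutrient <- nn
  }
  if (nrow(outputs) < 10) {
    stop("too few output rows (", nrow(outputs), ") to fit the model",
         call. = FALSE)
  }
  if (any(!is.finite(outputs$output)) || any(outputs$output < 0)) {
    bad <- which(!is.finite(outputs$output) | outputs$output < 0)
    stop("outputs must be finite and >= 0 for the square-root transform; ",
         length(bad), " offending row(s), first at index ", bad[1],
         call. = FALSE)
  }
  if (is.null(time_scaling)) time_scaling <- max(outputs$time_since_start)
  if (time_scaling <= 0) stop("time_scaling must be > 0", call. = FALSE)

  fr_levels <- intersect(c("1M", "1C", "2", "3", "4"), unique(outputs$fr))
  if (!ref_level %in% fr_levels) ref_level <- fr_levels[1]
  fr_levels <- c(ref_level, setdiff(fr_levels, ref_level))
  d <- data.frame(
    sqrt_o = sqrt(outputs$output),
    t_sc = outputs$time_since_start / time_scaling,
    fr = factor(outputs$fr, levels = fr_levels),
    site = factor(outputs$site),
    group_in_site = factor(paste(outputs$site, outputs$group, sep = ":")),
    calendar_year_f = factor(outputs$calendar_year)
  )
  degenerate_fr <- nlevels(droplevels(d$fr)) < 2
  fixed <- if (degenerate_fr) sqrt_o ~ t_sc + I(t_sc^2) else
    sqrt_o ~ fr * (t_sc + I(t_sc^2))
  form <- stats::update(fixed,
                        . ~ . + (1 | site) + (1 | group_in_site) +
                          (1 | calendar_year_f))
  conv_notes <- character()
  fit <- withCallingHandlers(
    tryCatch(
      lmerTest::lmer(form, data = d, REML = TRUE,
                     control = lme4::lmerControl(
                       optimizer = "bobyqa",
                       optCtrl = list(maxfun = 2e5))),
      error = function(e) {
        stop("mixed-model fit failed: ", conditionMessage(e), call. = FALSE)
      }
    ),
    warning = function(w) {
      conv_notes <<- c(conv_notes, conditionMessage(w))
      invokeRestart("muffleWarning")
    }
  )
  singular <- lme4::isSingular(fit)
  if (singular) {
    message("singular fit for nutrient ", nutrient,
            ": one or more variance components estimated at 0")
  }
  vc <- as.data.frame(lme4::VarCorr(fit))
  vget <- function(g) {
    v <- vc$vcov[vc$grp == g]
    if (length(v) == 0) 0 else v
  }
  varcomp <- c(site = vget("site"), group = vget("group_in_site"),
               year = vget("calendar_year_f"), residual = vget("Residual"))
  structure(
    list(fit = fit, nutrient = nutrient,
         scenario = if ("scenario" %in% names(outputs))
           unique(outputs$scenario)[1] else NA_character_,
         coefficients = lme4::fixef(fit),
         vcov = as.matrix(stats::vcov(fit)),
         varcomp = varcomp,
         time_scaling = time_scaling,
         time_range = range(outputs$time_since_start),
         fr_levels = levels(droplevels(d$fr)),
         degenerate_fr = degenerate_fr,
         n_obs = nrow(d),
         singular = singular,
         convergence_notes = conv_notes,
         data = d),
    class = "fr_model"
  )
}

#' @export
#' @method print fr_model
print.fr_model <- function(x, ...) {
  cat("Whole-rotation output model —", x$nutrient,
      if (!is.na(x$scenario)) paste0("(forage use: ", x$scenario, ")"), "\n")
  cat("  sqrt(O) ~ FR * (t + t^2) + (1|site) + (1|group:site) + (1|calendar year)\n")
  cat("  n =", x$n_obs, "; time scaling: t /", x$time_scaling, "years\n")
  if (x$singular) cat("  NOTE: singular fit (variance component(s) at 0)\n")
  print(round(x$coefficients, 4))
  invisible(x)
}

model_matrix_at <- function(model, fr, time) {
  d <- data.frame(t_sc = time / model$time_scaling,
                  fr = factor(fr, levels = levels(model$data$fr)))
  tt <- stats::delete.response(stats::terms(lme4::nobars(stats::formula(model$fit))))
  stats::model.matrix(tt, d)
}

#' Back-transformed model predictions
#'
#' Evaluates the fixed linear predictor \eqn{\mu} on the sqrt scale at the
#' requested FR levels and times, and back-transforms by squaring. The
#' 5-95% interval is formed on the sqrt scale from the fixed-coefficient
#' covariance, optionally widened by the sum of the random-intercept
#' variances (site, group, year) so the interval reflects where a typical
#' site/year/group lies, then its endpoints (clamped at 0) are squared —
#' squaring is monotone for non-negative bounds.
#'
#' @param model An [fit_output_model()] object.
#' @param fr FR label(s).
#' @param time Time(s) since start, in years. Values outside the fitted
#'   range trigger an extrapolation warning.
#' @param level Two-sided coverage of the interval (default 0.90, i.e.
#'   5-95%).
#' @param include_random Include the random-intercept variances in the
#'   interval (default `TRUE`); `FALSE` gives the narrower fixed-only
#'   interval.
#' @param include_residual Also add the residual variance, turning the
#'   interval into a prediction interval for a single new
#'   site-year-group observation (default `FALSE`).
#' @return A tibble with `fr`, `time`, `mu_sqrt`, `se_sqrt`, `predicted`,
#'   `lower`, `upper` (back-transformed units of the fitted nutrient).
#' @export
predict_outputs <- function(model, fr, time, level = 0.90,
                            include_random = TRUE, include_residual = FALSE) {
  stopifnot(inherits(model, "fr_model"))
  grid <- expand.grid(fr = fr, time = time, stringsAsFactors = FALSE)
  if (any(grid$time < model$time_range[1] - 1e-9 |
          grid$time > model$time_range[2] + 1e-9)) {
    warning("prediction outside the fitted time range [",
            model$time_range[1], ", ", model$time_range[2],
            "] is extrapolation", call. = FALSE)
  }
  X <- model_matrix_at(model, grid$fr, grid$time)
  mu <- drop(X %*% model$coefficients)
  v <- rowSums((X %*% model$vcov) * X)
  if (include_random) {
    v <- v + sum(model$varcomp[c("site", "group", "year")])
  }
  if (include_residual) {
    v <- v + model$varcomp[["residual"]]
  }
  se <- sqrt(v)
  z <- stats::qnorm(1 - (1 - level) / 2)
  tibble::tibble(
    fr = grid$fr, time = grid$time,
    mu_sqrt = mu, se_sqrt = se,
    predicted = pmax(0, mu)^2,
    lower = pmax(0, mu - z * se)^2,
    upper = pmax(0, mu + z * se)^2
  )
}

emmeans_at <- function(model, t_times, seed) {
  emmeans::emmeans(
    model$fit, ~ fr | t_sc,
    at = list(t_sc = t_times / model$time_scaling),
    lmer.df = "satterthwaite", lmerTest.limit = model$n_obs + 1,
    data = model$data
  )
}

contrast_summary <- function(con, seed, description) {
  raw <- as.data.frame(summary(con, adjust = "none"))
  adj <- withr::with_seed(as.integer(seed),
                          as.data.frame(summary(con, adjust = "mvt")))
  tibble::tibble(
    description = description,
    estimate = raw$estimate, se = raw$SE, df = raw$df,
    t_ratio = raw$t.ratio %||% raw$z.ratio,
    p_raw = raw$p.value, p_adj = adj$p.value
  )
}

#' Contrasts across FR levels at fixed times
#'
#' Square-root-scale contrasts of each FR level against the baseline
#' (default the cereal monoculture, 1M) at the same time, with
#' Satterthwaite degrees of freedom and two-sided p values adjusted for
#' multiplicity over the contrast family using the equicoordinate
#' multivariate t distribution (Monte-Carlo evaluated; deterministic for a
#' given `seed`).
#'
#' @param model An `fr_model`.
#' @param time Time(s) since start (years) at which to compare.
#' @param baseline Baseline FR label.
#' @param seed Seed for the multivariate-t integration.
#' @return A tibble of contrasts: `description`, `estimate` (sqrt scale),
#'   `se`, `df`, `t_ratio`, `p_raw`, `p_adj` (with `p_adj >= p_raw`).
#' @export
contrast_fr <- function(model, time, baseline = "1M", seed = 1L) {
  stopifnot(inherits(model, "fr_model"))
  if (model$degenerate_fr) {
    stop("model has a single FR level; FR contrasts are degenerate",
         call. = FALSE)
  }
  if (!baseline %in% model$fr_levels) {
    stop("baseline FR level ", baseline, " not in the fitted data",
         call. = FALSE)
  }
  out <- lapply(time, function(tt) {
    em <- emmeans_at(model, tt, seed)
    con <- emmeans::contrast(em, "trt.vs.ctrl",
                             ref = which(model$fr_levels == baseline))
    others <- setdiff(model$fr_levels, baseline)
    res <- contrast_summary(con, seed,
                            sprintf("FR %s vs FR %s @ %gy", others, baseline, tt))
    res$time <- tt
    res
  })
  dplyr::bind_rows(out)
}

#' Contrasts across time within an FR level
#'
#' Compares each requested time against `baseline_time` within one FR
#' level, on the sqrt scale, with the same Satterthwaite and
#' multivariate-t machinery as [contrast_fr()].
#'
#' @inheritParams contrast_fr
#' @param fr FR label within which to compare.
#' @param times Times (years) to compare against the baseline time.
#' @param baseline_time Reference time, default 0.
#' @export
contrast_time <- function(model, fr, times, baseline_time = 0, seed = 1L) {
  stopifnot(inherits(model, "fr_model"))
  if (!fr %in% model$fr_levels) {
    stop("FR level ", fr, " not in the fitted data", call. = FALSE)
  }
  t_other <- times[times != baseline_time]
  res <- NULL
  if (length(t_other) > 0) {
    t_all <- c(baseline_time, t_other)
    em <- emmeans::emmeans(
      model$fit, ~ t_sc | fr,
      at = list(t_sc = t_all / model$time_scaling, fr = fr),
      lmer.df = "satterthwaite", lmerTest.limit = model$n_obs + 1,
      data = model$data
    )
    con <- emmeans::contrast(em, "trt.vs.ctrl", ref = 1)
    res <- contrast_summary(con, seed,
                            sprintf("FR %s @ %gy vs @ %gy", fr, t_other,
                                    baseline_time))
    res$time <- t_other
  }
  if (any(times == baseline_time)) {
    # contrasting a time against itself is identically zero
    res <- dplyr::bind_rows(res, tibble::tibble(
      description = sprintf("FR %s @ %gy vs @ %gy", fr, baseline_time,
                            baseline_time),
      estimate = 0, se = 0, df = NA_real_, t_ratio = NA_real_,
      p_raw = 1, p_adj = 1, time = baseline_time
    ))
  }
  res$fr <- fr
  res
}

#' Marginal and conditional R-squared
#'
#' Variance-partition coefficients of determination for mixed models: the
#' marginal R2 is the share of total variance explained by the fixed
#' effects alone,
#' \eqn{R^2_m = \sigma^2_f / (\sigma^2_f + \sum_k \sigma^2_k + \sigma^2_e)},
#' where \eqn{\sigma^2_f} is the variance of the fitted fixed predictor
#' and \eqn{\sigma^2_k} the random-intercept variances; the conditional R2
#' adds the random components to the numerator.
#'
#' @param model An `fr_model`.
#' @return Named numeric vector `c(R2m, R2c)` with
#'   `0 <= R2m <= R2c <= 1`.
#' @export
r2_marginal_conditional <- function(model) {
  stopifnot(inherits(model, "fr_model"))
  X <- stats::model.matrix(model$fit)
  var_f <- stats::var(drop(X %*% model$coefficients))
  var_r <- sum(model$varcomp[c("site", "group", "year")])
  var_e <- model$varcomp[["residual"]]
  tot <- var_f + var_r + var_e
  c(R2m = var_f / tot, R2c = (var_f + var_r) / tot)
}

#' Serialize a fitted model to JSON
#'
#' Writes coefficients, their covariance, variance components, the time
#' scaling divisor, sample size and diagnostics — everything needed to
#' reconstruct predictions without the R object.
#'
#' @param model An `fr_model`.
#' @param path Output path.
#' @export
write_model_json <- function(model, path) {
  r2 <- r2_marginal_conditional(model)
  obj <- list(
    nutrient = model$nutrient, scenario = model$scenario,
    coefficients = as.list(model$coefficients),
    vcov = model$vcov,
    varcomp = as.list(model$varcomp),
    time_scaling = model$time_scaling,
    time_range = model$time_range,
    fr_levels = model$fr_levels,
    n_obs = model$n_obs, singular = model$singular,
    r2_marginal = unname(r2["R2m"]), r2_conditional = unname(r2["R2c"])
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Plot back-transformed model predictions
#'
#' @param model An `fr_model`.
#' @param times Times (years) at which to show predictions.
#' @inheritParams predict_outputs
#' @return A ggplot object.
#' @export
plot_predictions <- function(model, times = c(5, 10, 20), level = 0.90,
                             include_random = TRUE) {
  pred <- predict_outputs(model, fr = model$fr_levels, time = times,
                          level = level, include_random = include_random)
  ggplot2::ggplot(pred, ggplot2::aes(x = .data$fr, y = .data$predicted,
                                     colour = factor(.data$time))) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$lower,
                                          ymax = .data$upper),
                             position = ggplot2::position_dodge(width = 0.4)) +
    ggplot2::labs(x = "Functional richness", colour = "Years since start",
                  y = paste0(model$nutrient, " output (",
                             nutrient_unit(model$nutrient), ")")) +
    ggplot2::theme_minimal()
}
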