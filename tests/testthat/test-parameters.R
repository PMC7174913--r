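# Configuration defaults, validation and YAML round-trips.

test_that("default configuration reproduces the published input table", {
  cfg <- default_parameters()
  expect_s3_class(cfg, "dm_config")
  expect_silent(validate_config(cfg))

  # onset and economics
  expect_equal(cfg$onset$control, list(alpha = 0.177, beta = 0.8551))
  expect_equal(cfg$onset$lifestyle, list(alpha = 0.0749, beta = 0.96))
  expect_equal(param_value(cfg$onset$hr_lifestyle), 0.55)
  expect_equal(cfg$onset$hr_lifestyle$low, 0.40)
  expect_equal(cfg$onset$hr_lifestyle$high, 0.76)
  expect_equal(cfg$economics$discount_rate, 0.05)
  expect_equal(cfg$economics$wtp_threshold, 10276)
  expect_equal(cfg$economics$start_age, 45L)

  # relative risks, diabetic vs non-diabetic
  rr <- vapply(cfg$relative_risks, param_value, numeric(1))
  expect_equal(unname(rr[c("mi", "stroke", "cvd_death", "chf", "blindness",
                           "neuropathy", "esrd")]),
               c(2.00, 2.27, 2.38, 2.50, 1.43, 4.60, 2.38))

  # costs (2019 US$)
  costs <- cfg$costs
  expect_equal(param_value(costs$lifestyle_annual), 134.0)
  expect_equal(costs$lifestyle_annual$low, 43.8)
  expect_equal(costs$lifestyle_annual$high, 611.6)
  expect_equal(vapply(costs$antidiabetic_daily, param_value, numeric(1)),
               c(band1 = 0.5, band2 = 0.8, band3 = 1.2, band4 = 1.8))
  flat <- c(mi_event = 6955.0, mi_annual = 429.0, stroke_event = 2708.6,
            stroke_annual = 477.5, chf_annual = 1420.3, esrd_annual = 13003.0,
            blindness_annual = 1546.8, neuropathy_monthly = 57.4,
            dfu_uncomplicated_event = 71.7, dfu_complicated_event = 2160.3,
            minor_amputation_event = 3124.6, major_amputation_event = 4728.3,
            major_amputation_monthly = 318.5, severe_hypoglycemia_event = 534.4)
  for (nm in names(flat))
    expect_equal(param_value(costs[[nm]]), unname(flat[nm]), label = nm)

  # utilities
  expect_equal(param_value(cfg$utilities$base_t2dm), 0.876)
  expect_equal(param_value(cfg$utilities$prediabetes), 1.0)
  dec <- vapply(cfg$utilities$decrements, param_value, numeric(1))
  expect_equal(unname(dec[c("mi_hospitalization", "mi", "stroke_hospitalization",
                            "stroke", "chf", "esrd", "blindness", "neuropathy",
                            "dfu_uncomplicated", "dfu_complicated",
                            "minor_amputation", "major_amputation")]),
               c(1.000, 0.236, 1.000, 0.326, 0.236, 0.400, 0.157, 0.185,
                 0.250, 0.300, 0.320, 0.380))

  # distribution family assignments
  expect_equal(cfg$onset$hr_lifestyle$family, "normal")
  expect_equal(cfg$relative_risks$mi$family, "normal")
  expect_equal(cfg$costs$mi_event$family, "triangle")
  expect_equal(cfg$utilities$base_t2dm$family, "beta")
})

test_that("dist_spec defaults ranges to 75-125% and se to 25% of base", {
  s <- dist_spec(100)
  expect_equal(s$low, 75)
  expect_equal(s$high, 125)
  expect_equal(s$se, 25)
  s2 <- dist_spec(0.55, 0.40, 0.76, "normal")
  expect_equal(s2$se, (0.76 - 0.40) / (2 * 1.96))
  expect_error(dist_spec(1, low = 2, high = 3), "low <= base <= high")
})

test_that("annualize_daily_cost multiplies by 365 and rejects negatives", {
  expect_equal(annualize_daily_cost(0.5), 182.5)
  expect_equal(annualize_daily_cost(0), 0)
  expect_equal(annualize_daily_cost(1.8), 657.0)
  expect_error(annualize_daily_cost(-1), "non-negative")
})

test_that("config survives a YAML round-trip and the file is byte-stable", {
  cfg <- default_parameters()
  f1 <- withr::local_tempfile(fileext = ".yaml")
  f2 <- withr::local_tempfile(fileext = ".yaml")
  save_config(cfg, f1)
  back <- load_config(f1)
  expect_equal(back, cfg)
  save_config(back, f2)
  expect_identical(readLines(f1), readLines(f2))

  # an embedded life table round-trips too
  toy <- toy_model_config()
  f3 <- withr::local_tempfile(fileext = ".yaml")
  save_config(toy, f3)
  toy2 <- load_config(f3)
  expect_equal(toy2$life_table, toy$life_table)
  expect_equal(run_cohort(toy2, "lifestyle")$ly, 1.75)
})

test_that("validation names the offending fields", {
  cfg <- default_parameters()
  cfg$costs$mi_event$base <- -5
  cfg$costs$mi_event$low <- -5
  expect_error(validate_config(cfg), "costs.mi_event")

  cfg <- default_parameters()
  cfg$utilities <- NULL
  expect_error(validate_config(cfg), "missing section.*utilities")

  cfg <- default_parameters()
  cfg$drift <- list(not_a_covariate = 1)
  expect_error(validate_config(cfg), "not_a_covariate")

  cfg <- default_parameters()
  cfg$economics$horizon_age <- 40L
  expect_error(validate_config(cfg), "horizon_age")
})

test_that("unknown config keys are rejected by name on load", {
  cfg <- default_parameters()
  f <- withr::local_tempfile(fileext = ".yaml")
  save_config(cfg, f)
  txt <- readLines(f)
  writeLines(c(txt, "mystery_section: 3"), f)
  expect_error(load_config(f), "mystery_section")
  expect_error(load_config("/nonexistent/config.yaml"), "not found")

  # but optional risk-equation covariates extend the profile freely
  cfg2 <- default_parameters()
  cfg2$profile$hba1c <- 6.2
  f2 <- withr::local_tempfile(fileext = ".yaml")
  save_config(cfg2, f2)
  expect_equal(load_config(f2)$profile$hba1c, 6.2)
})

test_that("single-field perturbations violating invariants are rejected", {
  perturb <- list(
    function(c) { c$economics$discount_rate <- 1.2; c },
    function(c) { c$onset$control$alpha <- -1; c },
    function(c) { c$onset$hr_lifestyle$base <- 2.5; c$onset$hr_lifestyle$high <- 3; c },
    function(c) { c$utilities$decrements$chf$base <- 1.4; c$utilities$decrements$chf$high <- 2; c },
    function(c) { c$hazards$mi <- -0.01; c },
    function(c) { c$mortality$m_dm <- 0; c }
  )
  for (p in perturb) expect_error(validate_config(p(default_parameters())))
})

test_that("bundled life table is demographically sound", {
  lt <- default_life_table()
  expect_equal(lt$age, 0:100)
  expect_true(all(lt$qx >= 0 & lt$qx <= 1))
  expect_equal(lt$qx[101], 1)
  # qx non-decreasing from age 30 on
  expect_true(all(diff(lt$qx[lt$age >= 30]) >= 0))
  # remaining life expectancy at 45 in a plausible band for China 2009
  alive <- 1; e45 <- 0
  for (x in 45:100) { e45 <- e45 + alive; alive <- alive * (1 - lt$qx[x + 1]) }
  expect_gt(e45, 30)
  expect_lt(e45, 36)
})
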