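# Model configuration: typed parameter set, defaults, validation, YAML i/o.

#' Distribution specification for an uncertain parameter
#'
#' Wraps a base-case value together with its one-way range and the
#' distribution family used in probabilistic sensitivity analysis.
#' When no range is reported, the one-way range defaults to 75--125% of the
#' base value and the PSA standard error to 25% of the base value.
#'
#' @param base Base-case value.
#' @param low,high Range endpoints. Default `0.75*base` / `1.25*base`.
#' @param family One of `"beta"`, `"triangle"`, `"normal"`, `"fixed"`.
#'   Convention: probabilities/proportions/utilities are beta, costs are
#'   triangular (mode at the base value), hazard and relative risks are
#'   normal truncated at zero.
#' @param se Standard error for the sampling distribution. Default
#'   `(high - low)/(2 * 1.96)` when a range is given, else `0.25 * base`.
#' @return A list with elements `family`, `base`, `low`, `high`, `se`.
#' @export
dist_spec <- function(base, low = NULL, high = NULL,
                      family = c("triangle", "beta", "normal", "fixed"),
                      se = NULL) {
  family <- match.arg(family)
  stopifnot(is.numeric(base), length(base) == 1L, is.finite(base))
  had_range <- !is.null(low) && !is.null(high)
  if (is.null(low))  low  <- if (base >= 0) 0.75 * base else 1.25 * base
  if (is.null(high)) high <- if (base >= 0) 1.25 * base else 0.75 * base
  if (low > base || base > high)
    stop("dist_spec: need low <= base <= high, got (", low, ", ", base, ", ",
         high, ")", call. = FALSE)
  if (is.null(se))
    se <- if (had_range) (high - low) / (2 * 1.96) else 0.25 * abs(base)
  list(family = family, base = base, low = low, high = high, se = se)
}

is_dist_spec <- function(x) {
  is.list(x) && all(c("family", "base", "low", "high", "se") %in% names(x))
}

#' Base-case value of a parameter
#'
#' Returns `x$base` for a distribution specification and `x` itself for a
#' plain number, so config fields can hold either.
#' @param x Parameter (number or [dist_spec()]).
#' @export
param_value <- function(x) {
  if (is_dist_spec(x)) x$base else x
}

# Registry of the complication submodels. kind "event_state": acute event
# (per-event cost, optional acute decrement) entering an absorbing post-state;
# "state": absorbing state with annual cost/decrement; "event": recurrent
# cost-only or one-cycle-decrement event. rr = NA means diabetes-specific
# (no incidence among non-diabetics).
complication_registry <- function() {
  data.frame(
    name = c("mi", "stroke", "chf", "esrd", "blindness", "neuropathy",
             "minor_amputation", "major_amputation",
             "dfu_uncomplicated", "dfu_complicated"),
    kind = c("event_state", "event_state", "state", "state", "state", "state",
             "event_state", "event_state", "event", "event"),
    rr = c("mi", "stroke", "chf", "esrd", "blindness", "neuropathy",
           NA, NA, NA, NA),
    stringsAsFactors = FALSE
  )
}

absorbing_complications <- function() {
  reg <- complication_registry()
  reg$name[reg$kind %in% c("event_state", "state")]
}

recurrent_events <- function() {
  reg <- complication_registry()
  c(reg$name[reg$kind == "event"], "severe_hypoglycemia")
}

#' Default model configuration
#'
#' Returns the complete base-case parameter set of the lifetime
#' cost-effectiveness model: Weibull onset parameters fitted to the Da Qing
#' 23-year Kaplan-Meier curves for each arm, relative risks of complications
#' for diabetic versus non-diabetic subjects, unit costs in 2019 US$,
#' utility weights and decrements, economic settings (5% annual discounting,
#' willingness-to-pay threshold $10,276/QALY = China's 2019 per-capita GDP),
#' and the calibratable complication hazards and diabetic mortality
#' multiplier.
#'
#' @return An object of class `dm_config`.
#' @examples
#' cfg <- default_parameters()
#' param_value(cfg$costs$lifestyle_annual)  # 134
#' @export
default_parameters <- function() {
  ds <- dist_spec
  cfg <- list(
    schema_version = 1L,
    economics = list(
      discount_rate = 0.05,
      wtp_threshold = 10276,
      start_age = 45L,
      horizon_age = 100L
    ),
    # Mean baseline profile of the modelled IGT cohort (Da Qing-like).
    profile = list(
      age = 45, male_fraction = 0.54, bmi = 25.8, sbp = 132.9, dbp = 87.6,
      fpg = 5.57, smoker_fraction = 0.412
    ),
    onset = list(
      control   = list(alpha = 0.177,  beta = 0.8551),
      lifestyle = list(alpha = 0.0749, beta = 0.96),
      # HR of diabetes, lifestyle vs none; used by sensitivity analyses.
      hr_lifestyle = ds(0.55, 0.40, 0.76, "normal"),
      hazard_scale = 1.0
    ),
    relative_risks = list(
      mi         = ds(2.00, 1.83, 2.19, "normal"),
      stroke     = ds(2.27, 1.95, 2.65, "normal"),
      cvd_death  = ds(2.38, 1.45, 3.92, "normal"),  # inert: CVD death not a counted outcome
      chf        = ds(2.50, 2.30, 2.70, "normal"),
      blindness  = ds(1.43, 1.04, 2.32, "normal"),
      neuropathy = ds(4.60, 3.18, 6.02, "normal"),
      esrd       = ds(2.38, 1.45, 3.92, "normal")
    ),
    costs = list(
      lifestyle_annual = ds(134.0, 43.8, 611.6, "triangle"),
      antidiabetic_daily = list(
        band1 = ds(0.5, 0.1, 1.2, "triangle"),  # disease duration [0, 3) years
        band2 = ds(0.8, 0.1, 1.6, "triangle"),  # [3, 6)
        band3 = ds(1.2, 0.3, 2.3, "triangle"),  # [6, 10)
        band4 = ds(1.8, 0.7, 3.0, "triangle")   # [10, Inf)
      ),
      mi_event                 = ds(6955.0, 6128, 7782, "triangle"),
      mi_annual                = ds(429.0, 271.9, 586.1, "triangle"),
      stroke_event             = ds(2708.6, 2058, 4463.6, "triangle"),
      stroke_annual            = ds(477.5, 420.1, 780, "triangle"),
      chf_annual               = ds(1420.3, 1181.9, 2479.7, "triangle"),
      esrd_annual              = ds(13003.0, 12391.3, 13724.6, "triangle"),
      blindness_annual         = ds(1546.8, 1347.5, 1746, "triangle"),
      neuropathy_monthly       = ds(57.4, 24.7, 95.5, "triangle"),
      dfu_uncomplicated_event  = ds(71.7, 0, 213, "triangle"),
      dfu_complicated_event    = ds(2160.3, 1157.2, 2713.8, "triangle"),
      minor_amputation_event   = ds(3124.6, 2039.7, 4746.8, "triangle"),
      major_amputation_event   = ds(4728.3, 2808.3, 7289.6, "triangle"),
      major_amputation_monthly = ds(318.5, 0, 565.9, "triangle"),
      severe_hypoglycemia_event = ds(534.4, 400.8, 667.9, "triangle")
    ),
    utilities = list(
      base_t2dm   = ds(0.876, 0.736, 1, "beta"),
      prediabetes = 1.0,
      decrements = list(
        # Acute hospitalisation decrements apply for one month (prorated 1/12
        # within the incident cycle); both endpoints stored as printed.
        mi_hospitalization     = ds(1.000, 0.236, 1, "beta"),
        mi                     = ds(0.236, 0.026, 0.446, "beta"),
        stroke_hospitalization = ds(1.000, 0.326, 1, "beta"),
        stroke                 = ds(0.326, 0.036, 0.616, "beta"),
        chf                    = ds(0.236, 0.026, 0.446, "beta"),
        esrd                   = ds(0.400, 0.19, 0.61, "beta"),
        blindness              = ds(0.157, 0.007, 0.307, "beta"),
        neuropathy             = ds(0.185, 0.015, 0.355, "beta"),
        dfu_uncomplicated      = ds(0.250, 0.213, 0.287, "beta"),
        dfu_complicated        = ds(0.300, 0.165, 0.435, "beta"),
        minor_amputation       = ds(0.320, 0.204, 0.436, "beta"),
        major_amputation       = ds(0.380, 0.264, 0.496, "beta")
      )
    ),
    # Annual hazards of each complication among diabetics, referenced to the
    # cohort entry age; the engine scales them by
    # exp(hazard_age_gradient * (age - start_age)), so lifetime risk rises
    # with age (doubling per decade at the default gradient).
    # Order-of-magnitude starting values; resolved by calibrate_all() against
    # the published control-arm cumulative incidences.
    hazards = list(
      mi = 0.0006, stroke = 0.0015, chf = 0.0008, esrd = 0.00025,
      blindness = 0.0003, neuropathy = 0.0013,
      minor_amputation = 0.0008, major_amputation = 0.0006,
      dfu_uncomplicated = 0.005, dfu_complicated = 0.00125,
      severe_hypoglycemia = 0
    ),
    mortality = list(
      m_dm = 1.6,             # all-cause mortality multiplier, diabetic vs life table
      mult_nondiabetic = 1.0,
      chf_extra = 1.0,        # optional extra multipliers on diabetic mortality
      esrd_extra = 1.0
    ),
    case_fatality = list(mi = 0, stroke = 0),
    program = list(lifestyle_years = 6L),  # annual program cost charged while non-diabetic
    drift = list(),          # per-year additive drift on profile covariates
    risk_equations = list(), # optional per-complication log-link risk equations
    options = list(
      half_cycle_correction = FALSE,
      utility_combine = "additive",
      amputation_ulcer_coupling = 0,
      # per-year log-hazard age gradient for complications; ln(2)/10 means
      # incidence doubles per decade of age. 0 gives constant hazards.
      hazard_age_gradient = log(2) / 10
    ),
    life_table = NULL        # optional inline life table (age, qx); else bundled fixture
  )
  structure(cfg, class = "dm_config")
}

#' Annualize a daily cost
#'
#' @param cost_per_day Cost in US$/day, non-negative.
#' @return Cost in US$/year (`cost_per_day * 365`).
#' @export
annualize_daily_cost <- function(cost_per_day) {
  if (any(cost_per_day < 0)) stop("cost_per_day must be non-negative", call. = FALSE)
  cost_per_day * 365
}

# ---- validation -------------------------------------------------------------

check_spec_range <- function(x, field, lo = -Inf, hi = Inf, problems) {
  v <- param_value(x)
  if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
    return(c(problems, sprintf("%s: not a finite number", field)))
  }
  if (v < lo || v > hi)
    problems <- c(problems, sprintf("%s: value %g outside [%g, %g]", field, v, lo, hi))
  if (is_dist_spec(x)) {
    if (x$low > x$base || x$base > x$high)
      problems <- c(problems, sprintf("%s: range does not satisfy low <= base <= high", field))
  }
  problems
}

#' Validate a model configuration
#'
#' Checks every structural and numeric invariant of the configuration and
#' stops with a message listing all offending fields.
#'
#' @param config A `dm_config` object.
#' @return Invisibly `TRUE` if valid.
#' @export
validate_config <- function(config) {
  p <- character(0)
  need <- setdiff(names(default_parameters()), "life_table")
  missing <- setdiff(need, names(config))
  if (length(missing))
    stop("config is missing section(s): ", paste(missing, collapse = ", "),
         call. = FALSE)

  ec <- config$economics
  if (ec$discount_rate < 0 || ec$discount_rate >= 1)
    p <- c(p, "economics.discount_rate: must be in [0, 1)")
  if (ec$wtp_threshold <= 0) p <- c(p, "economics.wtp_threshold: must be > 0")
  if (ec$horizon_age <= ec$start_age)
    p <- c(p, "economics.horizon_age: must exceed start_age")

  for (arm in c("control", "lifestyle")) {
    w <- config$onset[[arm]]
    if (is.null(w) || w$alpha <= 0 || w$beta <= 0)
      p <- c(p, sprintf("onset.%s: alpha and beta must be > 0", arm))
  }
  hr <- param_value(config$onset$hr_lifestyle)
  if (hr <= 0 || hr >= 2) p <- c(p, "onset.hr_lifestyle: must be in (0, 2)")
  if (config$onset$hazard_scale < 0) p <- c(p, "onset.hazard_scale: must be >= 0")

  for (nm in names(config$relative_risks))
    p <- check_spec_range(config$relative_risks[[nm]],
                          paste0("relative_risks.", nm), lo = 1e-12, problems = p)

  flat_costs <- c(config$costs[setdiff(names(config$costs), "antidiabetic_daily")],
                  stats::setNames(config$costs$antidiabetic_daily,
                    paste0("antidiabetic_daily.", names(config$costs$antidiabetic_daily))))
  for (nm in names(flat_costs))
    p <- check_spec_range(flat_costs[[nm]], paste0("costs.", nm), lo = 0, problems = p)

  p <- check_spec_range(config$utilities$base_t2dm, "utilities.base_t2dm", 0, 1, p)
  p <- check_spec_range(config$utilities$prediabetes, "utilities.prediabetes", 0, 1, p)
  for (nm in names(config$utilities$decrements))
    p <- check_spec_range(config$utilities$decrements[[nm]],
                          paste0("utilities.decrements.", nm), 0, 1, p)

  for (nm in names(config$hazards))
    p <- check_spec_range(config$hazards[[nm]], paste0("hazards.", nm), lo = 0, problems = p)
  for (nm in names(config$case_fatality))
    p <- check_spec_range(config$case_fatality[[nm]],
                          paste0("case_fatality.", nm), 0, 1, p)

  if (param_value(config$mortality$m_dm) <= 0) p <- c(p, "mortality.m_dm: must be > 0")
  if (config$mortality$mult_nondiabetic <= 0) p <- c(p, "mortality.mult_nondiabetic: must be > 0")
  if (config$program$lifestyle_years < 0) p <- c(p, "program.lifestyle_years: must be >= 0")

  bad_drift <- setdiff(names(config$drift), names(config$profile))
  if (length(bad_drift))
    p <- c(p, paste0("drift: unmodelled covariate(s): ", paste(bad_drift, collapse = ", ")))

  pf <- config$profile
  if (pf$age < 18 || pf$age > 100) p <- c(p, "profile.age: must be in [18, 100]")
  for (nm in c("male_fraction", "smoker_fraction"))
    if (pf[[nm]] < 0 || pf[[nm]] > 1) p <- c(p, sprintf("profile.%s: must be in [0, 1]", nm))

  if (!is.null(config$life_table)) p <- c(p, validate_life_table(config$life_table))

  if (length(p))
    stop("invalid configuration:\n  - ", paste(p, collapse = "\n  - "), call. = FALSE)
  invisible(TRUE)
}

validate_life_table <- function(lt) {
  p <- character(0)
  lt <- as.data.frame(lt)
  if (!all(c("age", "qx") %in% names(lt))) {
    return("life_table: needs columns age, qx")
  }
  if (any(lt$qx < 0 | lt$qx > 1)) p <- c(p, "life_table: qx outside [0, 1]")
  if (any(diff(lt$age) != 1)) p <- c(p, "life_table: ages not contiguous")
  if (lt$qx[nrow(lt)] != 1) p <- c(p, "life_table: terminal qx must be 1")
  p
}

# ---- i/o --------------------------------------------------------------------

# unclass recursively so yaml output is stable plain lists
strip_config <- function(x) {
  if (is.list(x)) {
    x <- lapply(x, strip_config)
  }
  if (is.data.frame(x)) x <- as.list(x)
  unclass(x)
}

#' Write a configuration to a YAML file
#'
#' The written file round-trips through [load_config()] and is byte-stable
#' under repeated save/load cycles.
#' @param config A `dm_config`.
#' @param path Output file path.
#' @export
save_config <- function(config, path) {
  validate_config(config)
  out <- strip_config(config)
  if (!is.null(config$life_table))
    out$life_table <- lapply(as.data.frame(config$life_table), as.vector)
  yaml::write_yaml(out, path, precision = 12L)
  invisible(path)
}

#' Read and validate a configuration file
#'
#' Parses the YAML configuration, rejects unknown keys by name, coerces the
#' distribution specifications, and runs [validate_config()].
#' @param path Path to a YAML configuration written by [save_config()].
#' @return A `dm_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- tryCatch(
    yaml::read_yaml(path),
    error = function(e) stop("could not parse config ", path, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  template <- strip_config(default_parameters())
  check_unknown_keys(raw, template, "")
  if (!is.null(raw$life_table))
    raw$life_table <- as.data.frame(raw$life_table)
  cfg <- structure(raw, class = "dm_config")
  validate_config(cfg)
  cfg
}

# sections with free-form names are not key-checked below this level
# (profile admits optional risk-equation covariates such as HbA1c)
FREE_SECTIONS <- c("drift", "risk_equations", "life_table", "profile")

check_unknown_keys <- function(x, template, prefix) {
  if (!is.list(x) || !is.list(template) || is_dist_spec(template)) return(invisible())
  unknown <- setdiff(names(x), names(template))
  if (length(unknown))
    stop("unknown config key(s): ",
         paste0(sub("^\\.", "", paste0(prefix, ".", unknown)), collapse = ", "),
         call. = FALSE)
  for (nm in names(x)) {
    if (nm %in% FREE_SECTIONS) next
    check_unknown_keys(x[[nm]], template[[nm]], paste0(prefix, ".", nm))
  }
  invisible()
}

#' @export
print.dm_config <- function(x, ...) {
  ec <- x$economics
  cat("<dm_config> lifetime diabetes-prevention model configuration\n")
  cat(sprintf("  ages %d-%d, discount %.1f%%, WTP $%s/QALY\n",
              ec$start_age, ec$horizon_age, 100 * ec$discount_rate,
              format(ec$wtp_threshold, big.mark = ",")))
  cat(sprintf("  onset: control Weibull(alpha=%.4g, beta=%.4g); lifestyle Weibull(alpha=%.4g, beta=%.4g)\n",
              x$onset$control$alpha, x$onset$control$beta,
              x$onset$lifestyle$alpha, x$onset$lifestyle$beta))
  invisible(x)
}

# ---- life tables ------------------------------------------------------------

#' Read a life table CSV
#'
#' Expects a header `age,qx` with contiguous integer ages and terminal
#' probability 1.
#' @param path CSV path.
#' @return A data frame with columns `age`, `qx`.
#' @export
read_life_table <- function(path) {
  if (!file.exists(path)) stop("life table not found: ", path, call. = FALSE)
  lt <- utils::read.csv(path)
  p <- validate_life_table(lt)
  if (length(p)) stop(paste(p, collapse = "; "), call. = FALSE)
  lt[c("age", "qx")]
}

#' Bundled synthetic China-2009-like life table
#'
#' A Gompertz-Makeham all-cause mortality table (a = 3.2e-5, b = 0.100,
#' c = 6e-4, generated by [make_life_table()]) matched to WHO China-2009
#' summary demography (life expectancy at birth about 74 years, at age 45
#' about 31.5 years). It is a synthetic stand-in for the WHO table, not the
#' WHO table itself.
#' @return A data frame with columns `age`, `qx` for ages 0-100.
#' @export
default_life_table <- function() {
  path <- system.file("extdata", "life_table_china2009_synthetic.csv",
                      package = "diabprev", mustWork = TRUE)
  read_life_table(path)
}
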