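# Synthetic data generators: Weibull event-time datasets with Kaplan-Meier
# estimation, Gompertz-Makeham life tables, and a hand-checkable toy
# configuration. Everything the test-suite consumes is generated here; no
# downloads.

#' Simulate time-to-diabetes data from a Weibull onset model
#'
#' Inverse-CDF draws `t = (-ln u / alpha)^(1/beta)`, administratively
#' censored at `censor_time` (emulating the structure of a long-term
#' prevention trial's follow-up).
#' @param params List with `alpha`, `beta` (both > 0).
#' @param n Number of subjects (>= 1).
#' @param censor_time Censoring horizon in years (> 0).
#' @param seed RNG seed (generators take explicit seeds; no global state is
#'   relied on).
#' @return Data frame with columns `time` (years) and `event` (1 = onset
#'   observed, 0 = censored).
#' @export
simulate_event_times <- function(params, n, censor_time = 23, seed = 1) {
  stopifnot(params$alpha > 0, params$beta > 0, n >= 1, censor_time > 0)
  set.seed(seed)
  u <- stats::runif(n)
  t <- (-log(u) / params$alpha)^(1 / params$beta)
  data.frame(time = pmin(t, censor_time),
             event = as.integer(t <= censor_time))
}

#' Kaplan-Meier estimate of the diabetes-free curve
#'
#' Product-limit estimator (via \pkg{survival}); one row per distinct
#' observed time, with the survival fraction and the size of the risk set.
#' All-censored data yield a curve identically 1.
#' @param data Data frame with columns `time`, `event`.
#' @return Data frame with columns `time`, `survival`, `at_risk`.
#' @export
km_estimate <- function(data) {
  data <- as.data.frame(data)
  stopifnot(nrow(data) >= 1, all(c("time", "event") %in% names(data)))
  fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = data)
  data.frame(time = fit$time, survival = fit$surv, at_risk = fit$n.risk)
}

#' Generate a Gompertz-Makeham life table
#'
#' Annual death probabilities `qx(age) = 1 - exp(-(c + a * exp(b * age)))`
#' for ages 0..`max_age`, with the terminal probability set to 1.
#' @param a Gompertz level (>= 0).
#' @param b Gompertz slope (per year, >= 0).
#' @param c Makeham age-independent hazard (>= 0).
#' @param max_age Final tabulated age.
#' @return Data frame with columns `age`, `qx`.
#' @export
make_life_table <- function(a, b, c = 0, max_age = 100) {
  stopifnot(a >= 0, b >= 0, c >= 0, max_age >= 1)
  age <- 0:max_age
  qx <- pmin(1, 1 - exp(-(c + a * exp(b * age))))
  qx[length(qx)] <- 1
  data.frame(age = age, qx = qx)
}

#' Hand-checkable toy configuration
#'
#' A three-cycle, no-onset, no-complication configuration with a constant
#' annual death probability of 0.5, zero discounting, prediabetes utility
#' 0.8 and an annual program cost of 100, embedded life table included.
#' Run with the `"lifestyle"` strategy it yields exactly LY = 1.75
#' (occupancy 1 + 0.5 + 0.25), cost = 175 and QALY = 1.40, and its
#' trajectory matches a 3-state transition-matrix computation by
#' construction.
#' @return A `dm_config`.
#' @export
toy_model_config <- function() {
  cfg <- default_parameters()
  cfg$economics$discount_rate <- 0
  cfg$economics$start_age <- 45L
  cfg$economics$horizon_age <- 48L
  cfg$onset$hazard_scale <- 0
  cfg$options$hazard_age_gradient <- 0
  for (nm in names(cfg$hazards)) cfg$hazards[[nm]] <- 0
  cfg$mortality$m_dm <- 1
  cfg$utilities$prediabetes <- 0.8
  cfg$costs$lifestyle_annual <- 100
  cfg$program$lifestyle_years <- 10L
  cfg$life_table <- data.frame(age = 45:48, qx = c(0.5, 0.5, 0.5, 1))
  cfg
}
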