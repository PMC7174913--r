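# Annual-cycle cohort state-transition engine.
#
# The cohort starts diabetes-free at the start age and is advanced one year
# per cycle. Within each cycle the order is: all-cause death, diabetes onset,
# complication incidence (with optional acute case fatality), risk-factor
# drift, then ageing and duration-band shift. Life-years accrue on start-of-
# cycle occupancy (no half-cycle correction by default); QALYs and costs are
# discounted at the configured annual rate, life-years are not.

#' Initial cohort state
#'
#' @param config A `dm_config`.
#' @return An object of class `dm_state`: fractional occupancies of a unit
#'   cohort (alive/dead, non-diabetic/diabetic with a diabetes-duration
#'   distribution, complication prevalence trackers) plus the risk-factor
#'   levels.
#' @export
init_cohort_state <- function(config) {
  comp <- absorbing_complications()
  allc <- c(comp, recurrent_events())
  ncyc <- config$economics$horizon_age - config$economics$start_age
  structure(list(
    age = config$economics$start_age,
    cycle = 0L,
    alive = 1, dead = 0,
    nondiabetic = 1,
    # dm_duration[i] = diabetic mass with duration (i - 1) completed years
    dm_duration = numeric(ncyc + 1L),
    prev_nd = stats::setNames(numeric(length(comp)), comp),
    prev_dm = stats::setNames(numeric(length(comp)), comp),
    cum_incidence = stats::setNames(numeric(length(allc)), allc),
    incidence = stats::setNames(numeric(length(allc)), allc),
    cum_diabetes = 0,
    risk_factors = unlist(config$profile)
  ), class = "dm_state")
}

diabetic_mass <- function(state) sum(state$dm_duration)

# resolve the life table actually used by a run
resolve_life_table <- function(config, life_table) {
  if (!is.null(life_table)) return(as.data.frame(life_table))
  if (!is.null(config$life_table)) return(as.data.frame(config$life_table))
  default_life_table()
}

lookup_qx <- function(life_table, age) {
  i <- age - life_table$age[1] + 1L
  n <- nrow(life_table)
  ifelse(i < 1L, 0, ifelse(i > n, 1, life_table$qx[pmax(1L, pmin(i, n))]))
}

# Per-run context: everything constant across cycles, precomputed once.
build_ctx <- function(config, strategy, life_table = NULL, onset_override = NULL) {
  strategy <- match.arg(strategy, c("none", "lifestyle"))
  lt <- resolve_life_table(config, life_table)
  onset <- if (!is.null(onset_override)) {
    onset_override
  } else {
    arm <- if (strategy == "lifestyle") "lifestyle" else "control"
    onset_model(config$onset[[arm]], hazard_scale = config$onset$hazard_scale)
  }
  comp <- absorbing_complications()
  rr_slot <- complication_registry()$rr[match(comp, complication_registry()$name)]
  rr <- vapply(rr_slot, function(s) {
    if (is.na(s)) Inf else param_value(config$relative_risks[[s]])
  }, numeric(1))
  names(rr) <- comp
  hz <- vapply(comp, function(nm) param_value(config$hazards[[nm]]), numeric(1))
  ev <- recurrent_events()
  hz_ev <- vapply(ev, function(nm) param_value(config$hazards[[nm]]), numeric(1))

  cost <- function(nm) param_value(config$costs[[nm]])
  annual_care <- c(
    mi = cost("mi_annual"), stroke = cost("stroke_annual"),
    chf = cost("chf_annual"), esrd = cost("esrd_annual"),
    blindness = cost("blindness_annual"),
    neuropathy = 12 * cost("neuropathy_monthly"),
    minor_amputation = 0,
    major_amputation = 12 * cost("major_amputation_monthly")
  )
  event_cost <- c(
    mi = cost("mi_event"), stroke = cost("stroke_event"),
    chf = 0, esrd = 0, blindness = 0, neuropathy = 0,
    minor_amputation = cost("minor_amputation_event"),
    major_amputation = cost("major_amputation_event"),
    dfu_uncomplicated = cost("dfu_uncomplicated_event"),
    dfu_complicated = cost("dfu_complicated_event"),
    severe_hypoglycemia = cost("severe_hypoglycemia_event")
  )
  dec <- config$utilities$decrements
  state_dec <- vapply(comp, function(nm) param_value(dec[[nm]]), numeric(1))
  acute_dec <- c(mi = param_value(dec$mi_hospitalization) / 12,
                 stroke = param_value(dec$stroke_hospitalization) / 12,
                 dfu_uncomplicated = param_value(dec$dfu_uncomplicated),
                 dfu_complicated = param_value(dec$dfu_complicated))
  band_annual <- vapply(config$costs$antidiabetic_daily, function(x)
    annualize_daily_cost(param_value(x)), numeric(1))

  list(
    strategy = strategy, life_table = lt, onset = onset,
    comp = comp, rr = rr, hazards = hz, hazards_event = hz_ev,
    annual_care = annual_care, event_cost = event_cost,
    state_dec = state_dec, acute_dec = acute_dec,
    band_annual = band_annual,
    lifestyle_annual = cost("lifestyle_annual"),
    program_years = config$program$lifestyle_years,
    u_base = param_value(config$utilities$base_t2dm),
    u_pre = param_value(config$utilities$prediabetes),
    m_dm = param_value(config$mortality$m_dm),
    mult_nd = config$mortality$mult_nondiabetic,
    chf_extra = config$mortality$chf_extra,
    esrd_extra = config$mortality$esrd_extra,
    cf = c(mi = param_value(config$case_fatality$mi),
           stroke = param_value(config$case_fatality$stroke)),
    drift = unlist(config$drift),
    risk_equations = config$risk_equations,
    coupling = config$options$amputation_ulcer_coupling,
    age_gradient = config$options$hazard_age_gradient,
    r = config$economics$discount_rate,
    start_age = config$economics$start_age,
    horizon_age = config$economics$horizon_age
  )
}

# effective annual hazard for a complication, including the optional
# log-link risk-equation modulation by current risk-factor levels
effective_hazard <- function(ctx, name, base_hazard, risk_factors) {
  eq <- ctx$risk_equations[[name]]
  if (is.null(eq)) return(base_hazard)
  covs <- unlist(eq$coefficients)
  lp <- sum(covs * risk_factors[names(covs)])
  base_hazard * eq$baseline_hazard * exp(lp)
}

#' Annual complication probability
#'
#' Converts a constant annual hazard `h` into a one-cycle probability.
#' Diabetics: `1 - exp(-h)`. Non-diabetics: `1 - exp(-h / rr)`, the
#' diabetic absolute risk deflated by the relative risk of diabetic versus
#' non-diabetic subjects (`rr = Inf` marks diabetes-specific complications).
#' @param hazard Annual hazard among diabetics (>= 0).
#' @param rr Relative risk, diabetic vs non-diabetic (> 0, may be `Inf`).
#' @param diabetic Logical.
#' @export
complication_probability <- function(hazard, rr = 1, diabetic = TRUE) {
  if (any(hazard < 0)) stop("hazard must be non-negative", call. = FALSE)
  if (any(rr <= 0)) stop("rr must be positive", call. = FALSE)
  h <- if (diabetic) hazard else ifelse(is.infinite(rr), 0, hazard / rr)
  1 - exp(-h)
}

#' All-cause mortality probability of a cohort state
#'
#' Life-table annual death probability at the given age, multiplied by the
#' configured disease-state multipliers and clipped to \[0, 1\]:
#' non-diabetics use `mult_nondiabetic` (default 1), diabetics `m_dm`, with
#' optional extra multipliers weighted by the within-diabetic CHF/ESRD
#' prevalence shares. Returns the occupancy-weighted probability; ages
#' beyond the table use the terminal qx = 1.
#' @param age Integer age in years.
#' @param state A `dm_state`.
#' @param config A `dm_config`.
#' @param life_table Optional life table (data frame `age`, `qx`).
#' @export
all_cause_mortality <- function(age, state, config, life_table = NULL) {
  ctx <- build_ctx(config, "none", life_table)
  q <- mortality_probs(ctx, age, state)
  dm <- diabetic_mass(state)
  if (state$alive <= 0) return(0)
  (state$nondiabetic * q[["nd"]] + dm * q[["dm"]]) / state$alive
}

mortality_probs <- function(ctx, age, state) {
  qx <- lookup_qx(ctx$life_table, age)
  dm <- diabetic_mass(state)
  m_eff <- ctx$m_dm
  if (dm > 0 && (ctx$chf_extra != 1 || ctx$esrd_extra != 1)) {
    m_eff <- m_eff * (1 + (ctx$chf_extra - 1) * state$prev_dm[["chf"]] / dm +
                          (ctx$esrd_extra - 1) * state$prev_dm[["esrd"]] / dm)
  }
  c(nd = min(1, qx * ctx$mult_nd), dm = min(1, qx * m_eff))
}

#' Advance a cohort state by one annual cycle
#'
#' Applies, in order: all-cause death, diabetes onset, complication
#' incidence (with acute case fatality, default 0), risk-factor drift, then
#' ageing and the diabetes-duration shift. The returned state's `incidence`
#' field holds the fractions incident during this step. Mass is conserved
#' to 1e-12 or the function stops.
#' @param state A `dm_state`.
#' @param config A `dm_config`.
#' @param strategy `"none"` or `"lifestyle"`.
#' @param life_table Optional life table.
#' @export
step_cycle <- function(state, config, strategy = "none", life_table = NULL) {
  ctx <- build_ctx(config, strategy, life_table)
  step_cycle_ctx(state, ctx)
}

step_cycle_ctx <- function(state, ctx) {
  comp <- ctx$comp
  # (1) all-cause death
  q <- mortality_probs(ctx, state$age, state)
  nd <- state$nondiabetic * (1 - q[["nd"]])
  dm_dur <- state$dm_duration * (1 - q[["dm"]])
  prev_nd <- state$prev_nd * (1 - q[["nd"]])
  prev_dm <- state$prev_dm * (1 - q[["dm"]])
  dead <- state$dead + state$nondiabetic * q[["nd"]] +
    diabetic_mass(state) * q[["dm"]]

  # (2) onset of diabetes among survivors
  p_on <- annual_onset_probability(state$cycle, ctx$onset)
  new_dm <- nd * p_on
  nd <- nd - new_dm
  prev_dm <- prev_dm + prev_nd * p_on
  prev_nd <- prev_nd * (1 - p_on)
  cum_diabetes <- state$cum_diabetes + new_dm
  dm_total <- sum(dm_dur) + new_dm

  # (3) complication incidence
  inc <- state$incidence
  inc[] <- 0
  # complication hazards rise with attained age (doubling per decade at the
  # default gradient); severe hypoglycemia stays age-constant
  af <- exp(ctx$age_gradient * (state$age - ctx$start_age))
  hz <- ctx$hazards * af
  if (length(ctx$risk_equations)) {
    for (nm in comp)
      hz[nm] <- effective_hazard(ctx, nm, hz[nm], state$risk_factors)
  }
  hz_ev <- ctx$hazards_event
  dfu <- c("dfu_uncomplicated", "dfu_complicated")
  hz_ev[dfu] <- hz_ev[dfu] * af
  # recurrent events first (feeds the optional ulcer -> amputation coupling)
  ev_dm <- dm_total * (1 - exp(-hz_ev))
  inc[names(ev_dm)] <- ev_dm
  if (ctx$coupling > 0 && dm_total > 0) {
    ulcer_rate <- (ev_dm[["dfu_uncomplicated"]] + ev_dm[["dfu_complicated"]]) / dm_total
    amp <- c("minor_amputation", "major_amputation")
    hz[amp] <- hz[amp] * (1 + ctx$coupling * ulcer_rate)
  }
  for (nm in comp) {
    at_dm <- max(0, dm_total - prev_dm[[nm]])
    at_nd <- max(0, nd - prev_nd[[nm]])
    i_dm <- at_dm * complication_probability(hz[[nm]], diabetic = TRUE)
    i_nd <- at_nd * complication_probability(hz[[nm]], ctx$rr[[nm]], diabetic = FALSE)
    cf <- if (nm %in% names(ctx$cf)) ctx$cf[[nm]] else 0
    if (cf > 0) {
      dead <- dead + (i_dm + i_nd) * cf
      dm_total <- dm_total - i_dm * cf
      nd <- nd - i_nd * cf
      i_dm <- i_dm * (1 - cf)
      i_nd <- i_nd * (1 - cf)
    }
    prev_dm[nm] <- prev_dm[[nm]] + i_dm
    prev_nd[nm] <- prev_nd[[nm]] + i_nd
    inc[nm] <- i_dm + i_nd
  }
  # case fatality removed mass uniformly; rescale the duration distribution
  sdur <- sum(dm_dur) + new_dm
  if (dm_total < sdur && sdur > 0) {
    scale <- dm_total / sdur
    dm_dur <- dm_dur * scale
    new_dm <- new_dm * scale
  }

  # (4) risk-factor drift
  rf <- state$risk_factors
  if (length(ctx$drift)) rf[names(ctx$drift)] <- rf[names(ctx$drift)] + ctx$drift

  # (5) age + 1, duration bands shift; new diabetics enter at duration 0
  n <- length(dm_dur)
  dm_next <- c(new_dm, dm_dur[-n])
  dm_next[n] <- dm_next[n] + dm_dur[n]  # terminal band absorbs

  out <- state
  out$age <- state$age + 1L
  out$cycle <- state$cycle + 1L
  out$nondiabetic <- nd
  out$dm_duration <- dm_next
  out$alive <- nd + sum(dm_next)
  out$dead <- dead
  out$prev_nd <- prev_nd
  out$prev_dm <- prev_dm
  out$incidence <- inc
  out$cum_incidence <- state$cum_incidence + inc
  out$cum_diabetes <- cum_diabetes
  out$risk_factors <- rf
  if (abs(out$alive + out$dead - 1) > 1e-12)
    stop("internal consistency error: cohort mass not conserved (|err| = ",
         format(abs(out$alive + out$dead - 1)), ")", call. = FALSE)
  if (out$alive < -1e-15 || out$nondiabetic < -1e-15)
    stop("internal consistency error: negative occupancy", call. = FALSE)
  out
}

#' Apply per-year linear drift to the tracked risk factors
#'
#' Hook for risk-factor progression (e.g. HbA1c, SBP, cholesterol worsening
#' over time); drifts default to zero and feed the optional risk equations.
#' @param state A `dm_state`.
#' @param config A `dm_config` whose `drift` section names profile covariates.
#' @export
update_risk_factors <- function(state, config) {
  bad <- setdiff(names(config$drift), names(state$risk_factors))
  if (length(bad))
    stop("drift on unmodelled covariate(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  d <- unlist(config$drift)
  if (length(d)) state$risk_factors[names(d)] <- state$risk_factors[names(d)] + d
  state
}

#' Run the cohort model for one strategy
#'
#' Deterministic expected-value projection of a unit cohort from the start
#' age to the horizon age. The strategy affects only the onset model (each
#' arm has its own fitted Weibull) and the accrual of the lifestyle program
#' cost, which is charged annually while alive and non-diabetic for at most
#' `program$lifestyle_years` years.
#'
#' @param config A `dm_config`.
#' @param strategy `"none"` or `"lifestyle"`.
#' @param life_table Optional life table (data frame `age`, `qx`); defaults
#'   to the table embedded in the config, else the bundled fixture.
#' @param onset_override Optional [onset_model()] replacing the arm's own
#'   fit (used when the intervention arm is driven by a hazard ratio).
#' @return A `dm_sim`: per-cycle trajectory, cumulative incidences,
#'   undiscounted life-years, discounted QALYs and discounted cost.
#' @export
run_cohort <- function(config, strategy = c("none", "lifestyle"),
                       life_table = NULL, onset_override = NULL) {
  strategy <- match.arg(strategy)
  validate_config(config)
  ctx <- build_ctx(config, strategy, life_table, onset_override)
  ncyc <- ctx$horizon_age - ctx$start_age
  state <- init_cohort_state(config)
  v <- 1 / (1 + ctx$r)
  hcc <- isTRUE(config$options$half_cycle_correction)

  traj <- matrix(0, nrow = ncyc, ncol = 9 + length(state$incidence))
  colnames(traj) <- c("cycle", "age", "alive", "nondiabetic", "diabetic",
                      "dead", "ly", "qaly", "cost",
                      paste0("inc_", names(state$incidence)))
  ly <- qaly <- cost <- 0
  for (t in seq_len(ncyc) - 1L) {
    nxt <- step_cycle_ctx(state, ctx)
    occ <- state
    if (hcc) {  # trapezoid occupancy
      occ$alive <- (state$alive + nxt$alive) / 2
      occ$nondiabetic <- (state$nondiabetic + nxt$nondiabetic) / 2
      occ$dm_duration <- (state$dm_duration +
                            c(nxt$dm_duration[-1], 0)) / 2
      occ$prev_nd <- (state$prev_nd + nxt$prev_nd) / 2
      occ$prev_dm <- (state$prev_dm + nxt$prev_dm) / 2
    }
    u <- cycle_utility_ctx(occ, ctx, nxt$incidence)
    co <- cycle_cost_ctx(occ, ctx, nxt$incidence, t)
    d <- v^t
    ly <- ly + occ$alive
    qaly <- qaly + d * u * occ$alive
    cost <- cost + d * co
    traj[t + 1L, ] <- c(t, state$age, occ$alive, occ$nondiabetic,
                        diabetic_mass(occ), state$dead,
                        occ$alive, d * u * occ$alive, d * co,
                        nxt$incidence)
    state <- nxt
  }
  structure(list(
    strategy = strategy,
    trajectory = as.data.frame(traj),
    cumulative_incidence = state$cum_incidence,
    cumulative_diabetes = state$cum_diabetes,
    ly = ly, qaly = qaly, cost = cost,
    discount_rate = ctx$r,
    start_age = ctx$start_age, horizon_age = ctx$horizon_age,
    final_state = state
  ), class = "dm_sim")
}

#' @export
print.dm_sim <- function(x, ...) {
  cat(sprintf("<dm_sim> strategy '%s', ages %d-%d, discount %.1f%%\n",
              x$strategy, x$start_age, x$horizon_age, 100 * x$discount_rate))
  cat(sprintf("  cumulative diabetes %.2f%% | LY %.2f | QALY %.2f | cost $%s\n",
              100 * x$cumulative_diabetes, x$ly, x$qaly,
              format(round(x$cost), big.mark = ",")))
  invisible(x)
}

#' Export a simulation trajectory to CSV
#' @param sim A `dm_sim`.
#' @param path Output CSV path.
#' @export
write_trajectory <- function(sim, path) {
  utils::write.csv(sim$trajectory, path, row.names = FALSE)
  invisible(path)
}

#' Individual-level microsimulation of diabetes onset and death
#'
#' Monte-Carlo cross-check of the cohort engine on the onset/mortality
#' skeleton: samples per-individual annual onset and death and returns the
#' lifetime cumulative diabetes probability with its standard error.
#' @param config A `dm_config`.
#' @param strategy `"none"` or `"lifestyle"`.
#' @param n Number of simulated individuals.
#' @param seed RNG seed.
#' @param life_table Optional life table.
#' @return List with `cum_diabetes`, `se` and `n`.
#' @export
microsim_diabetes <- function(config, strategy = "none", n = 1e5, seed = 1,
                              life_table = NULL) {
  ctx <- build_ctx(config, strategy, life_table)
  set.seed(seed)
  ncyc <- ctx$horizon_age - ctx$start_age
  alive <- rep(TRUE, n)
  diabetic <- rep(FALSE, n)
  ever_dm <- rep(FALSE, n)
  for (t in seq_len(ncyc) - 1L) {
    age <- ctx$start_age + t
    qx <- lookup_qx(ctx$life_table, age)
    qd <- min(1, qx * ctx$m_dm)
    qn <- min(1, qx * ctx$mult_nd)
    u <- stats::runif(n)
    dies <- alive & (ifelse(diabetic, u < qd, u < qn))
    alive[dies] <- FALSE
    p_on <- annual_onset_probability(t, ctx$onset)
    onset <- alive & !diabetic & (stats::runif(n) < p_on)
    diabetic[onset] <- TRUE
    ever_dm[onset] <- TRUE
    if (!any(alive)) break
  }
  p <- mean(ever_dm)
  list(cum_diabetes = p, se = sqrt(p * (1 - p) / n), n = n)
}
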