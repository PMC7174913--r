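# Utility and cost accrual, discounting, incremental cost-effectiveness.

#' Discount factor for cycle t
#'
#' @param t Cycle index (integer >= 0).
#' @param r Annual discount rate (>= 0); the model default is 0.05.
#' @return `(1 + r)^(-t)`.
#' @export
discount_factor <- function(t, r) {
  stopifnot(all(t >= 0), r >= 0)
  (1 + r)^(-t)
}

# ctx-level accrual helpers used by run_cohort ------------------------------

cycle_utility_ctx <- function(state, ctx, incidence = state$incidence) {
  if (state$alive <= 0) return(0)
  nd <- state$nondiabetic
  dm <- diabetic_mass(state)
  u_dm <- if (dm > 0)
    max(0, ctx$u_base - sum(state$prev_dm * ctx$state_dec) / dm) else 0
  u_nd <- if (nd > 0)
    max(0, ctx$u_pre - sum(state$prev_nd * ctx$state_dec) / nd) else 0
  acute <- incidence[["mi"]] * ctx$acute_dec[["mi"]] +
    incidence[["stroke"]] * ctx$acute_dec[["stroke"]] +
    incidence[["dfu_uncomplicated"]] * ctx$acute_dec[["dfu_uncomplicated"]] +
    incidence[["dfu_complicated"]] * ctx$acute_dec[["dfu_complicated"]]
  max(0, (nd * u_nd + dm * u_dm - acute) / state$alive)
}

antidiabetic_band_masses <- function(dm_duration) {
  n <- length(dm_duration)
  idx <- function(lo, hi) sum(dm_duration[seq.int(lo, min(hi, n))])
  c(band1 = if (n >= 1) idx(1, 3) else 0,    # durations 0-2
    band2 = if (n >= 4) idx(4, 6) else 0,    # 3-5
    band3 = if (n >= 7) idx(7, 10) else 0,   # 6-9
    band4 = if (n >= 11) idx(11, n) else 0)  # >= 10
}

cycle_cost_ctx <- function(state, ctx, incidence = state$incidence, cycle = state$cycle) {
  total <- 0
  if (ctx$strategy == "lifestyle" && cycle < ctx$program_years)
    total <- total + ctx$lifestyle_annual * state$nondiabetic
  bands <- antidiabetic_band_masses(state$dm_duration)
  total <- total + sum(bands * ctx$band_annual)
  prev <- state$prev_nd + state$prev_dm
  total <- total + sum(prev * ctx$annual_care)
  total <- total + sum(incidence * ctx$event_cost[names(incidence)])
  total
}

#' Occupancy-weighted utility of a cohort state for one cycle
#'
#' Non-diabetics carry the prediabetes utility (default 1.0); diabetics the
#' base T2DM utility (0.876) minus the additive complication decrements of
#' their prevalent conditions, floored at zero. Acute hospitalisation
#' decrements (MI/stroke, one month) are prorated 1/12 on the fractions
#' incident within the cycle; foot-ulcer decrements apply for the incident
#' cycle.
#' @param state A `dm_state` (its `incidence` field supplies the in-cycle
#'   incident fractions).
#' @param utilities The `utilities` section of a `dm_config` (defaults used
#'   when a full config is passed).
#' @param config A `dm_config` supplying the decrement table; defaults to
#'   [default_parameters()].
#' @return Mean utility weight per alive cohort member.
#' @export
cycle_utility <- function(state, utilities = NULL, config = default_parameters()) {
  if (!is.null(utilities)) config$utilities <- utilities
  ctx <- build_ctx(config, "none", life_table = data.frame(age = 0, qx = 1))
  cycle_utility_ctx(state, ctx)
}

#' Cost of a cohort state for one cycle (US$, undiscounted)
#'
#' Sums the lifestyle program cost (lifestyle arm, while non-diabetic,
#' within the program duration), duration-banded antidiabetic therapy cost,
#' annual complication care costs on prevalent fractions, and per-event
#' costs on incident fractions.
#' @param state A `dm_state`.
#' @param costs The `costs` section of a `dm_config` (optional override).
#' @param strategy `"none"` or `"lifestyle"`.
#' @param config A `dm_config`; defaults to [default_parameters()].
#' @export
cycle_cost <- function(state, costs = NULL, strategy = "none",
                       config = default_parameters()) {
  if (!is.null(costs)) config$costs <- costs
  ctx <- build_ctx(config, strategy, life_table = data.frame(age = 0, qx = 1))
  cycle_cost_ctx(state, ctx)
}

#' Net monetary benefit
#'
#' @param delta_effect Incremental effect (QALYs).
#' @param delta_cost Incremental cost (US$).
#' @param lambda Willingness-to-pay threshold (US$/QALY, >= 0).
#' @return `lambda * delta_effect - delta_cost`; positive iff cost-effective
#'   at `lambda`.
#' @export
net_monetary_benefit <- function(delta_effect, delta_cost, lambda) {
  stopifnot(all(lambda >= 0))
  lambda * delta_effect - delta_cost
}

#' Incremental cost-effectiveness of intervention versus control
#'
#' Computes incremental discounted cost and QALYs, the ICER, and a
#' dominance classification at the willingness-to-pay threshold:
#' `dominant` (cheaper and more effective), `dominated` (costlier and less
#' effective), `equivalent`, or a trade-off classified by the sign of the
#' net monetary benefit.
#' @param control,intervention `dm_sim` results on the same horizon and
#'   discount rate.
#' @param lambda Willingness-to-pay threshold (US$/QALY).
#' @return An object of class `dm_icer`.
#' @export
compute_icer <- function(control, intervention,
                         lambda = default_parameters()$economics$wtp_threshold) {
  if (control$horizon_age != intervention$horizon_age ||
      control$start_age != intervention$start_age ||
      control$discount_rate != intervention$discount_rate)
    stop("arms were run on different horizons or discount rates", call. = FALSE)
  dc <- intervention$cost - control$cost
  de <- intervention$qaly - control$qaly
  icer <- if (de != 0) dc / de else NA_real_
  nmb <- net_monetary_benefit(de, dc, lambda)
  classification <-
    if (dc < 0 && de > 0) "dominant"
    else if (dc > 0 && de < 0) "dominated"
    else if (dc == 0 && de == 0) "equivalent"
    else if (nmb > 0) "tradeoff_cost_effective"
    else "tradeoff_not_cost_effective"
  structure(list(delta_cost = dc, delta_effect = de, icer = icer,
                 nmb = nmb, lambda = lambda,
                 classification = classification),
            class = "dm_icer")
}

#' @export
print.dm_icer <- function(x, ...) {
  cat("<dm_icer>\n")
  cat(sprintf("  delta cost  $%.1f\n  delta QALY  %.4f\n", x$delta_cost, x$delta_effect))
  cat(sprintf("  ICER        %s\n",
              if (is.na(x$icer)) "undefined (delta effect = 0)"
              else sprintf("$%.0f/QALY", x$icer)))
  cat(sprintf("  at lambda $%s/QALY: %s (NMB $%.0f)\n",
              format(x$lambda, big.mark = ","), x$classification, x$nmb))
  invisible(x)
}

#' Base-case results table for the two strategies
#'
#' The canonical report: one row per outcome (cumulative diabetes, each
#' complication's cumulative incidence, total QALY, LY and discounted
#' cost), with control, intervention and difference columns.
#' @param control,intervention `dm_sim` results.
#' @return A data frame with columns `outcome`, `control`, `lifestyle`,
#'   `difference`.
#' @export
base_case_table <- function(control, intervention) {
  comp <- absorbing_complications()
  out <- data.frame(
    outcome = c("cumulative_diabetes", paste0("cumulative_", comp),
                "total_qaly", "total_ly", "total_cost"),
    control = c(control$cumulative_diabetes, unname(control$cumulative_incidence[comp]),
                control$qaly, control$ly, control$cost),
    lifestyle = c(intervention$cumulative_diabetes,
                  unname(intervention$cumulative_incidence[comp]),
                  intervention$qaly, intervention$ly, intervention$cost),
    stringsAsFactors = FALSE
  )
  out$difference <- out$lifestyle - out$control
  out
}

#' Serialize an ICER result to JSON
#' @param icer A `dm_icer`.
#' @param path Output path.
#' @export
write_icer_json <- function(icer, path) {
  jsonlite::write_json(unclass(icer), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
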