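# One-way (tornado) and probabilistic sensitivity analysis.
#
# The varied parameter set is the published input table: the onset hazard
# ratio (normal, truncated at zero), the diabetic-vs-non-diabetic relative
# risks (normal), every unit cost (triangular, mode at the base value) and
# the utility weight and decrements (beta, moment-matched). Calibrated
# engine internals are held fixed. Within a PSA iteration one common
# parameter draw drives both arms (second-order Monte Carlo), and the
# intervention arm's onset model is the control-arm Weibull scaled by the
# drawn hazard ratio.

#' Enumerate the PSA parameter set of a configuration
#'
#' Walks the configuration in a fixed, documented order (onset hazard
#' ratio, relative risks, costs, utilities) and returns every
#' distribution-specified parameter with its config path. The order defines
#' the RNG draw order, so results are reproducible across platforms.
#' @param config A `dm_config`.
#' @return Named list of entries `list(path, spec)`.
#' @export
psa_parameters <- function(config) {
  out <- list()
  add <- function(name, path, spec) {
    if (is_dist_spec(spec) && spec$family != "fixed")
      out[[name]] <<- list(path = path, spec = spec)
  }
  add("onset_hr", c("onset", "hr_lifestyle"), config$onset$hr_lifestyle)
  for (nm in names(config$relative_risks))
    add(paste0("rr_", nm), c("relative_risks", nm), config$relative_risks[[nm]])
  for (nm in names(config$costs)) {
    if (nm == "antidiabetic_daily") {
      for (b in names(config$costs$antidiabetic_daily))
        add(paste0("cost_antidiabetic_", b), c("costs", "antidiabetic_daily", b),
            config$costs$antidiabetic_daily[[b]])
    } else {
      add(paste0("cost_", nm), c("costs", nm), config$costs[[nm]])
    }
  }
  add("utility_base_t2dm", c("utilities", "base_t2dm"), config$utilities$base_t2dm)
  for (nm in names(config$utilities$decrements))
    add(paste0("utility_dec_", nm), c("utilities", "decrements", nm),
        config$utilities$decrements[[nm]])
  out
}

# Build the inverse-CDF sampler for one spec; warnings (e.g. infeasible beta
# moments) surface once, at preparation time.
prepare_sampler <- function(spec, warn = TRUE) {
  base <- spec$base; low <- spec$low; high <- spec$high
  se <- if (!is.null(spec$se) && is.finite(spec$se)) spec$se else 0.25 * abs(base)
  switch(spec$family,
    fixed = function(u) rep(base, length(u)),
    triangle = {
      if (high <= low) return(function(u) rep(base, length(u)))
      fc <- (base - low) / (high - low)
      function(u) {
        ifelse(u < fc,
               low + sqrt(u * (high - low) * (base - low)),
               high - sqrt((1 - u) * (high - low) * (high - base)))
      }
    },
    normal = {
      sd <- if (se > 0) se else 0.25 * abs(base)
      p0 <- stats::pnorm(0, base, sd)
      function(u) stats::qnorm(p0 + u * (1 - p0), base, sd)  # truncated at 0
    },
    beta = {
      if (base <= 0 || base >= 1 || se^2 >= base * (1 - base)) {
        if (warn)
          warning(sprintf(
            "beta moments infeasible (base %.3f, se %.3f); falling back to uniform on [%.3f, %.3f]",
            base, se, low, high), call. = FALSE)
        function(u) low + u * (high - low)
      } else {
        nu <- base * (1 - base) / se^2 - 1
        a <- base * nu; b <- (1 - base) * nu
        function(u) stats::qbeta(u, a, b)
      }
    },
    stop("unknown distribution family: ", spec$family, call. = FALSE)
  )
}

#' Draw one value from a parameter's distribution
#'
#' Inverse-CDF sampling: beta by moment matching on (base, se), triangular
#' on (low, mode = base, high), normal truncated at zero with
#' `se = (high - low)/(2 * 1.96)` (or 25% of base when no range is given).
#' Infeasible beta moments fall back to a uniform on the range, with a
#' warning.
#' @param spec A [dist_spec()].
#' @param u Uniform(0,1) variate(s); defaults to a fresh draw.
#' @export
sample_parameter <- function(spec, u = stats::runif(1)) {
  prepare_sampler(spec)(u)
}

# replace each drawn parameter by its realized numeric value (a sampled
# value may legitimately fall outside the one-way range, so the dist spec
# is collapsed rather than having its base overwritten)
apply_draws <- function(config, params, values) {
  for (nm in names(params)) {
    path <- params[[nm]]$path
    config[[path]] <- unname(values[[nm]])
  }
  config
}

run_arms <- function(config, life_table, hr = NULL) {
  ctrl <- run_cohort(config, "none", life_table)
  ov <- if (!is.null(hr))
    scale_onset_hazard(onset_model(config$onset$control,
                                   config$onset$hazard_scale), hr)
  intv <- run_cohort(config, "lifestyle", life_table, onset_override = ov)
  list(control = ctrl, lifestyle = intv)
}

#' Probabilistic sensitivity analysis
#'
#' Second-order Monte Carlo: `n` independent draws of the full parameter
#' set, one paired model run (both arms, common parameters) per draw,
#' recording incremental discounted cost and QALYs. The same seed
#' reproduces the result bitwise.
#' @param config A (typically calibrated) `dm_config`.
#' @param n Iterations (>= 1); the reference analysis uses 1000.
#' @param seed RNG seed.
#' @param life_table Optional life table.
#' @return A `dm_psa`: sampled parameter matrix and per-iteration
#'   `delta_cost`, `delta_effect`, plus the per-arm totals.
#' @export
run_psa <- function(config, n = 1000, seed = 1, life_table = NULL) {
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  validate_config(config)
  lt <- resolve_life_table(config, life_table)
  params <- psa_parameters(config)
  samplers <- lapply(params, function(p) prepare_sampler(p$spec))
  P <- length(params)
  set.seed(seed)
  U <- matrix(stats::runif(n * P), nrow = n, byrow = TRUE,
              dimnames = list(NULL, names(params)))
  values <- matrix(NA_real_, nrow = n, ncol = P,
                   dimnames = list(NULL, names(params)))
  for (nm in names(params)) values[, nm] <- samplers[[nm]](U[, nm])
  dc <- de <- cost_c <- cost_i <- qaly_c <- qaly_i <- numeric(n)
  for (i in seq_len(n)) {
    cfg_i <- apply_draws(config, params, values[i, ])
    arms <- run_arms(cfg_i, lt, hr = if ("onset_hr" %in% colnames(values))
      values[i, "onset_hr"] else NULL)
    cost_c[i] <- arms$control$cost;   qaly_c[i] <- arms$control$qaly
    cost_i[i] <- arms$lifestyle$cost; qaly_i[i] <- arms$lifestyle$qaly
    dc[i] <- cost_i[i] - cost_c[i]
    de[i] <- qaly_i[i] - qaly_c[i]
  }
  structure(list(
    n = n, seed = seed, parameters = as.data.frame(values),
    delta_cost = dc, delta_effect = de,
    cost_control = cost_c, cost_lifestyle = cost_i,
    qaly_control = qaly_c, qaly_lifestyle = qaly_i
  ), class = "dm_psa")
}

#' @export
print.dm_psa <- function(x, ...) {
  cat(sprintf("<dm_psa> %d iterations (seed %d)\n", x$n, x$seed))
  cat(sprintf("  mean delta cost $%.1f, mean delta QALY %.4f\n",
              mean(x$delta_cost), mean(x$delta_effect)))
  invisible(x)
}

#' Cost-effectiveness acceptability curve
#'
#' At each willingness-to-pay value, the fraction of PSA samples with
#' positive net monetary benefit.
#' @param psa A `dm_psa`.
#' @param lambda_grid Numeric grid of thresholds (non-empty). The default
#'   spans $0-30,000/QALY and includes the $10,276 reference threshold.
#' @return Data frame with columns `lambda`, `prob_ce`.
#' @export
ceac <- function(psa, lambda_grid = default_lambda_grid()) {
  if (length(lambda_grid) == 0) stop("empty lambda grid", call. = FALSE)
  prob <- vapply(lambda_grid, function(l)
    mean(net_monetary_benefit(psa$delta_effect, psa$delta_cost, l) > 0),
    numeric(1))
  data.frame(lambda = lambda_grid, prob_ce = prob)
}

#' @rdname ceac
#' @export
default_lambda_grid <- function() {
  sort(unique(c(seq(0, 30000, by = 500),
                default_parameters()$economics$wtp_threshold)))
}

#' One-way sensitivity analysis (tornado)
#'
#' Reruns both arms with each published parameter at its low and high value
#' (all others at base) and reports the ICER at each end. When the
#' incremental effect changes sign inside a parameter's range the ICER
#' scale is meaningless, so the bar is reported on the net-monetary-benefit
#' scale (`scale == "nmb"`). Entries are sorted by descending bar width.
#' @param config A (typically calibrated) `dm_config`.
#' @param lambda Willingness-to-pay threshold.
#' @param life_table Optional life table.
#' @return Data frame with columns `parameter`, `low`, `high`, `icer_low`,
#'   `icer_high`, `nmb_low`, `nmb_high`, `scale`, `width`.
#' @export
one_way_sa <- function(config, lambda = config$economics$wtp_threshold,
                       life_table = NULL) {
  validate_config(config)
  lt <- resolve_life_table(config, life_table)
  params <- psa_parameters(config)
  rows <- lapply(names(params), function(nm) {
    p <- params[[nm]]
    at <- function(value) {
      cfg <- config
      cfg[[p$path]] <- value
      arms <- run_arms(cfg, lt, hr = if (nm == "onset_hr") value else NULL)
      compute_icer(arms$control, arms$lifestyle, lambda)
    }
    lo <- at(p$spec$low); hi <- at(p$spec$high)
    use_nmb <- lo$delta_effect <= 0 || hi$delta_effect <= 0
    data.frame(parameter = nm, low = p$spec$low, high = p$spec$high,
               icer_low = lo$icer, icer_high = hi$icer,
               nmb_low = lo$nmb, nmb_high = hi$nmb,
               scale = if (use_nmb) "nmb" else "icer",
               width = if (use_nmb) abs(hi$nmb - lo$nmb)
                       else abs(hi$icer - lo$icer),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$width), ]
  rownames(out) <- NULL
  out
}

#' Summarise a PSA
#'
#' Reports mean incremental cost and effect, the ratio-of-means ICER, a
#' percentile interval of the per-sample ICERs restricted to samples with
#' positive incremental effect (dominant samples keep their negative
#' ratio), net-monetary-benefit summaries, and the 95% covariance ellipse
#' of the (delta effect, delta cost) cloud for plotting.
#' @param psa A `dm_psa`.
#' @param lambda Willingness-to-pay threshold.
#' @return A `dm_psa_summary`.
#' @export
psa_summary <- function(psa, lambda = default_parameters()$economics$wtp_threshold) {
  de <- psa$delta_effect; dc <- psa$delta_cost
  if (all(de == 0)) stop("all samples have zero incremental effect", call. = FALSE)
  mean_de <- mean(de); mean_dc <- mean(dc)
  pos <- de > 0
  icers <- dc[pos] / de[pos]
  ci <- if (length(icers)) stats::quantile(icers, c(0.025, 0.975), names = FALSE)
        else c(NA_real_, NA_real_)
  nmb <- net_monetary_benefit(de, dc, lambda)
  xy <- cbind(effect = de, cost = dc)
  cv <- stats::cov(xy)
  structure(list(
    n = psa$n, lambda = lambda,
    mean_delta_cost = mean_dc, mean_delta_effect = mean_de,
    icer_ratio_of_means = mean_dc / mean_de,
    icer_mean = if (length(icers)) mean(icers) else NA_real_,
    icer_ci = ci, n_excluded = sum(!pos),
    prob_ce = mean(nmb > 0),
    nmb_mean = mean(nmb),
    nmb_ci = stats::quantile(nmb, c(0.025, 0.975), names = FALSE),
    ellipse = list(center = colMeans(xy), cov = cv,
                   radius2 = stats::qchisq(0.95, df = 2))
  ), class = "dm_psa_summary")
}

#' @export
print.dm_psa_summary <- function(x, ...) {
  cat(sprintf("<dm_psa_summary> n = %d, lambda $%s/QALY\n",
              x$n, format(x$lambda, big.mark = ",")))
  cat(sprintf("  mean delta cost $%.0f, mean delta QALY %.3f\n",
              x$mean_delta_cost, x$mean_delta_effect))
  cat(sprintf("  per-sample ICER mean $%.0f (95%% CI $%.0f to $%.0f)\n",
              x$icer_mean, x$icer_ci[1], x$icer_ci[2]))
  cat(sprintf("  P(cost-effective) = %.3f\n", x$prob_ce))
  invisible(x)
}

#' Points inside the 95% covariance ellipse
#'
#' Helper for coverage checks and plotting: squared Mahalanobis distance of
#' each (delta effect, delta cost) pair from the ellipse centre, compared
#' with the chi-square 2-df radius.
#' @param summary A `dm_psa_summary`.
#' @param psa The `dm_psa` the summary came from.
#' @return Logical vector: inside the ellipse.
#' @export
ellipse_contains <- function(summary, psa) {
  xy <- cbind(psa$delta_effect, psa$delta_cost)
  d2 <- stats::mahalanobis(xy, summary$ellipse$center, summary$ellipse$cov)
  d2 <= summary$ellipse$radius2
}
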