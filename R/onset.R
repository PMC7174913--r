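# Progression from prediabetes to T2DM: Weibull survival model of time to
# diabetes, S(t) = exp(-alpha * t^beta), on the time-since-entry clock.

#' Construct a diabetes onset model
#'
#' @param params List with `alpha` (scale, > 0) and `beta` (shape, > 0).
#' @param hazard_scale Multiplier on the cumulative hazard (proportional
#'   hazards action); `hazard_scale = 0` disables onset.
#' @return An object of class `dm_onset`.
#' @export
onset_model <- function(params, hazard_scale = 1.0) {
  stopifnot(is.list(params), params$alpha > 0, params$beta > 0,
            hazard_scale >= 0)
  structure(list(alpha = params$alpha, beta = params$beta,
                 hazard_scale = hazard_scale), class = "dm_onset")
}

#' Weibull survival (fraction still free of diabetes)
#'
#' `S(t) = exp(-hazard_scale * alpha * t^beta)` with `t` in years since
#' cohort entry.
#' @param t Time(s) in years, non-negative.
#' @param model A [onset_model()].
#' @return Survival fraction(s) in (0, 1].
#' @export
weibull_survival <- function(t, model) {
  if (any(t < 0)) stop("t must be non-negative", call. = FALSE)
  exp(-model$hazard_scale * model$alpha * t^model$beta)
}

#' Annual probability of developing diabetes in cycle k
#'
#' Discretizes the Weibull onset curve to annual cycles:
#' `p_k = 1 - S(k + 1)/S(k)`, the conditional probability of onset during
#' year `k` given diabetes-free at its start. The product of `(1 - p_k)`
#' telescopes back to `S(K)` exactly.
#' @param k Cycle index (integer years since entry, >= 0).
#' @param model A [onset_model()].
#' @export
annual_onset_probability <- function(k, model) {
  if (any(k < 0)) stop("k must be non-negative", call. = FALSE)
  # via the cumulative-hazard increment, which stays finite where S(k)
  # itself underflows
  dH <- model$hazard_scale * model$alpha * ((k + 1)^model$beta - k^model$beta)
  1 - exp(-dH)
}

#' Rescale the onset hazard by a hazard ratio
#'
#' Proportional-hazards action on the cumulative hazard; used to apply the
#' trial hazard ratio of lifestyle intervention versus no prevention
#' (base case 0.55) in sensitivity analyses.
#' @param model A [onset_model()].
#' @param hr Hazard ratio, > 0.
#' @export
scale_onset_hazard <- function(model, hr) {
  if (!is.numeric(hr) || length(hr) != 1L || hr <= 0)
    stop("hr must be a positive number", call. = FALSE)
  model$hazard_scale <- model$hazard_scale * hr
  model
}

#' Fit Weibull onset parameters to Kaplan-Meier points
#'
#' Least-squares fit on the log-cumulative-hazard linearization
#' `ln(-ln S) = ln(alpha) + beta * ln(t)`, the standard way of matching a
#' Weibull to published survival curves. Deterministic.
#'
#' @param points Data frame with columns `time` (> 0) and `survival`
#'   (in (0, 1), non-increasing); an optional `at_risk` column is ignored
#'   by the fit.
#' @return List with `alpha` and `beta`.
#' @export
fit_weibull <- function(points) {
  points <- as.data.frame(points)
  stopifnot(all(c("time", "survival") %in% names(points)))
  ok <- points$time > 0 & points$survival > 0 & points$survival < 1
  pts <- points[ok, , drop = FALSE]
  if (nrow(pts) < 3L)
    stop("fit infeasible: need >= 3 points with time > 0 and 0 < survival < 1",
         call. = FALSE)
  x <- log(pts$time)
  if (length(unique(x)) < 2L)
    stop("fit infeasible: design is rank-deficient (all times identical)",
         call. = FALSE)
  y <- log(-log(pts$survival))
  fit <- stats::lm.fit(cbind(1, x), y)
  list(alpha = unname(exp(fit$coefficients[1])),
       beta = unname(fit$coefficients[2]))
}

#' Read Kaplan-Meier points from CSV
#'
#' Header `time,survival[,at_risk]`.
#' @param path CSV path.
#' @export
read_km_points <- function(path) {
  if (!file.exists(path)) stop("KM points file not found: ", path, call. = FALSE)
  km <- utils::read.csv(path)
  stopifnot(all(c("time", "survival") %in% names(km)))
  if (any(km$survival < 0 | km$survival > 1) || any(km$time < 0) ||
      any(diff(km$survival[order(km$time)]) > 1e-12))
    stop("invalid KM points: survival must be in [0,1] and non-increasing in time",
         call. = FALSE)
  km
}

#' @export
print.dm_onset <- function(x, ...) {
  cat(sprintf("<dm_onset> Weibull(alpha=%.4g, beta=%.4g), hazard scale %.3g\n",
              x$alpha, x$beta, x$hazard_scale))
  invisible(x)
}
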