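# Calibration of the engine's internal scalars to published control-arm
# outcomes: each complication's constant annual hazard is fitted to the
# control-arm lifetime cumulative incidence, and the diabetic mortality
# multiplier m_dm to the control-arm undiscounted life expectancy. The
# intervention arm is never touched, so its outcomes are model predictions.

#' Bundled control-arm calibration targets
#'
#' The published base-case control column: lifetime cumulative incidence of
#' the eight counted complications and total undiscounted life-years.
#' @return Data frame with columns `outcome`, `arm`, `target`, `tolerance`.
#' @export
default_calibration_targets <- function() {
  path <- system.file("extdata", "control_calibration_targets.csv",
                      package = "diabprev", mustWork = TRUE)
  read_calibration_targets(path)
}

#' Read calibration targets from CSV
#'
#' Header `outcome,arm,target,tolerance`; `outcome` is a complication name
#' or `"ly"`.
#' @param path CSV path.
#' @export
read_calibration_targets <- function(path) {
  if (!file.exists(path)) stop("targets file not found: ", path, call. = FALSE)
  tg <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("outcome", "arm", "target", "tolerance")
  if (!all(need %in% names(tg)))
    stop("targets CSV needs columns ", paste(need, collapse = ","), call. = FALSE)
  valid <- c(absorbing_complications(), "ly")
  bad <- setdiff(tg$outcome, valid)
  if (length(bad))
    stop("unknown calibration outcome(s): ", paste(bad, collapse = ", "), call. = FALSE)
  if (any(tg$tolerance <= 0)) stop("tolerances must be > 0", call. = FALSE)
  frac <- tg$outcome != "ly"
  if (any(tg$target[frac] < 0 | tg$target[frac] > 1))
    stop("fraction targets must lie in [0, 1]", call. = FALSE)
  tg
}

control_outcome <- function(config, outcome, life_table) {
  sim <- run_cohort(config, "none", life_table)
  if (outcome == "ly") sim$ly else unname(sim$cumulative_incidence[outcome])
}

set_scalar <- function(config, outcome, value) {
  if (outcome == "ly") config$mortality$m_dm <- value
  else config$hazards[[outcome]] <- value
  config
}

get_scalar <- function(config, outcome) {
  if (outcome == "ly") param_value(config$mortality$m_dm)
  else param_value(config$hazards[[outcome]])
}

# bracketing bisection for a monotone response; direction inferred from the
# endpoint evaluations, which double as the monotonicity/bracket check
bisect_monotone <- function(f, target, bounds, tol, max_iter = 60L) {
  lo <- bounds[1]; hi <- bounds[2]
  flo <- f(lo); fhi <- f(hi)
  if ((flo - target) * (fhi - target) > 0)
    stop(sprintf("target %g not bracketed by bounds [%g, %g] (f = %g, %g)",
                 target, lo, hi, flo, fhi), call. = FALSE)
  increasing <- fhi >= flo
  for (i in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    fm <- f(mid)
    if (abs(fm - target) <= tol) return(mid)
    if ((fm < target) == increasing) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Calibrate one scalar to one control-arm target
#'
#' Returns the multiplier on the config's current scalar (complication
#' hazard, or `m_dm` for the `"ly"` outcome) that reproduces the target;
#' a target already met at the current value returns 1.
#' @param target One-row data frame (or list) with `outcome`, `target`,
#'   `tolerance`.
#' @param config A `dm_config`.
#' @param bounds Multiplier search interval.
#' @param life_table Optional life table.
#' @return The calibrated multiplier.
#' @export
calibrate_scalar <- function(target, config, bounds = c(1e-4, 50),
                             life_table = NULL) {
  outcome <- target$outcome
  base <- get_scalar(config, outcome)
  if (base <= 0) stop("current scalar for ", outcome, " is zero; nothing to scale",
                      call. = FALSE)
  f <- function(s) control_outcome(set_scalar(config, outcome, s * base),
                                   outcome, life_table)
  if (abs(f(1) - target$target) <= target$tolerance) return(1)
  bisect_monotone(f, target$target, bounds, tol = target$tolerance / 4)
}

#' Calibrate all internal scalars to the control-arm targets
#'
#' Coordinate-wise bisection: each complication's hazard is fitted to its
#' cumulative-incidence target, then `m_dm` to the life-year target, with
#' up to `sweeps` outer passes (the complication incidences depend on
#' survival, so a refinement pass follows the mortality fit). Deterministic.
#'
#' @param targets Data frame from [default_calibration_targets()] or
#'   [read_calibration_targets()]; an empty frame returns the config
#'   unchanged.
#' @param config A `dm_config`.
#' @param life_table Optional life table.
#' @param sweeps Maximum outer sweeps.
#' @param tol_frac,tol_ly Inner bisection tolerances for fraction and
#'   life-year outcomes.
#' @return List with elements `config` (calibrated), `report` (data frame of
#'   targets, achieved values, residuals) and `converged`.
#' @export
calibrate_all <- function(targets, config, life_table = NULL, sweeps = 3L,
                          tol_frac = 2e-4, tol_ly = 5e-3) {
  if (nrow(targets) == 0)
    return(list(config = config, report = targets, converged = TRUE))
  if (anyDuplicated(targets$outcome))
    stop("duplicate calibration outcome(s): each target must reference a distinct scalar",
         call. = FALSE)
  validate_config(config)
  comp_rows <- which(targets$outcome != "ly")
  ly_row <- which(targets$outcome == "ly")

  for (sweep in seq_len(sweeps)) {
    for (i in comp_rows) {
      tg <- targets[i, ]
      f <- function(h) control_outcome(set_scalar(config, tg$outcome, h),
                                       tg$outcome, life_table)
      cur <- f(get_scalar(config, tg$outcome))
      if (abs(cur - tg$target) <= tol_frac) next
      h <- bisect_monotone(f, tg$target, c(1e-8, 2.5), tol = tol_frac)
      config <- set_scalar(config, tg$outcome, h)
    }
    if (length(ly_row)) {
      tg <- targets[ly_row, ]
      f <- function(m) control_outcome(set_scalar(config, "ly", m), "ly", life_table)
      cur <- f(get_scalar(config, "ly"))
      if (abs(cur - tg$target) > tol_ly) {
        m <- bisect_monotone(f, tg$target, c(0.2, 30), tol = tol_ly)
        config <- set_scalar(config, "ly", m)
      }
    }
    achieved <- vapply(seq_len(nrow(targets)), function(i)
      control_outcome(config, targets$outcome[i], life_table), numeric(1))
    resid <- achieved - targets$target
    if (all(abs(resid) <= targets$tolerance)) break
  }
  report <- cbind(targets,
                  achieved = achieved,
                  residual = resid,
                  scalar = vapply(targets$outcome, get_scalar,
                                  numeric(1), config = config))
  rownames(report) <- NULL
  list(config = config, report = report,
       converged = all(abs(resid) <= targets$tolerance))
}
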