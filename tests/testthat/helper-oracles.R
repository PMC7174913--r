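# Shared fixtures and independent oracles, all built in code.

const_life_table <- function(qx, from = 45, to = 100) {
  data.frame(age = from:to, qx = c(rep(qx, to - from), 1))
}

# Independent 3-state (non-diabetic, diabetic, dead) transition-matrix
# oracle for constant annual death probability and constant onset
# probability, with death applied before onset within a cycle (the engine's
# order). Occupancy is counted at the start of each cycle.
oracle_three_state <- function(qx, p_onset, m_dm, n_cycles) {
  q_nd <- min(1, qx)
  q_dm <- min(1, qx * m_dm)
  # states: 1 nd, 2 dm, 3 dead; row = from, col = to
  P <- rbind(
    c((1 - q_nd) * (1 - p_onset), (1 - q_nd) * p_onset, q_nd),
    c(0, 1 - q_dm, q_dm),
    c(0, 0, 1)
  )
  occ <- c(1, 0, 0)
  ly <- 0
  cum_dm <- 0
  alive <- numeric(n_cycles)
  for (t in seq_len(n_cycles)) {
    alive[t] <- occ[1] + occ[2]
    ly <- ly + alive[t]
    cum_dm <- cum_dm + occ[1] * (1 - q_nd) * p_onset
    occ <- as.numeric(occ %*% P)
  }
  list(ly = ly, cum_diabetes = cum_dm, alive = alive)
}

# brute-force CEAC counter, deliberately loop-based and independent of ceac()
brute_force_ceac <- function(psa, lambda) {
  hits <- 0L
  for (i in seq_len(psa$n)) {
    if (lambda * psa$delta_effect[i] - psa$delta_cost[i] > 0) hits <- hits + 1L
  }
  hits / psa$n
}

# config with no onset, no complications, unit utility: pure survival model
survival_only_config <- function(qx = 0.02, horizon = 65L, m_dm = 1) {
  cfg <- toy_model_config()
  cfg$economics$horizon_age <- as.integer(horizon)
  cfg$mortality$m_dm <- m_dm
  cfg$utilities$prediabetes <- 1
  cfg$costs$lifestyle_annual <- 0
  cfg$life_table <- const_life_table(qx, 45, horizon)
  cfg
}

# constant-hazard 3-state config: exponential onset (beta = 1) so the
# annual onset probability is constant, no complications
three_state_config <- function(qx = 0.02, onset_alpha = 0.1, m_dm = 2,
                               horizon = 65L) {
  cfg <- survival_only_config(qx, horizon, m_dm)
  cfg$onset$hazard_scale <- 1
  cfg$onset$control <- list(alpha = onset_alpha, beta = 1)
  cfg
}

# expensive shared objects, computed once per test session
.cache <- new.env(parent = emptyenv())
cached <- function(name, expr) {
  if (!exists(name, envir = .cache)) assign(name, force(expr), envir = .cache)
  get(name, envir = .cache)
}

calibrated_default_config <- function() {
  cached("calibrated_config", {
    fit <- calibrate_all(default_calibration_targets(), default_parameters())
    stopifnot(fit$converged)
    fit$config
  })
}

default_psa_1000 <- function() {
  cached("psa_1000", {
    suppressWarnings(run_psa(calibrated_default_config(), n = 1000, seed = 20260924))
  })
}
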