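# Independent oracles used across the suite. These deliberately do not
# share code with the package internals: the beta density is hand-coded
# from log-gamma functions, the rare-mutant fitness oracle runs the
# two-type simulator instead of the time-average formula, and the
# score-function gradient differentiates the log density itself.

# Hand-coded beta log-density (mean/scale parametrisation).
oracle_log_beta <- function(tau, mu, s) {
  a <- mu / s
  b <- (1 - mu) / s
  (a - 1) * log(tau) + (b - 1) * log1p(-tau) -
    (lgamma(a) + lgamma(b) - lgamma(a + b))
}

oracle_beta <- function(tau, mu, s) exp(oracle_log_beta(tau, mu, s))

# Rare-mutant invasion fitness: introduce the mutant at M0 = 1e-8 into the
# resident attractor and measure its average log growth over the same
# post-burn-in window the package averages over.
# M0 must be small enough that even tail-amplified competition pressure
# (alpha_NM can reach exp(several hundred) where the TPCs barely overlap)
# times M stays negligible against the resident.
oracle_rare_mutant_fitness <- function(resident, mutant, regime, params,
                                       cfg, M0 = 1e-30) {
  # one step past L so the final averaging step has its update too
  ts <- generate_temperature(regime, cfg$horizon_L + 1L)
  warm <- simulate_resident(cfg$N0, ts, params)
  # restart the pair at the burn-in state so the averaging windows match
  N_burn <- warm$N[cfg$burn_in + 1L]
  ts_win <- ts
  win <- (cfg$burn_in + 1L):(cfg$horizon_L + 1L)
  ts_win$values <- ts$values[win]
  ts_win$noise_draws <- ts$noise_draws[win]
  traj <- simulate_pair(N_burn, M0, ts_win, params, resident, mutant)
  mean(diff(log(traj$M)))
}

# Score-function form of the selection gradient: the attractor average of
# w_t * d log beta(tau_t; mu, s) / d(mu or s) evaluated at the resident,
# with the log-density derivative computed by its own central difference.
oracle_score_gradient <- function(resident, regime, params, cfg,
                                  h = 1e-5) {
  ts <- generate_temperature(regime, cfg$horizon_L)
  traj <- simulate_resident(cfg$N0, ts, params)
  idx <- (cfg$burn_in + 1L):cfg$horizon_L
  tau <- ts$values[idx]
  w <- growth_rate(tau, params) * traj$N[idx] /
    carrying_capacity(tau, params)
  mu <- resident$mu; s <- resident$s
  score_mu <- (oracle_log_beta(tau, mu + h, s) -
                 oracle_log_beta(tau, mu - h, s)) / (2 * h)
  score_s <- (oracle_log_beta(tau, mu, s + h) -
                oracle_log_beta(tau, mu, s - h)) / (2 * h)
  c(g_mu = mean(w * score_mu), g_s = mean(w * score_s))
}

fig2a_regime <- function(seed = 42L)
  thermal_regime(0.5, 0.25, 13 * pi / 20, 0.5, seed)

fig2b_regime <- function(seed = 42L)
  thermal_regime(0.5, 0.25, 13 * pi / 20, 1.5, seed)

constant_regime <- function(seed = 1L)
  thermal_regime(0.5, 0.25, 2 * pi, 0, seed)

ref_params <- function() demography_params()

fast_cfg <- function(L = 2e4, burn = 1e3) invasion_config(L, burn)
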