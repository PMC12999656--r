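test_that("constant environment drives the population to k and holds it", {
  reg <- constant_regime()           # tau = 0.25 at every integer step
  ts <- generate_temperature(reg, 3000)
  p <- ref_params()
  traj <- simulate_resident(0.1, ts, p)
  k_star <- carrying_capacity(0.25, p)
  expect_lt(abs(traj$N[3000] - k_star), 1e-8)
  # monotone approach from below after the first step
  expect_true(all(diff(traj$N[1:100]) > 0))
  summ <- attractor_summary(traj, burn_in = 2000)
  expect_lt(abs(summ$mean_N - k_star), 1e-8)
  expect_lt(summ$sd_N, 1e-8)
})

test_that("initial conditions are forgotten on a frozen noise sequence", {
  reg <- fig2a_regime(seed = 33)
  ts <- generate_temperature(reg, 600)
  p <- ref_params()
  trajs <- lapply(c(0.1, 0.2, 0.3), simulate_resident, tau = ts, params = p)
  late <- 201:600
  d13 <- max(abs(trajs[[1]]$N[late] - trajs[[3]]$N[late]))
  d12 <- max(abs(trajs[[1]]$N[late] - trajs[[2]]$N[late]))
  expect_lt(d13, 1e-6)
  expect_lt(d12, 1e-6)
  expect_true(all(trajs[[1]]$N > 0))
})

test_that("stronger noise depresses long-run population size", {
  p <- ref_params()
  m_low <- attractor_summary(
    simulate_resident(0.1, generate_temperature(fig2a_regime(7), 2e4), p),
    1000)$mean_N
  m_high <- attractor_summary(
    simulate_resident(0.1, generate_temperature(fig2b_regime(7), 2e4), p),
    1000)$mean_N
  expect_gt(m_low, m_high)
})

test_that("identical shapes make the pair dynamics collapse to one type", {
  reg <- fig2a_regime(5)
  ts <- generate_temperature(reg, 2000)
  p <- ref_params()
  sh <- tpc_shape(0.3, 0.08)
  pair <- simulate_pair(0.15, 0.05, ts, p, sh, sh)
  # equal per-capita growth: M/N ratio frozen
  ratio <- pair$M / pair$N
  expect_lt(max(abs(ratio - ratio[1])), 1e-10 * ratio[1])
  # the summed population obeys the single-type map
  lump <- simulate_resident(0.2, ts, p)
  expect_lt(max(abs(pair$N + pair$M - lump$N)), 1e-10)
})

test_that("a zero mutant is absorbing and leaves the resident untouched", {
  reg <- fig2b_regime(6)
  ts <- generate_temperature(reg, 1500)
  p <- ref_params()
  pair <- simulate_pair(0.1, 0, ts, p, tpc_shape(0.3, 0.08),
                        tpc_shape(0.32, 0.08))
  expect_identical(pair$M, rep(0, 1500))
  solo <- simulate_resident(0.1, ts, p)
  expect_identical(pair$N, solo$N)
})

test_that("attractor summaries are insensitive to burn-in on converged runs", {
  reg <- fig2a_regime(9)
  ts <- generate_temperature(reg, 1e4)
  traj <- simulate_resident(0.1, ts, ref_params())
  m0 <- attractor_summary(traj, 0)$mean_N
  m100 <- attractor_summary(traj, 100)$mean_N
  expect_lt(abs(m0 - m100) / m100, 0.01)
  expect_error(attractor_summary(traj, 1e4), "burn_in")
  expect_error(attractor_summary(traj, -1), "burn_in")
})

test_that("the noise-free map recovers steady vs chaotic regimes", {
  # reference parameters: damped approach to a stable fixed point
  ts <- generate_temperature(constant_regime(), 2000)
  p_ref <- ref_params()
  traj <- simulate_resident(0.1, ts, p_ref)
  expect_lt(sd(traj$N[1500:2000]), 1e-10)
  # alternate reference values (r0 = 5, k0 = 1): r(0.25) ~ 3.45 > 2.692,
  # the Ricker chaos threshold; positive finite-time Lyapunov exponent
  p_ch <- demography_params(r0 = 5, k0 = 1)
  traj_ch <- simulate_resident(0.1, ts, p_ch)
  r <- growth_rate(0.25, p_ch); k <- carrying_capacity(0.25, p_ch)
  n <- traj_ch$N[500:1999]
  lyap <- mean(log(abs((1 - r * n / k) * exp(r * (1 - n / k)))))
  expect_gt(lyap, 0)
})

test_that("divergent trajectories abort with the offending step", {
  # exponent r0*(1 - N/k) exceeds 700 on the very first update
  p <- demography_params(r0 = 2000, c = 0.1, r1 = 0.1, k0 = 2)
  ts <- generate_temperature(constant_regime(), 10)
  expect_error(simulate_resident(1e-6, ts, p), "step 1")
})

test_that("trajectory containers are consistent and exportable", {
  ts <- generate_temperature(fig2a_regime(2), 100)
  pair <- simulate_pair(0.1, 0.01, ts, ref_params(),
                        tpc_shape(0.3, 0.08), tpc_shape(0.31, 0.08))
  df <- as.data.frame(pair)
  expect_named(df, c("t", "tau", "N", "M", "alpha_MN"))
  expect_equal(nrow(df), 100)
  expect_true(all(df$N > 0))
  expect_error(simulate_resident(-1, ts, ref_params()), "positive")
  expect_error(simulate_pair(0.1, -0.5, ts, ref_params(),
                             tpc_shape(0.3, 0.1), tpc_shape(0.3, 0.1)),
               "nonnegative")
})
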