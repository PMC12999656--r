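test_that("a resident is selectively neutral against itself", {
  p <- ref_params()
  cfg <- invasion_config(horizon_L = 1e5, burn_in = 1e3)
  for (reg in list(fig2a_regime(3), fig2b_regime(3))) {
    for (sh in list(tpc_shape(0.2, 0.05), tpc_shape(0.35, 0.15))) {
      lam <- invasion_fitness(sh, sh, reg, p, cfg)
      expect_lt(abs(lam), 1e-3)
      # the self-fitness average telescopes to a boundary term
      ts <- generate_temperature(reg, cfg$horizon_L + 1L)
      traj <- simulate_resident(cfg$N0, ts, p)
      tele <- (log(traj$N[cfg$horizon_L + 1L]) -
                 log(traj$N[cfg$burn_in + 1L])) /
        (cfg$horizon_L - cfg$burn_in)
      expect_equal(lam, tele, tolerance = 1e-10)
    }
  }
})

test_that("time-average fitness equals the rare-mutant simulation oracle", {
  p <- ref_params()
  cfg <- fast_cfg()
  set.seed(202)
  for (i in 1:8) {
    reg <- thermal_regime(0.5, 0.25, runif(1, 0.3, 2) * pi,
                          runif(1, 0.2, 1.5), seed = 300 + i)
    mu <- runif(1, 0.12, 0.4); s <- runif(1, 0.04, 0.2)
    res <- tpc_shape(mu, s)
    mut <- tpc_shape(mu + runif(1, -0.002, 0.002),
                     s + runif(1, -0.002, 0.002))
    lam <- invasion_fitness(res, mut, reg, p, cfg)
    lam_oracle <- oracle_rare_mutant_fitness(res, mut, reg, p, cfg)
    expect_lt(abs(lam - lam_oracle), 1e-6)
  }
})

test_that("gradient evaluation is bit-identical under a frozen seed", {
  reg <- fig2a_regime(17)
  cfg <- fast_cfg(L = 1e4)
  g1 <- selection_gradient(tpc_shape(0.2, 0.06), reg, ref_params(), cfg)
  g2 <- selection_gradient(tpc_shape(0.2, 0.06), reg, ref_params(), cfg)
  expect_identical(as.numeric(g1), as.numeric(g2))
  expect_equal(attr(g1, "seed"), 17L)
})

test_that("finite-difference gradients match the score-function form", {
  # lambda depends on mutant traits only through -alpha_MN, so the
  # gradient is the attractor average of w_t * d log beta / d theta;
  # checked on a 5x5 resident grid at 1% relative accuracy
  reg <- fig2a_regime(23)
  p <- ref_params()
  cfg <- fast_cfg()
  for (mu in seq(0.15, 0.45, length.out = 5)) {
    for (s in seq(0.04, 0.2, length.out = 5)) {
      res <- tpc_shape(mu, s)
      g <- selection_gradient(res, reg, p, cfg)
      g_or <- oracle_score_gradient(res, reg, p, cfg)
      expect_lt(max(abs(as.numeric(g) - g_or)) / max(abs(g_or)), 0.01)
    }
  }
})

test_that("gradients respect the finite-difference domain precondition", {
  reg <- fig2a_regime(1)
  cfg <- invasion_config(horizon_L = 5e3, burn_in = 500, fd_step = 0.01)
  expect_error(selection_gradient(tpc_shape(0.995, 0.05), reg,
                                  ref_params(), cfg), "stencil")
  expect_error(selection_gradient(tpc_shape(0.5, 0.005), reg,
                                  ref_params(), cfg), "stencil")
})

test_that("the fitness Hessian is symmetric and negative definite at a CSS", {
  reg <- fig2a_regime(42)
  p <- ref_params()
  cfg <- fast_cfg()
  fit <- find_singularity(c(0.2, 0.05), reg, p, cfg)
  H <- fitness_hessian(tpc_shape(fit$mu_star, fit$s_star), reg, p, cfg)
  expect_true(all(H$eigenvalues < 0))
  expect_equal(H$entries[1, 2], H$entries[2, 1])
  # mixed partials commute: nested one-sided differences in the two
  # mutant traits (resident held fixed) agree with the 4-point stencil
  h1 <- 1e-4; h2 <- 1e-3
  x <- c(fit$mu_star, fit$s_star)
  fd_mu_at_s <- function(ds) {
    (invasion_fitness(x, x + c(h1, ds), reg, p, cfg) -
       invasion_fitness(x, x + c(-h1, ds), reg, p, cfg)) / (2 * h1)
  }
  h12_alt <- (fd_mu_at_s(h2) - fd_mu_at_s(-h2)) / (2 * h2)
  expect_lt(abs(H$entries[1, 2] - h12_alt) / max(abs(H$entries)), 0.01)
})

test_that("ensemble averaging across noise streams is available", {
  reg <- fig2a_regime(5)
  p <- ref_params()
  cfg1 <- invasion_config(horizon_L = 5e3, burn_in = 500,
                          ensemble_reps = 1)
  cfg3 <- invasion_config(horizon_L = 5e3, burn_in = 500,
                          ensemble_reps = 3)
  res <- tpc_shape(0.25, 0.08); mut <- tpc_shape(0.26, 0.08)
  l1 <- invasion_fitness(res, mut, reg, p, cfg1)
  l3 <- invasion_fitness(res, mut, reg, p, cfg3)
  expect_false(identical(l1, l3))
  expect_lt(abs(l1 - l3), 0.05)  # same quantity, different noise sample
})
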