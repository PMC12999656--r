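# Singularity location and classification. These tests run at a reduced
# averaging length (L = 2e4, or less where noted) -- ample for the
# solver-consistency properties they assert.

test_that("Newton and canonical continuation agree on the singularity", {
  reg <- fig2a_regime(42)
  p <- ref_params()
  cfg <- fast_cfg()
  rep_newton <- find_singularity(c(0.2, 0.05), reg, p, cfg)
  expect_false(rep_newton$boundary)
  expect_lt(rep_newton$grad_norm, 1e-3)
  traj <- canonical_trajectory(c(0.35, 0.15), reg, p, cfg,
                               canonical_config(grad_tol = 5e-3))
  expect_true(attr(traj, "converged"))
  xe <- attr(traj, "endpoint")
  expect_lt(sqrt(sum((xe - c(rep_newton$mu_star,
                             rep_newton$s_star))^2)), 0.005)
})

test_that("a converged singularity is a fixed point of the flow", {
  reg <- fig2a_regime(42)
  p <- ref_params()
  cfg <- fast_cfg()
  rep <- find_singularity(c(0.2, 0.05), reg, p, cfg)
  traj <- canonical_trajectory(c(rep$mu_star, rep$s_star), reg, p, cfg)
  expect_true(attr(traj, "converged"))
  expect_lte(nrow(traj), 2)
  xe <- attr(traj, "endpoint")
  expect_lt(abs(xe[["mu"]] - rep$mu_star), 1e-4)
  expect_lt(abs(xe[["s"]] - rep$s_star), 1e-4)
})

test_that("the singularity and its stability do not depend on the
           mutational covariance", {
  reg <- fig2a_regime(42)
  p <- ref_params()
  cfg <- fast_cfg()
  rep_id <- find_singularity(c(0.2, 0.05), reg, p, cfg,
                             canonical_config(E = diag(2)))
  set.seed(31)
  for (i in 1:5) {
    A <- matrix(rnorm(4), 2)
    E <- crossprod(A) + 0.1 * diag(2)    # random SPD
    rep_E <- find_singularity(c(0.2, 0.05), reg, p, cfg,
                              canonical_config(E = E))
    expect_lt(abs(rep_E$mu_star - rep_id$mu_star), 1e-4)
    expect_lt(abs(rep_E$s_star - rep_id$s_star), 1e-4)
    expect_equal(all(Re(rep_E$jacobian_eigs) < 0),
                 all(Re(rep_id$jacobian_eigs) < 0))
  }
})

test_that("canonical trajectories reach the singularity from afar and
           under a random covariance", {
  reg <- fig2a_regime(42)
  p <- ref_params()
  cfg <- fast_cfg(L = 5e3, burn = 500)
  target <- find_singularity(c(0.2, 0.05), reg, p, cfg)
  can <- canonical_config(grad_tol = 5e-3, max_iters = 4000)
  traj <- canonical_trajectory(c(0.5, 0.3), reg, p, cfg, can)
  xe <- attr(traj, "endpoint")
  expect_lt(sqrt(sum((xe - c(target$mu_star, target$s_star))^2)), 0.02)
  set.seed(8)
  A <- matrix(rnorm(4), 2)
  canE <- canonical_config(E = crossprod(A) + 0.1 * diag(2),
                           grad_tol = 5e-3, max_iters = 4000)
  trajE <- canonical_trajectory(c(0.5, 0.3), reg, p, cfg, canE)
  expect_lt(sqrt(sum((attr(trajE, "endpoint") -
                        c(target$mu_star, target$s_star))^2)), 0.02)
})

test_that("verdicts are a pure function of the stability eigenvalues", {
  reg <- fig2a_regime(42)
  cfg <- fast_cfg()
  rep <- find_singularity(c(0.2, 0.05), reg, ref_params(), cfg)
  expect_equal(rep$verdict,
               tpcevol:::verdict_from_eigs(rep$jacobian_eigs,
                                           rep$hessian_eigs))
  expect_equal(tpcevol:::verdict_from_eigs(c(-1, -2), c(-1, -3)), "CSS")
  expect_equal(tpcevol:::verdict_from_eigs(c(-1, -2), c(1, -3)),
               "convergence-stable-only (branching candidate)")
  expect_equal(tpcevol:::verdict_from_eigs(c(1, -2), c(-1, -3)),
               "ESS-only")
  expect_equal(tpcevol:::verdict_from_eigs(c(1i, 2), c(2, 1)), "repeller")
})

test_that("classification requires an actually singular point", {
  reg <- fig2a_regime(42)
  cfg <- fast_cfg(L = 5e3, burn = 500)
  expect_error(classify_singularity(tpc_shape(0.5, 0.3), reg,
                                    ref_params(), cfg), "not singular")
  rep <- find_singularity(c(0.2, 0.05), reg, ref_params(), cfg)
  rep2 <- classify_singularity(tpc_shape(rep$mu_star, rep$s_star), reg,
                               ref_params(), cfg)
  expect_equal(rep2$verdict, rep$verdict)
})

test_that("a constant environment drives the breadth to the boundary with
           the optimum at the mean temperature", {
  rep <- find_singularity(c(0.2, 0.08), constant_regime(), ref_params(),
                          invasion_config(horizon_L = 5e3, burn_in = 500))
  expect_true(rep$boundary)
  expect_equal(rep$boundary_coord, "s")
  expect_equal(rep$s_star, 0.005)      # lower edge of the trait box
  expect_lt(abs(rep$tau_opt_star - 0.25), 0.01)
  expect_lt(rep$breadth_star, 0.05)
  expect_equal(rep$verdict, "boundary")
})

test_that("nullclines intersect where the singularity solver converges", {
  reg <- fig2a_regime(42)
  p <- ref_params()
  cfg <- fast_cfg(L = 1e4)
  target <- find_singularity(c(0.2, 0.05), reg, p, cfg)
  nc <- nullclines(reg, p, cfg,
                   mu_grid = seq(0.08, 0.4, length.out = 15),
                   s_grid = seq(0.01, 0.15, length.out = 15))
  expect_gt(nrow(nc$g_mu_zero), 0)
  expect_gt(nrow(nc$g_s_zero), 0)
  expect_gte(nrow(nc$intersections), 1)
  d <- sqrt((nc$intersections$mu - target$mu_star)^2 +
              (nc$intersections$s - target$s_star)^2)
  expect_lt(min(d), 0.02)
  # a grid with no sign change warns and returns empty contours
  expect_warning(expect_warning(
    nc0 <- nullclines(reg, p, cfg,
                      mu_grid = seq(0.7, 0.8, length.out = 3),
                      s_grid = seq(0.5, 0.6, length.out = 3)),
    "g_mu has no sign change"), "g_s has no sign change")
  expect_equal(nrow(nc0$intersections), 0)
})
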