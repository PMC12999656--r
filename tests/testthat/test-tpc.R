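test_that("beta TPC agrees with an independently coded beta density", {
  set.seed(101)
  for (i in 1:25) {
    mu <- runif(1, 0.05, 0.95)
    s <- runif(1, 0.02, 1.5)
    tau <- runif(5, 0.01, 0.99)
    expect_equal(beta_density(tau, tpc_shape(mu, s)),
                 oracle_beta(tau, mu, s), tolerance = 1e-10)
  }
  expect_error(beta_density(0, tpc_shape(0.3, 0.1)), "strictly inside")
  expect_error(beta_density(1, tpc_shape(0.3, 0.1)), "strictly inside")
})

test_that("the TPC is a probability density: unit mass, conserved area", {
  for (sh in list(tpc_shape(0.17, 0.09), tpc_shape(0.5, 0.6),
                  tpc_shape(0.14, 0.14), tpc_shape(0.8, 0.3))) {
    integ <- integrate(function(x) beta_density(x, sh), 0, 1,
                       rel.tol = 1e-9)
    expect_lt(abs(integ$value - 1), 1e-6)
  }
})

test_that("symmetric shapes give mirror-image densities", {
  sh <- tpc_shape(0.5, 0.2)
  expect_equal(beta_density(0.3, sh), beta_density(0.7, sh))
})

test_that("thermal optimum reproduces reference values and grid argmax", {
  expect_equal(round(as.numeric(tpc_optimum(tpc_shape(0.17, 0.09))), 4),
               0.0976)
  expect_equal(tpc_optimum(tpc_shape(0.14, 0.14)), 0,
               ignore_attr = TRUE)
  expect_equal(tpc_optimum(tpc_shape(0.5, 0.1)), 0.5, ignore_attr = TRUE)
  # grid argmax agrees with the closed form for unimodal shapes
  grid <- seq(1e-4, 1 - 1e-4, length.out = 20001)
  for (sh in list(tpc_shape(0.17, 0.09), tpc_shape(0.3, 0.1),
                  tpc_shape(0.6, 0.2))) {
    am <- grid[which.max(beta_density(grid, sh))]
    expect_lt(abs(am - tpc_optimum(sh)), 1e-4)
  }
})

test_that("breadth statistics match the closed forms and the density", {
  expect_equal(round(tpc_breadth_squared(tpc_shape(0.13, 0.06)), 4),
               0.0064)
  expect_equal(tpc_breadth(tpc_shape(0.5, 1)), sqrt(0.25 / 2))
  expect_lt(tpc_breadth(tpc_shape(0.3, 1e-6)), 1e-3)
  # numerical variance of the density equals breadth_squared
  for (sh in list(tpc_shape(0.17, 0.09), tpc_shape(0.4, 0.3))) {
    m1 <- integrate(function(x) x * beta_density(x, sh), 0, 1,
                    rel.tol = 1e-10)$value
    m2 <- integrate(function(x) (x - m1)^2 * beta_density(x, sh), 0, 1,
                    rel.tol = 1e-10)$value
    expect_lt(abs(m2 - tpc_breadth_squared(sh)), 1e-6)
  }
})

test_that("shape classification follows the beta shape parameters", {
  expect_equal(classify_shape(tpc_shape(0.17, 0.09))$label,
               "unimodal-interior")
  expect_equal(classify_shape(tpc_shape(0.14, 0.14))$label,
               "right-skewed-J")
  expect_equal(classify_shape(tpc_shape(0.86, 0.14))$label,
               "left-skewed-J")
  cl <- classify_shape(tpc_shape(0.5, 0.6))
  expect_equal(cl$label, "U-shaped")
  expect_true(cl$symmetric)
  expect_false(classify_shape(tpc_shape(0.17, 0.09))$symmetric)
  # property: labels track a = mu/s, b = (1-mu)/s on random shapes
  set.seed(7)
  for (i in 1:40) {
    mu <- runif(1, 0.05, 0.95); s <- runif(1, 0.02, 1.9)
    a <- mu / s; b <- (1 - mu) / s
    lab <- classify_shape(tpc_shape(mu, s))$label
    expected <- if (a > 1 && b > 1) "unimodal-interior"
      else if (a <= 1 && b > 1) "right-skewed-J"
      else if (b <= 1 && a > 1) "left-skewed-J" else "U-shaped"
    expect_equal(lab, expected)
  }
  # U-shaped optimum is degenerate, at the more divergent boundary
  opt <- tpc_optimum(tpc_shape(0.3, 1.5))
  expect_true(attr(opt, "degenerate"))
  expect_equal(as.numeric(opt), 0)  # a < b: cold boundary diverges faster
})

test_that("competition coefficients are reciprocal and match the oracle", {
  sh <- tpc_shape(0.3, 0.05)
  cc <- competition_coefficients(0.42, sh, sh)
  expect_equal(cc$alpha_MN, 1)
  expect_equal(cc$alpha_NM, 1)
  res <- tpc_shape(0.30, 0.05); mut <- tpc_shape(0.35, 0.05)
  cc <- competition_coefficients(0.30, res, mut)
  expect_equal(cc$alpha_MN,
               oracle_beta(0.30, 0.30, 0.05) / oracle_beta(0.30, 0.35, 0.05),
               tolerance = 1e-10)
  # reciprocity at machine precision for random pairs and temperatures
  set.seed(11)
  for (i in 1:30) {
    r <- tpc_shape(runif(1, 0.1, 0.9), runif(1, 0.03, 0.8))
    m <- tpc_shape(runif(1, 0.1, 0.9), runif(1, 0.03, 0.8))
    tau <- runif(1, 0.05, 0.95)
    cc <- competition_coefficients(tau, r, m)
    expect_lt(abs(cc$alpha_MN * cc$alpha_NM - 1), 1e-12)
  }
})

test_that("extreme density ratios raise a numerical-range error", {
  res <- tpc_shape(0.9, 0.001)   # spike at 0.9
  mut <- tpc_shape(0.1, 0.001)   # spike at 0.1
  expect_error(competition_coefficients(0.9, res, mut), "numerical range")
})

test_that("narrow TPCs concentrate their mass around the mean", {
  for (s in c(0.05, 0.01, 0.002)) {
    sh <- tpc_shape(0.3, s)
    lo <- max(0, 0.3 - 3 * tpc_breadth(sh))
    hi <- min(1, 0.3 + 3 * tpc_breadth(sh))
    mass <- integrate(function(x) beta_density(x, sh), lo, hi)$value
    expect_gt(mass, 0.95)
  }
})

test_that("shape construction rejects out-of-range parameters", {
  expect_error(tpc_shape(0, 0.1), "mu")
  expect_error(tpc_shape(1, 0.1), "mu")
  expect_error(tpc_shape(0.5, 0), "s")
  expect_error(tpc_shape(0.5, -1), "s")
})
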