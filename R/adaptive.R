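# Canonical adaptive-dynamics machinery: trait trajectories under
# (mu_dot, s_dot) = 1/2 * Ne * E * (g_mu, g_s), evolutionary nullclines,
# singularity location by damped Newton iteration on the selection
# gradient, and CSS/ESS classification from the eigenvalues of the
# canonical Jacobian (convergence stability) and the fitness Hessian
# (evolutionary stability).
#
# The admissible trait box is mu in [0.01, 0.99], s in [0.005, 1.99].
# Boundary convergence -- required by the constant-environment limit, in
# which the breadth collapses toward zero -- is a first-class outcome, not
# an error.

TRAIT_LOWER <- c(0.01, 0.005)
TRAIT_UPPER <- c(0.99, 1.99)

#' Numerical controls for the canonical equations
#'
#' @param E 2x2 symmetric positive-definite mutational covariance matrix
#'   (default identity: independent mutations in `mu` and `s`). The factor
#'   1/2 of the canonical equations (the fraction of mutations surviving
#'   drift under directional selection) is applied internally. Because the
#'   mutation rate and variance only rescale time, trait trajectories have
#'   arbitrary time units; endpoints and signs are the meaningful output.
#' @param step_eta Step-size scale of the trait-space continuation (trait
#'   units): steps along the canonical direction start at `step_eta/10`,
#'   are capped at `step_eta/2.5`, and shrink whenever the direction field
#'   reverses (overshoot). Only the endpoint is meaningful; see `E` on the
#'   arbitrariness of the time units.
#' @param max_iters Iteration cap.
#' @param grad_tol Stopping tolerance on the selection-gradient norm (on
#'   the fitness scale).
#' @return An object of class `"canonical_config"`.
#' @export
canonical_config <- function(E = diag(2), step_eta = 0.05,
                             max_iters = 2000, grad_tol = 1e-3) {
  E <- as.matrix(E)
  if (!all(dim(E) == c(2, 2)) || max(abs(E - t(E))) > 1e-10)
    stop("'E' must be a symmetric 2x2 matrix", call. = FALSE)
  if (any(eigen(E, symmetric = TRUE, only.values = TRUE)$values <= 0))
    stop("'E' must be positive definite", call. = FALSE)
  stopifnot(step_eta > 0, max_iters >= 1, grad_tol > 0)
  structure(list(E = E, step_eta = step_eta,
                 max_iters = as.integer(max_iters), grad_tol = grad_tol),
            class = "canonical_config")
}

clamp_box <- function(x) pmin(pmax(x, TRAIT_LOWER), TRAIT_UPPER)

#' Canonical-equation trait trajectory
#'
#' Integrates the canonical equations of adaptive dynamics,
#' \deqn{(\dot\mu, \dot s) = \tfrac{1}{2} \hat N_e \, E \, (\bar g_\mu, \bar g_s),}
#' from a starting strategy by steering along the direction of the
#' canonical vector field with adaptive arc-length steps (shrunk on
#' direction reversal), clamped to the admissible trait box (clamps are
#' counted in the `"clamp_events"` attribute). Because mutation rate and
#' variance only rescale time, the trajectory's parametrisation is
#' arbitrary; its path and endpoint are the meaningful output. \eqn{\hat N_e}
#' is the attractor average of the resident population size; the resident's
#' own dynamics do not involve its competition TPC, so re-estimating it
#' along the trajectory returns the same cached value for a fixed regime.
#'
#' @param start Starting [tpc_shape()] (or `(mu, s)` vector).
#' @param regime A [thermal_regime()].
#' @param params A [demography_params()].
#' @param inv_cfg An [invasion_config()].
#' @param can_cfg A [canonical_config()].
#' @return A data frame with columns `iter`, `mu`, `s`, `g_mu`, `g_s`,
#'   with attributes `converged` (gradient norm below tolerance),
#'   `boundary` (ended clamped to the trait box with outward-pointing
#'   gradient), `clamp_events`, and `Ne`.
#' @export
canonical_trajectory <- function(start, regime, params,
                                 inv_cfg = invasion_config(),
                                 can_cfg = canonical_config()) {
  start <- as_tpc_shape(start)
  ctx <- resolve_ctx(regime, params, inv_cfg)
  pref <- 0.5 * ctx$Ne * can_cfg$E
  x <- c(start$mu, start$s)
  # Trait-space arc-length continuation along the canonical direction
  # field: the direction (not the magnitude) of 1/2 * Ne * E * g sets each
  # move, with the step length shrinking on overshoot (direction
  # reversal). The gradient magnitude only rescales time, which is
  # arbitrary here; steering by direction keeps the integration robust
  # when an anisotropic E makes the gradient norm rise along the true
  # flow.
  len <- can_cfg$step_eta / 10
  len_max <- can_cfg$step_eta / 2.5
  rows <- vector("list", can_cfg$max_iters + 1L)
  g <- gradient_ctx(ctx, x)
  gn <- sqrt(sum(g^2))
  v_old <- NULL
  rows[[1]] <- c(0, x, g)
  clamps <- 0L
  converged <- FALSE
  i <- 0L
  while (i < can_cfg$max_iters) {
    i <- i + 1L
    if (gn < can_cfg$grad_tol) { converged <- TRUE; break }
    v <- drop(pref %*% g)
    vn <- sqrt(sum(v^2))
    if (vn == 0) { converged <- TRUE; break }
    if (!is.null(v_old)) {
      if (sum(v * v_old) < 0) len <- max(len / 2, 1e-6)  # overshoot
      else len <- min(len * 1.3, len_max)
    }
    xn <- clamp_box(x + len * v / vn)
    if (any(xn != x + len * v / vn)) clamps <- clamps + 1L
    g_new <- tryCatch(gradient_ctx(ctx, xn), error = function(e) NULL)
    if (is.null(g_new)) break
    if (all(xn == x)) break   # fully pinned against the box: stalled
    v_old <- v
    x <- xn
    g <- g_new
    gn <- sqrt(sum(g^2))
    rows[[i + 1L]] <- c(i, x, g)
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  out <- as.data.frame(do.call(rbind, rows))
  names(out) <- c("iter", "mu", "s", "g_mu", "g_s")
  on_bound <- (x <= TRAIT_LOWER & drop(pref %*% g) < 0) |
              (x >= TRAIT_UPPER & drop(pref %*% g) > 0)
  attr(out, "converged") <- converged
  attr(out, "boundary") <- !converged && any(on_bound)
  attr(out, "clamp_events") <- clamps
  attr(out, "Ne") <- ctx$Ne
  attr(out, "endpoint") <- c(mu = x[1], s = x[2])
  out
}

# Damped, box-clamped Newton iteration on the gradient map. Returns the
# final point plus convergence diagnostics.
newton_singularity <- function(ctx, x0, tol = 1e-8, maxit = 60,
                               jac_step = 1e-3) {
  x <- clamp_box(x0)
  g <- gradient_ctx(ctx, x)
  gn <- sqrt(sum(g^2))
  for (i in seq_len(maxit)) {
    if (gn < tol) break
    J <- fd_jacobian(function(y) gradient_ctx(ctx, y), x, jac_step)
    dx <- tryCatch(-solve(J, g), error = function(e) -0.01 * g)
    improved <- FALSE
    for (damp in 2^-(0:8)) {
      xn <- clamp_box(x + damp * dx)
      gn_new <- tryCatch(sqrt(sum(gradient_ctx(ctx, xn)^2)),
                         error = function(e) Inf)
      if (gn_new < gn) { improved <- TRUE; break }
    }
    if (!improved) break
    x <- xn
    g <- gradient_ctx(ctx, x)
    gn <- sqrt(sum(g^2))
  }
  list(x = x, g = g, gnorm = gn, iters = i,
       interior = all(x > TRAIT_LOWER & x < TRAIT_UPPER))
}

fd_jacobian <- function(f, x, h) {
  n <- length(x)
  cols <- lapply(seq_len(n), function(j) {
    e <- numeric(n); e[j] <- h
    (f(x + e) - f(x - e)) / (2 * h)
  })
  do.call(cbind, cols)
}

verdict_from_eigs <- function(jacobian_eigs, hessian_eigs) {
  conv <- all(Re(jacobian_eigs) < 0)
  ess <- all(hessian_eigs < 0)
  if (conv && ess) "CSS"
  else if (!conv && ess) "ESS-only"
  else if (conv && !ess) "convergence-stable-only (branching candidate)"
  else "repeller"
}

build_report <- function(ctx, x, g, can_cfg, boundary = FALSE,
                         boundary_coord = character(0),
                         diagnostics = list()) {
  x <- unname(x)
  shape <- tpc_shape(x[1], x[2])
  cl <- classify_shape(shape)
  hess <- fitness_hessian(shape, ctx, ctx$params, ctx$cfg)
  pref <- 0.5 * ctx$Ne * can_cfg$E
  field <- function(y) drop(pref %*% gradient_ctx(ctx, clamp_box(y)))
  J <- fd_jacobian(field, x, 1e-3)
  jac_eigs <- eigen(J, only.values = TRUE)$values
  verdict <- if (boundary) "boundary"
             else verdict_from_eigs(jac_eigs, hess$eigenvalues)
  structure(list(mu_star = x[1], s_star = x[2],
                 tau_opt_star = as.numeric(tpc_optimum(shape)),
                 breadth_star = tpc_breadth(shape),
                 breadth_sq_star = tpc_breadth_squared(shape),
                 shape_class = cl,
                 gradient = g,
                 grad_norm = sqrt(sum(g^2)),
                 jacobian = J,
                 jacobian_eigs = jac_eigs,
                 hessian = hess,
                 hessian_eigs = hess$eigenvalues,
                 verdict = verdict,
                 boundary = boundary,
                 boundary_coord = boundary_coord,
                 Ne = ctx$Ne,
                 seed = ctx$seed,
                 regime = ctx$regime, params = ctx$params,
                 inv_cfg = ctx$cfg, can_cfg = can_cfg,
                 diagnostics = diagnostics),
            class = "singularity_report")
}

#' Locate the evolutionary singularity
#'
#' Finds a joint root of the two selection gradients by damped Newton
#' iteration (with a finite-difference Jacobian of the gradient map) from
#' an interior initial guess, falling back to canonical-trajectory
#' continuation when Newton stalls. If selection pushes a trait against the
#' admissible box -- as the breadth in a constant environment, where the
#' singular TPC collapses toward a spike at the mean temperature -- the
#' clamped coordinate is held at the boundary, the remaining gradient
#' component is solved to zero along the edge, and the report is flagged
#' `boundary` rather than classified.
#'
#' @param initial_guess Starting [tpc_shape()] (or `(mu, s)` vector).
#' @inheritParams canonical_trajectory
#' @return An object of class `"singularity_report"`: the singular strategy
#'   `(mu_star, s_star)` with its derived optimum, breadth (and square),
#'   shape class, selection gradient and norm at the root, canonical
#'   Jacobian and its eigenvalues (convergence stability), fitness Hessian
#'   and its eigenvalues (evolutionary stability), the verdict (`"CSS"`,
#'   `"ESS-only"`, `"convergence-stable-only (branching candidate)"`,
#'   `"repeller"`, or `"boundary"`), the effective population size, the
#'   noise seed, and solver diagnostics.
#' @examples
#' \donttest{
#' reg <- thermal_regime(sigma_eps = 0.5, seed = 1)
#' cfg <- invasion_config(horizon_L = 2e4)
#' find_singularity(c(mu = 0.2, s = 0.05), reg, demography_params(), cfg)
#' }
#' @export
find_singularity <- function(initial_guess, regime, params,
                             inv_cfg = invasion_config(),
                             can_cfg = canonical_config()) {
  guess <- as_tpc_shape(initial_guess)
  ctx <- resolve_ctx(regime, params, inv_cfg)
  ns <- newton_singularity(ctx, c(guess$mu, guess$s))
  if (ns$interior && ns$gnorm < can_cfg$grad_tol)
    return(build_report(ctx, ns$x, ns$g, can_cfg,
                        diagnostics = list(method = "newton",
                                           iters = ns$iters,
                                           residual = ns$gnorm)))
  # Newton stalled or hit the box: continue along the canonical flow.
  # (Damped Newton alone can drift into the flat far field, where the
  # gradient is small but nonzero; the flow cannot.)
  traj <- canonical_trajectory(guess, ctx, params, inv_cfg, can_cfg)
  xe <- unname(attr(traj, "endpoint"))
  if (attr(traj, "converged")) {
    ns2 <- newton_singularity(ctx, xe)
    use <- if (ns2$interior && ns2$gnorm < can_cfg$grad_tol &&
               sqrt(sum((ns2$x - xe)^2)) < 0.05) ns2
      else list(x = xe, g = gradient_ctx(ctx, xe),
                gnorm = sqrt(sum(gradient_ctx(ctx, xe)^2)), iters = 0L)
    return(build_report(ctx, use$x, use$g, can_cfg,
                        diagnostics = list(method = "continuation+newton",
                                           iters = use$iters,
                                           residual = use$gnorm)))
  }
  # Boundary convergence: pin the clamped coordinate(s), solve the rest.
  x <- clamp_box(xe)
  g <- gradient_ctx(ctx, x)
  pinned <- (x <= TRAIT_LOWER & g < 0) | (x >= TRAIT_UPPER & g > 0)
  if (any(pinned)) {
    free <- which(!pinned)
    if (length(free) == 1L) {
      f1 <- function(v) { y <- x; y[free] <- v; gradient_ctx(ctx, y)[free] }
      br <- c(TRAIT_LOWER[free] + 2 * ctx$cfg$fd_step,
              TRAIT_UPPER[free] - 2 * ctx$cfg$fd_step)
      root <- tryCatch(stats::uniroot(f1, br, tol = 1e-9)$root,
                       error = function(e) x[free])
      x[free] <- root
    }
    g <- gradient_ctx(ctx, x)
    return(build_report(ctx, x, g, can_cfg, boundary = TRUE,
                        boundary_coord = c("mu", "s")[pinned],
                        diagnostics = list(method = "boundary",
                                           residual_free =
                                             sqrt(sum(g[!pinned]^2)))))
  }
  stop("singularity search did not converge: endpoint (",
       paste(format(x, digits = 5), collapse = ", "),
       ") with gradient norm ", format(sqrt(sum(g^2)), digits = 4),
       "; inspect the canonical trajectory from this start", call. = FALSE)
}

#' Classify an evolutionary singularity
#'
#' Computes convergence stability (eigenvalues of the finite-difference
#' Jacobian of the canonical vector field with respect to the resident
#' traits) and evolutionary stability (eigenvalues of the invasion-fitness
#' Hessian in the mutant traits), and combines them into a verdict: a CSS
#' is both an attractor of gradual evolution and uninvadable. The point
#' must already be singular (gradient norm below `can_cfg$grad_tol`).
#'
#' @param point A [tpc_shape()] (or `(mu, s)` vector) at which both
#'   selection gradients vanish.
#' @inheritParams canonical_trajectory
#' @return A `"singularity_report"`, as for [find_singularity()].
#' @export
classify_singularity <- function(point, regime, params,
                                 inv_cfg = invasion_config(),
                                 can_cfg = canonical_config()) {
  point <- as_tpc_shape(point)
  ctx <- resolve_ctx(regime, params, inv_cfg)
  x <- c(point$mu, point$s)
  g <- gradient_ctx(ctx, x)
  if (sqrt(sum(g^2)) >= can_cfg$grad_tol)
    stop("point is not singular: gradient norm ",
         format(sqrt(sum(g^2)), digits = 4), " >= grad_tol ",
         can_cfg$grad_tol, call. = FALSE)
  build_report(ctx, x, g, can_cfg,
               diagnostics = list(method = "classify-only"))
}

#' Evolutionary nullclines on a trait grid
#'
#' Evaluates both selection gradients on a rectangular `(mu, s)` grid and
#' extracts the zero contours of each by linear interpolation along grid
#' edges. Grid cells in which both components change sign provide
#' approximate nullcline intersections (candidate singularities), refined
#' by a local linear solve within the cell. The mutational covariance does
#' not enter the gradients, so nullclines are invariant under it.
#'
#' @param regime A [thermal_regime()].
#' @param params A [demography_params()].
#' @param inv_cfg An [invasion_config()].
#' @param mu_grid,s_grid Increasing grid vectors inside the admissible box.
#' @return A list with data frames `g_mu_zero` and `g_s_zero` (contour
#'   points), `intersections` (approximate joint roots), and `field` (the
#'   full grid with both gradient components). Empty contours trigger a
#'   warning.
#' @export
nullclines <- function(regime, params, inv_cfg = invasion_config(),
                       mu_grid = seq(0.05, 0.6, length.out = 30),
                       s_grid = seq(0.01, 0.3, length.out = 30)) {
  stopifnot(all(diff(mu_grid) > 0), all(diff(s_grid) > 0),
            min(mu_grid) >= TRAIT_LOWER[1], max(mu_grid) <= TRAIT_UPPER[1],
            min(s_grid) >= TRAIT_LOWER[2], max(s_grid) <= TRAIT_UPPER[2])
  ctx <- resolve_ctx(regime, params, inv_cfg)
  nm <- length(mu_grid); ns <- length(s_grid)
  gmu <- matrix(NA_real_, nm, ns)
  gs <- matrix(NA_real_, nm, ns)
  for (j in seq_len(ns)) for (i in seq_len(nm)) {
    g <- gradient_ctx(ctx, c(mu_grid[i], s_grid[j]))
    gmu[i, j] <- g[1]; gs[i, j] <- g[2]
  }
  contour_pts <- function(z) {
    pts <- list()
    for (j in seq_len(ns)) for (i in seq_len(nm - 1)) {
      z1 <- z[i, j]; z2 <- z[i + 1, j]
      if (is.finite(z1) && is.finite(z2) && z1 * z2 < 0) {
        f <- z1 / (z1 - z2)
        pts[[length(pts) + 1]] <-
          c(mu_grid[i] + f * (mu_grid[i + 1] - mu_grid[i]), s_grid[j])
      }
    }
    for (i in seq_len(nm)) for (j in seq_len(ns - 1)) {
      z1 <- z[i, j]; z2 <- z[i, j + 1]
      if (is.finite(z1) && is.finite(z2) && z1 * z2 < 0) {
        f <- z1 / (z1 - z2)
        pts[[length(pts) + 1]] <-
          c(mu_grid[i], s_grid[j] + f * (s_grid[j + 1] - s_grid[j]))
      }
    }
    if (length(pts) == 0)
      return(data.frame(mu = numeric(0), s = numeric(0)))
    out <- as.data.frame(do.call(rbind, pts))
    names(out) <- c("mu", "s")
    out
  }
  cmu <- contour_pts(gmu)
  cs <- contour_pts(gs)
  if (nrow(cmu) == 0) warning("g_mu has no sign change on the grid")
  if (nrow(cs) == 0) warning("g_s has no sign change on the grid")
  inter <- list()
  for (j in seq_len(ns - 1)) for (i in seq_len(nm - 1)) {
    c1 <- c(gmu[i, j], gmu[i + 1, j], gmu[i, j + 1], gmu[i + 1, j + 1])
    c2 <- c(gs[i, j], gs[i + 1, j], gs[i, j + 1], gs[i + 1, j + 1])
    if (all(is.finite(c(c1, c2))) &&
        min(c1) < 0 && max(c1) > 0 && min(c2) < 0 && max(c2) > 0) {
      # local linear model g ~ g0 + a*(mu-mu_i) + b*(s-s_j) from corners
      dmu <- mu_grid[i + 1] - mu_grid[i]; dsv <- s_grid[j + 1] - s_grid[j]
      A <- rbind(c((c1[2] - c1[1] + c1[4] - c1[3]) / (2 * dmu),
                   (c1[3] - c1[1] + c1[4] - c1[2]) / (2 * dsv)),
                 c((c2[2] - c2[1] + c2[4] - c2[3]) / (2 * dmu),
                   (c2[3] - c2[1] + c2[4] - c2[2]) / (2 * dsv)))
      b <- -c(mean(c1), mean(c2))
      sol <- tryCatch(solve(A, b), error = function(e) c(0, 0))
      centre <- c(mean(mu_grid[i:(i + 1)]), mean(s_grid[j:(j + 1)]))
      pt <- centre + sol
      if (pt[1] < mu_grid[i] || pt[1] > mu_grid[i + 1] ||
          pt[2] < s_grid[j] || pt[2] > s_grid[j + 1]) pt <- centre
      inter[[length(inter) + 1]] <- pt
    }
  }
  inter <- if (length(inter) == 0)
    data.frame(mu = numeric(0), s = numeric(0))
  else {
    out <- as.data.frame(do.call(rbind, inter)); names(out) <- c("mu", "s")
    out
  }
  field <- expand.grid(mu = mu_grid, s = s_grid)
  field$g_mu <- as.vector(gmu); field$g_s <- as.vector(gs)
  list(g_mu_zero = cmu, g_s_zero = cs, intersections = inter, field = field)
}

#' @export
print.singularity_report <- function(x, ...) {
  cat("Evolutionary singularity: (mu*, s*) = (",
      format(x$mu_star, digits = 4), ", ", format(x$s_star, digits = 4),
      ")\n", sep = "")
  cat("  tau_opt* = ", format(x$tau_opt_star, digits = 4),
      ", breadth* = ", format(x$breadth_star, digits = 4),
      " (breadth^2 = ", format(x$breadth_sq_star, digits = 4), ")\n",
      sep = "")
  cat("  shape:", x$shape_class$label, " verdict:", x$verdict, "\n")
  if (x$boundary)
    cat("  (boundary convergence in ",
        paste(x$boundary_coord, collapse = ", "), ")\n", sep = "")
  cat("  |gradient| =", format(x$grad_norm, digits = 3),
      " Ne =", format(x$Ne, digits = 4), " seed =", x$seed, "\n")
  invisible(x)
}
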