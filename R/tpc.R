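# Competition thermal performance curves (TPCs) as beta probability
# densities on (0, 1), parametrised by their mean mu and a breadth-scaling
# parameter s. The standard beta shape parameters are a = mu/s and
# b = (1 - mu)/s: this is the unique parametrisation whose mode equals
# (mu - s)/(1 - 2s) and whose variance equals s*mu*(1-mu)/(s+1), the two
# summary statistics used throughout. Because every TPC integrates to 1, a
# broader curve necessarily has a lower peak: the generalist-specialist
# trade-off is built in.

#' Competition TPC shape
#'
#' A thermal performance curve for competitive ability, represented as the
#' beta density \eqn{\beta(\tau; a, b)} with \eqn{a = \mu/s},
#' \eqn{b = (1-\mu)/s}. `mu` is the mean of the curve and `s` scales its
#' breadth (small `s` = narrow thermal specialist).
#'
#' @param mu Mean of the performance curve, strictly inside (0, 1).
#' @param s Positive scaling parameter. Values up to 2 are used in sweep
#'   grids; the type itself only requires `s > 0`.
#' @return An object of class `"tpc_shape"`.
#' @examples
#' sh <- tpc_shape(0.17, 0.09)
#' tpc_optimum(sh)
#' tpc_breadth(sh)
#' classify_shape(sh)
#' @export
tpc_shape <- function(mu, s) {
  stopifnot(is.numeric(mu), length(mu) == 1L, is.numeric(s),
            length(s) == 1L)
  mu <- unname(mu); s <- unname(s)
  if (!is.finite(mu) || mu <= 0 || mu >= 1)
    stop("'mu' must lie strictly inside (0, 1)", call. = FALSE)
  if (!is.finite(s) || s <= 0)
    stop("'s' must be > 0", call. = FALSE)
  structure(list(mu = mu, s = s), class = "tpc_shape")
}

as_tpc_shape <- function(x) {
  if (inherits(x, "tpc_shape")) return(x)
  if (is.numeric(x) && length(x) == 2L) {
    nm <- names(x)
    if (!is.null(nm) && all(c("mu", "s") %in% nm))
      return(tpc_shape(x[["mu"]], x[["s"]]))
    return(tpc_shape(x[[1]], x[[2]]))
  }
  stop("cannot interpret input as a TPC shape (need tpc_shape or length-2 numeric)",
       call. = FALSE)
}

beta_ab <- function(shape) {
  c(a = shape$mu / shape$s, b = (1 - shape$mu) / shape$s)
}

#' @export
print.tpc_shape <- function(x, ...) {
  cl <- classify_shape(x)
  cat("Competition TPC: mu = ", x$mu, ", s = ", x$s,
      "  [", cl$label, if (cl$symmetric) ", symmetric", "]\n", sep = "")
  cat("  tau_opt = ", format(tpc_optimum(x), digits = 4),
      ", breadth = ", format(tpc_breadth(x), digits = 4),
      ", breadth^2 = ", format(tpc_breadth_squared(x), digits = 4),
      "\n", sep = "")
  invisible(x)
}

#' Beta-density competition TPC evaluated at a temperature
#'
#' The beta probability density with shape parameters `mu/s` and
#' `(1-mu)/s`, i.e. the competitive performance of a type with TPC shape
#' `shape` at ambient temperature `tau`. Integrates to 1 over (0, 1).
#' Vectorised over `tau`.
#'
#' @param tau Temperature(s), strictly inside (0, 1); the density may be
#'   unbounded at the endpoints, which are rejected.
#' @param shape A [tpc_shape()].
#' @param log If `TRUE`, return the log density.
#' @return Density value(s).
#' @export
beta_density <- function(tau, shape, log = FALSE) {
  shape <- as_tpc_shape(shape)
  check_tau_domain(tau)
  ab <- beta_ab(shape)
  stats::dbeta(tau, ab[["a"]], ab[["b"]], log = log)
}

#' Classify the shape of a competition TPC
#'
#' With \eqn{a = \mu/s}, \eqn{b = (1-\mu)/s}: the density is
#' unimodal with an interior peak iff `a > 1` and `b > 1`; a monotone
#' right-skewed J-curve (peak at the cold boundary) iff `a <= 1 < b`; a
#' left-skewed J-curve iff `b <= 1 < a`; and bimodal U-shaped (unbounded at
#' both boundaries) iff `a < 1` and `b < 1`.
#'
#' @param shape A [tpc_shape()].
#' @return An object of class `"shape_class"`: list with `label` (one of
#'   `"unimodal-interior"`, `"right-skewed-J"`, `"left-skewed-J"`,
#'   `"U-shaped"`), `symmetric` (`mu == 0.5` to within 1e-12, robust to
#'   serialization round-trips), and the shape parameters `a`, `b`.
#' @export
classify_shape <- function(shape) {
  shape <- as_tpc_shape(shape)
  ab <- beta_ab(shape)
  a <- ab[["a"]]; b <- ab[["b"]]
  label <- if (a > 1 && b > 1) "unimodal-interior"
    else if (a <= 1 && b > 1) "right-skewed-J"
    else if (b <= 1 && a > 1) "left-skewed-J"
    else "U-shaped"
  structure(list(label = label,
                 symmetric = abs(shape$mu - 0.5) < 1e-12,
                 a = a, b = b),
            class = "shape_class")
}

#' @export
print.shape_class <- function(x, ...) {
  cat("TPC shape class:", x$label,
      if (x$symmetric) "(symmetric)", "\n")
  invisible(x)
}

#' Thermal optimum of a competition TPC
#'
#' For an interior-unimodal curve this is the beta mode
#' \eqn{(\mu - s)/(1 - 2s)}. Monotone J-curves peak at a thermal boundary:
#' 0 for a right-skewed J, 1 for a left-skewed J. A U-shaped curve has no
#' well-defined optimum; the boundary with the stronger divergence is
#' returned and the result is flagged degenerate.
#'
#' @param shape A [tpc_shape()].
#' @return The optimal temperature in `[0, 1]`, with attribute
#'   `"degenerate"` set to `TRUE` for U-shaped curves.
#' @examples
#' tpc_optimum(tpc_shape(0.17, 0.09))  # 0.0976
#' tpc_optimum(tpc_shape(0.14, 0.14))  # 0 (right-skewed J)
#' @export
tpc_optimum <- function(shape) {
  shape <- as_tpc_shape(shape)
  cl <- classify_shape(shape)
  out <- switch(cl$label,
    "unimodal-interior" = (shape$mu - shape$s) / (1 - 2 * shape$s),
    "right-skewed-J" = 0,
    "left-skewed-J" = 1,
    "U-shaped" = if (cl$a <= cl$b) 0 else 1)
  attr(out, "degenerate") <- identical(cl$label, "U-shaped")
  out
}

#' Performance breadth of a competition TPC
#'
#' The breadth is the standard deviation of the beta TPC,
#' \eqn{\sigma = \sqrt{s\mu(1-\mu)/(s+1)}}; its square is the variance
#' \eqn{s\mu(1-\mu)/(s+1)}. Both are exposed because summary tables in the
#' field report sometimes the one, sometimes the other.
#'
#' @param shape A [tpc_shape()].
#' @return Nonnegative breadth (standard deviation) or squared breadth
#'   (variance).
#' @examples
#' tpc_breadth_squared(tpc_shape(0.13, 0.06))  # 0.0064
#' @export
tpc_breadth <- function(shape) {
  sqrt(tpc_breadth_squared(shape))
}

#' @rdname tpc_breadth
#' @export
tpc_breadth_squared <- function(shape) {
  shape <- as_tpc_shape(shape)
  shape$s * shape$mu * (1 - shape$mu) / (shape$s + 1)
}

#' Temperature-dependent competition coefficients
#'
#' The per-capita competitive effect of residents on mutants is the ratio
#' of their TPC densities at the current temperature,
#' \eqn{\alpha_{MN}(\tau) = \beta_N(\tau)/\beta_M(\tau)}, and the reverse
#' effect is its reciprocal. Identical shapes give
#' \eqn{\alpha_{MN} = \alpha_{NM} = 1}; unequal shapes give asymmetric
#' competition with \eqn{\alpha_{MN}\alpha_{NM} = 1} exactly. Computed as a
#' difference of log densities then exponentiated, so that boundary-near
#' temperatures where one density is astronomically larger do not overflow
#' prematurely; a log-ratio beyond 700 in magnitude is outside double range
#' and raises a numerical-range error.
#'
#' @param tau Temperature(s), strictly inside (0, 1).
#' @param resident,mutant [tpc_shape()] objects.
#' @return A list with components `alpha_MN` and `alpha_NM` (vectors the
#'   length of `tau`).
#' @export
competition_coefficients <- function(tau, resident, mutant) {
  resident <- as_tpc_shape(resident); mutant <- as_tpc_shape(mutant)
  check_tau_domain(tau)
  d <- beta_density(tau, resident, log = TRUE) -
    beta_density(tau, mutant, log = TRUE)
  bad <- !is.finite(d) | abs(d) > 700
  if (any(bad)) {
    i <- which(bad)[1]
    stop(sprintf(paste0("competition coefficient out of numerical range at ",
                        "tau = %.6g (log density ratio %.3g); resident ",
                        "(mu = %g, s = %g), mutant (mu = %g, s = %g)"),
                 tau[i], d[i], resident$mu, resident$s, mutant$mu, mutant$s),
         call. = FALSE)
  }
  list(alpha_MN = exp(d), alpha_NM = exp(-d))
}
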