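#' Original-scale model parameters
#'
#' The unscaled SI model is
#' \deqn{dS/dt = \theta - \beta S I^2 - \gamma S, \qquad
#'       dI/dt = \beta S I^2 - \gamma I,}
#' with birth rate `theta`, contact rate `beta` and natural death rate
#' `gamma`, all strictly positive.
#'
#' @param theta birth rate (individuals per unit time).
#' @param beta contact rate (per squared individual per unit time).
#' @param gamma natural death rate (per unit time).
#' @return An object of class `si_params`.
#' @examples
#' model_params(theta = 2.5, beta = 1, gamma = 1)
#' @export
model_params <- function(theta, beta, gamma) {
  for (nm in c("theta", "beta", "gamma")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("invalid parameter: `", nm, "` must be a positive finite scalar",
           call. = FALSE)
  }
  structure(list(theta = theta, beta = beta, gamma = gamma),
            class = "si_params")
}

#' Nondimensionalise the SI model
#'
#' Applies the scaling `S = k1*x`, `I = k2*y`, `t = k3*tau` with
#' `k3 = 1/gamma` and `beta*k2^2*k3 = 1`, which reduces the model to the
#' one-parameter form `dx/dtau = a - y^2*x - x`, `dy/dtau = y^2*x - y`.
#' The susceptible scale `k1` is not pinned by those two constraints; this
#' package adopts the convention `k1 = k2`, so that `x` and `y` share one
#' scale and the scaling is the identity when `beta = gamma = 1`. The
#' scaled recruitment is then `a = k3*theta/k1`.
#'
#' @param params an [model_params()] object.
#' @return A list with components `scaled` (list with the single entry
#'   `a`) and `constants` (list `k1`, `k2`, `k3`).
#' @examples
#' sc <- scale_model(model_params(2.5, 1, 1))
#' sc$scaled$a        # 2.5: identity scaling when beta = gamma = 1
#' @seealso [scale_state()], [unscale_state()]
#' @export
scale_model <- function(params) {
  if (!inherits(params, "si_params"))
    params <- do.call(model_params, as.list(params)[c("theta", "beta", "gamma")])
  k3 <- 1 / params$gamma
  k2 <- sqrt(1 / (params$beta * k3))
  k1 <- k2
  a <- k3 * params$theta / k1
  list(scaled = list(a = a), constants = list(k1 = k1, k2 = k2, k3 = k3))
}

#' Map an original-scale state and time into scaled coordinates
#'
#' @param S,I,t original-scale susceptibles, infecteds, time.
#' @param constants the `constants` component of [scale_model()].
#' @return List `x`, `y`, `tau`.
#' @export
scale_state <- function(S, I, t, constants) {
  list(x = S / constants$k1, y = I / constants$k2, tau = t / constants$k3)
}

#' @rdname scale_state
#' @param x,y,tau scaled susceptibles, infecteds, time.
#' @export
unscale_state <- function(x, y, tau, constants) {
  list(S = x * constants$k1, I = y * constants$k2, t = tau * constants$k3)
}

#' Scaled vector field
#'
#' Right-hand side of the scaled continuous system
#' `dx/dtau = a - y^2*x - x`, `dy/dtau = y^2*x - y`. Defined on the whole
#' plane; the model's state space is the first quadrant.
#'
#' @param state numeric length-2 vector `c(x, y)`.
#' @param a scaled recruitment parameter.
#' @return Numeric length-2 vector of derivatives.
#' @examples
#' rhs_scaled(c(2, 0.5), a = 2.5)   # an equilibrium: c(0, 0)
#' @export
rhs_scaled <- function(state, a) {
  x <- state[[1]]; y <- state[[2]]
  c(a - y^2 * x - x, y^2 * x - y)
}

#' Epidemic threshold of the scaled system
#'
#' The quantity `R0 = a^2/4` governs the interior equilibria: two interior
#' equilibria exist iff `R0 > 1`, they coincide at `R0 = 1`, and none
#' exist below.
#'
#' @param a scaled recruitment parameter (positive).
#' @return The scalar `a^2/4`.
#' @examples
#' threshold_R0(2.5)  # 1.5625
#' @export
threshold_R0 <- function(a) {
  if (!is.numeric(a) || length(a) != 1L || !is.finite(a) || a <= 0)
    stop("invalid parameter: `a` must be a positive finite scalar",
         call. = FALSE)
  a^2 / 4
}

#' Jacobian of the scaled vector field
#'
#' @param state numeric length-2 vector `c(x, y)`.
#' @param a scaled recruitment parameter.
#' @return The 2x2 matrix `[[-1 - y^2, -2*x*y], [y^2, -1 + 2*x*y]]`.
#' @examples
#' si_jacobian(c(2.5, 0), 2.5)  # diag(-1, -1) at the disease-free point
#' @export
si_jacobian <- function(state, a) {
  x <- state[[1]]; y <- state[[2]]
  matrix(c(-1 - y^2, y^2, -2 * x * y, -1 + 2 * x * y), nrow = 2)
}

#' Classify an equilibrium of the scaled system
#'
#' Computes the Jacobian eigenvalues at a point that must already satisfy
#' the equilibrium equations, and assigns a linear type from the sign of
#' the determinant, then the trace, then the discriminant. For the
#' interior equilibria the trace is `-y^2 < 0` and the determinant is
#' `y^2 - 1`, so the lower interior point (`y < 1`) is a saddle and the
#' upper one (`y > 1`) is stable.
#'
#' @param eq_location numeric length-2 vector; must satisfy
#'   `max(abs(rhs_scaled(eq_location, a))) < 1e-8`.
#' @param a scaled recruitment parameter.
#' @param tol tolerance set, see [si_tolerances()]; `tol$residual` scaled
#'   up to 1e-8 gates the equilibrium check, and near-zero determinant or
#'   discriminant (within 1e-10) yields `"degenerate"` rather than a
#'   guess.
#' @return An object of class `si_equilibrium`: list with `x`, `y`,
#'   `eigenvalues` (complex pair), `kind` (one of `"stable-node"`,
#'   `"unstable-node"`, `"saddle"`, `"stable-focus"`, `"unstable-focus"`,
#'   `"degenerate"`).
#' @examples
#' classify_equilibrium(c(2, 0.5), 2.5)$kind  # "saddle"
#' @export
classify_equilibrium <- function(eq_location, a, tol = si_tolerances()) {
  res <- max(abs(rhs_scaled(eq_location, a)))
  if (res >= 1e-8)
    stop("invalid argument: point is not an equilibrium (residual ",
         format(res), ")", call. = FALSE)
  J <- si_jacobian(eq_location, a)
  ev <- eigen(J, only.values = TRUE)$values
  tr <- J[1, 1] + J[2, 2]
  dt <- J[1, 1] * J[2, 2] - J[1, 2] * J[2, 1]
  disc <- tr^2 - 4 * dt
  # |det| ~ 0 means an eigenvalue ~ 0 (the R0 = 1 boundary): degenerate.
  # A vanishing discriminant with det > 0 is a repeated-eigenvalue node,
  # still a node, and is classified by the trace sign.
  kind <- if (abs(dt) < 1e-10) {
    "degenerate"
  } else if (dt < 0) {
    "saddle"
  } else if (disc >= -1e-10) {
    if (tr < 0) "stable-node" else "unstable-node"
  } else {
    if (tr < 0) "stable-focus" else "unstable-focus"
  }
  structure(list(x = eq_location[[1]], y = eq_location[[2]],
                 eigenvalues = as.complex(ev), kind = kind),
            class = "si_equilibrium")
}

#' @export
print.si_equilibrium <- function(x, ...) {
  cat(sprintf("<equilibrium> (%.10g, %.10g)  %s  eigenvalues: %s, %s\n",
              x$x, x$y, x$kind,
              format(x$eigenvalues[1]), format(x$eigenvalues[2])))
  invisible(x)
}

#' Equilibria of the scaled system
#'
#' The boundary (disease-free) equilibrium `E0 = (a, 0)` always exists.
#' When `R0 = a^2/4 > 1` two interior equilibria appear,
#' `E1 = ((a + s)/2, (a - s)/2)` and `E2 = ((a - s)/2, (a + s)/2)` with
#' `s = sqrt(a^2 - 4)`; both satisfy `x*y = 1`. At `R0 = 1` they coincide
#' and are reported once as degenerate.
#'
#' @inheritParams threshold_R0
#' @param tol tolerance set, see [si_tolerances()].
#' @return A list of `si_equilibrium` objects ordered E0, then E1 (lower
#'   interior), then E2 (upper interior) when they exist.
#' @examples
#' eqs <- find_equilibria(2.5)
#' vapply(eqs, `[[`, "", "kind")
#' @export
find_equilibria <- function(a, tol = si_tolerances()) {
  R0 <- threshold_R0(a)
  out <- list(classify_equilibrium(c(a, 0), a, tol))
  if (R0 > 1) {
    s <- sqrt(a^2 - 4)
    out <- c(out,
             list(classify_equilibrium(c((a + s) / 2, (a - s) / 2), a, tol),
                  classify_equilibrium(c((a - s) / 2, (a + s) / 2), a, tol)))
  } else if (R0 == 1) {
    out <- c(out, list(classify_equilibrium(c(a / 2, a / 2), a, tol)))
  }
  out
}

#' Nullclines of the scaled system
#'
#' The x-nullcline L1 (`dx/dtau = 0`) is the curve `x = a/(1 + y^2)`.
#' The y-nullcline L2 (`dy/dtau = 0`) has two disjoint branches, the axis
#' `y = 0` and the hyperbola `x*y = 1`; they are returned as separately
#' labelled branches. Nullcline intersections are the equilibria.
#'
#' @inheritParams threshold_R0
#' @param y_grid nonnegative y values at which to evaluate the curves.
#' @return A data frame with columns `curve` (`"L1"`, `"L2-axis"`,
#'   `"L2-hyperbola"`), `x`, `y`. The hyperbola branch omits `y = 0`.
#' @examples
#' nullclines(2.5, y_grid = c(0, 0.5, 1.6))
#' @export
nullclines <- function(a, y_grid) {
  if (any(y_grid < 0)) stop("y_grid values must be >= 0", call. = FALSE)
  l1 <- data.frame(curve = "L1", x = a / (1 + y_grid^2), y = y_grid)
  # axis branch: y = 0 for all x; reuse the grid values as an x-grid
  l2a <- data.frame(curve = "L2-axis", x = y_grid, y = 0)
  yy <- y_grid[y_grid > 0]
  l2h <- data.frame(curve = "L2-hyperbola", x = 1 / yy, y = yy)
  rbind(l1, l2a, l2h)
}
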