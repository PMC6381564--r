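#' Eigenvectors of the saddle equilibrium
#'
#' Eigen-decomposition of the Jacobian at the interior saddle
#' `E1 = ((a + s)/2, (a - s)/2)`, `s = sqrt(a^2 - 4)`, which exists for
#' `R0 = a^2/4 > 1`. The characteristic equation is
#' `lambda^2 + y1^2*lambda + y1^2 - 1 = 0` with real roots of opposite
#' sign. Both eigenvectors are unit-normalised and oriented with a
#' positive y-component, the direction the homoclinic geometry uses:
#' the unstable branch leaves `E1` with `y` increasing (above the
#' x-nullcline) and the stable branch approaches from above-left (below
#' the hyperbola branch of the y-nullcline).
#'
#' @param a scaled recruitment parameter with `threshold_R0(a) > 1`.
#' @return List `E1` (the saddle location), `v_stable`, `v_unstable`
#'   (unit eigenvectors), `values` (named numeric: `stable`, `unstable`).
#' @examples
#' saddle_eigenvectors(2.5)$values   # -1 and 0.75
#' @export
saddle_eigenvectors <- function(a) {
  if (threshold_R0(a) <= 1)
    stop("no saddle: R0 = a^2/4 <= 1", call. = FALSE)
  s <- sqrt(a^2 - 4)
  E1 <- c((a + s) / 2, (a - s) / 2)
  J <- si_jacobian(E1, a)
  ed <- eigen(J)
  vals <- Re(ed$values)
  iu <- which.max(vals); is <- which.min(vals)
  orient <- function(v) { v <- Re(v); if (v[2] < 0) v <- -v; v / sqrt(sum(v^2)) }
  list(E1 = E1,
       v_stable = orient(ed$vectors[, is]),
       v_unstable = orient(ed$vectors[, iu]),
       values = c(stable = vals[is], unstable = vals[iu]))
}

# Shared shooting loop: seed at E1 + eps*v, integrate (direction +1
# forward / -1 reversed) to the line y = target, refine eps by halving
# until the endpoint x moves < x_tol.
.shoot <- function(a, v, target, direction, tol, branch,
                   eps0 = NULL, x_tol = 1e-6, max_halvings = 10L,
                   t_max = 1000) {
  sv <- saddle_eigenvectors(a)
  E1 <- sv$E1
  if (is.null(eps0)) eps0 <- 1e-6 * (1 + sqrt(sum(E1^2)))
  eps <- eps0
  x_prev <- NA_real_
  for (k in 0:max_halvings) {
    seed <- E1 + eps * v
    seg <- .flow_to_line(seed, a, target, t_max, tol,
                         direction = direction, n_store = 2L,
                         upward_only = FALSE)
    if (!seg$hit)
      stop("no-intersection: the ", branch, " manifold branch did not ",
           "reach y = ", target, " within t = ", t_max, call. = FALSE)
    x_end <- seg$state_end[1]
    if (!is.na(x_prev) && abs(x_end - x_prev) < x_tol) {
      return(structure(list(branch = branch, eps = eps,
                            endpoint = c(x_end, target),
                            direction = v, E1 = E1,
                            t_flight = seg$t_end),
                       class = "si_shot"))
    }
    x_prev <- x_end
    eps <- eps / 2
  }
  stop("seed refinement did not converge after ", max_halvings,
       " halvings (last endpoint move >= ", x_tol, ")", call. = FALSE)
}

#' Shoot the unstable manifold of the saddle to the impulse line
#'
#' Seeds just off the saddle along the unstable eigenvector (branch with
#' `y` increasing), integrates forward until the trajectory reaches
#' `y = h2`, and refines the seed offset by halving until the hit
#' x-coordinate is stable. The hit point is the point A of the
#' homoclinic construction; it lies to the right of the x-nullcline's
#' intersection with the impulse line.
#'
#' @param a scaled recruitment parameter with `threshold_R0(a) > 1`.
#' @param h2 impulse threshold.
#' @param tol tolerance set, see [si_tolerances()].
#' @param eps0 initial seed offset (default `1e-6 * (1 + |E1|)`).
#' @param x_tol endpoint-convergence tolerance for the eps refinement.
#' @return An object of class `si_shot`: list `branch`, `eps`,
#'   `endpoint` (`c(x_A, h2)`), `direction` (eigenvector used), `E1`,
#'   `t_flight`.
#' @examples
#' \donttest{shoot_unstable(2.5, 1.6)$endpoint}
#' @export
shoot_unstable <- function(a, h2, tol = si_tolerances(), eps0 = NULL,
                           x_tol = 1e-6) {
  sv <- saddle_eigenvectors(a)
  if (h2 > (a + sqrt(a^2 - 4)) / 2)
    warning("h2 lies above y2; the unstable branch may not reach it",
            call. = FALSE)
  .shoot(a, sv$v_unstable, h2, direction = 1, tol = tol,
         branch = "unstable", eps0 = eps0, x_tol = x_tol)
}

#' Shoot the stable manifold of the saddle back to the phase line
#'
#' Seeds along the stable eigenvector (the branch approaching the saddle
#' from above-left, below the hyperbola branch of the y-nullcline) and
#' integrates the time-reversed field until `y = (1-q)*h2`. The endpoint
#' is the point B of the homoclinic construction.
#'
#' @inheritParams shoot_unstable
#' @param q treatment fraction defining the phase line `y = (1-q)*h2`.
#' @return An `si_shot` with `endpoint = c(x_B, (1-q)*h2)`.
#' @examples
#' \donttest{shoot_stable(2.5, 0.5, 1.6)$endpoint}
#' @export
shoot_stable <- function(a, q, h2, tol = si_tolerances(), eps0 = NULL,
                         x_tol = 1e-6) {
  sv <- saddle_eigenvectors(a)
  .shoot(a, sv$v_stable, (1 - q) * h2, direction = -1, tol = tol,
         branch = "stable", eps0 = eps0, x_tol = x_tol)
}

#' @export
print.si_shot <- function(x, ...) {
  cat(sprintf("<%s-manifold shot> endpoint (%.8g, %g), eps = %.3g, t = %.4g\n",
              x$branch, x$endpoint[1], x$endpoint[2], x$eps, x$t_flight))
  invisible(x)
}

#' Critical vaccination rate for the order-1 homoclinic cycle
#'
#' The unstable manifold of the saddle hits the impulse line at
#' `x_A`; the stable manifold crosses the phase line at `x_B < x_A`.
#' The jump map sends `x_A` to `(1-p)*x_A`, so exactly one vaccination
#' rate, `p' = 1 - x_B/x_A`, maps A onto B and closes the loop
#' (unstable manifold from the saddle to A, jump line A->B, stable
#' manifold from B back to the saddle): the order-1 homoclinic cycle.
#'
#' @inheritParams shoot_stable
#' @return List `x_A`, `x_B`, `p_crit`, and the two `si_shot` objects
#'   (`shot_unstable`, `shot_stable`).
#' @examples
#' \donttest{critical_vaccination(2.5, 0.5, 1.6)$p_crit}
#' @export
critical_vaccination <- function(a, q, h2, tol = si_tolerances(),
                                 eps0 = NULL, x_tol = 1e-6) {
  su <- shoot_unstable(a, h2, tol, eps0, x_tol)
  ss <- shoot_stable(a, q, h2, tol, eps0, x_tol)
  x_A <- su$endpoint[1]; x_B <- ss$endpoint[1]
  if (x_B >= x_A)
    stop("degenerate geometry: x_B >= x_A, no p in (0, 1) closes the cycle",
         call. = FALSE)
  p_crit <- 1 - x_B / x_A
  list(x_A = x_A, x_B = x_B, p_crit = p_crit,
       shot_unstable = su, shot_stable = ss)
}

#' Classify the control regime
#'
#' With `R0 <= 1` there are no interior equilibria (`"subthreshold"`).
#' Otherwise the critical rate `p'` splits the control plane: `p > p'`
#' drives the infection extinct (trajectories are eventually captured by
#' the disease-free node), `p < p'` sustains an order-1 periodic
#' solution, and `|p - p'| < proximal_tol` is flagged
#' `"homoclinic-proximal"`.
#'
#' @param a scaled recruitment parameter.
#' @param control an [control_params()] object.
#' @param tol tolerance set, see [si_tolerances()].
#' @param proximal_tol half-width of the homoclinic-proximal band on `p`.
#' @param find_orbit when `TRUE` (default) and the regime is periodic,
#'   the order-1 orbit is attached.
#' @return List `regime` (one of `"subthreshold"`, `"extinction"`,
#'   `"periodic"`, `"homoclinic-proximal"`), `p_crit` (NA when
#'   subthreshold), and `orbit` (an `si_orbit` or NULL).
#' @examples
#' \donttest{
#' classify_regime(2.5, control_params(0.65, 0.5, 1.6), find_orbit = FALSE)
#' }
#' @export
classify_regime <- function(a, control, tol = si_tolerances(),
                            proximal_tol = 1e-3, find_orbit = TRUE) {
  if (threshold_R0(a) <= 1)
    return(list(regime = "subthreshold", p_crit = NA_real_, orbit = NULL))
  cv <- critical_vaccination(a, control$q, control$h2, tol)
  p_crit <- cv$p_crit
  if (abs(control$p - p_crit) < proximal_tol)
    return(list(regime = "homoclinic-proximal", p_crit = p_crit, orbit = NULL))
  if (control$p > p_crit)
    return(list(regime = "extinction", p_crit = p_crit, orbit = NULL))
  orbit <- NULL
  if (find_orbit)
    orbit <- tryCatch(find_order1_periodic(a, control, tol,
                                           check_monotone = 0L),
                      error = function(e) NULL)
  list(regime = "periodic", p_crit = p_crit, orbit = orbit)
}
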