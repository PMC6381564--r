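#' Successor function on the phase line
#'
#' For a start point `(x0, (1-q)*h2)` on the phase set N, flows to the
#' first upward hit of the impulse set M (`y = h2`), applies the jump
#' map, and returns `g = x_succ - x0` where `x_succ = (1-p)*x_hit`.
#' Zeros of `g` are order-1 periodic solutions. Trajectories captured by
#' an attractor below the impulse line return `reached = FALSE` with `g`
#' undefined.
#'
#' @param x0 coordinate on the phase line (nonnegative).
#' @param a scaled recruitment parameter.
#' @param control an [control_params()] object.
#' @param t_max arc time horizon.
#' @param tol tolerance set, see [si_tolerances()].
#' @return An object of class `si_successor`: list `x0`, `reached`, and
#'   when reached also `x_hit` (coordinate on M), `x_succ`, `g`,
#'   `t_hit` (flow time from N to M).
#' @examples
#' ctrl <- control_params(0.3, 0.5, 1.6)
#' successor_function(0.55, 2.5, ctrl)$g
#' @export
successor_function <- function(x0, a, control, t_max = 500,
                               tol = si_tolerances()) {
  if (!is.numeric(x0) || length(x0) != 1L || x0 < 0)
    stop("`x0` must be a nonnegative scalar", call. = FALSE)
  start <- c(x0, (1 - control$q) * control$h2)
  seg <- .flow_to_line(start, a, control$h2, t_max, tol, n_store = 2L)
  if (!seg$hit)
    return(structure(list(x0 = x0, reached = FALSE), class = "si_successor"))
  x_hit <- seg$state_end[1]
  x_succ <- (1 - control$p) * x_hit
  structure(list(x0 = x0, reached = TRUE, x_hit = x_hit, x_succ = x_succ,
                 g = x_succ - x0, t_hit = seg$t_end),
            class = "si_successor")
}

#' @export
print.si_successor <- function(x, ...) {
  if (x$reached)
    cat(sprintf("<successor> x0 = %.8g -> x_succ = %.8g (g = %+.3e, t = %.4g)\n",
                x$x0, x$x_succ, x$g, x$t_hit))
  else
    cat(sprintf("<successor> x0 = %.8g: impulse line not reached\n", x$x0))
  invisible(x)
}

#' Bracket on the phase line containing the order-1 fixed point
#'
#' The existence construction jumps two landmark points of the impulse
#' line onto the phase line: C, the intersection of M with the
#' x-nullcline (`x_C = a/(1 + h2^2)`), maps to the lower end
#' `x_low = (1-p)*x_C`; A, the hit point of the saddle's unstable
#' manifold on M, maps to the upper end `x_high = (1-p)*x_A`. The
#' successor function changes sign across `[x_low, x_high]` whenever the
#' vaccination rate is below the homoclinic-critical value. Close to the
#' critical rate the corner image `(1-p)*x_C` falls below the
#' stable-manifold coordinate `x_B`, inside the disease-free basin where
#' the successor map is undefined; the lower end is then clipped to just
#' above `x_B`, which preserves the sign change (the successor there is
#' approximately `(1-p)*x_A - x_B > 0`).
#'
#' @inheritParams successor_function
#' @param shot optional precomputed [shoot_unstable()] result (reused to
#'   avoid repeating the manifold shot).
#' @param p_crit optional precomputed critical rate; recomputed when
#'   missing.
#' @return List `x_low`, `x_high`, plus the `x_A`, `x_B` and `p_crit`
#'   used.
#' @export
periodic_bracket <- function(a, control, tol = si_tolerances(),
                             shot = NULL, p_crit = NULL) {
  if (threshold_R0(a) <= 1)
    stop("no interior equilibria: R0 <= 1", call. = FALSE)
  if (is.null(shot)) shot <- shoot_unstable(a, control$h2, tol = tol)
  x_A <- shot$endpoint[1]
  shotB <- shoot_stable(a, control$q, control$h2, tol = tol)
  x_B <- shotB$endpoint[1]
  if (is.null(p_crit)) p_crit <- 1 - x_B / x_A
  if (control$p >= p_crit)
    stop("no bracket: p = ", control$p, " >= critical rate p' = ",
         format(p_crit), " (extinction regime)", call. = FALSE)
  x_C <- a / (1 + control$h2^2)
  # the corner image (1-p)*x_C is the textbook lower end, but close to
  # the critical rate it drops below the stable-manifold coordinate x_B
  # and into the disease-free basin, where the successor map is
  # undefined; clip just inside the reaching region
  x_low <- max((1 - control$p) * x_C, x_B + 1e-4 * (1 + abs(x_B)))
  x_high <- (1 - control$p) * x_A
  if (x_low >= x_high)
    stop("degenerate bracket: x_low >= x_high", call. = FALSE)
  list(x_low = x_low, x_high = x_high, x_A = x_A, x_B = x_B,
       p_crit = p_crit)
}

#' Find the order-1 periodic solution
#'
#' Locates the unique fixed point of the successor map on the bracket of
#' [periodic_bracket()] by bisection (the successor function is strictly
#' monotone there, so the root is unique). The returned orbit carries the
#' full arc from the phase line to the impulse line, the period (the
#' continuous-arc time; the jump is instantaneous), and a finite-
#' difference estimate of the successor-map multiplier.
#'
#' @inheritParams successor_function
#' @param check_monotone number of grid points at which strict
#'   monotonicity of `g` is verified (0 skips the check).
#' @return An object of class `si_orbit`: list `x_star`, `period`,
#'   `impulse_x`, `orbit` (list `times`, `states` for one arc, plus the
#'   jump as `pre_state`/`post_state`), `stable` (multiplier magnitude
#'   < 1), `contraction` (central-difference slope of the successor map
#'   at the fixed point), `bracket`.
#' @examples
#' \donttest{
#' ctrl <- control_params(0.3, 0.5, 1.6)
#' orb <- find_order1_periodic(2.5, ctrl)
#' orb$x_star
#' }
#' @export
find_order1_periodic <- function(a, control, tol = si_tolerances(),
                                 t_max = 500, check_monotone = 32L) {
  br <- periodic_bracket(a, control, tol)
  g_of <- function(x) {
    s <- successor_function(x, a, control, t_max, tol)
    if (!s$reached)
      stop("successor undefined at x0 = ", format(x),
           ": trajectory did not reach the impulse line", call. = FALSE)
    s$g
  }
  g_lo <- g_of(br$x_low); g_hi <- g_of(br$x_high)
  if (sign(g_lo) == sign(g_hi)) {
    prof_x <- seq(br$x_low, br$x_high, length.out = 16L)
    prof_g <- vapply(prof_x, g_of, 0)
    stop("no sign change of the successor function on the bracket; ",
         "sampled profile: ",
         paste(sprintf("g(%.5g)=%.3e", prof_x, prof_g), collapse = ", "),
         call. = FALSE)
  }
  if (check_monotone > 0L) {
    gx <- seq(br$x_low, br$x_high, length.out = check_monotone)
    gg <- vapply(gx, g_of, 0)
    if (any(diff(gg) >= 0))
      warning("successor function not strictly decreasing on the bracket ",
              "at the sampled resolution", call. = FALSE)
  }
  lo <- br$x_low; hi <- br$x_high
  repeat {
    mid <- (lo + hi) / 2
    gm <- g_of(mid)
    if (abs(gm) < tol$root || (hi - lo) / 2 < tol$root * 1e-3) break
    if (sign(gm) == sign(g_lo)) { lo <- mid; g_lo <- gm } else hi <- mid
  }
  x_star <- mid
  # one dense arc for the orbit itself
  start <- c(x_star, (1 - control$q) * control$h2)
  arc <- .flow_to_line(start, a, control$h2, t_max, tol, n_store = 400L)
  pre <- arc$state_end
  post <- apply_impulse(pre, control, tol)
  delta <- 1e-5
  Phi <- function(x) x + g_of(x)
  contraction <- (Phi(x_star + delta) - Phi(x_star - delta)) / (2 * delta)
  structure(list(x_star = x_star, period = arc$t_end,
                 impulse_x = pre[1],
                 orbit = list(times = arc$times, states = arc$states,
                              pre_state = pre, post_state = post),
                 stable = abs(contraction) < 1,
                 contraction = contraction, bracket = br,
                 a = a, control = control),
            class = "si_orbit")
}

#' @export
print.si_orbit <- function(x, ...) {
  cat(sprintf("<order-1 periodic orbit> x* = %.8g on y = %g\n",
              x$x_star, (1 - x$control$q) * x$control$h2))
  cat(sprintf("  period T = %.6g, impulse at x = %.8g on y = %g\n",
              x$period, x$impulse_x, x$control$h2))
  cat(sprintf("  successor-map multiplier: %.4g (%s)\n", x$contraction,
              if (x$stable) "orbitally stable" else "unstable"))
  invisible(x)
}

#' Assess orbital stability of an order-1 periodic solution
#'
#' Iterates the successor map from perturbed starts `x_star*(1 +/- eps)`
#' and checks (i) convergence back to the fixed point (gap eventually
#' decreasing over the final window and below `gap_tol` at the end) and
#' (ii) the alternating-monotone approach characteristic of a negative
#' successor-map multiplier: iterates alternate sides of the fixed point,
#' the odd subsequence increasing and the even one decreasing when the
#' start is above. Perturbations that leave the reaching region are
#' halved up to 5 times, then skipped with a warning.
#'
#' @param orbit an `si_orbit` from [find_order1_periodic()].
#' @param n_perturb number of successor-map iterations per replicate.
#' @param eps relative perturbation sizes.
#' @param gap_tol final-gap threshold for the stable verdict.
#' @param window length of the final window over which the gap must be
#'   nonincreasing.
#' @param tol tolerance set, see [si_tolerances()].
#' @return List with `stable`, `contraction` (geometric-mean gap ratio
#'   over the iterations), `alternating` (logical: the alternating
#'   pattern held in all replicates), and per-replicate `trajectories`
#'   (each the iterate sequence).
#' @export
assess_stability <- function(orbit, n_perturb = 40L,
                             eps = c(1e-2, 1e-3), gap_tol = 1e-6,
                             window = 10L, tol = si_tolerances()) {
  a <- orbit$a; control <- orbit$control
  x_star <- orbit$x_star
  runs <- list(); ratios <- c(); alternating <- TRUE; stable <- TRUE
  for (e in eps) for (sgn in c(1, -1)) {
    this_eps <- e
    x0 <- NA
    for (k in 0:5) {
      cand <- x_star * (1 + sgn * this_eps)
      s <- successor_function(cand, a, control, tol = tol)
      if (s$reached) { x0 <- cand; break }
      this_eps <- this_eps / 2
    }
    if (is.na(x0)) {
      warning("perturbed start outside the reaching region; replicate skipped",
              call. = FALSE)
      next
    }
    xs <- numeric(n_perturb + 1L); xs[1] <- x0
    ok <- TRUE
    for (i in seq_len(n_perturb)) {
      s <- successor_function(xs[i], a, control, tol = tol)
      if (!s$reached) { ok <- FALSE; break }
      xs[i + 1L] <- s$x_succ
    }
    if (!ok) {
      warning("iterate left the reaching region; replicate skipped",
              call. = FALSE)
      next
    }
    runs[[length(runs) + 1L]] <- xs
    gaps <- abs(xs - x_star)
    tail_gaps <- gaps[seq.int(max(1L, length(gaps) - window), length(gaps))]
    dec <- all(diff(tail_gaps) <= tol$root)
    stable <- stable && dec && gaps[length(gaps)] < gap_tol
    # the pattern is only resolvable above the fixed-point resolution
    # floor (x_star itself is known to the root tolerance)
    nz <- gaps > max(100 * tol$root, 1e-6)
    if (sum(nz) >= 3) {
      dev <- (xs - x_star)[nz]
      # negative multiplier: consecutive deviations flip sign, and each
      # one-sided subsequence approaches x_star monotonically
      flips <- all(sign(dev[-1]) == -sign(dev[-length(dev)]))
      above <- dev[dev > 0]; below <- dev[dev < 0]
      mono <- (length(above) < 2 || all(diff(above) < 0)) &&
              (length(below) < 2 || all(diff(below) > 0))
      alternating <- alternating && flips && mono
    }
    # contraction from iterations still above the fixed-point resolution
    # floor (x_star is only known to the root tolerance)
    floor_gap <- max(100 * tol$root, 1e-6)
    usable <- which(gaps[-length(gaps)] > floor_gap & gaps[-1] > floor_gap)
    if (length(usable) > 0)
      ratios <- c(ratios, exp(mean(log(gaps[usable + 1L] / gaps[usable]))))
  }
  if (length(runs) == 0)
    stop("all perturbation replicates were skipped", call. = FALSE)
  list(stable = stable, contraction = mean(ratios),
       alternating = alternating, trajectories = runs)
}
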