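#' Impulsive control parameters
#'
#' The control fires on the impulse line `y = h2` (set M) and maps states
#' to the phase line `y = (1-q)*h2` (set N) via
#' `(x, h2) -> ((1-p)x, (1-q)h2)`: a fraction `p` of susceptibles is
#' vaccinated and a fraction `q` of infecteds treated, instantaneously.
#'
#' @param p vaccination fraction, strictly in (0, 1).
#' @param q treatment fraction, strictly in (0, 1).
#' @param h2 impulse threshold on the scaled infected axis, positive.
#' @param a optional scaled recruitment; when supplied and `R0 > 1`, a
#'   warning (not an error) is issued if `h2` exceeds the upper interior
#'   equilibrium's `y`, outside the geometry the theory assumes.
#' @return An object of class `si_control`.
#' @examples
#' control_params(p = 0.3, q = 0.5, h2 = 1.6)
#' @export
control_params <- function(p, q, h2, a = NULL) {
  if (!is.numeric(p) || length(p) != 1L || !is.finite(p) || p <= 0 || p >= 1)
    stop("`p` must be strictly between 0 and 1", call. = FALSE)
  if (!is.numeric(q) || length(q) != 1L || !is.finite(q) || q <= 0 || q >= 1)
    stop("`q` must be strictly between 0 and 1", call. = FALSE)
  if (!is.numeric(h2) || length(h2) != 1L || !is.finite(h2) || h2 <= 0)
    stop("`h2` must be a positive finite scalar", call. = FALSE)
  if (!is.null(a) && threshold_R0(a) > 1) {
    y2 <- (a + sqrt(a^2 - 4)) / 2
    if (h2 > y2)
      warning("h2 = ", h2, " exceeds y2 = ", format(y2),
              "; the impulse line lies above the endemic equilibrium",
              call. = FALSE)
  }
  structure(list(p = p, q = q, h2 = h2), class = "si_control")
}

#' Impulse (jump) map
#'
#' Applies the instantaneous control to a state on the impulse line:
#' `(x, h2) -> ((1-p)*x, (1-q)*h2)`.
#'
#' @param state numeric length-2 vector with `state[2]` on the impulse
#'   line `y = h2` to within `tol$event`.
#' @param control an [control_params()] object.
#' @param tol tolerance set, see [si_tolerances()].
#' @return The post-impulse state `c((1-p)*x, (1-q)*h2)`.
#' @examples
#' apply_impulse(c(1, 1.6), control_params(0.5, 0.5, 1.6))  # c(0.5, 0.8)
#' @export
apply_impulse <- function(state, control, tol = si_tolerances()) {
  if (abs(state[[2]] - control$h2) > max(tol$event, 1e-8))
    stop("contract violation: state is not on the impulse set y = h2 ",
         "(y = ", format(state[[2]]), ")", call. = FALSE)
  c((1 - control$p) * state[[1]], (1 - control$q) * control$h2)
}

# deSolve-facing RHS; `direction` = -1 integrates the time-reversed field.
.si_deriv <- function(t, s, parms) {
  list(parms$direction * rhs_scaled(s, parms$a))
}

.si_rootfun <- function(t, s, parms) s[2] - parms$h

# Integrate the scaled field from `state0`, stopping at the first upward
# crossing of y = h (downward or tangential roots are stepped past and
# integration resumes). Returns the sampled arc and hit metadata.
# `n_store` controls how many output times are requested per call.
.flow_to_line <- function(state0, a, h, t_max, tol, direction = 1,
                          n_store = 400L, upward_only = TRUE) {
  parms <- list(a = a, h = h, direction = direction)
  t0 <- 0
  seg <- NULL
  state <- as.numeric(state0)
  repeat {
    times <- seq(t0, t_max, length.out = max(2L, n_store))
    out <- deSolve::lsodar(state, times, .si_deriv, parms,
                           rootfunc = .si_rootfun,
                           rtol = tol$rtol, atol = tol$atol)
    seg <- if (is.null(seg)) unclass(out) else rbind(seg, unclass(out)[-1, , drop = FALSE])
    fin <- seg[nrow(seg), ]
    at_root <- abs(fin[3] - h) <= max(tol$event, 1e-7)
    if (!at_root || is.null(h)) {
      return(list(times = seg[, 1], states = seg[, 2:3, drop = FALSE],
                  hit = FALSE, t_end = unname(fin[1]), state_end = unname(fin[2:3])))
    }
    dy <- direction * rhs_scaled(fin[2:3], a)[2]
    if (!upward_only || dy > 0) {
      return(list(times = seg[, 1], states = seg[, 2:3, drop = FALSE],
                  hit = TRUE, t_end = unname(fin[1]), state_end = unname(fin[2:3])))
    }
    # touched the line moving down: nudge past the root and continue
    t0 <- fin[1] + 1e-10 * max(1, t_max)
    state <- fin[2:3]
    if (t0 >= t_max) {
      return(list(times = seg[, 1], states = seg[, 2:3, drop = FALSE],
                  hit = FALSE, t_end = unname(fin[1]), state_end = unname(fin[2:3])))
    }
  }
}

# Clamp round-off negativity; abort on genuinely negative states.
.clip_state <- function(state, tol) {
  neg <- state < 0
  if (any(state < -tol$clip))
    stop("state left the first quadrant: (", paste(format(state), collapse = ", "),
         ")", call. = FALSE)
  state[neg] <- 0
  state
}

#' Integrate until the trajectory reaches the impulse line
#'
#' Flows the scaled system from `state0` until the first upward crossing
#' of `y = h2` (events where the trajectory touches the line moving
#' downward are ignored), or until `t_max`. A start above the impulse
#' line is rejected.
#'
#' @param state0 numeric length-2 start state with `state0[2] <= h2`.
#' @param a scaled recruitment parameter.
#' @param control an [control_params()] object (only `h2` is used here).
#' @param t_max time horizon for this arc.
#' @param tol tolerance set, see [si_tolerances()].
#' @param n_store number of stored output points along the arc.
#' @return A list with `times`, `states` (matrix with columns x, y),
#'   `hit` (logical: reached the impulse line), `t_end`, `state_end`.
#' @examples
#' ctrl <- control_params(0.3, 0.5, 1.6)
#' seg <- integrate_to_impulse(c(0.15, 0.895), 2.5, ctrl, t_max = 100)
#' seg$hit
#' @export
integrate_to_impulse <- function(state0, a, control, t_max = 500,
                                 tol = si_tolerances(), n_store = 400L) {
  state0 <- .clip_state(as.numeric(state0), tol)
  if (state0[2] > control$h2 + tol$event)
    stop("invalid start: y0 = ", format(state0[2]), " lies above the ",
         "impulse line h2 = ", control$h2, call. = FALSE)
  .flow_to_line(state0, a, control$h2, t_max, tol, n_store = n_store)
}

#' Simulate the hybrid (impulsive) system
#'
#' Alternates continuous flow and jumps: each arc runs until the
#' trajectory reaches the impulse line `y = h2` from below, the impulse
#' map is applied, and integration restarts on the phase line
#' `y = (1-q)*h2`. Terminates after `max_impulses` events, cumulative
#' time `t_max`, or when an arc fails to reach the impulse line (the
#' trajectory has been captured by an attractor below it).
#'
#' @inheritParams integrate_to_impulse
#' @param max_impulses maximum number of impulse events (Zeno guard; the
#'   dynamics itself cannot chatter because `(1-q)*h2 < h2` strictly).
#' @param t_max cumulative time horizon.
#' @return An object of class `si_trajectory`: list with `arcs` (each a
#'   list `times`, `states`), `events` (each a list `time`, `pre_state`,
#'   `post_state`), `terminal` (one of `"max-impulses"`, `"max-time"`,
#'   `"converged-to-attractor"`), and the inputs.
#' @examples
#' ctrl <- control_params(0.3, 0.5, 1.6)
#' tr <- simulate_hybrid(c(0.15, 0.895), 2.5, ctrl, max_impulses = 5)
#' length(tr$events)
#' @export
simulate_hybrid <- function(state0, a, control, max_impulses = 500L,
                            t_max = 1000, tol = si_tolerances(),
                            n_store = 400L) {
  state <- .clip_state(as.numeric(state0), tol)
  if (state[2] > control$h2 + tol$event)
    stop("invalid start: y0 above the impulse line", call. = FALSE)
  arcs <- list(); events <- list()
  t_now <- 0
  terminal <- "max-impulses"
  repeat {
    seg <- .flow_to_line(state, a, control$h2, t_max - t_now, tol,
                         n_store = n_store)
    seg$times <- seg$times + t_now
    arcs[[length(arcs) + 1L]] <- list(times = seg$times, states = seg$states)
    t_now <- seg$times[length(seg$times)]
    if (!seg$hit) {
      terminal <- .attractor_terminal(seg$state_end, a, tol)
      break
    }
    if (length(events) >= max_impulses) { terminal <- "max-impulses"; break }
    pre <- seg$state_end
    post <- apply_impulse(pre, control, tol)
    events[[length(events) + 1L]] <- list(time = t_now, pre_state = pre,
                                          post_state = post)
    if (t_now >= t_max) { terminal <- "max-time"; break }
    state <- post
  }
  structure(list(arcs = arcs, events = events, terminal = terminal,
                 a = a, control = control, state0 = as.numeric(state0)),
            class = "si_trajectory")
}

# Label a no-hit terminal state: near E0 or E2 -> converged, else max-time.
.attractor_terminal <- function(state, a, tol) {
  targets <- list(c(a, 0))
  if (threshold_R0(a) > 1) {
    s <- sqrt(a^2 - 4)
    targets <- c(targets, list(c((a - s) / 2, (a + s) / 2)))
  }
  d <- vapply(targets, function(e) sqrt(sum((state - e)^2)), 0)
  if (any(d < tol$attractor)) "converged-to-attractor" else "max-time"
}

#' @export
print.si_trajectory <- function(x, ...) {
  cat(sprintf("<hybrid trajectory> a = %g, p = %g, q = %g, h2 = %g\n",
              x$a, x$control$p, x$control$q, x$control$h2))
  cat(sprintf("  %d arc(s), %d impulse event(s), terminal: %s\n",
              length(x$arcs), length(x$events), x$terminal))
  if (length(x$events) > 0) {
    px <- vapply(x$events, function(e) e$post_state[1], 0)
    cat(sprintf("  last post-impulse x: %.8g\n", px[length(px)]))
  }
  invisible(x)
}

#' Post-impulse x-coordinates of a hybrid trajectory
#'
#' Convenience accessor for the sequence that the successor-map theory
#' reasons about: the x-coordinate on the phase line after each impulse.
#'
#' @param traj an `si_trajectory`.
#' @return Numeric vector (length = number of events).
#' @export
post_impulse_x <- function(traj) {
  vapply(traj$events, function(e) e$post_state[1], 0)
}

#' Flatten a hybrid trajectory to a long-format data frame
#'
#' One row per stored integration point, with impulse events duplicated
#' as flagged pre/post rows, matching the CSV schema written by
#' [write_trajectory_csv()].
#'
#' @param traj an `si_trajectory`.
#' @return Data frame with columns `time`, `x`, `y`, `arc_index`,
#'   `is_event` (`""`, `"pre"` or `"post"`).
#' @export
as.data.frame.si_trajectory <- function(x, ...) {
  traj <- x
  rows <- lapply(seq_along(traj$arcs), function(k) {
    arc <- traj$arcs[[k]]
    df <- data.frame(time = arc$times, x = arc$states[, 1],
                     y = arc$states[, 2], arc_index = k, is_event = "")
    if (k <= length(traj$events)) {
      ev <- traj$events[[k]]
      df <- rbind(df, data.frame(
        time = c(ev$time, ev$time),
        x = c(ev$pre_state[1], ev$post_state[1]),
        y = c(ev$pre_state[2], ev$post_state[2]),
        arc_index = k, is_event = c("pre", "post")))
    }
    df
  })
  do.call(rbind, rows)
}

#' Write a hybrid trajectory as CSV plus a JSON summary
#'
#' @param traj an `si_trajectory`.
#' @param file CSV output path; a summary JSON (terminal reason, event
#'   times, post-impulse x sequence) is written alongside with extension
#'   `.json` unless `summary_file` is given.
#' @param summary_file optional JSON path.
#' @return Invisibly, the data frame written.
#' @export
write_trajectory_csv <- function(traj, file, summary_file = NULL) {
  df <- as.data.frame(traj)
  utils::write.csv(df, file, row.names = FALSE)
  if (is.null(summary_file))
    summary_file <- sub("\\.csv$", ".json", file)
  summary <- list(terminal = traj$terminal,
                  n_events = length(traj$events),
                  event_times = vapply(traj$events, `[[`, 0, "time"),
                  post_impulse_x = post_impulse_x(traj))
  jsonlite::write_json(summary, summary_file, auto_unbox = TRUE, digits = NA)
  invisible(df)
}
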