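#' Phase-portrait data for a parameter set
#'
#' Collects, as plain data frames, everything a phase portrait draws:
#' nullclines, equilibria with their kinds, the impulse and phase lines,
#' and optionally a trajectory. Plotting functions sit on top of this so
#' that figures are always backed by numeric data that can be written to
#' CSV and checked without touching pixels.
#'
#' @param a scaled recruitment parameter.
#' @param control optional [control_params()]; when given the impulse
#'   line `y = h2` and phase line `y = (1-q)*h2` are included.
#' @param traj optional `si_trajectory` from [simulate_hybrid()].
#' @param y_max upper edge of the y-grid for the nullclines.
#' @param n_grid nullcline grid resolution.
#' @return List of data frames: `nullclines`, `equilibria` (x, y, kind),
#'   `lines` (label, y), `trajectory` (possibly NULL, long format of
#'   [as.data.frame.si_trajectory()]).
#' @export
phase_portrait_data <- function(a, control = NULL, traj = NULL,
                                y_max = NULL, n_grid = 400L) {
  if (is.null(y_max))
    y_max <- max(a, if (!is.null(control)) 1.5 * control$h2 else 0, 3)
  yg <- seq(0, y_max, length.out = n_grid)
  eqs <- find_equilibria(a)
  eq_df <- data.frame(x = vapply(eqs, `[[`, 0, "x"),
                      y = vapply(eqs, `[[`, 0, "y"),
                      kind = vapply(eqs, `[[`, "", "kind"))
  lines_df <- NULL
  if (!is.null(control))
    lines_df <- data.frame(
      label = c("impulse-set-M", "phase-set-N"),
      y = c(control$h2, (1 - control$q) * control$h2))
  list(nullclines = nullclines(a, yg),
       equilibria = eq_df,
       lines = lines_df,
       trajectory = if (!is.null(traj)) as.data.frame(traj) else NULL)
}

#' Draw a phase portrait
#'
#' Base-graphics phase portrait of the scaled system: nullclines,
#' equilibria marked by linear type (filled = stable, open = unstable,
#' cross = saddle), impulse/phase lines, and an optional hybrid
#' trajectory.
#'
#' @inheritParams phase_portrait_data
#' @param main plot title.
#' @param xlim,ylim axis limits (defaults derived from the data).
#' @param data_file optional path; when given, the portrait's underlying
#'   curves are also written as a single long CSV (columns `layer`,
#'   `label`, `x`, `y`).
#' @return Invisibly, the [phase_portrait_data()] list.
#' @export
plot_phase_portrait <- function(a, control = NULL, traj = NULL,
                                main = NULL, xlim = NULL, ylim = NULL,
                                y_max = NULL, data_file = NULL) {
  pd <- phase_portrait_data(a, control, traj, y_max)
  if (is.null(xlim)) xlim <- c(0, 1.1 * max(a, pd$equilibria$x))
  if (is.null(ylim)) ylim <- c(0, max(pd$nullclines$y))
  if (is.null(main)) main <- sprintf("Scaled SI phase plane (a = %g)", a)
  graphics::plot(NA, xlim = xlim, ylim = ylim, xlab = "x (susceptible)",
                 ylab = "y (infected)", main = main)
  for (cv in unique(pd$nullclines$curve)) {
    d <- pd$nullclines[pd$nullclines$curve == cv, ]
    d <- d[d$x <= xlim[2] & d$x >= xlim[1], ]
    graphics::lines(d$x, d$y, lty = 2,
                    col = if (cv == "L1") "forestgreen" else "steelblue")
  }
  if (!is.null(pd$lines))
    graphics::abline(h = pd$lines$y, col = c("firebrick", "orange"), lty = 3)
  if (!is.null(pd$trajectory)) {
    tr <- pd$trajectory
    for (k in unique(tr$arc_index)) {
      dk <- tr[tr$arc_index == k & tr$is_event == "", ]
      graphics::lines(dk$x, dk$y, col = "grey30")
    }
    ev <- tr[tr$is_event != "", ]
    if (nrow(ev) > 0) graphics::points(ev$x, ev$y, pch = 4, col = "grey50")
  }
  pch_of <- function(kind) switch(kind,
    "saddle" = 13, "stable-node" = 19, "stable-focus" = 19,
    "unstable-node" = 1, "unstable-focus" = 1, 8)
  graphics::points(pd$equilibria$x, pd$equilibria$y,
                   pch = vapply(pd$equilibria$kind, pch_of, 0), cex = 1.4)
  if (!is.null(data_file)) {
    layers <- rbind(
      data.frame(layer = "nullcline", label = pd$nullclines$curve,
                 x = pd$nullclines$x, y = pd$nullclines$y),
      data.frame(layer = "equilibrium", label = pd$equilibria$kind,
                 x = pd$equilibria$x, y = pd$equilibria$y),
      if (!is.null(pd$trajectory))
        data.frame(layer = "trajectory",
                   label = paste0("arc", pd$trajectory$arc_index),
                   x = pd$trajectory$x, y = pd$trajectory$y))
    utils::write.csv(layers, data_file, row.names = FALSE)
  }
  invisible(pd)
}

#' Draw time series of a hybrid trajectory
#'
#' Plots `x(tau)` and `y(tau)` with impulse times marked by vertical
#' dashes; companion CSV identical to [write_trajectory_csv()].
#'
#' @param traj an `si_trajectory`.
#' @param which `"both"`, `"x"` or `"y"`.
#' @param data_file optional CSV path for the long-format trajectory.
#' @return Invisibly, the long-format data frame.
#' @export
plot_time_series <- function(traj, which = c("both", "x", "y"),
                             data_file = NULL) {
  which <- match.arg(which)
  if (length(traj$arcs) == 0) stop("empty trajectory", call. = FALSE)
  df <- as.data.frame(traj)
  pts <- df[df$is_event == "", ]
  ev_t <- vapply(traj$events, `[[`, 0, "time")
  panel <- function(var, col) {
    graphics::plot(pts$time, pts[[var]], type = "n",
                   xlab = expression(tau), ylab = var)
    for (k in unique(pts$arc_index)) {
      dk <- pts[pts$arc_index == k, ]
      graphics::lines(dk$time, dk[[var]], col = col)
    }
    if (length(ev_t) > 0)
      graphics::abline(v = ev_t, col = "grey70", lty = 3)
  }
  if (which == "both") {
    op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
    on.exit(graphics::par(op))
    panel("x", "forestgreen"); panel("y", "firebrick")
  } else {
    panel(which, if (which == "x") "forestgreen" else "firebrick")
  }
  if (!is.null(data_file)) utils::write.csv(df, data_file, row.names = FALSE)
  invisible(df)
}
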