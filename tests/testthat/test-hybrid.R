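test_that("jump map: formula, fixed points, contract violation", {
  ctrl <- control_params(0.5, 0.5, 1.6)
  expect_equal(apply_impulse(c(1.0, 1.6), ctrl), c(0.5, 0.8))
  expect_equal(apply_impulse(c(0, 1.6), ctrl), c(0, 0.8))
  expect_error(apply_impulse(c(1, 1.0), ctrl), "contract violation")
  expect_error(control_params(1.2, 0.5, 1.6), "strictly between")
  expect_error(control_params(0.5, 0, 1.6), "strictly between")
  expect_error(control_params(0.5, 0.5, -1), "positive")
  expect_warning(control_params(0.5, 0.5, 2.5, a = 2.5), "exceeds y2")
})

test_that("event integrator stops on the impulse line, or reports capture", {
  ctrl <- ctrl_periodic()
  seg <- integrate_to_impulse(c(0.15, 0.895), 2.5, ctrl, t_max = 200)
  expect_true(seg$hit)
  expect_lt(abs(seg$state_end[2] - 1.6), 1e-9)
  # dy/dtau > 0 at the event: upward crossing only
  expect_gt(rhs_scaled(seg$state_end, 2.5)[2], 0)
  # a start in the disease-free basin never reaches the line
  seg2 <- integrate_to_impulse(c(2.5, 0.01), 2.5, ctrl, t_max = 500)
  expect_false(seg2$hit)
  expect_lt(sqrt(sum((seg2$state_end - c(2.5, 0))^2)), 1e-4)
  expect_error(integrate_to_impulse(c(1, 2.0), 2.5, ctrl), "invalid start")
})

test_that("adaptive event integrator agrees with a fixed-step RK4 oracle", {
  # impulse-free arc: threshold far above the trajectory's range
  ctrl <- control_params(0.3, 0.5, 9)
  times <- seq(0, 5, by = 0.05)
  seg <- integrate_to_impulse(c(0.15, 0.895), 2.5, ctrl, t_max = 5,
                              n_store = length(times))
  expect_false(seg$hit)
  expect_equal(seg$times, times, tolerance = 1e-12)
  oracle <- rk4_flow(c(0.15, 0.895), 2.5, times, h_step = 1e-4)
  expect_lt(max(abs(seg$states - oracle)), 1e-6)
})

test_that("hybrid simulation satisfies the flow/jump chain invariants", {
  ctrl <- ctrl_periodic()
  tr <- simulate_hybrid(c(0.15, 0.895), 2.5, ctrl, max_impulses = 30)
  expect_s3_class(tr, "si_trajectory")
  expect_length(tr$events, 30)
  for (k in seq_along(tr$events)) {
    ev <- tr$events[[k]]
    arc_end <- tr$arcs[[k]]$states[nrow(tr$arcs[[k]]$states), ]
    expect_equal(unname(arc_end), ev$pre_state, tolerance = 1e-9)
    expect_lt(abs(ev$pre_state[2] - ctrl$h2), 1e-9)
    # jump consistency, exact to round-off
    expect_equal(ev$post_state[1] / ev$pre_state[1], 1 - ctrl$p,
                 tolerance = 1e-14)
    expect_identical(ev$post_state[2], (1 - ctrl$q) * ctrl$h2)
    if (k < length(tr$arcs)) {
      arc_start <- tr$arcs[[k + 1]]$states[1, ]
      expect_equal(unname(arc_start), ev$post_state, tolerance = 1e-12)
    }
  }
  # times strictly increase across the whole object
  all_t <- unlist(lapply(tr$arcs, `[[`, "times"))
  expect_true(all(diff(all_t) >= 0))
  expect_true(all(diff(vapply(tr$events, `[[`, 0, "time")) > 0))
})

test_that("post-impulse x splits into alternating monotone subsequences", {
  # the successor-map multiplier is negative: from a start on the phase
  # line away from the fixed point, odd and even post-impulse iterates
  # approach the limit from opposite sides, each monotonically
  ctrl <- ctrl_periodic()
  tr <- simulate_hybrid(c(0.5, 0.8), 2.5, ctrl, max_impulses = 12)
  px <- post_impulse_x(tr)
  lim <- px[length(px)]
  resolved <- which(abs(px - lim) > 1e-6)
  odd <- px[resolved[resolved %% 2 == 1]]
  even <- px[resolved[resolved %% 2 == 0]]
  if (length(odd) > 1) expect_true(all(diff(odd) > 0) || all(diff(odd) < 0))
  if (length(even) > 1) expect_true(all(diff(even) > 0) || all(diff(even) < 0))
  if (length(odd) > 0 && length(even) > 0)
    expect_true((max(odd) < lim + 1e-9 && min(even) > lim - 1e-9) ||
                (max(even) < lim + 1e-9 && min(odd) > lim - 1e-9))
})

test_that("terminal labels: extinction converges to the disease-free node", {
  tr <- simulate_hybrid(c(0.15, 0.895), 2.5, ctrl_extinction(),
                        max_impulses = 100, t_max = 600)
  expect_equal(tr$terminal, "converged-to-attractor")
  expect_lt(length(tr$events), 100)
  final_arc <- tr$arcs[[length(tr$arcs)]]
  final <- final_arc$states[nrow(final_arc$states), ]
  expect_lt(sqrt(sum((final - c(2.5, 0))^2)), 1e-3)
})

test_that("max_impulses = 0 degenerates to a single arc", {
  ctrl <- ctrl_periodic()
  tr <- simulate_hybrid(c(0.15, 0.895), 2.5, ctrl, max_impulses = 0)
  expect_length(tr$arcs, 1)
  expect_length(tr$events, 0)
  expect_equal(tr$terminal, "max-impulses")
  seg <- integrate_to_impulse(c(0.15, 0.895), 2.5, ctrl)
  expect_equal(tr$arcs[[1]]$states[nrow(tr$arcs[[1]]$states), ],
               seg$state_end, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("first-quadrant invariance and uniform boundedness", {
  a <- 2.5
  starts <- list(c(0.01, 0.02), c(3.5, 0.5), c(0.05, 5), c(2, 3), c(1, 9.99))
  for (s0 in starts) {
    seg <- pulseSI:::.flow_to_line(s0, a, h = -1, t_max = 200,
                                   tol = si_tolerances(), n_store = 2000L)
    expect_gt(min(seg$states), -1e-9)
    # after a transient the flow sits inside a fixed box
    tail_idx <- seg$times > 50
    expect_lt(max(seg$states[tail_idx, 1]), a + 1e-6)
    expect_lt(max(seg$states[tail_idx, 2]), a)
  }
  expect_error(pulseSI:::.clip_state(c(-1e-3, 1), si_tolerances()),
               "first quadrant")
  expect_equal(pulseSI:::.clip_state(c(-1e-13, 1), si_tolerances()), c(0, 1))
})

test_that("trajectory CSV round-trips and keeps event consistency", {
  ctrl <- ctrl_periodic()
  tr <- simulate_hybrid(c(0.15, 0.895), 2.5, ctrl, max_impulses = 5)
  csv <- tempfile(fileext = ".csv")
  write_trajectory_csv(tr, csv)
  df <- utils::read.csv(csv)
  expect_named(df, c("time", "x", "y", "arc_index", "is_event"))
  pre <- df[df$is_event == "pre", ]
  post <- df[df$is_event == "post", ]
  expect_equal(nrow(pre), 5)
  expect_equal(post$x / pre$x, rep(1 - ctrl$p, 5), tolerance = 1e-12)
  expect_equal(post$y, rep((1 - ctrl$q) * ctrl$h2, 5))
  expect_equal(pre$y, rep(ctrl$h2, 5), tolerance = 1e-9)
  js <- jsonlite::read_json(sub("\\.csv$", ".json", csv),
                            simplifyVector = TRUE)
  expect_equal(js$n_events, 5)
  expect_equal(js$post_impulse_x, post$x, tolerance = 1e-12)
  unlink(c(csv, sub("\\.csv$", ".json", csv)))
})
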