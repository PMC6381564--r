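test_that("scaling satisfies its defining constraints and round-trips", {
  cases <- list(
    list(theta = 2.5, beta = 1, gamma = 1, a = 2.5),
    list(theta = 1, beta = 1, gamma = 1, a = 1),
    list(theta = 2.5, beta = 4, gamma = 1, a = NA),  # a fixed by k1 = k2
    list(theta = 3, beta = 0.5, gamma = 2, a = NA))
  for (cs in cases) {
    sc <- scale_model(model_params(cs$theta, cs$beta, cs$gamma))
    k <- sc$constants
    expect_equal(k$k3, 1 / cs$gamma, tolerance = 1e-12)
    expect_equal(cs$beta * k$k2^2 * k$k3, 1, tolerance = 1e-12)
    expect_equal(k$k1, k$k2)  # package convention
    expect_equal(sc$scaled$a, k$k3 * cs$theta / k$k1, tolerance = 1e-12)
    if (!is.na(cs$a)) expect_equal(sc$scaled$a, cs$a, tolerance = 1e-12)
    # round trip state + time
    st <- scale_state(S = 1.3, I = 0.7, t = 5, k)
    back <- unscale_state(st$x, st$y, st$tau, k)
    expect_equal(c(back$S, back$I, back$t), c(1.3, 0.7, 5), tolerance = 1e-12)
  }
  expect_equal(scale_model(model_params(2.5, 1, 1))$constants,
               list(k1 = 1, k2 = 1, k3 = 1))
  expect_error(model_params(-1, 1, 1), "invalid parameter")
  expect_error(model_params(1, 0, 1), "invalid parameter")
})

test_that("scaled vector field matches its closed form", {
  expect_equal(rhs_scaled(c(2.5, 0), 2.5), c(0, 0))
  expect_equal(rhs_scaled(c(2, 0.5), 2.5), c(0, 0))
  expect_equal(rhs_scaled(c(1, 1), 2.5), c(0.5, 0))
  # generic point against direct substitution
  expect_equal(rhs_scaled(c(0.3, 1.2), 1.7),
               c(1.7 - 1.2^2 * 0.3 - 0.3, 1.2^2 * 0.3 - 1.2))
})

test_that("epidemic threshold is a^2/4", {
  expect_identical(threshold_R0(2.5), 1.5625)
  expect_identical(threshold_R0(2), 1)
  expect_identical(threshold_R0(3), 2.25)
  expect_error(threshold_R0(-1), "invalid parameter")
})

test_that("equilibria: locations, kinds, residuals, algebraic identities", {
  eqs <- find_equilibria(2.5)
  expect_length(eqs, 3)
  expect_equal(c(eqs[[1]]$x, eqs[[1]]$y), c(2.5, 0), tolerance = 1e-12)
  expect_equal(c(eqs[[2]]$x, eqs[[2]]$y), c(2, 0.5), tolerance = 1e-12)
  expect_equal(c(eqs[[3]]$x, eqs[[3]]$y), c(0.5, 2), tolerance = 1e-12)
  expect_equal(vapply(eqs, `[[`, "", "kind"),
               c("stable-node", "saddle", "stable-node"))
  for (e in eqs)
    expect_lt(max(abs(rhs_scaled(c(e$x, e$y), 2.5))), 1e-10)
  # interior identities at several a: x*y = 1, x1 + x2 = a, x1*x2 = 1,
  # trace = -y^2, det = y^2 - 1
  for (a in c(2.1, 2.5, 3, 4)) {
    eqs <- find_equilibria(a)
    E1 <- eqs[[2]]; E2 <- eqs[[3]]
    expect_equal(E1$x * E1$y, 1, tolerance = 1e-12)
    expect_equal(E2$x * E2$y, 1, tolerance = 1e-12)
    expect_equal(E1$x + E2$x, a, tolerance = 1e-12)
    expect_equal(E1$x * E2$x, 1, tolerance = 1e-12)
    for (E in list(E1, E2)) {
      J <- si_jacobian(c(E$x, E$y), a)
      expect_equal(J[1, 1] + J[2, 2], -E$y^2, tolerance = 1e-12)
      expect_equal(det(J), E$y^2 - 1, tolerance = 1e-12)
    }
  }
})

test_that("subthreshold and boundary cases collapse correctly", {
  eqs <- find_equilibria(1)
  expect_length(eqs, 1)
  expect_equal(c(eqs[[1]]$x, eqs[[1]]$y), c(1, 0))
  expect_equal(eqs[[1]]$kind, "stable-node")
  # at the threshold the interior equilibria coincide and are degenerate
  eqs2 <- find_equilibria(2)
  expect_length(eqs2, 2)
  expect_equal(c(eqs2[[2]]$x, eqs2[[2]]$y), c(1, 1))
  expect_equal(eqs2[[2]]$kind, "degenerate")
  # threshold continuity: E1 and E2 approach each other as a decreases to 2
  gaps <- vapply(c(2.1, 2.01, 2.001), function(a) {
    eqs <- find_equilibria(a)
    sqrt((eqs[[2]]$x - eqs[[3]]$x)^2 + (eqs[[2]]$y - eqs[[3]]$y)^2)
  }, 0)
  expect_true(all(diff(gaps) < 0))
  expect_lt(gaps[3], 0.1)
})

test_that("Jacobian matches the entry formulas and a finite-difference oracle", {
  expect_equal(si_jacobian(c(2.5, 0), 2.5), diag(c(-1, -1)))
  expect_equal(si_jacobian(c(2, 0.5), 2.5),
               matrix(c(-1.25, 0.25, -2, 1), 2))
  # central-difference oracle on a grid of states
  set.seed(42)
  for (i in 1:10) {
    s <- runif(2, 0.1, 3); a <- runif(1, 0.5, 4)
    J <- si_jacobian(s, a)
    d <- 1e-6
    Jfd <- matrix(NA_real_, 2, 2)
    for (j in 1:2) {
      e <- c(0, 0); e[j] <- d
      Jfd[, j] <- (rhs_scaled(s + e, a) - rhs_scaled(s - e, a)) / (2 * d)
    }
    expect_equal(J, Jfd, tolerance = 1e-6)
  }
})

test_that("classification by eigenvalues: saddle, nodes, error contract", {
  e1 <- classify_equilibrium(c(2, 0.5), 2.5)
  expect_equal(e1$kind, "saddle")
  expect_equal(sort(Re(e1$eigenvalues)), c(-1, 0.75), tolerance = 1e-12)
  e0 <- classify_equilibrium(c(2.5, 0), 2.5)
  expect_equal(e0$kind, "stable-node")
  expect_equal(Re(e0$eigenvalues), c(-1, -1))
  e2 <- classify_equilibrium(c(0.5, 2), 2.5)
  expect_equal(e2$kind, "stable-node")
  expect_equal(sort(Re(e2$eigenvalues)), c(-3, -1), tolerance = 1e-12)
  # kind consistent with eigenvalue structure across a range of a
  for (a in c(2.05, 2.2, 3.5)) {
    for (e in find_equilibria(a)) {
      ev <- e$eigenvalues
      if (e$kind == "saddle")
        expect_true(all(Im(ev) == 0) && prod(Re(ev)) < 0)
      if (grepl("node", e$kind))
        expect_true(all(abs(Im(ev)) < 1e-10) && prod(Re(ev)) > 0)
      if (grepl("focus", e$kind))
        expect_true(any(Im(ev) != 0))
    }
  }
  expect_error(classify_equilibrium(c(1, 1), 2.5), "not an equilibrium")
})

test_that("nullclines: closed forms, branch labels, equilibria on both", {
  nc <- nullclines(2.5, c(0, 0.5, 1.6))
  l1 <- nc[nc$curve == "L1", ]
  expect_equal(l1$x, 2.5 / (1 + c(0, 0.5, 1.6)^2), tolerance = 1e-12)
  expect_equal(l1$x[l1$y == 1.6], 2.5 / 3.56, tolerance = 1e-12)
  expect_equal(l1$x[l1$y == 0.5], 2)          # L1 passes through E1
  expect_equal(l1$x[l1$y == 0], 2.5)          # and through E0
  hyp <- nc[nc$curve == "L2-hyperbola", ]
  expect_true(all(hyp$y > 0))
  expect_equal(hyp$x * hyp$y, rep(1, nrow(hyp)), tolerance = 1e-12)
  expect_equal(hyp$x[hyp$y == 0.5], 2)        # L2 also passes through E1
  expect_true("L2-axis" %in% nc$curve)
  expect_error(nullclines(2.5, c(-1, 0)), ">= 0")
})
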