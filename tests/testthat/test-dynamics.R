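make_traj <- function(states, model = "nD") {
  states <- as.matrix(states)
  structure(list(times = seq_len(nrow(states)) - 1L, states = states,
                 model = model),
            class = "trajectory")
}

test_that("gamma strengths implement the degree trade-off", {
  net <- bipartite_network(matrix(c(1, 1, 1, 0), 2, 2),
                           c("p1", "p2"), c("a1", "a2"))
  # p = 0: every link gets gamma0
  g0 <- gamma_matrix(net, gamma0 = 2, p = 0)
  expect_equal(g0$plant, net$incidence * 2, ignore_attr = TRUE)
  # p = 1: plant p1 has 2 partners -> strengths gamma0 / 2; zeros off-link
  g1 <- gamma_matrix(net, gamma0 = 1, p = 1)
  expect_equal(unname(g1$plant[1, ]), c(0.5, 0.5))
  expect_equal(unname(g1$plant[2, ]), c(1, 0))
  expect_equal(unname(g1$pollinator[2, ]), c(1, 0))
  # zero-degree species are an error unless explicitly allowed
  iso <- bipartite_network(matrix(c(1, 0, 1, 0), 2, 2), allow_isolated = TRUE)
  expect_error(gamma_matrix(iso), "zero-degree")
  expect_silent(gamma_matrix(iso, allow_isolated = TRUE))
})

test_that("the n-D vector field has the expected structure", {
  net <- bipartite_network(matrix(1, 1, 1), "p", "a")
  p <- nd_params(mu = 0)
  # total extinction is a fixed point when immigration is off
  expect_equal(nd_rhs(c(0, 0), p, net), c(0, 0))
  # symmetric pair with equal abundances stays symmetric
  d <- nd_rhs(c(0.7, 0.7), p, net)
  expect_equal(d[1], d[2])
  expect_error(nd_rhs(c(1, 1, 1), p, net), "length")
  # without mutualism a lone species settles at alpha / beta_ii
  solo <- nd_params(gamma0 = 0, mu = 0)
  traj <- integrate_dynamics("nD", solo, net, init = c(0.01, 0),
                             stop_early = FALSE, max_steps = 200)
  expect_equal(unname(traj$states[nrow(traj$states), 1]),
               solo$alpha / solo$beta_intra, tolerance = 1e-8)
})

test_that("the 2-D reduction matches its algebraic steady states", {
  # no mutualism, no immigration: logistic root alpha / beta
  p <- twod_params(mu = 0)
  traj <- integrate_dynamics("2D", p, init = c(1e-6, 1e-6),
                             stop_early = FALSE, max_steps = 300)
  expect_equal(unname(traj$states[nrow(traj$states), ]),
               rep(p$alpha / p$beta, 2), tolerance = 1e-8)

  # symmetric initial conditions stay symmetric for all time
  ps <- twod_params(gamma_P_avg = 0.8, gamma_A_avg = 0.8)
  traj <- integrate_dynamics("2D", ps, init = c(0.01, 0.01))
  expect_equal(traj$states[, 1], traj$states[, 2], tolerance = 1e-10)

  # mu > 0, gamma > 0: equilibrium equals an independent bracketing root
  f <- function(x) {
    ps$alpha * x - ps$beta * x^2 +
      (ps$gamma_P_avg * x / (1 + ps$h * ps$gamma_P_avg * x)) * x + ps$mu
  }
  xstar <- stats::uniroot(f, c(0.5, 50), tol = 1e-12)$root
  traj <- integrate_dynamics("2D", ps, init = c(1e-6, 1e-6),
                             stop_early = FALSE, max_steps = 300)
  expect_equal(unname(traj$states[nrow(traj$states), 1]), xstar,
               tolerance = 1e-6)
})

test_that("the 1-D vector field factorizes and matches a root oracle", {
  p <- oned_params(B = 0, beta_eff = 0)
  # cubic roots at 0, the Allee threshold, and the carrying capacity
  expect_equal(oned_rhs(0, p), 0)
  expect_equal(oned_rhs(p$C_allee, p), 0)
  expect_equal(oned_rhs(p$K, p), 0)
  # Allee decline between 0 and C_allee
  for (x in seq(0.05, 0.95, by = 0.1)) expect_lt(oned_rhs(x, p), 0)

  # with migration and mutualism: steady state equals a bracketed root
  pb <- oned_params(B = 0.1, beta_eff = 3)
  traj <- integrate_dynamics("1D", pb, init = 2, stop_early = FALSE,
                             max_steps = 300)
  xend <- unname(traj$states[nrow(traj$states), 1])
  xstar <- stats::uniroot(function(x) oned_rhs(x, pb), c(1, 50),
                          tol = 1e-12)$root
  expect_equal(xend, xstar, tolerance = 1e-6)
})

test_that("integration preserves fixed points and respects the Allee basin", {
  # start exactly at the carrying capacity: nothing moves
  p <- oned_params(B = 0, beta_eff = 0)
  traj <- integrate_dynamics("1D", p, init = p$K, max_steps = 50,
                             stop_early = FALSE)
  expect_lt(max(abs(diff(traj$states))), 1e-8)
  # init far below the Allee threshold with no migration: collapse to 0
  traj <- integrate_dynamics("1D", p, init = 1e-6)
  expect_lt(traj$states[nrow(traj$states), 1], 1e-8)
})

test_that("trajectories stay nonnegative across random parameter sweeps", {
  set.seed(31)
  for (k in 1:5) {
    net <- random_test_network(4, 5, C = 0.4, seed = k)
    pn <- nd_params(alpha = runif(1, -0.5, 0.5), gamma0 = runif(1, 0, 2),
                    p = runif(1, 0, 1))
    traj <- integrate_dynamics("nD", pn, net,
                               init = runif(9, 0, 2), max_steps = 80)
    expect_true(all(traj$states >= 0))
    p1 <- oned_params(B = runif(1, 0, 0.3), beta_eff = runif(1, 0, 5))
    traj <- integrate_dynamics("1D", p1, init = runif(1, 0, 6))
    expect_true(all(traj$states >= 0))
  }
})

test_that("settling time finds the first quiet window", {
  # exactly constant trajectory: ST = 0
  st <- detect_steady(make_traj(matrix(1, 10, 2)))
  expect_equal(as.numeric(st), 0)
  expect_true(attr(st, "settled"))

  # permanent oscillation above tolerance: sentinel, flagged unsettled
  osc <- matrix(rep(c(0, 1e-3), 150), ncol = 1)
  st <- detect_steady(make_traj(osc))
  expect_equal(as.numeric(st), 299)
  expect_false(attr(st, "settled"))

  # constant after step 12: ST = 12
  x <- c(seq(5, 5 - 12 * 0.1, by = -0.1), rep(5 - 1.2, 10))
  st <- detect_steady(make_traj(matrix(x, ncol = 1)))
  expect_equal(as.numeric(st), 12)

  expect_error(detect_steady(make_traj(matrix(1, 3, 1))), "window")
})

test_that("criteria aggregate survival, abundance, and settling", {
  # all four species comfortably above threshold: full persistence
  tr <- make_traj(matrix(rep(c(1, 2, 3, 4), each = 8), 8, 4))
  cr <- compute_criteria(tr, reference_S = 4)
  expect_equal(cr$persistence_P, 1)
  expect_equal(cr$abundance_X, 2.5)
  expect_equal(cr$settling_time_ST, 0)

  # total collapse: empty-mean convention gives X = 0
  cr <- compute_criteria(make_traj(matrix(0, 8, 4)), reference_S = 4)
  expect_equal(cr$persistence_P, 0)
  expect_equal(cr$abundance_X, 0)

  # 3 of 4 species above threshold
  tr <- make_traj(matrix(rep(c(1, 2, 3, 0), each = 8), 8, 4))
  expect_equal(compute_criteria(tr, reference_S = 4)$persistence_P, 0.75)

  # reduced models count topologically present species per guild
  tr2 <- make_traj(matrix(rep(c(2, 3), each = 8), 8, 2), model = "2D")
  cr <- compute_criteria(tr2, reference_S = 10, present = c(3, 4))
  expect_equal(cr$persistence_P, 0.7)
  tr1 <- make_traj(matrix(2, 8, 1), model = "1D")
  expect_equal(compute_criteria(tr1, reference_S = 10, present = 6)$persistence_P,
               0.6)
})

test_that("the 2-D reduction tracks the n-D mean on dense homogeneous networks", {
  net <- generate_network(generator_config(6, 6, 0.9, 0, seed = 2))
  pn <- nd_params()
  nd_traj <- integrate_dynamics("nD", pn, net,
                                init = rep(1e-6, 12), stop_early = FALSE,
                                max_steps = 300)
  nd_mean <- mean(nd_traj$states[nrow(nd_traj$states), ])
  p2 <- twod_params_from_network(net, pn)
  td_traj <- integrate_dynamics("2D", p2, init = c(1e-6, 1e-6),
                                stop_early = FALSE, max_steps = 300)
  td_mean <- mean(td_traj$states[nrow(td_traj$states), ])
  expect_lt(abs(td_mean - nd_mean) / nd_mean, 0.1)
})
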