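#' Parameters of the full n-dimensional mutualistic community model
#'
#' The n-D model couples every plant and pollinator: each species grows
#' logistically (intrinsic rate `alpha`, intraspecific competition
#' `beta_intra`, interspecific competition `beta_inter` within its guild),
#' gains from its mutualistic partners through a Holling type II saturating
#' term with half-saturation constant `h`, and receives a constant
#' immigration inflow `mu`. Per-link mutualistic strengths are
#' `gamma0 / D^p` where `D` is the species' partner count and `p` the
#' strength/generalism trade-off exponent (see [gamma_matrix()]).
#'
#' Defaults follow the standard parameterization of this model family;
#' every value can be overridden.
#'
#' @param alpha Intrinsic growth rate (per step).
#' @param beta_intra,beta_inter Intraguild competition coefficients
#'   (diagonal and off-diagonal); `beta_intra > 0` required.
#' @param h Half-saturation constant of the mutualistic benefit.
#' @param mu Immigration rate, added outside the per-capita bracket.
#' @param gamma0 Mutualistic strength scale.
#' @param p Trade-off exponent between strength and number of partners.
#' @return A list of class `nd_params`.
#' @export
nd_params <- function(alpha = 0.3, beta_intra = 1, beta_inter = 0.01,
                      h = 0.2, mu = 1e-4, gamma0 = 1, p = 0.5) {
  stopifnot(beta_intra > 0, h >= 0, gamma0 >= 0, p >= 0)
  structure(list(alpha = alpha, beta_intra = beta_intra,
                 beta_inter = beta_inter, h = h, mu = mu,
                 gamma0 = gamma0, p = p),
            class = "nd_params")
}

#' Parameters of the two-dimensional reduced model
#'
#' The 2-D reduction tracks one effective abundance per guild (`P_eff`,
#' `A_eff`) with logistic growth, a saturating mutualistic gain driven by
#' the network-averaged strengths `gamma_P_avg`, `gamma_A_avg`, and
#' immigration `mu`. Use [twod_params_from_network()] to derive the
#' effective strengths (and effective competition) from a network.
#'
#' @param alpha,beta,h,mu Scalars as in [nd_params()]; `beta > 0`.
#' @param gamma_P_avg,gamma_A_avg Effective mutualistic strengths felt by
#'   the plant and pollinator guilds.
#' @return A list of class `twod_params`.
#' @export
twod_params <- function(alpha = 0.3, beta = 1, h = 0.2, mu = 1e-4,
                        gamma_P_avg = 0, gamma_A_avg = 0) {
  stopifnot(beta > 0)
  structure(list(alpha = alpha, beta = beta, h = h, mu = mu,
                 gamma_P_avg = gamma_P_avg, gamma_A_avg = gamma_A_avg),
            class = "twod_params")
}

#' @describeIn twod_params Derive 2-D parameters from a network: the
#'   effective strengths are the degree-weighted averages of the per-species
#'   total mutualistic strengths `gamma0 * D^(1-p)`, and the effective
#'   competition is `beta_intra + beta_inter * (mean guild size - 1)`,
#'   recomputed after every network change.
#' @param net A [bipartite_network()] (isolated species allowed; they simply
#'   contribute no mutualistic strength).
#' @param nd An [nd_params()] supplying the microscopic parameter values.
#' @export
twod_params_from_network <- function(net, nd = nd_params()) {
  g <- gamma_averages(net, nd$gamma0, nd$p)
  n <- n_plants(net)
  m <- n_pollinators(net)
  beta <- nd$beta_intra + nd$beta_inter * max(0, mean(c(n, m)) - 1)
  twod_params(alpha = nd$alpha, beta = beta, h = nd$h, mu = nd$mu,
              gamma_P_avg = g[["plants"]], gamma_A_avg = g[["pollinators"]])
}

#' Parameters of the one-dimensional reduced model
#'
#' The 1-D model tracks a single effective abundance `x_eff` of the chosen
#' one-mode projection, with constant immigration `B`, logistic growth to
#' carrying capacity `K`, an Allee effect (negative growth below the
#' threshold `C_allee`), and a saturating mutualistic gain scaled by the
#' projection's effective nearest-neighbour degree `beta_eff`
#' (see [beta_eff()]); `D`, `E`, `H` parameterize the saturation.
#'
#' @param B Migration inflow.
#' @param K Carrying capacity.
#' @param C_allee Allee threshold, `0 < C_allee < K`.
#' @param D,E,H Mutualistic saturation parameters.
#' @param beta_eff Effective nearest-neighbour degree of the projection.
#' @return A list of class `oned_params`.
#' @export
oned_params <- function(B = 0.1, K = 5, C_allee = 1, D = 5, E = 0.9,
                        H = 0.1, beta_eff = 0) {
  stopifnot(C_allee > 0, C_allee < K, beta_eff >= 0, D > 0, E + H >= 0)
  structure(list(B = B, K = K, C_allee = C_allee, D = D, E = E, H = H,
                 beta_eff = beta_eff),
            class = "oned_params")
}

#' @describeIn oned_params Derive 1-D parameters from a network by
#'   projecting onto `side` and computing `beta_eff`.
#' @param net A [bipartite_network()].
#' @param side Guild to project onto.
#' @param weighted Use shared-partner counts in the projection.
#' @param base An [oned_params()] supplying the non-network parameters.
#' @export
oned_params_from_network <- function(net, side = c("plants", "pollinators"),
                                     weighted = TRUE, base = oned_params()) {
  side <- match.arg(side)
  be <- if (n_plants(net) == 0 || n_pollinators(net) == 0) 0 else
    beta_eff(project(net, side), weighted = weighted)
  base$beta_eff <- be
  base
}

#' Per-link mutualistic interaction strengths
#'
#' `gamma[i, j] = eps[i, j] * gamma0 / D_i^p`, where `eps` is the incidence
#' indicator and `D_i` the partner count of the focal species `i` in the
#' current network: generalists spread a fixed budget over more partners
#' when `p > 0`. Returned for both guilds (rows are always the focal side).
#'
#' @param net A [bipartite_network()].
#' @param gamma0 Strength scale.
#' @param p Trade-off exponent.
#' @param allow_isolated Permit zero-degree species (their strengths are all
#'   zero); by default their presence is an error, since the extinction
#'   cascade removes them from any standing network.
#' @return List with `plant` (`n x m`) and `pollinator` (`m x n`) strength
#'   matrices.
#' @export
gamma_matrix <- function(net, gamma0 = 1, p = 0.5, allow_isolated = FALSE) {
  stopifnot(p >= 0, gamma0 >= 0)
  eps <- net$incidence
  Dp <- rowSums(eps)
  Da <- colSums(eps)
  if (!allow_isolated && (any(Dp == 0) || any(Da == 0))) {
    stop("network contains zero-degree species; run the cascade first")
  }
  sp <- ifelse(Dp > 0, gamma0 / Dp^p, 0)
  sa <- ifelse(Da > 0, gamma0 / Da^p, 0)
  list(plant = eps * sp, pollinator = t(eps) * sa)
}

# Degree-weighted network averages of per-species total mutualistic
# strength gamma0 * D^(1-p), one per guild; the effective couplings of the
# 2-D reduction.
gamma_averages <- function(net, gamma0 = 1, p = 0.5) {
  avg <- function(D) {
    D <- D[D > 0]
    if (!length(D)) return(0)
    s <- gamma0 * D^(1 - p)
    sum(D * s) / sum(D)
  }
  c(plants = avg(rowSums(net$incidence)),
    pollinators = avg(colSums(net$incidence)))
}

# --- right-hand sides ------------------------------------------------------

# Precompute the static pieces of the n-D vector field for one network.
make_nd_context <- function(params, net) {
  n <- n_plants(net)
  m <- n_pollinators(net)
  g <- gamma_matrix(net, params$gamma0, params$p, allow_isolated = TRUE)
  comp <- function(k) {
    if (k == 0) return(matrix(0, 0, 0))
    matrix(params$beta_inter, k, k) +
      diag(params$beta_intra - params$beta_inter, k)
  }
  list(n = n, m = m, gP = g$plant, gA = g$pollinator,
       BP = comp(n), BA = comp(m),
       alpha = params$alpha, h = params$h, mu = params$mu)
}

nd_rhs_core <- function(state, ctx) {
  n <- ctx$n
  m <- ctx$m
  P <- pmax(state[seq_len(n)], 0)
  A <- pmax(state[n + seq_len(m)], 0)
  dP <- if (n) {
    uP <- if (m) as.numeric(ctx$gP %*% A) else numeric(n)
    P * (ctx$alpha - as.numeric(ctx$BP %*% P) + uP / (1 + ctx$h * uP)) + ctx$mu
  } else numeric(0)
  dA <- if (m) {
    uA <- if (n) as.numeric(ctx$gA %*% P) else numeric(m)
    A * (ctx$alpha - as.numeric(ctx$BA %*% A) + uA / (1 + ctx$h * uA)) + ctx$mu
  } else numeric(0)
  c(dP, dA)
}

#' Vector fields of the three dynamical models
#'
#' `nd_rhs` evaluates the full n-D model (state ordered as
#' `c(plants, pollinators)` following [species()]); `twod_rhs` the 2-D
#' reduction (state `c(P_eff, A_eff)`); `oned_rhs` the 1-D reduction
#' (scalar `x_eff`). Negative state entries are treated as 0.
#'
#' @param state,x Abundance state (vector / pair / scalar).
#' @param params Matching parameter object ([nd_params()], [twod_params()],
#'   [oned_params()]).
#' @param net The current [bipartite_network()] (n-D only).
#' @return Derivative of the same shape as the state.
#' @export
nd_rhs <- function(state, params, net) {
  if (length(state) != n_plants(net) + n_pollinators(net)) {
    stop("state length does not match the network's species count")
  }
  nd_rhs_core(state, make_nd_context(params, net))
}

#' @rdname nd_rhs
#' @export
twod_rhs <- function(state, params) {
  P <- max(state[[1L]], 0)
  A <- max(state[[2L]], 0)
  gP <- params$gamma_P_avg
  gA <- params$gamma_A_avg
  c(params$alpha * P - params$beta * P^2 +
      (gP * A / (1 + params$h * gP * A)) * P + params$mu,
    params$alpha * A - params$beta * A^2 +
      (gA * P / (1 + params$h * gA * P)) * A + params$mu)
}

#' @rdname nd_rhs
#' @export
oned_rhs <- function(x, params) {
  x <- max(x, 0)
  params$B + x * (1 - x / params$K) * (x / params$C_allee - 1) +
    params$beta_eff * x^2 / (params$D + (params$E + params$H) * x)
}

# --- integration -----------------------------------------------------------

#' Integrate a model to (near) steady state
#'
#' Adaptive stiff-safe integration (via [deSolve::ode()], `lsoda`) sampled
#' at unit time steps (1 step = 4 months). Sampled states are clipped at 0.
#' When `stop_early` is set, integration stops as soon as every state
#' component has changed by less than `steady_tol` over `steady_window`
#' consecutive steps (the settling rule of [detect_steady()]); otherwise
#' it runs to `max_steps` (default 300 steps = 100 years).
#'
#' @param model `"1D"`, `"2D"` or `"nD"`.
#' @param params Parameter object matching the model.
#' @param net Current [bipartite_network()]; required for `"nD"`, ignored
#'   otherwise (reduced models carry their network dependence inside
#'   `params`).
#' @param init Initial abundances (scalar / pair / full vector ordered as
#'   [species()]).
#' @param max_steps Time horizon in steps.
#' @param steady_tol,steady_window Early-stopping settling rule.
#' @param stop_early Stop once settled.
#' @param chunk Internal integration chunk length (steps) between clipping
#'   and settling checks.
#' @return A `trajectory`: list with `times` (0..T), `states` (time x
#'   component matrix), `model`.
#' @export
integrate_dynamics <- function(model = c("1D", "2D", "nD"), params, net = NULL,
                               init, max_steps = 300, steady_tol = 1e-6,
                               steady_window = 5, stop_early = TRUE,
                               chunk = 25) {
  model <- match.arg(model)
  if (any(init < 0)) stop("initial abundances must be nonnegative")
  rhs <- switch(model,
    "1D" = {
      stopifnot(length(init) == 1L, inherits(params, "oned_params"))
      function(t, y, parms) list(oned_rhs(y, params))
    },
    "2D" = {
      stopifnot(length(init) == 2L, inherits(params, "twod_params"))
      function(t, y, parms) list(twod_rhs(y, params))
    },
    "nD" = {
      stopifnot(inherits(params, "nd_params"), inherits(net, "bipartite_network"))
      if (length(init) != n_plants(net) + n_pollinators(net)) {
        stop("init length does not match the network's species count")
      }
      ctx <- make_nd_context(params, net)
      function(t, y, parms) list(nd_rhs_core(y, ctx))
    }
  )
  cn <- switch(model,
    "1D" = "x_eff",
    "2D" = c("P_eff", "A_eff"),
    "nD" = species(net)
  )
  y <- pmax(as.numeric(init), 0)
  states <- matrix(y, nrow = 1L, dimnames = list(NULL, cn))
  t0 <- 0L
  while (t0 < max_steps) {
    t1 <- min(t0 + chunk, max_steps)
    tt <- seq(t0, t1)
    sol <- tryCatch(
      deSolve::ode(y = y, times = tt, func = rhs, parms = NULL,
                   method = "lsoda"),
      warning = function(w) w, error = function(e) e
    )
    if (inherits(sol, "condition") || nrow(sol) < length(tt)) {
      traj <- structure(list(times = seq_len(nrow(states)) - 1L,
                             states = states, model = model),
                        class = "trajectory")
      cond <- simpleError(paste0("integrator failure in ", model, " model: ",
                                 conditionMessage(
                                   if (inherits(sol, "condition")) sol
                                   else simpleCondition("truncated output"))))
      cond$trajectory <- traj
      stop(cond)
    }
    new <- pmax(unname(sol[-1L, -1L, drop = FALSE]), 0)
    states <- rbind(states, new)
    y <- states[nrow(states), ]
    t0 <- t1
    if (stop_early && nrow(states) > steady_window) {
      tail_rows <- states[(nrow(states) - steady_window):nrow(states), ,
                          drop = FALSE]
      if (all(abs(diff(tail_rows)) < steady_tol)) break
    }
  }
  structure(list(times = seq_len(nrow(states)) - 1L, states = states,
                 model = model),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory: %s model, %d components, t = 0..%d>\n",
              x$model, ncol(x$states), max(x$times)))
  invisible(x)
}

#' Settling time of a trajectory
#'
#' The settling time `ST` is the first time step `t` such that every
#' component changes by less than `tol` over each of the next `window`
#' steps. A trajectory that never satisfies the rule gets the sentinel
#' `max(times)` with `settled = FALSE`.
#'
#' @param traj A trajectory from [integrate_dynamics()].
#' @param tol Per-step tolerance (default `1e-6`).
#' @param window Number of consecutive quiet steps required (default 5).
#' @return Settling time (steps) with attribute `settled` (logical).
#' @export
detect_steady <- function(traj, tol = 1e-6, window = 5) {
  S <- traj$states
  if (nrow(S) < window + 1L) {
    stop("trajectory needs at least window + 1 samples")
  }
  d <- abs(diff(S))
  quiet <- apply(d, 1L, max) < tol
  cs <- cumsum(quiet)
  runs <- cs - c(rep(0, window), utils::head(cs, -window))
  hit <- which(runs == window)
  if (length(hit)) {
    st <- hit[1L] - window  # time index where the quiet window begins
    structure(st, settled = TRUE)
  } else {
    structure(max(traj$times), settled = FALSE)
  }
}

#' Recovery criteria of a settled trajectory
#'
#' Computes the three criteria used to compare restoration strategies:
#' mean abundance of surviving species `X`, settling time `ST`
#' (see [detect_steady()]), and persistence `P` = surviving species /
#' species in the intact reference network. A species (n-D) or guild
#' (reduced models) survives if its final abundance exceeds
#' `extinct_threshold`. For the reduced models the species-level count is
#' carried in `present`: the number of species topologically present in
#' each guild, which survive or collapse together with their guild's
#' effective abundance.
#'
#' @param traj A trajectory from [integrate_dynamics()].
#' @param reference_S Species count of the intact network.
#' @param extinct_threshold Final abundance at or below which a species
#'   counts as extinct (default `1e-4`).
#' @param present For `"1D"`: total number of species topologically present;
#'   for `"2D"`: `c(plants, pollinators)` present counts. Ignored for
#'   `"nD"` (each present species has its own state).
#' @param tol,window Settling rule, passed to [detect_steady()].
#' @return A list of class `criteria_record` with `abundance_X`,
#'   `settling_time_ST`, `persistence_P`, `settled`.
#' @export
compute_criteria <- function(traj, reference_S, extinct_threshold = 1e-4,
                             present = NULL, tol = 1e-6, window = 5) {
  final <- traj$states[nrow(traj$states), ]
  st <- detect_steady(traj, tol = tol, window = window)
  alive <- final > extinct_threshold
  if (traj$model == "nD") {
    survivors <- sum(alive)
    X <- if (survivors) mean(final[alive]) else 0
  } else if (traj$model == "2D") {
    stopifnot(length(present) == 2L)
    survivors <- sum(present * alive)
    X <- if (survivors > 0 && any(alive)) mean(final[alive]) else 0
  } else {
    stopifnot(length(present) == 1L)
    survivors <- if (alive[[1L]]) present else 0
    X <- if (survivors > 0) final[[1L]] else 0
  }
  structure(list(abundance_X = unname(X),
                 settling_time_ST = as.numeric(st),
                 persistence_P = unname(survivors / reference_S),
                 settled = isTRUE(attr(st, "settled"))),
            class = "criteria_record")
}
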