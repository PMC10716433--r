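#' Species-reintroduction strategy
#'
#' Network-guided strategies rank the removed species by a centrality
#' measured on the original intact network (default) or recomputed on the
#' current partially restored network; `beta_eff_greedy` instead grows the
#' network so that each reintroduction maximizes the incremental gain in
#' the projection's effective nearest-neighbour degree; `random` is the
#' null model (seeded shuffle).
#'
#' @param kind One of `"degree"`, `"closeness"`, `"betweenness"`,
#'   `"beta_eff_greedy"`, `"random"`.
#' @param reference_network `"original"` (rank once on the intact network)
#'   or `"current"` (re-rank at every step); ignored by `beta_eff_greedy`,
#'   which is always greedy on the current network.
#' @param seed Seed for the `random` kind.
#' @return A list of class `restoration_strategy`.
#' @export
restoration_strategy <- function(kind = c("degree", "closeness",
                                          "betweenness", "beta_eff_greedy",
                                          "random"),
                                 reference_network = c("original", "current"),
                                 seed = 1L) {
  kind <- match.arg(kind)
  reference_network <- match.arg(reference_network)
  structure(list(kind = kind, reference_network = reference_network,
                 seed = as.integer(seed)),
            class = "restoration_strategy")
}

#' Rank removed species for reintroduction
#'
#' Orders the removed set by descending centrality. With
#' `reference_network = "original"` the centrality is computed once on the
#' intact network; with `"current"` each next species is the candidate with
#' the highest centrality when tentatively placed into the current
#' partially restored network. Ties are broken by ascending species label,
#' so every ranking is deterministic. The `random` kind returns a seeded
#' shuffle.
#'
#' @param original_net The intact [bipartite_network()].
#' @param removed Character vector of species to reintroduce.
#' @param strategy A [restoration_strategy()] with kind `degree`,
#'   `closeness`, `betweenness` or `random`.
#' @param degraded_net The post-cascade network; required for
#'   `reference_network = "current"`.
#' @return Ordered character vector (a permutation of `removed`).
#' @export
rank_sequence <- function(original_net, removed, strategy,
                          degraded_net = NULL) {
  stopifnot(length(removed) > 0)
  unknown <- setdiff(removed, species(original_net))
  if (length(unknown)) {
    stop("species not in original network: ", paste(unknown, collapse = ", "))
  }
  if (strategy$kind == "random") {
    return(with_seed(strategy$seed, sample(removed)))
  }
  if (!strategy$kind %in% c("degree", "closeness", "betweenness")) {
    stop("rank_sequence handles centrality and random strategies; use beta_eff_greedy_sequence() for beta_eff_greedy")
  }
  if (strategy$reference_network == "original") {
    sc <- centrality(original_net, strategy$kind)$scores[removed]
    return(removed[order(-sc, removed)])
  }
  if (is.null(degraded_net)) {
    stop("reference_network = 'current' needs the degraded network")
  }
  present <- species(degraded_net)
  remaining <- sort(removed)
  seq_out <- character()
  while (length(remaining)) {
    sc <- vapply(remaining, function(s) {
      cur <- subnetwork(original_net, c(present, s), allow_isolated = TRUE)
      centrality(cur, strategy$kind)$scores[[s]]
    }, numeric(1))
    pick <- remaining[order(-sc, remaining)][1L]
    seq_out <- c(seq_out, pick)
    present <- c(present, pick)
    remaining <- setdiff(remaining, pick)
  }
  seq_out
}

#' Greedy beta_eff-maximizing reintroduction sequence
#'
#' At each step every remaining candidate is tentatively reinserted (with
#' its original links to the currently present species), the effective
#' nearest-neighbour degree of the chosen-side projection is computed, and
#' the maximizer is committed. Ties are broken by ascending species label.
#'
#' @param original_net The intact [bipartite_network()].
#' @param degraded_net The post-cascade network.
#' @param removed Species to reintroduce.
#' @param side Projection side for [beta_eff()].
#' @param weighted Weighted projection (shared-partner counts).
#' @return Ordered character vector (a permutation of `removed`).
#' @export
beta_eff_greedy_sequence <- function(original_net, degraded_net, removed,
                                     side = c("plants", "pollinators"),
                                     weighted = TRUE) {
  side <- match.arg(side)
  stopifnot(length(removed) > 0)
  present <- species(degraded_net)
  remaining <- sort(removed)
  seq_out <- character()
  while (length(remaining)) {
    gains <- vapply(remaining, function(s) {
      cur <- subnetwork(original_net, c(present, s), allow_isolated = TRUE)
      beta_eff(project(cur, side), weighted = weighted)
    }, numeric(1))
    pick <- remaining[which.max(gains)]  # remaining is sorted: label tie-break
    seq_out <- c(seq_out, pick)
    present <- c(present, pick)
    remaining <- setdiff(remaining, pick)
  }
  seq_out
}

#' Enumerate every restoration pathway
#'
#' All orderings of the removed set, exactly once each, lexicographic in
#' species label. With 6 removed species this is 6! = 720 pathways; a
#' configurable cap bounds the factorial cost.
#'
#' @param removed Species to reintroduce.
#' @param cap Maximum number of species to enumerate over (default 8).
#' @return List of character vectors, each a permutation of `removed`.
#' @export
enumerate_pathways <- function(removed, cap = 8L) {
  if (length(removed) > cap) {
    stop(sprintf(
      "%d removed species exceed the enumeration cap (%d! orderings); sample sequences instead",
      length(removed), cap))
  }
  permutations_of(sort(removed))
}

#' Simulate a sequential restoration run
#'
#' Starting from the degraded, post-cascade community, reintroduces the
#' species of `sequence` one at a time. Each reintroduction adds the
#' species back with all of its original links to currently present
#' species (never inventing links), sets its abundance to
#' `init_abundance`, integrates the chosen model to steady state, and
#' records the three criteria plus the current network attributes.
#' Surviving species carry their abundances forward between steps
#' (`reinit = "fresh"` instead restarts every species at `init_abundance`
#' each step). A reintroduced species with no currently present partner is
#' kept; it simply has no mutualistic support until a partner follows.
#'
#' @param original_net The intact [bipartite_network()].
#' @param outcome A [cascade()] / [perturb()] outcome.
#' @param sequence Permutation of `primary_removed` plus
#'   `secondary_removed` (complete recovery is the goal).
#' @param model `"1D"`, `"2D"` or `"nD"`.
#' @param params [oned_params()] for `"1D"`, otherwise [nd_params()]
#'   (the 2-D reduction derives its effective parameters from it at every
#'   step). Network-derived parts (`beta_eff`, effective strengths,
#'   per-link strengths) are recomputed after every reintroduction.
#' @param control List of optional settings: `init_abundance` (1e-6),
#'   `extinct_threshold` (1e-4), `max_steps` (300), `steady_tol` (1e-6),
#'   `steady_window` (5), `side` ("plants"), `weighted` (TRUE), `reinit`
#'   ("carry" or "fresh"), `track_attributes` (TRUE).
#' @param strategy Optional [restoration_strategy()] stored as metadata.
#' @return A list of class `restoration_run`: `sequence`, `per_step`
#'   (data.frame: step, species, X, ST, P, settled, S, A, C, NODF),
#'   `baseline` (criteria of the degraded state), `model`, `strategy`,
#'   `failed` (TRUE if a model failure truncated the run).
#' @export
simulate_restoration <- function(original_net, outcome, sequence,
                                 model = c("1D", "2D", "nD"), params = NULL,
                                 control = list(), strategy = NULL) {
  model <- match.arg(model)
  ctl <- utils::modifyList(
    list(init_abundance = 1e-6, extinct_threshold = 1e-4, max_steps = 300,
         steady_tol = 1e-6, steady_window = 5, side = "plants",
         weighted = TRUE, reinit = "carry", track_attributes = TRUE),
    control)
  removed_all <- c(outcome$primary_removed, outcome$secondary_removed)
  # an empty sequence is a no-op: report the degraded baseline only
  if (length(sequence) > 0 &&
      (!setequal(sequence, removed_all) ||
       length(sequence) != length(removed_all))) {
    stop("sequence must be a permutation of the primary plus secondary removed species")
  }
  if (is.null(params)) {
    params <- if (model == "1D") oned_params() else nd_params()
  }
  S_ref <- n_plants(original_net) + n_pollinators(original_net)
  present <- species(outcome$degraded_net)

  run_step <- function(cur, init) {
    p <- switch(model,
      "1D" = oned_params_from_network(cur, side = ctl$side,
                                      weighted = ctl$weighted, base = params),
      "2D" = twod_params_from_network(cur, nd = params),
      "nD" = params
    )
    traj <- integrate_dynamics(model, p, net = cur, init = init,
                               max_steps = ctl$max_steps,
                               steady_tol = ctl$steady_tol,
                               steady_window = ctl$steady_window)
    pres <- switch(model,
      "1D" = n_plants(cur) + n_pollinators(cur),
      "2D" = c(n_plants(cur), n_pollinators(cur)),
      "nD" = NULL
    )
    crit <- compute_criteria(traj, reference_S = S_ref,
                             extinct_threshold = ctl$extinct_threshold,
                             present = pres, tol = ctl$steady_tol,
                             window = ctl$steady_window)
    list(crit = crit, final = traj$states[nrow(traj$states), ])
  }

  empty_crit <- structure(
    list(abundance_X = 0, settling_time_ST = 0, persistence_P = 0,
         settled = TRUE),
    class = "criteria_record")

  # degraded baseline
  carried <- switch(model,
    "1D" = ctl$init_abundance,
    "2D" = rep(ctl$init_abundance, 2L),
    "nD" = stats::setNames(rep(ctl$init_abundance, length(present)), present)
  )
  if (length(present)) {
    base <- run_step(outcome$degraded_net, carried)
    baseline <- base$crit
    carried <- base$final
    if (model == "nD") names(carried) <- species(outcome$degraded_net)
  } else {
    baseline <- empty_crit
  }

  steps <- vector("list", length(sequence))
  failed <- FALSE
  for (i in seq_along(sequence)) {
    s <- sequence[i]
    present <- c(present, s)
    cur <- subnetwork(original_net, present, allow_isolated = TRUE)
    init <- switch(model,
      "1D" = if (ctl$reinit == "fresh") ctl$init_abundance else carried,
      "2D" = if (ctl$reinit == "fresh") rep(ctl$init_abundance, 2L) else carried,
      "nD" = {
        v <- stats::setNames(rep(ctl$init_abundance, length(species(cur))),
                             species(cur))
        if (ctl$reinit != "fresh") {
          old <- intersect(names(carried), names(v))
          v[old] <- carried[old]
        }
        v
      }
    )
    res <- tryCatch(run_step(cur, init), error = function(e) e)
    if (inherits(res, "error")) {
      failed <- TRUE
      warning("model failure at restoration step ", i, ": ",
              conditionMessage(res))
      steps <- steps[seq_len(i - 1L)]
      break
    }
    carried <- res$final
    if (model == "nD") names(carried) <- species(cur)
    at <- if (ctl$track_attributes) network_attributes(cur) else NULL
    steps[[i]] <- data.frame(
      step = i, species = s,
      X = res$crit$abundance_X, ST = res$crit$settling_time_ST,
      P = res$crit$persistence_P, settled = res$crit$settled,
      S = if (is.null(at)) NA_real_ else at$size_S,
      A = if (is.null(at)) NA_real_ else at$asymmetry_A,
      C = if (is.null(at)) NA_real_ else at$connectance_C,
      NODF = if (is.null(at)) NA_real_ else at$nestedness_NODF,
      stringsAsFactors = FALSE)
  }
  per_step <- if (length(steps)) do.call(rbind, steps) else
    data.frame(step = integer(), species = character(), X = numeric(),
               ST = numeric(), P = numeric(), settled = logical(),
               S = numeric(), A = numeric(), C = numeric(), NODF = numeric())
  structure(list(sequence = sequence, per_step = per_step,
                 baseline = baseline, model = model, strategy = strategy,
                 failed = failed),
            class = "restoration_run")
}

#' @export
print.restoration_run <- function(x, ...) {
  cat(sprintf("<restoration_run: %s model, %d reintroductions%s>\n",
              x$model, length(x$sequence),
              if (x$failed) ", FAILED" else ""))
  invisible(x)
}
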