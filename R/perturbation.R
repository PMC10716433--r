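#' Species-removal perturbation scenario
#'
#' Three sampling scenarios define which species are lost in a
#' perturbation: `random` (uniform), `generalist_preferred` (selection
#' probability proportional to current degree) and `specialist_preferred`
#' (probability inversely proportional to current degree). The standard
#' experiment applies each at removal fractions 0.3, 0.6, 0.9.
#'
#' @param kind Sampling scenario.
#' @param fraction_removed Fraction of the target pool removed, in (0, 1).
#' @param target_side Pool of candidate species: `"both"` (all nodes,
#'   the default), `"plants"` or `"pollinators"`.
#' @param seed Integer seed for the sequential draws.
#' @return A list of class `perturbation_scenario`.
#' @export
perturbation_scenario <- function(kind = c("random", "generalist_preferred",
                                           "specialist_preferred"),
                                  fraction_removed,
                                  target_side = c("both", "plants",
                                                  "pollinators"),
                                  seed = 1L) {
  kind <- match.arg(kind)
  target_side <- match.arg(target_side)
  stopifnot(fraction_removed > 0, fraction_removed < 1)
  structure(list(kind = kind, fraction_removed = fraction_removed,
                 target_side = target_side, seed = as.integer(seed)),
            class = "perturbation_scenario")
}

#' Sample the primary extinction list
#'
#' Draws `round(fraction * pool size)` species sequentially without
#' replacement (rounding half away from zero, so 20% of 31 plants is 6).
#' After each draw the drawn species is deleted and degrees are recomputed
#' on the remaining network, so selection weights track the shrinking
#' community; `frozen_weights = TRUE` keeps the intact-network degrees
#' throughout instead. Candidates whose degree has dropped to zero are
#' passed over while any positive-degree candidate remains (they are
#' already doomed as secondary extinctions).
#'
#' @param net The intact [bipartite_network()].
#' @param scenario A [perturbation_scenario()].
#' @param frozen_weights Freeze sampling weights at the intact network.
#' @return Ordered character vector of primary-removed species.
#' @export
sample_primary <- function(net, scenario, frozen_weights = FALSE) {
  pool <- switch(scenario$target_side,
    both = species(net),
    plants = net$plant_labels,
    pollinators = net$pollinator_labels
  )
  if (!length(pool)) stop("empty candidate pool")
  k <- round_half_up(scenario$fraction_removed * length(pool))
  if (k < 1) {
    stop(sprintf("fraction %.3g of %d species removes no species",
                 scenario$fraction_removed, length(pool)))
  }
  deg0 <- degrees(net)
  with_seed(scenario$seed, {
    inc <- net$incidence
    chosen <- character(k)
    remaining <- pool
    for (i in seq_len(k)) {
      deg <- if (frozen_weights) deg0 else
        c(rowSums(inc), colSums(inc))[species(net)]
      d <- deg[remaining]
      cand <- if (any(d > 0)) remaining[d > 0] else remaining
      w <- switch(scenario$kind,
        random = rep(1, length(cand)),
        generalist_preferred = pmax(deg[cand], 1e-12),
        specialist_preferred = 1 / pmax(deg[cand], 1e-12)
      )
      pick <- cand[sample.int(length(cand), 1L, prob = w)]
      chosen[i] <- pick
      remaining <- setdiff(remaining, pick)
      if (pick %in% net$plant_labels) {
        inc[pick, ] <- 0
      } else {
        inc[, pick] <- 0
      }
    }
    chosen
  })
}

#' Obligate-mutualism extinction cascade
#'
#' Removes the listed species, then iterates the obligate-mutualism rule to
#' a fixed point: any species left without a single mutualistic partner
#' goes secondarily extinct and is removed in turn. The surviving set is
#' independent of the order in which removals are processed.
#'
#' @param net A [bipartite_network()].
#' @param removed Character vector of species to remove (primary
#'   extinctions).
#' @return A list of class `perturbation_outcome` with `primary_removed`
#'   (ordered as given), `secondary_removed`, and `degraded_net` (possibly
#'   empty, never containing isolated species).
#' @export
cascade <- function(net, removed) {
  unknown <- setdiff(removed, species(net))
  if (length(unknown)) {
    stop("species not in network: ", paste(unknown, collapse = ", "))
  }
  keep_p <- setdiff(net$plant_labels, removed)
  keep_a <- setdiff(net$pollinator_labels, removed)
  inc <- net$incidence[keep_p, keep_a, drop = FALSE]
  secondary <- character()
  repeat {
    dead_p <- rownames(inc)[rowSums(inc) == 0]
    dead_a <- colnames(inc)[colSums(inc) == 0]
    # an empty matrix dimension kills the whole other side
    if (nrow(inc) == 0) dead_a <- colnames(inc)
    if (ncol(inc) == 0) dead_p <- rownames(inc)
    dead <- c(dead_p, dead_a)
    if (!length(dead)) break
    secondary <- c(secondary, dead)
    inc <- inc[setdiff(rownames(inc), dead), setdiff(colnames(inc), dead),
               drop = FALSE]
  }
  degraded <- bipartite_network(inc, rownames(inc), colnames(inc),
                                allow_isolated = TRUE)
  structure(list(primary_removed = removed,
                 secondary_removed = secondary,
                 degraded_net = degraded),
            class = "perturbation_outcome")
}

#' @export
print.perturbation_outcome <- function(x, ...) {
  cat(sprintf("<perturbation_outcome: %d primary + %d secondary extinctions, %d species survive>\n",
              length(x$primary_removed), length(x$secondary_removed),
              length(species(x$degraded_net))))
  invisible(x)
}

#' Apply a perturbation scenario end to end
#'
#' Convenience wrapper: [sample_primary()] then [cascade()].
#'
#' @inheritParams sample_primary
#' @return A `perturbation_outcome`.
#' @export
perturb <- function(net, scenario, frozen_weights = FALSE) {
  cascade(net, sample_primary(net, scenario, frozen_weights))
}
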