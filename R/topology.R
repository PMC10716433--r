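#' Summary attributes of a bipartite network
#'
#' The four structural attributes used throughout the restoration analyses:
#' size `S = n + m`, asymmetry `A = m / n` (pollinators per plant),
#' connectance `C = L / (n * m)`, and NODF nestedness, together with the raw
#' counts.
#'
#' @param net A [bipartite_network()].
#' @return A list of class `network_attributes` with fields `size_S`,
#'   `asymmetry_A`, `connectance_C`, `nestedness_NODF`, `n_plants`,
#'   `m_pollinators`, `L_links`.
#' @export
network_attributes <- function(net) {
  n <- n_plants(net)
  m <- n_pollinators(net)
  L <- n_links(net)
  structure(
    list(
      size_S = n + m,
      asymmetry_A = if (n > 0) m / n else NA_real_,
      connectance_C = if (n > 0 && m > 0) L / (n * m) else NA_real_,
      nestedness_NODF = if (n > 1 && m > 1) nodf(net) else NA_real_,
      n_plants = n, m_pollinators = m, L_links = L
    ),
    class = "network_attributes"
  )
}

#' @export
print.network_attributes <- function(x, ...) {
  cat(sprintf("S = %d (n = %d plants, m = %d pollinators), A = %.3f, C = %.3f, NODF = %.2f, L = %d\n",
              x$size_S, x$n_plants, x$m_pollinators, x$asymmetry_A,
              x$connectance_C, x$nestedness_NODF, x$L_links))
  invisible(x)
}

#' NODF nestedness of a binary incidence matrix
#'
#' Nestedness based on Overlap and Decreasing Fill (Almeida-Neto et al.):
#' the mean, over all row pairs and all column pairs, of the percentage
#' paired overlap of the less-filled member with the more-filled member,
#' where a pair with equal marginal totals contributes 0. Ranges from 0
#' (completely non-nested, e.g. an identity matrix) to 100 (perfectly
#' nested, e.g. a strict staircase). Computation is delegated to
#' [vegan::nestednodf()] with rows/columns sorted by decreasing fill, which
#' realizes exactly this pairwise rule.
#'
#' @param net A [bipartite_network()] or a binary incidence matrix.
#' @return NODF score in `[0, 100]`.
#' @export
nodf <- function(net) {
  mat <- if (inherits(net, "bipartite_network")) net$incidence else as.matrix(net)
  if (nrow(mat) < 2 || ncol(mat) < 2) {
    warning("NODF undefined with a single plant or pollinator; returning 0")
    return(0)
  }
  res <- vegan::nestednodf(mat, order = TRUE, weighted = FALSE)
  unname(res$statistic["NODF"])
}

#' Species centrality on the bipartite graph
#'
#' Degree, closeness, and betweenness computed on the full bipartite graph
#' with both guilds as a single node set. Closeness is the harmonic variant
#' (sum of inverse shortest-path distances; unreachable species contribute
#' 0), which stays finite and comparable on the disconnected graphs that
#' arise mid-cascade. Betweenness is unnormalized shortest-path counting;
#' normalization would not change any species ordering.
#'
#' @param net A [bipartite_network()].
#' @param measure `"degree"`, `"closeness"` or `"betweenness"`.
#' @return A list of class `centrality_scores` with `measure` and named
#'   nonnegative `scores` covering every species.
#' @export
centrality <- function(net, measure = c("degree", "closeness", "betweenness")) {
  measure <- match.arg(measure)
  g <- as_igraph(net)
  scores <- switch(measure,
    degree = igraph::degree(g),
    closeness = igraph::harmonic_centrality(g, normalized = FALSE),
    betweenness = igraph::betweenness(g, directed = FALSE)
  )
  scores <- scores[species(net)]
  structure(list(measure = measure, scores = scores),
            class = "centrality_scores")
}

#' One-mode projection of a bipartite network
#'
#' Projects the bipartite network onto one guild: two plants (or two
#' pollinators) are adjacent iff they share at least one mutualistic
#' partner, with edge weight equal to the number of shared partners. The
#' projection's weighted adjacency is the coupling matrix of the
#' one-dimensional reduced model.
#'
#' @param net A [bipartite_network()].
#' @param side `"plants"` or `"pollinators"`.
#' @return A list of class `projected_network` with `side`, symmetric
#'   zero-diagonal `adjacency`, and `labels`.
#' @export
project <- function(net, side = c("plants", "pollinators")) {
  side <- match.arg(side)
  M <- net$incidence
  adj <- if (side == "plants") tcrossprod(M) else crossprod(M)
  diag(adj) <- 0
  labels <- if (side == "plants") net$plant_labels else net$pollinator_labels
  dimnames(adj) <- list(labels, labels)
  structure(list(side = side, adjacency = adj, labels = labels),
            class = "projected_network")
}

#' Effective nearest-neighbour degree of a projection
#'
#' The single topological control parameter of the one-dimensional reduced
#' model: `beta_eff = <s^2> / <s> = (1' A s) / (1' A 1)` where `s` is the
#' (weighted) degree vector of the projected adjacency `A` -- the mean
#' degree of the neighbour of a randomly chosen edge endpoint. By default
#' the weighted projection (shared-partner counts) is used; `weighted =
#' FALSE` binarizes the adjacency first.
#'
#' @param proj A [project()] result.
#' @param weighted Use shared-partner counts (default) or the binary view.
#' @return Scalar `>= 0`; 0 for an edgeless projection.
#' @export
beta_eff <- function(proj, weighted = TRUE) {
  A <- proj$adjacency
  if (!weighted) A <- (A > 0) + 0
  s <- rowSums(A)
  tot <- sum(s)
  if (tot == 0) return(0)
  sum(s^2) / tot
}
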