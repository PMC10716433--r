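#' Construct a bipartite plant-pollinator interaction network
#'
#' A `bipartite_network` is an unweighted, undirected bipartite species
#' interaction network: plants on the rows, pollinators on the columns, and
#' `incidence[i, j] = 1` iff plant `i` and pollinator `j` interact. This is
#' the object that perturbation, cascade, and restoration act on.
#'
#' @param incidence Numeric matrix with entries in `{0, 1}` (any positive
#'   entry is binarized, since interaction weights are not modelled).
#' @param plant_labels,pollinator_labels Character vectors of species
#'   identifiers; default to the matrix dimnames or `P1..Pn` / `A1..Am`.
#' @param allow_isolated Permit rows/columns with no interactions. Isolated
#'   species are forbidden in a valid standing network (obligate mutualism
#'   removes them), but arise transiently during restoration when a species
#'   is reintroduced before any of its partners.
#'
#' @return An object of class `bipartite_network` with elements `incidence`,
#'   `plant_labels`, `pollinator_labels`.
#' @export
bipartite_network <- function(incidence, plant_labels = NULL,
                              pollinator_labels = NULL,
                              allow_isolated = FALSE) {
  incidence <- as.matrix(incidence)
  if (any(incidence < 0)) {
    stop("incidence matrix contains negative entries; interactions must be 0/1")
  }
  mode(incidence) <- "numeric"
  incidence[incidence > 0] <- 1
  n <- nrow(incidence)
  m <- ncol(incidence)
  plant_labels <- as.character(
    plant_labels %||% rownames(incidence) %||%
      (if (n) paste0("P", seq_len(n)) else character())
  )
  pollinator_labels <- as.character(
    pollinator_labels %||% colnames(incidence) %||%
      (if (m) paste0("A", seq_len(m)) else character())
  )
  if (length(plant_labels) != n || length(pollinator_labels) != m) {
    stop("label lengths do not match incidence dimensions")
  }
  all_labels <- c(plant_labels, pollinator_labels)
  if (anyDuplicated(all_labels)) {
    stop("duplicate species labels: ",
         paste(unique(all_labels[duplicated(all_labels)]), collapse = ", "))
  }
  if (!allow_isolated && n > 0 && m > 0) {
    bad_p <- plant_labels[rowSums(incidence) == 0]
    bad_a <- pollinator_labels[colSums(incidence) == 0]
    if (length(bad_p) || length(bad_a)) {
      stop("isolated species (no mutualistic partners): ",
           paste(c(bad_p, bad_a), collapse = ", "))
    }
  }
  dimnames(incidence) <- list(plant_labels, pollinator_labels)
  structure(
    list(incidence = incidence, plant_labels = plant_labels,
         pollinator_labels = pollinator_labels),
    class = "bipartite_network"
  )
}

#' @export
print.bipartite_network <- function(x, ...) {
  cat(sprintf("<bipartite_network: %d plants x %d pollinators, %d links>\n",
              n_plants(x), n_pollinators(x), n_links(x)))
  invisible(x)
}

#' Species counts and labels
#'
#' @param net A `bipartite_network`.
#' @return Counts (`n_plants`, `n_pollinators`, `n_links`) or a character
#'   vector of all species labels, plants first (`species`).
#' @export
n_plants <- function(net) nrow(net$incidence)

#' @rdname n_plants
#' @export
n_pollinators <- function(net) ncol(net$incidence)

#' @rdname n_plants
#' @export
n_links <- function(net) sum(net$incidence)

#' @rdname n_plants
#' @export
species <- function(net) c(net$plant_labels, net$pollinator_labels)

#' Species degrees on the bipartite graph
#'
#' @param net A `bipartite_network`.
#' @return Named vector of mutualistic-partner counts for every species,
#'   plants first.
#' @export
degrees <- function(net) {
  c(rowSums(net$incidence), colSums(net$incidence))
}

# Induced subnetwork on a set of species labels (links inherited from net).
subnetwork <- function(net, keep, allow_isolated = FALSE) {
  keep_p <- intersect(net$plant_labels, keep)
  keep_a <- intersect(net$pollinator_labels, keep)
  inc <- net$incidence[keep_p, keep_a, drop = FALSE]
  bipartite_network(inc, keep_p, keep_a, allow_isolated = allow_isolated)
}

#' Convert to an igraph bipartite graph
#'
#' Both guilds enter one node set (vertex attribute `type` marks
#' pollinators), which is the graph the centrality measures are defined on.
#'
#' @param net A `bipartite_network`.
#' @return An `igraph` object with vertex names equal to [species()].
#' @export
as_igraph <- function(net) {
  igraph::graph_from_biadjacency_matrix(net$incidence)
}

#' Read a bipartite incidence network from disk
#'
#' Two dialects are supported: `weblife_csv` (incidence matrix CSV as
#' distributed by the Web of Life database: first row pollinator labels,
#' first column plant labels, numeric cells) and `edge_list` (two-column TSV
#' `plant, pollinator` with a header). Positive cell values (e.g. visit
#' counts) are binarized on read: the framework models unweighted networks.
#'
#' @param path File path.
#' @param dialect `"weblife_csv"` or `"edge_list"`.
#' @return A [bipartite_network()].
#' @export
read_incidence <- function(path, dialect = c("weblife_csv", "edge_list")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (dialect == "weblife_csv") {
    df <- utils::read.csv(path, row.names = 1, check.names = FALSE)
    mat <- as.matrix(df)
    if (!is.numeric(mat)) stop("non-numeric cells in incidence CSV: ", path)
    if (any(mat < 0)) stop("negative cell in incidence CSV: ", path)
    net <- bipartite_network(mat, rownames(df), colnames(df))
  } else {
    df <- utils::read.delim(path, colClasses = "character")
    if (ncol(df) < 2L) stop("edge list needs two columns (plant, pollinator)")
    plants <- sort(unique(df[[1L]]))
    polls <- sort(unique(df[[2L]]))
    mat <- matrix(0, length(plants), length(polls),
                  dimnames = list(plants, polls))
    mat[cbind(df[[1L]], df[[2L]])] <- 1
    net <- bipartite_network(mat, plants, polls)
  }
  net
}

#' Write a bipartite incidence network to disk
#'
#' Inverse of [read_incidence()]: output is deterministic (row/column order
#' is the stored label order; edge lists are sorted by plant, then
#' pollinator) and round-trips bit-exactly through the same dialect.
#'
#' @inheritParams read_incidence
#' @param net A `bipartite_network`.
#' @return `path`, invisibly.
#' @export
write_incidence <- function(net, path, dialect = c("weblife_csv", "edge_list")) {
  dialect <- match.arg(dialect)
  if (dialect == "weblife_csv") {
    df <- as.data.frame(net$incidence)
    utils::write.csv(df, path, row.names = TRUE, quote = FALSE)
  } else {
    idx <- which(net$incidence == 1, arr.ind = TRUE)
    df <- data.frame(plant = net$plant_labels[idx[, 1L]],
                     pollinator = net$pollinator_labels[idx[, 2L]],
                     stringsAsFactors = FALSE)
    df <- df[order(df$plant, df$pollinator), , drop = FALSE]
    utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}
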