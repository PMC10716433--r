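test_that("incidence files round-trip through both dialects", {
  net <- random_test_network(5, 7, C = 0.4, seed = 11)
  for (dialect in c("weblife_csv", "edge_list")) {
    path <- withr::local_tempfile(fileext = ".csv")
    write_incidence(net, path, dialect)
    back <- read_incidence(path, dialect)
    expect_identical(back$incidence, net$incidence)
    expect_identical(species(back), species(net))
    # deterministic output: two writes are byte-identical
    path2 <- withr::local_tempfile(fileext = ".csv")
    write_incidence(net, path2, dialect)
    expect_identical(readLines(path), readLines(path2))
  }
  # edge_list has one data row per link
  path <- withr::local_tempfile(fileext = ".tsv")
  m <- matrix(c(1, 0, 1, 1), 2, 2)
  write_incidence(bipartite_network(m), path, "edge_list")
  expect_equal(length(readLines(path)) - 1L, 3L)
})

test_that("reading binarizes weights and rejects malformed files", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(",A1,A2", "P1,3,0", "P2,1,7"), path)
  net <- read_incidence(path, "weblife_csv")
  expect_equal(unname(net$incidence), matrix(c(1, 1, 0, 1), 2, 2))
  expect_equal(n_links(net), 3)

  writeLines(c(",A1,A2", "P1,-1,1", "P2,1,1"), path)
  expect_error(read_incidence(path, "weblife_csv"), "negative")

  writeLines(c(",A1,A2", "P1,0,0", "P2,1,1"), path)
  expect_error(read_incidence(path, "weblife_csv"), "P1")
})

test_that("network construction enforces the invariants", {
  expect_error(bipartite_network(matrix(-1, 1, 1)), "negative")
  expect_error(bipartite_network(matrix(1, 2, 2), c("X", "X"), c("A", "B")),
               "duplicate")
  expect_error(bipartite_network(matrix(c(1, 0, 1, 0), 2, 2)), "isolated")
  # a 2x2 all-ones CSV-style matrix: complete bipartite
  net <- bipartite_network(matrix(1, 2, 2))
  expect_equal(c(n_plants(net), n_pollinators(net), n_links(net)), c(2, 2, 4))
})

test_that("attributes follow the S, A, C definitions exactly", {
  m <- matrix(0, 2, 3, dimnames = list(c("p1", "p2"), c("a1", "a2", "a3")))
  m[1, 1] <- m[1, 2] <- m[2, 3] <- 1
  at <- network_attributes(bipartite_network(m))
  expect_equal(at$size_S, 5)
  expect_equal(at$asymmetry_A, 1.5)
  expect_equal(at$connectance_C, 0.5)

  expect_equal(network_attributes(bipartite_network(matrix(1, 4, 4)))$connectance_C, 1)

  set.seed(23)
  for (seed in 1:20) {
    net <- random_test_network(sample(3:8, 1), sample(3:8, 1),
                               C = runif(1, 0.3, 0.7), seed = seed)
    at <- network_attributes(net)
    expect_identical(at$size_S, at$n_plants + at$m_pollinators)
    expect_equal(at$connectance_C * at$n_plants * at$m_pollinators,
                 at$L_links)
  }
})

test_that("NODF matches calibration matrices and the brute-force oracle", {
  expect_equal(nodf(staircase_matrix(4)), 100)
  expect_equal(nodf(diag(4)), 0)
  expect_warning(v <- nodf(matrix(1, 1, 3)), "single")
  expect_equal(v, 0)

  set.seed(42)
  for (k in 1:200) {
    M <- random_binary_matrix(sample(2:6, 1), sample(2:6, 1), runif(1, .2, .8))
    if (sum(M) == 0) next
    expect_equal(nodf(M), nodf_oracle(M), tolerance = 1e-12)
  }
})

test_that("centralities behave on star and path graphs", {
  # plant hub linked to 4 pollinators
  star <- bipartite_network(matrix(1, 1, 4), "hub", paste0("a", 1:4))
  deg <- centrality(star, "degree")$scores
  expect_equal(unname(deg["hub"]), 4)
  expect_true(all(deg[paste0("a", 1:4)] == 1))
  cl <- centrality(star, "closeness")$scores
  expect_gt(cl[["hub"]], cl[["a1"]])

  # bipartite path p1 - a1 - p2: a1 bridges
  path <- bipartite_network(matrix(c(1, 1), 2, 1), c("p1", "p2"), "a1")
  bt <- centrality(path, "betweenness")$scores
  expect_gt(bt[["a1"]], bt[["p1"]])
  expect_gt(bt[["a1"]], bt[["p2"]])

  expect_error(centrality(star, "pagerank"))
})

test_that("degree centrality equals incidence margins on any network", {
  for (seed in 1:10) {
    net <- random_test_network(6, 9, C = 0.35, seed = seed)
    expect_equal(centrality(net, "degree")$scores, degrees(net))
  }
})

test_that("harmonic closeness stays finite on disconnected graphs", {
  # two separate plant-pollinator pairs
  m <- matrix(c(1, 0, 0, 1), 2, 2)
  net <- bipartite_network(m)
  cl <- centrality(net, "closeness")$scores
  expect_true(all(is.finite(cl)))
  expect_true(all(cl > 0))
})

test_that("one-mode projection counts shared partners", {
  # one plant linked to a, b, c: pollinator projection is a triangle
  net <- bipartite_network(matrix(1, 1, 3), "p", c("a", "b", "c"))
  pr <- project(net, "pollinators")
  expect_true(all(pr$adjacency[upper.tri(pr$adjacency)] == 1))
  expect_true(all(diag(pr$adjacency) == 0))

  # two plants with disjoint pollinator sets: no plant-plant edge
  m <- matrix(c(1, 0, 1, 0, 0, 1), 2, 3)
  pr <- project(bipartite_network(m), "plants")
  expect_equal(sum(pr$adjacency), 0)

  # two plants sharing 2 pollinators: edge weight 2
  m <- matrix(1, 2, 2)
  pr <- project(bipartite_network(m), "plants")
  expect_equal(pr$adjacency[1, 2], 2)
})

test_that("beta_eff equals the nearest-neighbour mean degree", {
  # unweighted star: hub degree 3, leaves 1 -> (9+1+1+1)/(3+1+1+1) = 2
  A <- matrix(0, 4, 4)
  A[1, 2:4] <- A[2:4, 1] <- 1
  star <- structure(list(side = "plants", adjacency = A,
                         labels = paste0("p", 1:4)),
                    class = "projected_network")
  expect_equal(beta_eff(star, weighted = FALSE), 2)

  # k-regular projection: beta_eff = k (ring of 5, k = 2)
  R <- matrix(0, 5, 5)
  for (i in 1:5) {
    R[i, i %% 5 + 1] <- 1
    R[i %% 5 + 1, i] <- 1
  }
  ring <- structure(list(side = "plants", adjacency = R,
                         labels = paste0("p", 1:5)),
                    class = "projected_network")
  expect_equal(beta_eff(ring), 2)

  empty <- structure(list(side = "plants", adjacency = matrix(0, 3, 3),
                          labels = paste0("p", 1:3)),
                     class = "projected_network")
  expect_equal(beta_eff(empty), 0)
})

test_that("projection and beta_eff are invariant to species relabeling", {
  set.seed(17)
  net <- random_test_network(6, 8, C = 0.4, bias = 1, seed = 3)
  be <- beta_eff(project(net, "plants"))
  perm_p <- sample(n_plants(net))
  perm_a <- sample(n_pollinators(net))
  shuffled <- bipartite_network(net$incidence[perm_p, perm_a],
                                net$plant_labels[perm_p],
                                net$pollinator_labels[perm_a])
  expect_equal(beta_eff(project(shuffled, "plants")), be)
})

test_that("degree and betweenness are strongly rank-correlated on heterogeneous networks", {
  rhos <- vapply(1:5, function(seed) {
    net <- random_test_network(12, 18, C = 0.25, bias = 2, seed = seed)
    stats::cor(centrality(net, "degree")$scores,
               centrality(net, "betweenness")$scores,
               method = "spearman")
  }, numeric(1))
  expect_gt(mean(rhos), 0.7)
})
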