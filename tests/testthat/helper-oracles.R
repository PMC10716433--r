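# Independent oracles and fixture builders shared across the test files.

# Brute-force NODF: enumerate all row pairs and column pairs, credit the
# percentage paired overlap only under strictly decreasing marginal totals.
nodf_oracle <- function(M) {
  M <- as.matrix(M)
  score_pairs <- function(vecs) {
    fills <- vapply(vecs, sum, numeric(1))
    total <- 0
    npair <- 0L
    for (i in seq_len(length(vecs) - 1L)) {
      for (j in (i + 1L):length(vecs)) {
        npair <- npair + 1L
        hi <- if (fills[i] >= fills[j]) i else j
        lo <- if (fills[i] >= fills[j]) j else i
        if (fills[hi] > fills[lo] && fills[lo] > 0) {
          total <- total + 100 * sum(vecs[[hi]] * vecs[[lo]]) / fills[lo]
        }
      }
    }
    c(total, npair)
  }
  r <- score_pairs(asplit(M, 1))
  c_ <- score_pairs(asplit(M, 2))
  (r[1] + c_[1]) / (r[2] + c_[2])
}

# Naive extinction-cascade fixpoint: recompute all degrees from scratch
# every round, delete every zero-degree species, repeat.
cascade_oracle <- function(net, removed) {
  keep_p <- setdiff(net$plant_labels, removed)
  keep_a <- setdiff(net$pollinator_labels, removed)
  repeat {
    inc <- net$incidence[keep_p, keep_a, drop = FALSE]
    dp <- keep_p[rowSums(inc) == 0 | ncol(inc) == 0]
    da <- keep_a[colSums(inc) == 0 | nrow(inc) == 0]
    if (!length(dp) && !length(da)) break
    keep_p <- setdiff(keep_p, dp)
    keep_a <- setdiff(keep_a, da)
  }
  sort(c(keep_p, keep_a))
}

# Brute-force two-sample KS statistic: evaluate both ECDFs on a dense set
# of candidate points and take the max absolute difference.
ks_oracle <- function(a, b) {
  pts <- sort(c(a, b))
  max(abs(vapply(pts, function(x) mean(a <= x) - mean(b <= x), numeric(1))))
}

# 5x5 strict staircase: row i has ones in columns 1..(6-i); perfectly
# nested with all marginal totals distinct.
staircase_matrix <- function(k = 5) {
  outer(seq_len(k), seq_len(k), function(i, j) as.numeric(j <= k + 1 - i))
}

# Small random valid network (no isolates) for property loops.
random_test_network <- function(n, m, C = 0.4, bias = 0, seed = 1) {
  generate_network(generator_config(n, m, C, attachment_bias = bias,
                                    seed = seed))
}

# Random binary matrix (may contain empty rows/columns; NODF oracle only).
random_binary_matrix <- function(n, m, p = 0.5) {
  matrix(rbinom(n * m, 1, p), n, m)
}

# Induced subnetwork built independently of the package internals.
subnet_for_test <- function(net, keep) {
  kp <- intersect(net$plant_labels, keep)
  ka <- intersect(net$pollinator_labels, keep)
  bipartite_network(net$incidence[kp, ka, drop = FALSE], kp, ka,
                    allow_isolated = TRUE)
}
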