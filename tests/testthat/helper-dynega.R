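# Shared fixtures and cached simulation runs for the test suite.

# A small deterministic weighted network: two 5-cliques joined by one weak
# bridge edge (within-weight 0.8, bridge 0.05).
two_clique_network <- function(within = 0.8, bridge = 0.05) {
  W <- matrix(0, 10, 10)
  for (block in list(1:5, 6:10)) {
    W[block, block] <- within
  }
  diag(W) <- 0
  W[5, 6] <- W[6, 5] <- bridge
  W
}

# Weighted Newman-Girvan modularity computed from first principles (used as
# an independent check on community solutions).
modularity_by_hand <- function(W, membership) {
  W <- abs(W)
  m2 <- sum(W) # 2m
  k <- rowSums(W)
  q <- 0
  for (i in seq_len(nrow(W))) {
    for (j in seq_len(ncol(W))) {
      if (membership[i] == membership[j]) {
        q <- q + W[i, j] - k[i] * k[j] / m2
      }
    }
  }
  q / m2
}

# Cache for the embedding-dimension sub-study shared by several acceptance
# checks (one full run, reused).
.dynega_test_cache <- new.env(parent = emptyenv())

substudy_records <- function() {
  if (is.null(.dynega_test_cache$substudy)) {
    conds <- mc_conditions(t_points = 100, loading = c(0.40, 0.55, 0.70, 1),
                           vars_per_topic = 5, error_sd = 0.15,
                           n_embed = c(3, 5, 7, 9))
    .dynega_test_cache$substudy <-
      run_monte_carlo(conds, reps = 25, seed = 2024)
  }
  .dynega_test_cache$substudy
}
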