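#' Walktrap topic partition of a weighted network
#'
#' Clusters the nodes of a weighted network with the Pons-Latapy Walktrap
#' algorithm (random walks of `steps` steps; merge-tree cut by maximum
#' weighted modularity). Random-walk transition probabilities must be
#' nonnegative, so absolute edge weights are used. Each connected component
#' is clustered separately and the labels are made globally contiguous;
#' isolated nodes become singleton communities.
#'
#' @param net A `dynega_network`, or a symmetric weight matrix.
#' @param steps Length of the random walks (default 4).
#'
#' @return An integer membership vector (labels `1..N_F`) with the number of
#'   topics in `attr(, "n_topics")`.
#' @export
walktrap_partition <- function(net, steps = 4) {
  W <- if (inherits(net, "dynega_network")) net$weights else as.matrix(net)
  p <- ncol(W)
  stopifnot(p >= 1, isTRUE(all.equal(W, t(W), tolerance = 1e-8)))
  g <- igraph::graph_from_adjacency_matrix(abs(W), mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  if (igraph::ecount(g) == 0) {
    warning("empty network: every node assigned its own community")
    membership <- seq_len(p)
  } else {
    comp <- igraph::components(g)
    membership <- integer(p)
    next_label <- 0L
    for (k in seq_len(comp$no)) {
      nodes <- which(comp$membership == k)
      if (length(nodes) == 1L) {
        membership[nodes] <- next_label + 1L
        next_label <- next_label + 1L
      } else {
        sub <- igraph::induced_subgraph(g, nodes)
        wt <- igraph::cluster_walktrap(sub, weights = igraph::E(sub)$weight,
                                       steps = steps)
        m <- igraph::membership(wt)
        membership[nodes] <- next_label + as.integer(m)
        next_label <- next_label + max(as.integer(m))
      }
    }
  }
  # contiguous labels in order of first appearance is not required; keep 1..N_F
  membership <- match(membership, sort(unique(membership)))
  names(membership) <- colnames(W)
  attr(membership, "n_topics") <- length(unique(membership))
  membership
}
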