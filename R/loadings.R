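#' Node strength
#'
#' Absolute row sums of a network's weight matrix:
#' \eqn{S_i = \sum_j |W_{ij}|}.
#'
#' @param net A `dynega_network` or weight matrix.
#' @return Named numeric vector of strengths.
#' @export
node_strength <- function(net) {
  W <- if (inherits(net, "dynega_network")) net$weights else as.matrix(net)
  rowSums(abs(W))
}

#' Network loadings
#'
#' Splits each node's strength by topic: the unstandardized loading of node
#' \eqn{i} on topic \eqn{c} is \eqn{\ell_{ic} = \sum_{j \in c} |w_{ij}|}, and
#' the standardized loading is
#' \eqn{\aleph_{ic} = \ell_{ic} / \sqrt{\sum_{i \in c} \ell_{ic}}} (division
#' by the square root of the summed loadings of the nodes belonging to topic
#' \eqn{c}). Loadings are computed on absolute weights; the sign of
#' \eqn{\sum_{j \in c} w_{ij}} is applied afterwards, mirroring the sign
#' convention of factor loadings. Nodes with no edges into a topic have an
#' exact zero loading there.
#'
#' @param net A `dynega_network` or symmetric weight matrix.
#' @param membership Integer topic membership vector (one entry per node).
#'
#' @return A list of class `dynega_loadings` with elements `unstd` and `std`
#'   (both p x N_F matrices) and `membership`.
#' @export
network_loadings <- function(net, membership) {
  W <- if (inherits(net, "dynega_network")) net$weights else as.matrix(net)
  p <- ncol(W)
  stopifnot(length(membership) == p)
  topics <- sort(unique(membership))
  if (any(tabulate(match(membership, topics)) == 0)) stop("empty topic")
  unstd <- sapply(topics, function(k) {
    rowSums(abs(W[, membership == k, drop = FALSE]))
  })
  signs <- sapply(topics, function(k) {
    s <- sign(rowSums(W[, membership == k, drop = FALSE]))
    ifelse(s == 0, 1, s)
  })
  unstd <- matrix(unstd, nrow = p)
  denom <- sqrt(vapply(seq_along(topics), function(j) {
    sum(unstd[membership == topics[j], j])
  }, numeric(1)))
  denom[denom == 0] <- 1
  std <- sweep(unstd, 2, denom, "/") * signs
  nm <- colnames(W)
  if (is.null(nm)) nm <- paste0("V", seq_len(p))
  dimnames(unstd) <- dimnames(std) <- list(nm, paste0("topic", topics))
  structure(list(unstd = unstd, std = std, membership = membership),
            class = "dynega_loadings")
}

#' @method print dynega_loadings
#' @export
print.dynega_loadings <- function(x, digits = 3, ...) {
  cat("Standardized network loadings (", nrow(x$std), " nodes, ",
      ncol(x$std), " topics):\n", sep = "")
  print(round(x$std, digits))
  invisible(x)
}

#' Network topic scores
#'
#' Computes a score series per topic as a weighted composite of the observed
#' variables with nonzero standardized loadings on that topic. Weights are
#' the standardized loadings divided by each variable's sample standard
#' deviation, renormalized to proportions within the topic, so the scores are
#' invariant to per-variable linear rescaling of the data.
#'
#' @param data Observed T x p matrix (columns aligned with loading rows by
#'   name when available, otherwise by position).
#' @param loadings A `dynega_loadings` object.
#'
#' @return A T x N_F matrix of topic scores.
#' @export
network_scores <- function(data, loadings) {
  stopifnot(inherits(loadings, "dynega_loadings"))
  data <- as.matrix(data)
  std <- loadings$std
  if (!is.null(colnames(data)) && all(rownames(std) %in% colnames(data))) {
    data <- data[, rownames(std), drop = FALSE]
  }
  stopifnot(ncol(data) == nrow(std))
  sds <- apply(data, 2, stats::sd)
  scores <- matrix(NA_real_, nrow(data), ncol(std),
                   dimnames = list(NULL, colnames(std)))
  for (j in seq_len(ncol(std))) {
    nz <- which(std[, j] != 0)
    if (length(nz) == 0) stop("topic ", j, " has all-zero loadings")
    if (any(sds[nz] == 0)) stop("zero-variance variable with nonzero loading")
    w <- std[nz, j] / sds[nz]
    w <- w / sum(w)
    scores[, j] <- data[, nz, drop = FALSE] %*% w
  }
  scores
}
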