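#' Pearson correlation matrix of derivative columns
#'
#' Thin wrapper over [stats::cor()] that validates its input the way the
#' network estimators expect it: at least three rows, no zero-variance
#' columns, and a symmetric result with unit diagonal.
#'
#' @param x Numeric matrix (rows = observations, columns = variables).
#' @return A symmetric correlation matrix.
#' @export
pearson_corr <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 3) stop("need at least 3 rows to correlate")
  s <- apply(x, 2, stats::sd)
  if (any(s == 0 | !is.finite(s))) {
    stop("zero-variance column(s): ",
         paste(colnames(x)[s == 0 | !is.finite(s)], collapse = ", "))
  }
  R <- stats::cor(x)
  (R + t(R)) / 2
}

new_network <- function(W, method, n_obs, gamma = NA_real_, lambda = NA_real_) {
  diag(W) <- 0
  W <- (W + t(W)) / 2
  structure(list(weights = W, method = method, n_obs = n_obs,
                 gamma = gamma, lambda = lambda),
            class = "dynega_network")
}

#' @method print dynega_network
#' @export
print.dynega_network <- function(x, ...) {
  p <- ncol(x$weights)
  ne <- sum(abs(x$weights[upper.tri(x$weights)]) > 0)
  cat("Weighted network (", x$method, "): ", p, " nodes, ", ne, " edges\n",
      sep = "")
  if (!is.na(x$gamma)) cat("EBIC gamma used:", x$gamma, "\n")
  invisible(x)
}

# Gaussian log-likelihood part of EBIC for a precision matrix Theta given a
# correlation matrix R and sample size n.
ebic_score <- function(R, theta, n_obs, gamma) {
  p <- ncol(R)
  E <- sum(abs(theta[upper.tri(theta)]) > 1e-10)
  ll <- (n_obs / 2) * (determinant(theta, logarithm = TRUE)$modulus[1] -
                         sum(R * theta))
  -2 * ll + E * log(n_obs) + 4 * gamma * E * log(p)
}

# Precision matrix -> partial correlation network: -theta_ij / sqrt(ii * jj)
precision_to_pcor <- function(theta) {
  d <- sqrt(diag(theta))
  P <- -theta / tcrossprod(d)
  diag(P) <- 0
  P[abs(P) < 1e-10] <- 0
  (P + t(P)) / 2
}

#' EBIC-tuned graphical LASSO network
#'
#' Estimates a sparse Gaussian graphical model over a path of `n_lambda`
#' penalty values (log-spaced from the largest absolute off-diagonal
#' correlation down to `lambda_min_ratio` times it) and returns the partial
#' correlation network of the model minimizing the extended Bayesian
#' information criterion
#' \deqn{EBIC = -2\,l(\Theta) + E \log n + 4 \gamma E \log p,}
#' where \eqn{E} is the number of edges. Selection starts at \eqn{\gamma} =
#' 0.5; if the chosen network leaves any node with no edges, the next value of
#' `gamma_schedule` is tried (0.25, then 0, at which point EBIC equals BIC).
#'
#' @param R Correlation matrix (symmetric, unit diagonal).
#' @param n_obs Number of observations behind `R`.
#' @param n_lambda Length of the penalty path.
#' @param lambda_min_ratio Ratio of the smallest to the largest penalty.
#' @param gamma_schedule Nonincreasing EBIC hyperparameter schedule.
#' @param penalize_diagonal Apply the L1 penalty to the precision diagonal as
#'   well (the reference implementations of this estimator leave it
#'   unpenalized, the default here).
#'
#' @return A `dynega_network` whose weights are partial correlations; the
#'   `gamma` element records the hyperparameter actually used.
#' @export
ebic_glasso <- function(R, n_obs, n_lambda = 100, lambda_min_ratio = 0.1,
                        gamma_schedule = c(0.5, 0.25, 0),
                        penalize_diagonal = FALSE) {
  R <- as.matrix(R)
  p <- ncol(R)
  stopifnot(p >= 2, n_obs > 2, all(diff(gamma_schedule) <= 0),
            all(gamma_schedule >= 0))
  ev_min <- min(eigen(R, symmetric = TRUE, only.values = TRUE)$values)
  if (ev_min < -1e-8) {
    if (ev_min < -0.1) stop("correlation matrix is not positive semidefinite")
    # ridge repair for slightly non-PSD input
    R <- (R + diag(abs(ev_min) + 1e-8, p)) / (1 + abs(ev_min) + 1e-8)
    warning("correlation matrix ridge-repaired (min eigenvalue ",
            signif(ev_min, 3), ")")
  }
  lmax <- max(abs(R[upper.tri(R)]))
  if (lmax <= 0) lmax <- 1e-4
  lambda <- exp(seq(log(lmax), log(lmax * lambda_min_ratio),
                    length.out = n_lambda))
  thetas <- glasso_path_cpp(R, lambda, penalize_diag = penalize_diagonal)$theta
  nets <- lapply(seq_len(n_lambda), function(l) precision_to_pcor(thetas[, , l]))
  for (g in gamma_schedule) {
    sc <- vapply(seq_len(n_lambda), function(l) {
      ebic_score(R, thetas[, , l], n_obs, g)
    }, numeric(1))
    best <- which.min(sc)
    W <- nets[[best]]
    if (all(rowSums(abs(W)) > 0) || g == gamma_schedule[length(gamma_schedule)]) {
      dimnames(W) <- dimnames(R)
      return(new_network(W, "glasso", n_obs, gamma = g,
                         lambda = lambda[best]))
    }
  }
}

#' Triangulated maximally filtered graph
#'
#' Builds a planar-constructible network of exactly \eqn{3p - 6} edges by the
#' greedy TMFG procedure: seed with the four variables having the highest sum
#' of correlations to all others (a tetrahedron), then repeatedly insert the
#' remaining vertex that maximizes its summed correlation to the three
#' vertices of an existing triangular face, splitting that face in three.
#' Edge weights are the zero-order correlations.
#'
#' @param R Correlation matrix with at least 4 variables.
#' @param n_obs Number of observations behind `R` (metadata only).
#'
#' @return A `dynega_network` with correlation weights and `3p - 6` edges.
#' @export
tmfg <- function(R, n_obs = NA_integer_) {
  R <- as.matrix(R)
  p <- ncol(R)
  if (p < 4) stop("TMFG requires at least 4 variables")
  A <- matrix(0, p, p, dimnames = dimnames(R))

  # seed tetrahedron: top 4 by (signed) sum of correlations, ties by index
  s <- rowSums(R) - diag(R)
  seed <- order(-s, seq_len(p))[1:4]
  for (i in seed) for (j in seed) if (i != j) A[i, j] <- R[i, j]
  faces <- utils::combn(seed, 3, simplify = FALSE)
  remaining <- setdiff(seq_len(p), seed)

  while (length(remaining) > 0) {
    # gain of inserting vertex v into face f = sum of correlations to f
    best_gain <- -Inf; best_v <- NA; best_f <- NA
    for (fi in seq_along(faces)) {
      f <- faces[[fi]]
      gains <- rowSums(R[remaining, f, drop = FALSE])
      vi <- which.max(gains) # which.max takes the first (lowest index) on ties
      if (gains[vi] > best_gain) {
        best_gain <- gains[vi]; best_v <- remaining[vi]; best_f <- fi
      }
    }
    f <- faces[[best_f]]
    v <- best_v
    A[v, f] <- R[v, f]
    A[f, v] <- R[f, v]
    faces <- c(faces[-best_f],
               list(c(f[1], f[2], v), c(f[1], f[3], v), c(f[2], f[3], v)))
    remaining <- setdiff(remaining, v)
  }
  new_network(A, "tmfg", n_obs)
}

#' Write a network as an edge list
#'
#' @param net A `dynega_network`.
#' @param file Path of the TSV file to write (`i`, `j`, `weight`).
#' @return Invisibly, the edge-list data frame.
#' @export
write_network <- function(net, file) {
  W <- net$weights
  idx <- which(upper.tri(W) & abs(W) > 0, arr.ind = TRUE)
  nm <- colnames(W)
  if (is.null(nm)) nm <- as.character(seq_len(ncol(W)))
  edges <- data.frame(i = nm[idx[, 1]], j = nm[idx[, 2]],
                      weight = W[idx], stringsAsFactors = FALSE)
  utils::write.table(edges, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(edges)
}
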