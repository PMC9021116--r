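#' Specify a direct autoregressive factor score (DAFS) simulation
#'
#' Bundles the parameters of the DAFS data-generating process: latent topic
#' scores follow a first-order vector autoregression
#' \eqn{f_t = B f_{t-1} + v_t} with shock covariance \eqn{\Sigma}, and the
#' observed indicators are \eqn{u_t = \Lambda f_t + e_t} with block-diagonal
#' loading matrix \eqn{\Lambda} (constant loading within a topic's block) and
#' measurement error \eqn{e_t \sim N(0, \sigma_e^2 I)}. Defaults follow the
#' stationary regime commonly used in dimensionality-recovery studies:
#' autoregression 0.8, no cross-regression, shock variance 0.36 with
#' covariance 0.18, burn-in of 1000 steps.
#'
#' @param n_topics Number of latent topics (factors).
#' @param vars_per_topic Indicators per topic (5 or 10 in the study grid).
#' @param loading Common loading of each indicator on its topic.
#' @param t_points Length of the retained series (50, 100 or 200 in the grid).
#' @param error_sd Measurement error standard deviation (0.15 or 0.25).
#' @param ar Autoregressive coefficient (diagonal of B).
#' @param cross Cross-regressive coefficient (off-diagonal of B).
#' @param shock_var,shock_cov Diagonal and off-diagonal of \eqn{\Sigma}.
#' @param burn_in Number of initial steps discarded.
#' @param data_type `"continuous"` or `"categorical"` (4 ordered categories).
#' @param thresholds Cut points for [categorize4()] when
#'   `data_type = "categorical"`.
#'
#' @return A list of class `dafs_spec`.
#' @export
dafs_spec <- function(n_topics = 3, vars_per_topic = 5, loading = 0.70,
                      t_points = 100, error_sd = 0.15, ar = 0.8, cross = 0,
                      shock_var = 0.36, shock_cov = 0.18, burn_in = 1000,
                      data_type = c("continuous", "categorical"),
                      thresholds = c(-1.5, 0, 1.5)) {
  data_type <- match.arg(data_type)
  stopifnot(n_topics >= 1, vars_per_topic >= 1, t_points >= 2,
            error_sd >= 0, burn_in >= 0, all(diff(thresholds) > 0))
  sigma <- matrix(shock_cov, n_topics, n_topics)
  diag(sigma) <- shock_var
  if (min(eigen(sigma, symmetric = TRUE, only.values = TRUE)$values) <= 0) {
    stop("shock covariance matrix is not positive definite")
  }
  structure(list(n_topics = n_topics, vars_per_topic = vars_per_topic,
                 loading = loading, t_points = t_points, error_sd = error_sd,
                 ar = ar, cross = cross, sigma = sigma, burn_in = burn_in,
                 data_type = data_type, thresholds = thresholds),
            class = "dafs_spec")
}

#' Simulate one individual's data from the DAFS model
#'
#' Iterates the latent VAR(1) for `burn_in + t_points` steps starting from
#' zero, discards the burn-in, and maps the retained factor scores to
#' observed indicators through the block-diagonal loading matrix plus
#' independent Gaussian measurement error. With `data_type = "categorical"`
#' the observed variables are then discretized into 4 ordered categories.
#'
#' @param spec A [dafs_spec()].
#' @param seed Optional integer seed for reproducibility.
#'
#' @return A list of class `dafs_sim`: `observed` (T x p matrix),
#'   `true_scores` (T x q), `membership` (true variable-to-topic assignment),
#'   and the `spec`.
#' @export
simulate_dafs <- function(spec = dafs_spec(), seed = NULL) {
  stopifnot(inherits(spec, "dafs_spec"))
  if (!is.null(seed)) set.seed(seed)
  q <- spec$n_topics
  p <- q * spec$vars_per_topic
  total <- spec$burn_in + spec$t_points
  B <- matrix(spec$cross, q, q)
  diag(B) <- spec$ar
  # multivariate normal shocks via Cholesky
  cs <- chol(spec$sigma)
  V <- matrix(stats::rnorm(total * q), total, q) %*% cs
  f <- matrix(0, total, q)
  f[1, ] <- V[1, ]
  for (t in 2:total) f[t, ] <- B %*% f[t - 1, ] + V[t, ]
  f <- f[(spec$burn_in + 1):total, , drop = FALSE]
  membership <- rep(seq_len(q), each = spec$vars_per_topic)
  lambda <- matrix(0, p, q)
  lambda[cbind(seq_len(p), membership)] <- spec$loading
  E <- matrix(stats::rnorm(spec$t_points * p, sd = spec$error_sd),
              spec$t_points, p)
  u <- f %*% t(lambda) + E
  colnames(u) <- paste0("V", seq_len(p))
  if (spec$data_type == "categorical") {
    u <- categorize4(u, thresholds = spec$thresholds)
  }
  structure(list(observed = u, true_scores = f, membership = membership,
                 spec = spec),
            class = "dafs_sim")
}

#' @method print dafs_sim
#' @export
print.dafs_sim <- function(x, ...) {
  cat("DAFS simulation:", nrow(x$observed), "time points,",
      ncol(x$observed), "variables,", x$spec$n_topics, "topics (",
      x$spec$data_type, ")\n")
  invisible(x)
}

#' Discretize continuous data into 4 ordered categories
#'
#' Standardizes each column and bins the values at the given thresholds,
#' producing integer categories 1-4. The default symmetric cuts at
#' (-1.5, 0, 1.5) yield roughly 7/43/43/7 percent category frequencies for
#' Gaussian data.
#'
#' @param x Numeric matrix.
#' @param thresholds Strictly increasing vector of 3 cut points on the
#'   standardized scale.
#' @return Integer matrix of the same shape with entries in 1..4.
#' @export
categorize4 <- function(x, thresholds = c(-1.5, 0, 1.5)) {
  stopifnot(length(thresholds) == 3, all(diff(thresholds) > 0))
  x <- as.matrix(x)
  out <- apply(x, 2, function(col) {
    s <- stats::sd(col)
    z <- if (s > 0) (col - mean(col)) / s else col * 0
    findInterval(z, thresholds) + 1L
  })
  dimnames(out) <- dimnames(x)
  out
}
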