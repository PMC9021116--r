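test_that("pearson_corr matches the textbook covariance formula", {
  expect_equal(pearson_corr(cbind(a = 1:5, b = 1:5))["a", "b"], 1)
  expect_equal(pearson_corr(cbind(a = 1:5, b = -(1:5)))["a", "b"], -1)
  set.seed(3)
  x <- matrix(rnorm(30), 10, 3)
  R <- pearson_corr(x)
  # hand-rolled covariance / sigma oracle
  for (i in 1:3) {
    for (j in 1:3) {
      cij <- sum((x[, i] - mean(x[, i])) * (x[, j] - mean(x[, j]))) / 9
      expect_equal(R[i, j], cij / (sd(x[, i]) * sd(x[, j])))
    }
  }
  expect_error(pearson_corr(cbind(1:5, rep(2, 5))), "zero-variance")
  expect_error(pearson_corr(matrix(rnorm(4), 2, 2)), "3 rows")
})

# Constrained Gaussian MLE for a given sparsity pattern by direct likelihood
# maximization over the free precision entries (independent oracle for the
# EBIC model search at p = 3).
fit_pattern_mle <- function(R, pattern) {
  p <- ncol(R)
  free <- which(upper.tri(R) & pattern, arr.ind = TRUE)
  build_theta <- function(par) {
    theta <- diag(exp(par[1:p]))
    if (nrow(free) > 0) {
      off <- par[-(1:p)]
      for (k in seq_len(nrow(free))) {
        theta[free[k, 1], free[k, 2]] <- off[k]
        theta[free[k, 2], free[k, 1]] <- off[k]
      }
    }
    theta
  }
  negll <- function(par) {
    theta <- build_theta(par)
    ev <- eigen(theta, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 1e-10) return(1e10)
    -(sum(log(ev)) - sum(R * theta))
  }
  opt <- optim(c(rep(0, p), rep(0, nrow(free))), negll, method = "BFGS",
               control = list(maxit = 500, reltol = 1e-12))
  list(theta = build_theta(opt$par), value = -opt$value)
}

test_that("EBIC-glasso selection agrees with exhaustive search at p = 3", {
  # identity input -> empty network
  Rid <- diag(3)
  net0 <- ebic_glasso(Rid, n_obs = 200)
  expect_true(all(net0$weights == 0))

  # one strong pair, near-zero elsewhere
  R <- matrix(c(1, 0.8, 0.03,
                0.8, 1, 0.05,
                0.03, 0.05, 1), 3, 3)
  n <- 500
  net <- ebic_glasso(R, n_obs = n)
  est_edges <- which(upper.tri(R) & abs(net$weights) > 1e-8)
  # brute force: all 2^3 sparsity patterns, each scored by EBIC at the MLE
  pairs <- which(upper.tri(R))
  best <- NULL
  for (mask in 0:7) {
    pattern <- matrix(FALSE, 3, 3)
    pattern[pairs] <- bitwAnd(mask, 2^(0:2)) > 0
    pattern <- pattern | t(pattern)
    fit <- fit_pattern_mle(R, pattern)
    E <- sum(pattern[upper.tri(pattern)])
    ebic <- -2 * (n / 2) * fit$value + E * log(n) + 4 * 0.5 * E * log(3)
    if (is.null(best) || ebic < best$ebic) {
      best <- list(ebic = ebic, edges = which(upper.tri(R) & pattern))
    }
  }
  expect_equal(est_edges, best$edges)
  expect_equal(est_edges, which(upper.tri(R))[1]) # the (1,2) edge only
})

test_that("glasso path is monotone in sparsity and EBIC reduces to BIC at gamma 0", {
  set.seed(8)
  x <- matrix(rnorm(400), 100, 4)
  x[, 2] <- x[, 1] + rnorm(100, sd = 0.6)
  R <- pearson_corr(x)
  lambda <- exp(seq(log(0.6), log(0.06), length.out = 25))
  thetas <- dynega:::glasso_path_cpp(R, lambda)$theta
  edges <- vapply(seq_along(lambda), function(l) {
    th <- thetas[, , l]
    sum(abs(th[upper.tri(th)]) > 1e-10)
  }, numeric(1))
  expect_true(all(diff(edges) >= 0)) # lambda decreasing -> density nondecreasing

  # EBIC at gamma = 0 equals BIC (= -2 loglik + E log n) identically
  for (l in c(1, 10, 25)) {
    th <- thetas[, , l]
    E <- sum(abs(th[upper.tri(th)]) > 1e-10)
    ll <- (100 / 2) * (determinant(th, logarithm = TRUE)$modulus[1] -
                         sum(R * th))
    expect_equal(dynega:::ebic_score(R, th, 100, gamma = 0),
                 -2 * ll + E * log(100))
  }
})

test_that("glasso solutions satisfy the stationarity conditions", {
  # KKT check against the penalized likelihood problem itself
  set.seed(12)
  x <- matrix(rnorm(600), 100, 6)
  x[, 2] <- x[, 1] + rnorm(100, sd = 0.5)
  x[, 4] <- x[, 3] + rnorm(100, sd = 0.5)
  R <- pearson_corr(x)
  rho <- 0.1
  th <- dynega:::glasso_path_cpp(R, rho)$theta[, , 1]
  W <- solve(th) # implied covariance estimate
  G <- W - R     # gradient of loglik part
  off <- upper.tri(R)
  active <- abs(th[off]) > 1e-10
  # active entries: gradient equals rho * sign; inactive: |gradient| <= rho
  expect_true(all(abs(G[off][active] -
                        rho * sign(th[off][active])) < 5e-3))
  expect_true(all(abs(G[off][!active]) <= rho + 5e-3))
})

test_that("TMFG builds a 3p-6 edge planar-constructible network", {
  # p = 4: complete graph
  set.seed(4)
  R4 <- pearson_corr(matrix(rnorm(200), 50, 4))
  net4 <- tmfg(R4)
  expect_equal(sum(abs(net4$weights[upper.tri(net4$weights)]) > 0), 6)

  # edge count and connectivity across sizes
  for (p in c(5, 8, 10, 17, 30)) {
    R <- pearson_corr(matrix(rnorm(60 * p), 60, p))
    net <- tmfg(R)
    W <- net$weights
    expect_equal(sum(abs(W[upper.tri(W)]) > 0), 3 * p - 6)
    expect_true(all(rowSums(abs(W)) > 0))
    expect_equal(W, t(W))
    expect_true(all(diag(W) == 0))
    # every vertex outside the seed has degree >= 3
    expect_true(all(colSums(abs(W) > 0) >= 3))
    g <- igraph::graph_from_adjacency_matrix(abs(W) > 0, mode = "undirected")
    expect_equal(igraph::components(g)$no, 1)
  }
  expect_error(tmfg(diag(3)), "at least 4")
})

test_that("TMFG matches a step-by-step re-execution of the greedy rule", {
  set.seed(9)
  R <- pearson_corr(matrix(rnorm(240), 40, 6))
  net <- tmfg(R)

  # independent straight-line trace of the published procedure
  p <- 6
  s <- rowSums(R) - diag(R)
  seed <- order(-s, 1:p)[1:4]
  A <- matrix(0, p, p)
  for (i in seed) for (j in seed) if (i != j) A[i, j] <- R[i, j]
  faces <- utils::combn(seed, 3, simplify = FALSE)
  rest <- setdiff(1:p, seed)
  while (length(rest)) {
    cand <- expand.grid(v = rest, f = seq_along(faces))
    gains <- apply(cand, 1, function(row) {
      sum(R[row[["v"]], faces[[row[["f"]]]]])
    })
    pick <- cand[which.max(gains), ]
    v <- pick$v; f <- faces[[pick$f]]
    A[v, f] <- R[v, f]; A[f, v] <- R[f, v]
    faces <- c(faces[-pick$f], lapply(utils::combn(f, 2, simplify = FALSE),
                                      function(e) c(e, v)))
    rest <- setdiff(rest, v)
  }
  expect_equal(unname(net$weights != 0), A != 0)
  expect_equal(unname(net$weights), A)
})

test_that("glasso separates simulated topics into dense blocks", {
  sim <- simulate_dafs(dafs_spec(loading = 0.70, t_points = 200), seed = 77)
  D <- build_derivatives(sim$observed, n_embed = 5)
  R <- pearson_corr(dynega:::derivative_columns(D, 1))
  net <- ebic_glasso(R, n_obs = nrow(D))
  W <- abs(net$weights)
  same <- outer(sim$membership, sim$membership, "==") & upper.tri(W)
  diff <- outer(sim$membership, sim$membership, "!=") & upper.tri(W)
  # within-topic edges are much denser than between-topic edges
  expect_gt(mean(W[same] > 0), 0.8)
  expect_lt(mean(W[diff] > 0), 0.3)
})

test_that("network edge-list export round-trips", {
  set.seed(19)
  net <- tmfg(pearson_corr(matrix(rnorm(300), 50, 6)))
  f <- tempfile(fileext = ".tsv")
  edges <- write_network(net, f)
  back <- read.delim(f)
  expect_equal(nrow(back), 3 * 6 - 6)
  expect_equal(back$weight, edges$weight)
})
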