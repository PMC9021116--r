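#' Topic-count recovery accuracy
#'
#' Fraction of Monte Carlo replications whose estimated number of topics
#' equals the simulated number.
#'
#' @param estimates Integer vector of estimated topic counts (one per run).
#' @param truth True number of topics (scalar or vector).
#' @return Proportion in `[0, 1]`.
#' @export
topic_accuracy <- function(estimates, truth) {
  stopifnot(length(estimates) >= 1)
  mean(estimates == truth)
}

#' Normalized mutual information between two labelings
#'
#' Mutual information between two partition vectors, normalized by the
#' maximum of the two marginal entropies. Equals 1 for identical partitions
#' (up to label permutation) and 0 for independent ones. Two single-cluster
#' vectors (both entropies zero) are defined to agree perfectly (NMI = 1).
#'
#' @param a,b Label vectors of equal length.
#' @return NMI in `[0, 1]`.
#'
#' @examples
#' nmi(c(1, 1, 1, 1, 1, 2, 2, 2, 2, 2), c(2, 2, 2, 2, 2, 1, 1, 1, 1, 1)) # 1
#' @export
nmi <- function(a, b) {
  if (length(a) != length(b)) stop("label vectors differ in length")
  n <- length(a)
  tab <- unname(table(a, b))
  pj <- rowSums(tab) / n
  pk <- colSums(tab) / n
  h <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
  ha <- h(pj); hb <- h(pk)
  if (ha == 0 && hb == 0) return(1)
  pjk <- tab / n
  mi <- 0
  for (j in seq_along(pj)) {
    for (k in seq_along(pk)) {
      if (pjk[j, k] > 0) {
        mi <- mi + pjk[j, k] * log(pjk[j, k] / (pj[j] * pk[k]))
      }
    }
  }
  as.numeric(mi / max(ha, hb))
}

# Optimal one-to-one column assignment maximizing the total of `gain`
# (rows = true columns, cols = estimated columns). Exhaustive over
# permutations for small problems, greedy otherwise.
match_columns <- function(gain) {
  k <- min(nrow(gain), ncol(gain))
  if (max(nrow(gain), ncol(gain)) <= 7) {
    rows <- seq_len(nrow(gain)); cols <- seq_len(ncol(gain))
    if (nrow(gain) <= ncol(gain)) {
      perms <- perms_of(cols, k)
      best <- -Inf; best_pair <- NULL
      for (i in seq_len(nrow(perms))) {
        tot <- sum(gain[cbind(rows[seq_len(k)], perms[i, ])])
        if (tot > best) { best <- tot; best_pair <- cbind(rows[seq_len(k)], perms[i, ]) }
      }
    } else {
      perms <- perms_of(rows, k)
      best <- -Inf; best_pair <- NULL
      for (i in seq_len(nrow(perms))) {
        tot <- sum(gain[cbind(perms[i, ], cols[seq_len(k)])])
        if (tot > best) { best <- tot; best_pair <- cbind(perms[i, ], cols[seq_len(k)]) }
      }
    }
    return(best_pair)
  }
  # greedy fallback for large numbers of topics
  pairs <- matrix(0L, k, 2)
  g <- gain
  for (i in seq_len(k)) {
    ij <- which(g == max(g), arr.ind = TRUE)[1, ]
    pairs[i, ] <- ij
    g[ij[1], ] <- -Inf
    g[, ij[2]] <- -Inf
  }
  pairs
}

# all ordered k-selections (partial permutations) of v
perms_of <- function(v, k) {
  if (k == 1) return(matrix(v, ncol = 1))
  out <- NULL
  for (i in seq_along(v)) {
    rest <- perms_of(v[-i], k - 1)
    out <- rbind(out, cbind(v[i], rest))
  }
  out
}

#' Recovery of simulated topic scores
#'
#' Correlates estimated topic score series with the simulated factor scores
#' under the optimal one-to-one matching that maximizes total absolute
#' Pearson correlation, and returns the mean matched `|r|`. Sign and column
#' order of the estimated scores are irrelevant by construction.
#'
#' @param estimated T x k matrix of estimated topic scores.
#' @param truth T x q matrix of simulated factor scores.
#' @return Mean absolute correlation over matched pairs, with the number of
#'   unmatched estimated columns in `attr(, "unmatched")`.
#' @export
score_recovery <- function(estimated, truth) {
  estimated <- as.matrix(estimated); truth <- as.matrix(truth)
  stopifnot(nrow(estimated) == nrow(truth))
  r <- abs(stats::cor(truth, estimated))
  r[!is.finite(r)] <- 0
  pairs <- match_columns(r)
  out <- mean(r[pairs])
  attr(out, "unmatched") <- ncol(estimated) - nrow(pairs)
  out
}

#' Condition grid of the topic-recovery simulation study
#'
#' Full factorial over series length, loading magnitude, indicators per
#' topic, measurement error and data type, with three topics throughout —
#' the design under which dynamic EGA's recovery rates are evaluated.
#'
#' @param t_points,loading,vars_per_topic,error_sd,data_type,n_embed Levels
#'   of each factor.
#' @return A data frame with one row per condition.
#' @export
mc_conditions <- function(t_points = c(50, 100, 200),
                          loading = c(0.40, 0.55, 0.70, 1),
                          vars_per_topic = c(5, 10),
                          error_sd = c(0.15, 0.25),
                          data_type = c("continuous", "categorical"),
                          n_embed = 5) {
  expand.grid(t_points = t_points, loading = loading,
              vars_per_topic = vars_per_topic, error_sd = error_sd,
              data_type = data_type, n_embed = n_embed,
              stringsAsFactors = FALSE)
}

#' Run the Monte Carlo topic-recovery study
#'
#' For every condition and replicate, simulates a DAFS dataset, runs the
#' dynamic EGA pipeline with each network method, and records the estimated
#' number of topics, whether it is correct, the NMI between true and
#' estimated variable memberships, the mean matched correlation between true
#' and estimated topic scores, and TEFI. The dataset of a given
#' (data-condition, replicate) pair is seeded independently of `n_embed` and
#' method, so conditions differing only in `n_embed` analyze identical data —
#' which is what embedding-tuning comparisons require.
#'
#' @param conditions Data frame as produced by [mc_conditions()].
#' @param reps Replicates per condition.
#' @param seed Master seed.
#' @param methods Network methods to run on each dataset.
#' @param tau,delta_t,order,steps Pipeline settings (see [dynega()]).
#' @param scores Also compute score recovery (slightly slower).
#' @param ... Further arguments passed to [ebic_glasso()].
#'
#' @return A data frame with one row per (condition, replicate, method).
#' @export
run_monte_carlo <- function(conditions = mc_conditions(), reps = 20,
                            seed = 1, methods = c("glasso", "tmfg"),
                            tau = 1, delta_t = 1, order = 1, steps = 4,
                            scores = FALSE, ...) {
  stopifnot(reps >= 1)
  data_cols <- c("t_points", "loading", "vars_per_topic", "error_sd",
                 "data_type")
  key <- do.call(paste, c(conditions[data_cols], sep = "|"))
  data_id <- match(key, unique(key))
  out <- vector("list", nrow(conditions) * reps)
  row <- 0L
  for (ci in seq_len(nrow(conditions))) {
    cond <- conditions[ci, ]
    spec <- dafs_spec(n_topics = 3, vars_per_topic = cond$vars_per_topic,
                      loading = cond$loading, t_points = cond$t_points,
                      error_sd = cond$error_sd, data_type = cond$data_type)
    for (rep in seq_len(reps)) {
      data_seed <- seed + data_id[ci] * 100000L + rep
      sim <- simulate_dafs(spec, seed = data_seed)
      D <- build_derivatives(sim$observed, n_embed = cond$n_embed, tau = tau,
                             delta_t = delta_t)
      recs <- lapply(methods, function(m) {
        fit <- tryCatch(
          estimate_topics(D, method = m, order = order, steps = steps, ...),
          error = function(e) NULL)
        if (is.null(fit)) {
          return(data.frame(n_topics = NA_integer_, correct = NA,
                            nmi = NA_real_, score_r = NA_real_,
                            tefi = NA_real_))
        }
        member <- align_membership(fit$membership, sim$membership)
        sr <- NA_real_
        if (scores) {
          est <- tryCatch(network_scores(sim$observed, fit$loadings),
                          error = function(e) NULL)
          if (!is.null(est)) sr <- as.numeric(score_recovery(est, sim$true_scores))
        }
        data.frame(n_topics = fit$n_topics,
                   correct = as.integer(fit$n_topics == spec$n_topics),
                   nmi = nmi(member, sim$membership),
                   score_r = sr, tefi = fit$tefi$tefi)
      })
      for (mi in seq_along(methods)) {
        row <- row + 1L
        out[[row]] <- cbind(cond, rep = rep, method = methods[mi],
                            recs[[mi]], row.names = NULL)
      }
    }
  }
  do.call(rbind, out)
}

# Map an estimated membership (possibly over a subset of variables, named)
# back onto the full true-variable vector; dropped variables get a fresh
# label so NMI still penalizes them.
align_membership <- function(membership, truth) {
  p <- length(truth)
  full <- rep(NA_integer_, p)
  nm <- names(membership)
  if (!is.null(nm) && all(grepl("^V[0-9]+$", nm))) {
    idx <- as.integer(sub("^V", "", nm))
    full[idx] <- as.integer(membership)
  } else {
    full[seq_along(membership)] <- as.integer(membership)
  }
  if (anyNA(full)) {
    full[is.na(full)] <- max(full, na.rm = TRUE) + seq_len(sum(is.na(full)))
  }
  full
}

#' Summarize Monte Carlo records by condition and method
#'
#' @param records Output of [run_monte_carlo()].
#' @return A data frame of per-condition-and-method means (accuracy, NMI,
#'   score recovery, TEFI) with replicate counts.
#' @export
summarize_monte_carlo <- function(records) {
  keys <- c("t_points", "loading", "vars_per_topic", "error_sd", "data_type",
            "n_embed", "method")
  agg <- stats::aggregate(
    records[c("correct", "nmi", "score_r", "tefi")],
    by = records[keys],
    FUN = function(v) mean(v, na.rm = TRUE))
  cnt <- stats::aggregate(list(n = records$correct), by = records[keys],
                          FUN = length)
  merge(agg, cnt, by = keys)
}
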