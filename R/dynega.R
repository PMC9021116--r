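#' Dynamic exploratory graph analysis
#'
#' Estimates how many latent topics (or factors) drive one or more
#' multivariate time series. Each variable's series is time-delay embedded
#' and its derivatives are estimated by generalized local linear
#' approximation; a network is then estimated over the Pearson correlations
#' of the chosen derivative order (first derivatives by default) using either
#' the EBIC-tuned graphical LASSO or the TMFG filter; finally the Walktrap
#' algorithm partitions the network into topics. Derivatives are always
#' computed per individual before any stacking, so no embedding window spans
#' two individuals.
#'
#' @param x A numeric matrix/data frame (rows = time points, columns =
#'   variables) for a single individual, or a list of such matrices sharing
#'   the same columns for several individuals.
#' @param level `"population"` stacks all individuals' derivative matrices
#'   into one analysis; `"individual"` fits each panel separately (returning
#'   a list); `"group"` stacks within the groups given by `group`.
#' @param group Factor/vector with one entry per panel (required for
#'   `level = "group"`).
#' @param method Network estimator: `"glasso"` or `"tmfg"`.
#' @param n_embed Number of embedding dimensions (window size of the
#'   derivative estimates).
#' @param tau Embedding lag.
#' @param delta_t Time between successive observations.
#' @param order Derivative order whose correlations define the network
#'   (0, 1 or 2; default 1).
#' @param steps Walktrap random-walk length.
#' @param tune Optional integer vector of candidate `n_embed` values; when
#'   supplied the candidate with the lowest TEFI is used (see
#'   [tune_embedding()]).
#' @param ... Further arguments passed to [ebic_glasso()].
#'
#' @return For a single analysis, an object of class `"dynega"` with elements
#'   `n_topics`, `membership`, `network`, `correlation`, `tefi`, `loadings`,
#'   `n_embed`, `method`, `n_obs` and `call`. Use [coef()] for the
#'   standardized network loadings and [predict()] for topic score series.
#'   For `level = "individual"` or `"group"`, a named list of such objects
#'   (class `"dynega_list"`).
#'
#' @examples
#' sim <- simulate_dafs(dafs_spec(loading = 0.7, t_points = 200), seed = 1)
#' fit <- dynega(sim$observed, method = "tmfg")
#' fit$n_topics
#' @export
dynega <- function(x, level = c("population", "individual", "group"),
                   group = NULL, method = c("glasso", "tmfg"), n_embed = 5,
                   tau = 1, delta_t = 1, order = 1, steps = 4, tune = NULL,
                   ...) {
  level <- match.arg(level)
  method <- match.arg(method)
  cl <- match.call()
  if (!is.null(tune)) {
    fit <- tune_embedding(x, candidates = tune, level = level, group = group,
                          method = method, tau = tau, delta_t = delta_t,
                          order = order, steps = steps, ...)
    fit$call <- cl
    return(fit)
  }
  panels <- if (is.list(x) && !is.data.frame(x)) x else list(x)
  if (length(panels) == 0) stop("no panels supplied")

  Ds <- list()
  kept <- integer(0)
  for (i in seq_along(panels)) {
    D <- tryCatch(
      build_derivatives(panels[[i]], n_embed = n_embed, tau = tau,
                        delta_t = delta_t),
      error = function(e) e)
    if (inherits(D, "error")) {
      warning("panel ", i, " excluded: ", conditionMessage(D))
    } else {
      Ds[[length(Ds) + 1]] <- D
      kept <- c(kept, i)
      nm <- names(panels)[i]
      names(Ds)[length(Ds)] <- if (!is.null(nm) && !is.na(nm) && nzchar(nm)) {
        nm
      } else {
        as.character(i)
      }
    }
  }
  if (length(Ds) == 0) stop("all panels were excluded")

  fit_one <- function(D_list, label) {
    D <- do.call(rbind, D_list)
    attr(D, "variables") <- attr(D_list[[1]], "variables")
    out <- estimate_topics(D, method = method, order = order, steps = steps,
                           ...)
    out$n_embed <- n_embed
    out$tau <- tau
    out$delta_t <- delta_t
    out$level <- label
    out$call <- cl
    out
  }

  if (level == "population") {
    fit_one(Ds, "population")
  } else if (level == "individual") {
    fits <- lapply(names(Ds), function(nm) fit_one(Ds[nm], nm))
    names(fits) <- names(Ds)
    structure(fits, class = "dynega_list")
  } else {
    if (is.null(group) || length(group) != length(panels)) {
      stop("level = 'group' requires one group label per panel")
    }
    group <- group[kept]
    fits <- lapply(unique(group), function(gr) {
      fit_one(Ds[group == gr], as.character(gr))
    })
    names(fits) <- unique(group)
    structure(fits, class = "dynega_list")
  }
}

#' Estimate the topic structure from a stacked derivative matrix
#'
#' The second half of the dynamic EGA pipeline: correlate the derivative
#' columns of the requested order, estimate the network, partition it with
#' Walktrap, and compute TEFI and network loadings. Derivative columns with
#' zero variance in the stack are dropped with a warning.
#'
#' @param D A derivative matrix from [build_derivatives()] (possibly
#'   row-bound over individuals, with `attr(, "variables")` set).
#' @inheritParams dynega
#' @return An object of class `"dynega"`.
#' @export
estimate_topics <- function(D, method = c("glasso", "tmfg"), order = 1,
                            steps = 4, ...) {
  method <- match.arg(method)
  X <- derivative_columns(D, order = order)
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) {
    warning("dropping zero-variance derivative column(s): ",
            paste(colnames(X)[sds == 0], collapse = ", "))
    X <- X[, sds > 0, drop = FALSE]
  }
  R <- pearson_corr(X)
  n_obs <- nrow(X)
  net <- if (method == "glasso") {
    ebic_glasso(R, n_obs = n_obs, ...)
  } else {
    tmfg(R, n_obs = n_obs)
  }
  membership <- walktrap_partition(net, steps = steps)
  fit_tefi <- tefi(R, membership)
  loadings <- network_loadings(net, membership)
  structure(list(n_topics = attr(membership, "n_topics"),
                 membership = membership, network = net, correlation = R,
                 tefi = fit_tefi, loadings = loadings, method = method,
                 n_obs = n_obs, order = order, steps = steps),
            class = "dynega")
}

#' Second-order topic structure from topic scores
#'
#' Runs the full dynamic EGA pipeline on a matrix of first-order topic score
#' series, estimating broad "themes" that group correlated topics — the
#' network analogue of second-order factors.
#'
#' @param scores T x N_F matrix of topic scores (e.g. from [predict.dynega()]);
#'   at least 4 topic series are required.
#' @param ... Arguments passed to [dynega()] (e.g. `method`, `n_embed`,
#'   `tune`).
#' @return A `"dynega"` fit over the topic-score series.
#' @export
second_order <- function(scores, ...) {
  scores <- as.matrix(scores)
  if (ncol(scores) < 4) stop("second-order analysis needs at least 4 topic series")
  dynega(scores, ...)
}

#' @method print dynega
#' @export
print.dynega <- function(x, ...) {
  cat("Dynamic EGA fit (", x$method, " network, walktrap)\n", sep = "")
  cat("  Topics estimated:", x$n_topics, "\n")
  cat("  Variables:", length(x$membership), " Observations (derivative rows):",
      x$n_obs, "\n")
  if (!is.null(x$n_embed)) {
    cat("  Embedding: n =", x$n_embed, ", tau =", x$tau,
        ", delta t =", x$delta_t, ", derivative order =", x$order, "\n")
  }
  cat("  TEFI:", format(x$tefi$tefi, digits = 5), "\n")
  invisible(x)
}

#' @method summary dynega
#' @export
summary.dynega <- function(object, ...) {
  print(object)
  cat("\nVariables per topic:\n")
  print(table(topic = object$membership))
  cat("\nStandardized network loadings:\n")
  print(round(object$loadings$std, 3))
  invisible(object)
}

#' @method print dynega_list
#' @export
print.dynega_list <- function(x, ...) {
  cat("Dynamic EGA fits for", length(x), "unit(s):\n")
  for (nm in names(x)) {
    cat("  ", nm, ": ", x[[nm]]$n_topics, " topics\n", sep = "")
  }
  invisible(x)
}

#' Standardized network loadings of a fit
#'
#' @param object A `"dynega"` fit.
#' @param standardized Return standardized (default) or unstandardized
#'   loadings.
#' @param ... Unused.
#' @return A p x N_F loading matrix.
#' @export
coef.dynega <- function(object, standardized = TRUE, ...) {
  if (standardized) object$loadings$std else object$loadings$unstd
}

#' Topic scores for observed data
#'
#' Computes the network topic score series implied by a fit for a data
#' matrix whose columns correspond to the fitted variables (by name when
#' available). By default scores summarize the observed (order-0) values, the
#' scale on which topic trends are usually plotted.
#'
#' @param object A `"dynega"` fit.
#' @param newdata T x p matrix of observed values. Required.
#' @param ... Unused.
#' @return A T x N_F matrix of topic scores.
#' @export
predict.dynega <- function(object, newdata, ...) {
  if (missing(newdata)) stop("newdata (observed series) is required")
  network_scores(newdata, object$loadings)
}

#' Plot a dynamic EGA network
#'
#' Draws the estimated network with nodes colored by topic membership.
#'
#' @param x A `"dynega"` fit.
#' @param ... Passed on to [igraph::plot.igraph()].
#' @export
plot.dynega <- function(x, ...) {
  W <- x$network$weights
  g <- igraph::graph_from_adjacency_matrix(abs(W), mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  pal <- grDevices::hcl.colors(max(2, x$n_topics), palette = "Dynamic")
  igraph::plot.igraph(
    g,
    vertex.color = pal[x$membership],
    vertex.label = colnames(W),
    edge.width = 3 * igraph::E(g)$weight / max(igraph::E(g)$weight),
    ...)
  invisible(x)
}

#' Write a JSON run report for a fit
#'
#' Serializes the headline results of a fit — estimator settings, number of
#' topics, TEFI, the EBIC gamma actually used, edge count, and the
#' variable-to-topic membership — to a JSON file.
#'
#' @param fit A `"dynega"` fit.
#' @param file Output path.
#' @return Invisibly, the report list.
#' @export
write_report <- function(fit, file) {
  stopifnot(inherits(fit, "dynega"))
  W <- fit$network$weights
  rep <- list(
    method = fit$method,
    level = fit$level,
    n_embed = fit$n_embed, tau = fit$tau, delta_t = fit$delta_t,
    derivative_order = fit$order,
    n_obs = fit$n_obs,
    n_topics = fit$n_topics,
    tefi = fit$tefi$tefi,
    gamma = fit$network$gamma,
    n_edges = sum(abs(W[upper.tri(W)]) > 0),
    membership = as.list(stats::setNames(as.integer(fit$membership),
                                  names(fit$membership))))
  jsonlite::write_json(rep, file, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(rep)
}
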