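#' Von Neumann entropy of a correlation matrix
#'
#' Scales a correlation matrix to a density matrix (trace one) by dividing by
#' its order, and returns \eqn{-\sum_i \lambda_i \log \lambda_i} over the
#' eigenvalues of the density matrix (with \eqn{0 \log 0 := 0}). For an
#' identity correlation matrix of order p this is \eqn{\log p}; for perfectly
#' collinear variables it approaches 0.
#'
#' @param R Symmetric positive semidefinite correlation (sub)matrix.
#' @param form `"spectral"` (the von Neumann definition, via eigenvalues of
#'   the density matrix; default) or `"elementwise"`, the literal
#'   trace-of-product-with-elementwise-log reading,
#'   \eqn{-\mathrm{tr}(\rho \cdot \log_{el} \rho)}, kept for comparison.
#'   The element-wise form is only defined when every entry of the density
#'   matrix is strictly positive.
#' @return The entropy in nats.
#' @export
von_neumann_entropy <- function(R, form = c("spectral", "elementwise")) {
  form <- match.arg(form)
  R <- as.matrix(R)
  if (nrow(R) == 1L) return(0)
  rho <- R / ncol(R)
  if (form == "elementwise") {
    if (any(rho <= 0)) {
      stop("element-wise entropy requires strictly positive density entries")
    }
    return(-sum(diag(rho %*% log(rho))))
  }
  ev <- eigen(rho, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev < -1e-8)) stop("matrix has negative eigenvalues; not PSD")
  ev <- pmax(ev, 0)
  ev <- ev[ev > 0]
  -sum(ev * log(ev))
}

#' Total entropy fit index (TEFI)
#'
#' Measures how well a partition of variables into topics fits a correlation
#' matrix, using von Neumann entropies of the full matrix and of each topic's
#' submatrix (each rescaled to trace one):
#' \deqn{TEFI = \left[\frac{\sum_i S(\rho_i)}{N_F} - S(\rho)\right] +
#'       \left[\left(S(\rho) - \sum_i S(\rho_i)\right)\sqrt{N_F}\right].}
#' Lower values indicate a better-fitting dimensional structure. For a single
#' topic covering all variables the two bracketed terms cancel identically
#' and TEFI is 0.
#'
#' @param R Correlation matrix of the analyzed variables.
#' @param membership Integer vector assigning each variable to a topic.
#'
#' @return A list of class `dynega_tefi`: `tefi`, `total_entropy`,
#'   `per_topic_entropies`, `n_topics`.
#' @export
tefi <- function(R, membership) {
  R <- as.matrix(R)
  stopifnot(length(membership) == ncol(R))
  topics <- sort(unique(membership))
  n_f <- length(topics)
  s_rho <- von_neumann_entropy(R)
  s_i <- vapply(topics, function(k) {
    idx <- which(membership == k)
    von_neumann_entropy(R[idx, idx, drop = FALSE])
  }, numeric(1))
  val <- (sum(s_i) / n_f - s_rho) + (s_rho - sum(s_i)) * sqrt(n_f)
  structure(list(tefi = val, total_entropy = s_rho,
                 per_topic_entropies = s_i, n_topics = n_f),
            class = "dynega_tefi")
}

#' @method print dynega_tefi
#' @export
print.dynega_tefi <- function(x, ...) {
  cat("TEFI:", format(x$tefi, digits = 5), "(", x$n_topics, "topics )\n")
  invisible(x)
}

#' Tune the number of embedding dimensions by TEFI
#'
#' Runs the full dynamic EGA pipeline once per candidate embedding dimension
#' and selects the candidate whose estimated topic structure attains the
#' lowest TEFI (ties broken toward the smaller dimension). Candidates too
#' large for the available series are skipped with a warning.
#'
#' @param x A single panel (matrix) or list of panels, as in [dynega()].
#' @param candidates Integer vector of embedding dimensions to compare.
#' @param ... Further arguments passed to [dynega()] (e.g. `method`, `tau`).
#'
#' @return The selected [dynega()] fit; per-candidate TEFI values are stored
#'   in its `tuning` element.
#' @export
tune_embedding <- function(x, candidates, ...) {
  stopifnot(length(candidates) >= 2)
  fits <- list()
  for (n in candidates) {
    f <- tryCatch(dynega(x, n_embed = n, ...), error = function(e) e)
    if (inherits(f, "error")) {
      warning("n_embed = ", n, " skipped: ", conditionMessage(f))
    } else {
      fits[[as.character(n)]] <- f
    }
  }
  if (length(fits) == 0) stop("no feasible embedding dimension among candidates")
  tefis <- vapply(fits, function(f) f$tefi$tefi, numeric(1))
  ns <- as.integer(names(fits))
  best <- fits[[order(tefis, ns)[1]]]
  best$tuning <- data.frame(n_embed = ns, tefi = unname(tefis))
  best
}
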