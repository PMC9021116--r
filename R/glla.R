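#' Time-delay embedding of a univariate series
#'
#' Stacks lagged copies of a scalar time series into the rows of a matrix so
#' that row \eqn{t} is the phase-space vector
#' \eqn{[x_t, x_{t+\tau}, \ldots, x_{t+(n-1)\tau}]}. The result has
#' \eqn{M = N - (n-1)\tau} rows, where \eqn{N} is the series length.
#'
#' @param x Numeric vector, the time series (equally spaced, no missing
#'   values).
#' @param n_embed Integer \eqn{\ge 2}, number of embedding dimensions.
#' @param tau Positive integer lag between successive embedding coordinates.
#'
#' @return A numeric matrix with `length(x) - (n_embed - 1) * tau` rows and
#'   `n_embed` columns.
#'
#' @examples
#' embed_series(5:14, n_embed = 5)
#' @export
embed_series <- function(x, n_embed = 5, tau = 1) {
  x <- as.numeric(x)
  stopifnot(n_embed >= 2, tau >= 1, tau == round(tau), n_embed == round(n_embed))
  N <- length(x)
  M <- N - (n_embed - 1) * tau
  if (M < 1) {
    stop("insufficient time points: N = ", N, " with n_embed = ", n_embed,
         " and tau = ", tau, " requires N >= ", (n_embed - 1) * tau + 1)
  }
  idx <- outer(seq_len(M), (seq_len(n_embed) - 1L) * tau, `+`)
  matrix(x[idx], nrow = M, ncol = n_embed)
}

#' GLLA weight matrix
#'
#' Builds the weight matrix used by generalized local linear approximation
#' (GLLA) to map a time-delay embedding onto derivative estimates. Column
#' \eqn{\alpha \in \{0, \ldots, k\}} is
#' \eqn{[\Delta_t (v - \bar v)]^\alpha / \alpha!} with \eqn{v = (1, \ldots, n)},
#' so the zeroth column is all ones and the higher columns form a polynomial
#' basis centered on the embedding window.
#'
#' @param n_embed Number of embedding dimensions \eqn{n}.
#' @param delta_t Time between successive observations.
#' @param max_order Highest derivative order \eqn{k} (1 or 2).
#'
#' @return An `n_embed` by `max_order + 1` matrix.
#'
#' @examples
#' glla_weights(5) # columns: ones, -2..2, (v - vbar)^2 / 2
#' @export
glla_weights <- function(n_embed = 5, delta_t = 1, max_order = 2) {
  stopifnot(n_embed >= 2, delta_t > 0, max_order %in% c(1, 2),
            n_embed > max_order)
  v <- seq_len(n_embed)
  vc <- delta_t * (v - mean(v))
  sapply(0:max_order, function(a) vc^a / factorial(a))
}

#' Estimate derivatives of a time series by GLLA
#'
#' Given a series, forms its time-delay embedding `X` and estimates
#' derivatives of order 0..`max_order` by the least-squares projection
#' \eqn{Y = X L (L'L)^{-1}}. GLLA is exact on polynomials of degree up to
#' `max_order`: column \eqn{\alpha + 1} of the result is the \eqn{\alpha}-th
#' derivative evaluated at the center of each embedding window.
#'
#' @inheritParams embed_series
#' @inheritParams glla_weights
#'
#' @return An \eqn{M \times (k+1)} matrix of derivative estimates; column 1
#'   holds the smoothed order-0 values, column 2 the first derivatives, and so
#'   on.
#'
#' @examples
#' y <- estimate_derivatives(5:14, n_embed = 5)
#' y[, 2] # first derivative of a unit-slope ramp: all ones
#' @export
estimate_derivatives <- function(x, n_embed = 5, tau = 1, delta_t = 1,
                                 max_order = 2) {
  X <- embed_series(x, n_embed = n_embed, tau = tau)
  L <- glla_weights(n_embed = n_embed, delta_t = delta_t,
                    max_order = max_order)
  # least-squares solve of L' Y' = ... ; same contract as X L (L'L)^{-1}
  # but better conditioned than forming the inverse explicitly
  Y <- t(solve(crossprod(L), t(X %*% L)))
  colnames(Y) <- paste0("Ord", 0:max_order)
  Y
}

#' Build the column-bound derivative matrix D for one individual
#'
#' Applies GLLA to every column of a multivariate time-series panel and binds
#' the per-variable derivative estimates into one matrix with columns named
#' `<variable>.Ord0`, `<variable>.Ord1`, ... Variables with zero variance over
#' the whole series are dropped with a warning (their derivative correlations
#' are undefined).
#'
#' @param panel Numeric matrix or data frame; rows are time points, columns
#'   are variables observed for a single individual.
#' @inheritParams estimate_derivatives
#'
#' @return A numeric matrix with \eqn{M = N - (n-1)\tau} rows and
#'   `3 * ncol(panel)` columns (for `max_order = 2`). The retained variable
#'   names are stored in `attr(, "variables")`.
#'
#' @export
build_derivatives <- function(panel, n_embed = 5, tau = 1, delta_t = 1,
                              max_order = 2) {
  panel <- as.matrix(panel)
  storage.mode(panel) <- "double"
  if (is.null(colnames(panel))) {
    colnames(panel) <- paste0("V", seq_len(ncol(panel)))
  }
  vars <- apply(panel, 2, stats::var)
  keep <- vars > 0 & is.finite(vars)
  if (!all(keep)) {
    warning("dropping zero-variance variable(s): ",
            paste(colnames(panel)[!keep], collapse = ", "))
    panel <- panel[, keep, drop = FALSE]
  }
  if (ncol(panel) == 0L) stop("no variables with nonzero variance")
  Ys <- lapply(colnames(panel), function(v) {
    Y <- estimate_derivatives(panel[, v], n_embed = n_embed, tau = tau,
                              delta_t = delta_t, max_order = max_order)
    colnames(Y) <- paste0(v, ".", colnames(Y))
    Y
  })
  D <- do.call(cbind, Ys)
  attr(D, "variables") <- colnames(panel)
  attr(D, "max_order") <- max_order
  D
}

# Extract the columns of a D matrix holding derivatives of a given order,
# one column per variable, named by variable.
derivative_columns <- function(D, order = 1) {
  vars <- attr(D, "variables")
  cols <- paste0(vars, ".Ord", order)
  missing <- setdiff(cols, colnames(D))
  if (length(missing)) {
    stop("derivative order ", order, " not present in D")
  }
  out <- D[, cols, drop = FALSE]
  colnames(out) <- vars
  out
}
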