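#' Dirichlet log density
#'
#' Closed-form log density of the Dirichlet distribution,
#' `log G(sum a) - sum log G(a_k) + sum (a_k - 1) log y_k`.
#' Boundary compositions (any part exactly 0 or 1) are outside the support;
#' close them onto the simplex first with [to_simplex()].
#'
#' @param y Composition: positive vector summing to 1, or a matrix with one
#'   composition per row.
#' @param alpha Positive concentration vector (recycled across rows) or a
#'   matrix matching `y`.
#' @return Log density, one value per row of `y`.
#' @export
#' @examples
#' ddirichlet_log(c(1 / 3, 1 / 3, 1 / 3), c(1, 1, 1)) # log 2
ddirichlet_log <- function(y, alpha) {
  ym <- if (is.null(dim(y))) matrix(y, nrow = 1) else as.matrix(y)
  am <- if (is.null(dim(alpha))) {
    matrix(alpha, nrow = nrow(ym), ncol = length(alpha), byrow = TRUE)
  } else {
    as.matrix(alpha)
  }
  if (any(am <= 0)) stop("alpha must be strictly positive", call. = FALSE)
  if (any(ym <= 0) || any(ym >= 1)) {
    stop("y must be interior to the simplex (zero-adjust boundary values)",
      call. = FALSE
    )
  }
  if (any(abs(rowSums(ym) - 1) > 1e-8)) {
    stop("compositions must sum to 1", call. = FALSE)
  }
  drop(
    lgamma(rowSums(am)) - rowSums(lgamma(am)) +
      rowSums((am - 1) * log(ym))
  )
}

#' Draw Dirichlet variates
#'
#' Gamma-ratio construction; used by the synthetic-data generator and by
#' Monte-Carlo checks of the density.
#'
#' @param n Number of draws.
#' @param alpha Positive concentration vector.
#' @return Matrix `n x length(alpha)` of simplex rows.
#' @export
rdirichlet <- function(n, alpha) {
  stopifnot(all(alpha > 0))
  g <- matrix(
    rgamma(n * length(alpha), shape = rep(alpha, each = n), rate = 1),
    nrow = n
  )
  g / rowSums(g)
}

#' Mean simplex and Dirichlet concentration from linear predictors
#'
#' Softmax link of the mean/precision parameterization: the mean composition
#' is `mu_k = exp(eta_k) / sum_j exp(eta_j)` (the reference category's linear
#' predictor is held at 0 by the caller) and the Dirichlet concentration is
#' `alpha = mu * phi` with a single scalar precision `phi`.
#'
#' @param eta Matrix of linear predictors, one row per observation, one column
#'   per category (reference column all zero), or a single vector.
#' @param phi Positive scalar precision.
#' @return List with `mu` (mean simplex rows) and `alpha`.
#' @export
#' @examples
#' dirichlet_mean(c(0, 0, 0), phi = 9)$mu # uniform thirds
dirichlet_mean <- function(eta, phi) {
  stopifnot(is.numeric(phi), length(phi) == 1, phi > 0)
  em <- if (is.null(dim(eta))) matrix(eta, nrow = 1) else as.matrix(eta)
  if (any(!is.finite(em))) {
    stop("non-finite linear predictor", call. = FALSE)
  }
  # subtract row max for overflow-safe softmax
  em <- em - apply(em, 1, max)
  e <- exp(em)
  mu <- e / rowSums(e)
  list(mu = mu, alpha = mu * phi)
}

#' Standardize a covariate
#'
#' Centres to mean 0 and scales to unit sample standard deviation, returning
#' the constants needed to transform new data (e.g. prediction grids) onto the
#' fitted scale.
#'
#' @param x Numeric vector with at least two distinct values.
#' @return List with `values`, `mean`, `sd`.
#' @export
#' @examples
#' standardize(c(1, 2, 3))$values
standardize <- function(x) {
  if (any(!is.finite(x))) stop("covariate has non-finite values", call. = FALSE)
  s <- sd(x)
  if (!is.finite(s) || s == 0) {
    stop("degenerate covariate: zero variance", call. = FALSE)
  }
  m <- mean(x)
  list(values = (x - m) / s, mean = m, sd = s)
}
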