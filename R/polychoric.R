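# Polychoric correlation machinery: vectorised bivariate normal CDF,
# two-step threshold + correlation estimation, and the pairwise matrix.

# Gauss-Legendre nodes/weights on [-1, 1] by Golub-Welsch; cached.
.gl_cache <- new.env(parent = emptyenv())
gauss_legendre <- function(n) {
  key <- as.character(n)
  if (!is.null(.gl_cache[[key]])) return(.gl_cache[[key]])
  k <- seq_len(n - 1)
  b <- k / sqrt(4 * k^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(k, k + 1)] <- b
  J[cbind(k + 1, k)] <- b
  es <- eigen(J, symmetric = TRUE)
  res <- list(nodes = rev(es$values), weights = rev(2 * es$vectors[1, ]^2))
  .gl_cache[[key]] <- res
  res
}

#' Bivariate standard normal CDF
#'
#' `P(X <= h, Y <= k)` for standard normal `(X, Y)` with correlation `rho`,
#' by Gauss-Legendre quadrature of the single-integral reduction
#' `Phi2(h,k,rho) = Phi(h) Phi(k) +
#'   (2 pi)^-1 int_0^rho exp(-(h^2 - 2 r h k + k^2) / (2 (1 - r^2))) /
#'   sqrt(1 - r^2) dr`.
#' Vectorised over `h` and `k` (recycled); infinite bounds are handled.
#'
#' @param h,k upper integration bounds (numeric vectors).
#' @param rho correlation, |rho| <= 0.9995 (scalar).
#' @param nodes quadrature nodes (default 48).
#' @return Vector of probabilities.
#' @export
pbinorm <- function(h, k, rho, nodes = 48L) {
  stopifnot(length(rho) == 1, abs(rho) <= 0.9995)
  n <- max(length(h), length(k))
  h <- rep_len(h, n)
  k <- rep_len(k, n)
  base <- stats::pnorm(h) * stats::pnorm(k)
  if (rho == 0) return(base)
  hc <- pmin(pmax(h, -8.5), 8.5)
  kc <- pmin(pmax(k, -8.5), 8.5)
  gl <- gauss_legendre(nodes)
  r <- rho / 2 * (gl$nodes + 1)          # map [-1,1] -> [0, rho]
  w <- gl$weights * rho / 2
  acc <- numeric(n)
  for (i in seq_along(r)) {
    ri <- r[i]
    acc <- acc + w[i] * exp(-(hc^2 - 2 * ri * hc * kc + kc^2) /
                              (2 * (1 - ri^2))) / sqrt(1 - ri^2)
  }
  # infinite/extreme bounds contribute nothing to the integral term
  acc[!is.finite(h) | !is.finite(k)] <- 0
  p <- base + acc / (2 * pi)
  pmin(pmax(p, 0), 1)
}

# Thresholds of an ordinal variable from its marginal proportions.
# Categories are taken as the sorted observed values; returns the normal
# quantiles of the interior cumulative proportions.
marginal_thresholds <- function(x) {
  tab <- table(factor(x))
  cp <- cumsum(tab) / sum(tab)
  stats::qnorm(cp[-length(cp)])
}

# Cell probabilities of the bivariate normal at threshold grids.
polychoric_cellprobs <- function(tau_x, tau_y, rho) {
  a <- c(-Inf, tau_x, Inf)
  b <- c(-Inf, tau_y, Inf)
  grid <- pbinorm(rep(a, times = length(b)), rep(b, each = length(a)), rho)
  Fm <- matrix(grid, length(a), length(b))
  P <- Fm[-1, -1, drop = FALSE] - Fm[-nrow(Fm), -1, drop = FALSE] -
    Fm[-1, -ncol(Fm), drop = FALSE] + Fm[-nrow(Fm), -ncol(Fm), drop = FALSE]
  pmax(P, 0)
}

#' Polychoric correlation of two ordinal variables
#'
#' Two-step estimate: thresholds from the marginal category proportions via
#' the normal quantile, then the latent correlation by maximising the
#' bivariate-normal likelihood of the contingency table over `rho`.
#'
#' @param x,y ordinal vectors (small ordered category sets), each with at
#'   least two observed categories.
#' @return List with `rho`, `tau_x`, `tau_y`, `loglik`.
#' @export
polychoric <- function(x, y) {
  stopifnot(length(x) == length(y))
  fx <- factor(x)
  fy <- factor(y)
  if (nlevels(fx) < 2 || nlevels(fy) < 2)
    stop("each variable needs at least 2 observed categories")
  tau_x <- marginal_thresholds(x)
  tau_y <- marginal_thresholds(y)
  counts <- table(fx, fy)
  negll <- function(rho) {
    P <- polychoric_cellprobs(tau_x, tau_y, rho)
    -sum(counts * log(pmax(P, 1e-300)))
  }
  opt <- stats::optimize(negll, c(-0.999, 0.999), tol = 1e-7)
  rho <- opt$minimum
  if (abs(rho) > 0.998) {
    warning("polychoric estimate at boundary; clipped to +/-0.999")
    rho <- sign(rho) * 0.999
  }
  list(rho = rho, tau_x = as.numeric(tau_x), tau_y = as.numeric(tau_y),
       loglik = -opt$objective)
}

#' Pairwise polychoric correlation matrix with thresholds
#'
#' @param values integer matrix of ordinal responses (rows = participants).
#' @param n_categories nominal number of categories (used only for sanity
#'   checks; thresholds come from the observed categories).
#' @return List with `rho` (correlation matrix) and `tau` (list of per-item
#'   threshold vectors on the standard-normal scale).
#' @export
polychoric_matrix <- function(values, n_categories = NULL) {
  x <- as.matrix(values)
  p <- ncol(x)
  ids <- colnames(x)
  if (is.null(ids)) ids <- paste0("V", seq_len(p))
  tau <- lapply(seq_len(p), function(j) marginal_thresholds(x[, j]))
  names(tau) <- ids
  rho <- diag(1, p)
  dimnames(rho) <- list(ids, ids)
  for (i in seq_len(p - 1)) {
    for (j in seq((i + 1), p)) {
      counts <- table(factor(x[, i]), factor(x[, j]))
      ti <- tau[[i]]
      tj <- tau[[j]]
      negll <- function(r) {
        P <- polychoric_cellprobs(ti, tj, r)
        -sum(counts * log(pmax(P, 1e-300)))
      }
      est <- stats::optimize(negll, c(-0.999, 0.999), tol = 1e-7)$minimum
      if (abs(est) > 0.998) est <- sign(est) * 0.999
      rho[i, j] <- rho[j, i] <- est
    }
  }
  list(rho = rho, tau = tau)
}

# Asymptotic variance of a two-step polychoric estimate: inverse observed
# information of the pairwise likelihood in rho at the estimate (thresholds
# held fixed), by central second difference. Used as the DWLS weight.
polychoric_avar <- function(counts, tau_x, tau_y, rho, eps = 1e-4) {
  ll <- function(r) {
    P <- polychoric_cellprobs(tau_x, tau_y, r)
    sum(counts * log(pmax(P, 1e-300)))
  }
  r0 <- min(max(rho, -0.995 + eps), 0.995 - eps)
  info <- -(ll(r0 + eps) - 2 * ll(r0) + ll(r0 - eps)) / eps^2
  if (!is.finite(info) || info <= 0) info <- sum(counts)  # fallback ~ n
  1 / info
}
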