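# Confirmatory machinery: DWLS estimation of an ordinal factor model on
# polychoric correlations, fit indices, and McDonald's omega.
#
# Estimator note: this is diagonally weighted least squares with UNADJUSTED
# chi-square and fit indices (weights = finite-sample variances of the
# polychoric estimates from the pairwise observed information). The
# mean-and-variance scaled (WLSMV) test statistic is deliberately not
# implemented; every report carries this flag.

#' Specification of a confirmatory factor model
#'
#' @param factor_map named list: factor name -> character vector of item
#'   ids. Every item loads on exactly one factor.
#' @param error_covariances list of length-2 character vectors naming item
#'   pairs whose residuals covary (taken as given model options, e.g. from a
#'   previously established model; no modification-index search is done).
#' @param estimator `"dwls"` (diagonally weighted least squares on
#'   polychoric correlations; chi-square unadjusted).
#' @param identification `"variance_std"`: factor variances fixed to 1, all
#'   loadings free (standardized solution).
#' @return An object of class `cfa_spec`.
#' @export
cfa_spec <- function(factor_map, error_covariances = list(),
                     estimator = c("dwls"),
                     identification = c("variance_std")) {
  estimator <- match.arg(estimator)
  identification <- match.arg(identification)
  stopifnot(is.list(factor_map), length(factor_map) >= 1,
            !is.null(names(factor_map)))
  items <- unlist(factor_map, use.names = FALSE)
  if (anyDuplicated(items))
    stop("every item must load on exactly one factor")
  for (ec in error_covariances) {
    if (length(ec) != 2 || ec[1] == ec[2])
      stop("error covariances must be pairs of distinct items")
    if (!all(ec %in% items))
      stop("error covariance names unknown item(s): ",
           paste(setdiff(ec, items), collapse = ", "))
  }
  structure(list(factor_map = factor_map,
                 error_covariances = error_covariances,
                 estimator = estimator, identification = identification,
                 items = items),
            class = "cfa_spec")
}

#' Read / write a CFA specification as JSON
#' @param spec a [cfa_spec()].
#' @param path file path.
#' @return `write_cfa_spec` returns `path` invisibly; `read_cfa_spec`
#'   returns a `cfa_spec`.
#' @export
write_cfa_spec <- function(spec, path) {
  jsonlite::write_json(list(factor_map = spec$factor_map,
                            error_covariances = spec$error_covariances,
                            estimator = spec$estimator,
                            identification = spec$identification),
                       path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_cfa_spec
#' @export
read_cfa_spec <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  ec <- j$error_covariances
  if (is.matrix(ec)) ec <- split(ec, seq_len(nrow(ec)))
  if (is.data.frame(ec)) ec <- lapply(seq_len(nrow(ec)), function(i) unlist(ec[i, ]))
  ec <- unname(lapply(ec, unname))
  cfa_spec(as.list(j$factor_map), ec %||% list(),
           estimator = j$estimator %||% "dwls",
           identification = j$identification %||% "variance_std")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# --- internal model structure -------------------------------------------

# Index bookkeeping for the free parameters of a single-group model:
# loadings (one per item), factor correlations (off-diagonal), error
# covariances.
cfa_structure <- function(spec) {
  items <- spec$items
  p <- length(items)
  k <- length(spec$factor_map)
  fac_of <- rep(seq_len(k), lengths(spec$factor_map))
  names(fac_of) <- items
  ec_idx <- t(vapply(spec$error_covariances,
                     function(ec) match(ec, items), integer(2)))
  if (length(spec$error_covariances) == 0) ec_idx <- matrix(0L, 0, 2)
  list(items = items, p = p, k = k, fac_of = fac_of, ec_idx = ec_idx,
       n_lambda = p, n_phi = k * (k - 1) / 2, n_ec = nrow(ec_idx))
}

# Model-implied latent-response covariance matrix (unit diagonal when
# psi is a correlation matrix) from loadings, factor covariance psi,
# residual variances theta_d, and error covariances ec.
cfa_implied_cov <- function(lambda, psi, theta_d, ec, st) {
  Lam <- matrix(0, st$p, st$k)
  Lam[cbind(seq_len(st$p), st$fac_of)] <- lambda
  sig <- Lam %*% psi %*% t(Lam)
  diag(sig) <- diag(sig) + theta_d
  if (st$n_ec > 0)
    for (e in seq_len(st$n_ec)) {
      i <- st$ec_idx[e, 1]; j <- st$ec_idx[e, 2]
      sig[i, j] <- sig[i, j] + ec[e]
      sig[j, i] <- sig[i, j]
    }
  sig
}

# Unpack single-group parameter vector into components; residual variances
# are 1 - communality (variance-standardised identification).
cfa_unpack <- function(par, st) {
  lambda <- par[seq_len(st$n_lambda)]
  psi <- diag(1, st$k)
  if (st$n_phi > 0)
    psi[upper.tri(psi)] <- psi[lower.tri(psi)] <-
      par[st$n_lambda + seq_len(st$n_phi)]
  ec <- if (st$n_ec > 0) par[st$n_lambda + st$n_phi + seq_len(st$n_ec)] else numeric(0)
  comm <- vapply(seq_len(st$p), function(i) {
    f <- st$fac_of[i]
    lambda[i]^2 * psi[f, f]
  }, numeric(1))
  list(lambda = lambda, psi = psi, ec = ec, theta_d = 1 - comm)
}

lower_vec <- function(m) m[lower.tri(m)]

# DWLS discrepancy of a single-group correlation structure:
# sum_j (s_j - sigma_j)^2 / w_j over the lower-triangle correlations.
cfa_discrepancy <- function(par, s, w, st) {
  u <- cfa_unpack(par, st)
  sig <- cfa_implied_cov(u$lambda, u$psi, u$theta_d, u$ec, st)
  r <- s - lower_vec(sig)
  sum(r * r / w)
}

# Crude data-driven starting values.
cfa_start <- function(S, st) {
  lam0 <- numeric(st$p)
  for (f in seq_len(st$k)) {
    idx <- which(st$fac_of == f)
    if (length(idx) >= 2) {
      rbar <- mean(S[idx, idx][lower.tri(diag(length(idx)))])
      lam0[idx] <- sqrt(min(max(rbar, 0.1), 0.9))
    } else lam0[idx] <- 0.7
  }
  phi0 <- numeric(st$n_phi)
  if (st$n_phi > 0) {
    pos <- 0
    for (f2 in 2:st$k) for (f1 in seq_len(f2 - 1)) {
      pos <- pos + 1
      i1 <- which(st$fac_of == f1); i2 <- which(st$fac_of == f2)
      phi0[pos] <- min(max(mean(S[i1, i2]) / (mean(lam0[i1]) * mean(lam0[i2])),
                           -0.9), 0.9)
    }
  }
  c(lam0, phi0, rep(0, st$n_ec))
}

# Fit the correlation structure by DWLS. Returns parameters, discrepancy.
cfa_optimize <- function(s, w, st, start = NULL, n_restarts = 3L, seed = 7L) {
  npar <- st$n_lambda + st$n_phi + st$n_ec
  lo <- c(rep(-0.995, st$n_lambda), rep(-0.995, st$n_phi), rep(-0.99, st$n_ec))
  hi <- -lo
  obj <- function(p) cfa_discrepancy(p, s, w, st)
  best <- NULL
  starts <- list()
  if (!is.null(start)) starts <- c(starts, list(start))
  set.seed(seed)
  for (r in seq_len(n_restarts)) {
    jitter <- if (r == 1) 0 else stats::rnorm(npar, 0, 0.1)
    base <- if (!is.null(start)) start else rep(0.5, npar) * c(rep(1, st$n_lambda), rep(0.8, st$n_phi + st$n_ec))
    starts <- c(starts, list(pmin(pmax(base + jitter, lo + 0.01), hi - 0.01)))
  }
  for (p0 in starts) {
    fit <- stats::nlminb(p0, obj, lower = lo, upper = hi,
                         control = list(rel.tol = 1e-12, x.tol = 1e-10,
                                        iter.max = 2000, eval.max = 4000))
    if (is.null(best) || fit$objective < best$objective) best <- fit
  }
  if (best$convergence != 0 && best$objective > 1e-6) {
    g <- numeric(npar)  # numeric gradient at the reported optimum
    f0 <- obj(best$par)
    for (i in seq_len(npar)) {
      d <- best$par; d[i] <- d[i] + 1e-6
      g[i] <- (obj(d) - f0) / 1e-6
    }
    if (sqrt(sum(g^2)) > 1e-3)
      stop(sprintf("CFA did not converge (gradient norm %.3g)", sqrt(sum(g^2))))
  }
  best
}

# Polychoric correlations + finite-sample diagonal weights for a data matrix.
polychoric_with_weights <- function(values) {
  x <- as.matrix(values)
  p <- ncol(x)
  ids <- colnames(x)
  if (is.null(ids)) ids <- paste0("V", seq_len(p))
  tau <- lapply(seq_len(p), function(j) marginal_thresholds(x[, j]))
  names(tau) <- ids
  rho <- diag(1, p); dimnames(rho) <- list(ids, ids)
  avar <- matrix(NA_real_, p, p, dimnames = list(ids, ids))
  for (i in seq_len(p - 1)) for (j in seq((i + 1), p)) {
    counts <- table(factor(x[, i]), factor(x[, j]))
    ti <- tau[[i]]; tj <- tau[[j]]
    negll <- function(r) -sum(counts * log(pmax(polychoric_cellprobs(ti, tj, r), 1e-300)))
    est <- stats::optimize(negll, c(-0.999, 0.999), tol = 1e-7)$minimum
    if (abs(est) > 0.998) est <- sign(est) * 0.999
    rho[i, j] <- rho[j, i] <- est
    avar[i, j] <- avar[j, i] <- polychoric_avar(counts, ti, tj, est)
  }
  list(rho = rho, tau = tau, avar = avar)
}

#' McDonald's omega from a fitted factor's parameters
#'
#' `omega = (sum lambda)^2 / ((sum lambda)^2 + sum theta + 2 sum error
#' covariances)` over the items of one factor.
#'
#' @param lambda loadings of the factor's items.
#' @param theta residual variances of those items.
#' @param error_cov sum is taken over residual covariances among those items
#'   (default none).
#' @return Omega (scalar in `[0, 1]` for admissible solutions).
#' @export
mcdonald_omega <- function(lambda, theta, error_cov = 0) {
  sl2 <- sum(lambda)^2
  sl2 / (sl2 + sum(theta) + 2 * sum(error_cov))
}

#' Ordinal confirmatory factor analysis by DWLS
#'
#' Estimates item thresholds and polychoric correlations in a first step,
#' then fits the factor structure to the polychoric correlations by
#' diagonally weighted least squares: minimise
#' `sum_j (s_j - sigma_j(theta))^2 / w_j` over the lower-triangle
#' correlations, where `w_j` is the finite-sample variance of the j-th
#' polychoric estimate from the pairwise observed information. The test
#' statistic equals the minimised weighted discrepancy (numerically
#' identical to scaling an n-free weight matrix by the sample size);
#' no mean-and-variance adjustment is applied, and all fit output is
#' flagged accordingly. Factor variances are fixed to 1 (standardized
#' solution); residual variances are `1 - communality`.
#'
#' @param matrix a [response_matrix()] (subset to the spec's items
#'   automatically).
#' @param spec a [cfa_spec()].
#' @return An object of class `cfa_fit`: loadings, `phi`, `theta`
#'   (residual variances), `error_covariances`, `tau` (per-item thresholds),
#'   `fit` (chisq, df, cfi, tli, rmsea + CI, srmr), `omega` per factor,
#'   `residuals`, `n`, `spec`.
#' @export
fit_cfa <- function(matrix, spec) {
  stopifnot(inherits(matrix, "response_matrix"), inherits(spec, "cfa_spec"))
  sub <- subset_items(matrix, spec$items)
  pw <- polychoric_with_weights(sub$values)
  fit_cfa_moments(pw$rho, pw$avar, spec, n = nrow(sub$values), tau = pw$tau)
}

#' Fit a CFA to a given correlation matrix
#'
#' Population-level interface: fits the model of `spec` directly to a
#' correlation matrix. With `weights = NULL` unit weights are used, making
#' the discrepancy an unweighted least-squares distance; `n` scales the test
#' statistic.
#'
#' @param corr correlation matrix over the spec's items.
#' @param spec a [cfa_spec()].
#' @param n nominal sample size for the test statistic.
#' @param weights optional matrix of variances for the correlations.
#' @return A `cfa_fit` object.
#' @export
cfa_from_corr <- function(corr, spec, n, weights = NULL) {
  corr <- as.matrix(corr)
  if (is.null(rownames(corr))) rownames(corr) <- colnames(corr) <- spec$items
  corr <- corr[spec$items, spec$items]
  if (is.null(weights)) {
    weights <- matrix(1 / (n - 1), nrow(corr), ncol(corr),
                      dimnames = dimnames(corr))
  } else {
    weights <- as.matrix(weights)[spec$items, spec$items]
  }
  fit_cfa_moments(corr, weights, spec, n = n, tau = NULL)
}

# Shared worker: fit the correlation structure, assemble indices and omega.
fit_cfa_moments <- function(rho, avar, spec, n, tau = NULL) {
  st <- cfa_structure(spec)
  rho <- rho[st$items, st$items]
  avar <- avar[st$items, st$items]
  s <- lower_vec(rho)
  w <- lower_vec(avar)
  npar <- st$n_lambda + st$n_phi + st$n_ec
  n_mom <- st$p * (st$p - 1) / 2
  if (n <= npar) stop("model not identified: n must exceed free parameters")
  if (n_mom < npar) stop("model not identified: more parameters than moments")
  best <- cfa_optimize(s, w, st, start = cfa_start(rho, st))
  u <- cfa_unpack(best$par, st)
  sig <- cfa_implied_cov(u$lambda, u$psi, u$theta_d, u$ec, st)
  chisq <- best$objective
  df <- n_mom - npar
  chisq_b <- sum(s^2 / w)
  df_b <- n_mom
  resid <- rho - sig
  srmr <- sqrt(mean(lower_vec(resid)^2))
  fi <- fit_indices(max(chisq, 0), df, n, chisq_b, df_b)
  Lam <- matrix(0, st$p, st$k,
                dimnames = list(st$items, names(spec$factor_map)))
  Lam[cbind(seq_len(st$p), st$fac_of)] <- u$lambda
  phi <- u$psi
  dimnames(phi) <- list(names(spec$factor_map), names(spec$factor_map))
  omega <- vapply(seq_len(st$k), function(f) {
    idx <- which(st$fac_of == f)
    ec_sum <- 0
    if (st$n_ec > 0)
      for (e in seq_len(st$n_ec))
        if (all(st$ec_idx[e, ] %in% idx)) ec_sum <- ec_sum + u$ec[e]
    mcdonald_omega(u$lambda[idx], u$theta_d[idx], ec_sum)
  }, numeric(1))
  names(omega) <- names(spec$factor_map)
  ecs <- if (st$n_ec > 0)
    stats::setNames(u$ec, vapply(spec$error_covariances, paste, "", collapse = "~~"))
  else numeric(0)
  structure(
    list(loadings = Lam, phi = phi,
         theta = stats::setNames(u$theta_d, st$items),
         error_covariances = ecs, tau = tau,
         fit = c(list(chisq = chisq, df = df,
                      baseline_chisq = chisq_b, baseline_df = df_b,
                      srmr = srmr), fi),
         omega = omega, residuals = resid, n = n, spec = spec,
         estimator = "DWLS (unadjusted chi-square; not mean-and-variance scaled)",
         discrepancy = best$objective / (n - 1), par = best$par),
    class = "cfa_fit")
}

#' @export
print.cfa_fit <- function(x, ...) {
  cat(sprintf("Ordinal CFA, %d items, %d factor(s), n = %d\n",
              nrow(x$loadings), ncol(x$loadings), x$n))
  cat("  estimator:", x$estimator, "\n")
  cat(sprintf("  chisq(%d) = %.2f, CFI = %.3f, TLI = %.3f, RMSEA = %.3f, SRMR = %.3f\n",
              x$fit$df, x$fit$chisq, x$fit$cfi, x$fit$tli, x$fit$rmsea,
              x$fit$srmr))
  cat(sprintf("  omega: %s\n",
              paste(sprintf("%s = %.2f", names(x$omega), x$omega), collapse = ", ")))
  invisible(x)
}

#' @export
summary.cfa_fit <- function(object, ...) {
  print(object)
  cat("\nStandardized loadings:\n")
  print(round(object$loadings, 3))
  if (ncol(object$phi) > 1) {
    cat("\nFactor correlations:\n")
    print(round(object$phi, 3))
  }
  if (length(object$error_covariances)) {
    cat("\nError covariances:\n")
    print(round(object$error_covariances, 3))
  }
  invisible(object)
}

#' @export
coef.cfa_fit <- function(object, ...) object$loadings
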