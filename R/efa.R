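# Exploratory machinery: factorability diagnostics, parallel analysis with
# principal axis factoring, oblimin rotation, fit indices, factor scores.

#' Kaiser-Meyer-Olkin sampling adequacy
#'
#' Contrasts squared correlations with squared anti-image partial
#' correlations: `KMO = sum r^2 / (sum r^2 + sum q^2)` over off-diagonal
#' cells, overall and per item. For a diagonal correlation matrix both sums
#' are zero; the index is then defined as 0 by convention.
#'
#' @param corr invertible correlation matrix.
#' @return List with `overall` and named `per_item` values in `[0, 1]`.
#' @export
kmo <- function(corr) {
  corr <- as.matrix(corr)
  inv <- tryCatch(solve(corr), error = function(e)
    stop("correlation matrix is singular; consider a ridge or removing items"))
  d <- 1 / sqrt(diag(inv))
  q <- -inv * outer(d, d)   # anti-image partial correlations
  diag(q) <- 0
  r <- corr
  diag(r) <- 0
  r2 <- r^2
  q2 <- q^2
  denom_o <- sum(r2) + sum(q2)
  overall <- if (denom_o == 0) 0 else sum(r2) / denom_o
  denom_i <- colSums(r2) + colSums(q2)
  per_item <- ifelse(denom_i == 0, 0, colSums(r2) / denom_i)
  names(per_item) <- colnames(corr)
  list(overall = overall, per_item = per_item)
}

#' Bartlett's test of sphericity
#'
#' `chisq = -(n - 1 - (2p + 5)/6) * log det(R)` with `df = p(p-1)/2`.
#'
#' @param corr correlation matrix (positive definite).
#' @param n number of observations (must exceed the number of items).
#' @return List with `chisq`, `df`, `p`.
#' @export
bartlett_sphericity <- function(corr, n) {
  corr <- as.matrix(corr)
  p <- ncol(corr)
  if (n <= p) stop("n must exceed the number of items")
  ld <- determinant(corr, logarithm = TRUE)
  if (ld$sign <= 0) stop("correlation matrix is not positive definite")
  chisq <- -(n - 1 - (2 * p + 5) / 6) * as.numeric(ld$modulus)
  df <- p * (p - 1) / 2
  list(chisq = chisq, df = df, p = stats::pchisq(chisq, df, lower.tail = FALSE))
}

# Squared multiple correlations from a correlation matrix.
smc <- function(corr) {
  inv <- solve(corr)
  1 - 1 / diag(inv)
}

# Eigenvalues of the reduced correlation matrix (SMC on the diagonal).
reduced_eigenvalues <- function(corr) {
  r <- as.matrix(corr)
  diag(r) <- smc(r)
  eigen(r, symmetric = TRUE, only.values = TRUE)$values
}

#' Parallel analysis with principal-axis eigenvalues
#'
#' Observed eigenvalues come from the reduced correlation matrix (squared
#' multiple correlations on the diagonal, as in principal axis factoring).
#' The reference curve is the per-position `quantile` of the same
#' eigenvalues computed from data whose columns are independently permuted,
#' which preserves the marginal (ordinal) distributions while destroying the
#' correlations. The retained number of factors is the length of the leading
#' run where observed exceeds reference.
#'
#' @param matrix a [response_matrix()] or a numeric matrix (rows =
#'   participants).
#' @param n_resamples number of column-permutation resamples (default 1000,
#'   minimum 100).
#' @param quantile reference quantile (default 0.95).
#' @param seed RNG seed.
#' @return An object of class `parallel_result`: list with
#'   `observed_eigenvalues`, `reference_eigenvalues`, `n_factors`.
#' @export
parallel_analysis <- function(matrix, n_resamples = 1000L, quantile = 0.95,
                              seed = 1L) {
  x <- if (inherits(matrix, "response_matrix")) matrix$values else as.matrix(matrix)
  if (n_resamples < 100) stop("n_resamples must be >= 100")
  if (nrow(x) <= ncol(x)) stop("need more participants than items")
  obs <- reduced_eigenvalues(stats::cor(x))
  p <- ncol(x)
  set.seed(seed)
  ref <- matrix(0, n_resamples, p)
  for (b in seq_len(n_resamples)) {
    perm <- apply(x, 2, sample)
    ref[b, ] <- reduced_eigenvalues(stats::cor(perm))
  }
  ref_q <- apply(ref, 2, stats::quantile, probs = quantile, names = FALSE)
  above <- obs > ref_q
  n_factors <- if (!above[1]) 0L else which.min(c(above, FALSE)) - 1L
  structure(list(observed_eigenvalues = obs, reference_eigenvalues = ref_q,
                 n_factors = as.integer(n_factors), quantile = quantile),
            class = "parallel_result")
}

#' @export
print.parallel_result <- function(x, ...) {
  cat(sprintf("Parallel analysis (PAF eigenvalues, %.0f%% reference): retain %d factor(s)\n",
              100 * x$quantile, x$n_factors))
  invisible(x)
}

#' Principal axis factoring
#'
#' Iterated eigendecomposition of the reduced correlation matrix:
#' communalities start at the squared multiple correlations, the first
#' `n_factors` eigenpairs give the loadings, and the diagonal is replaced by
#' the implied communalities until `max |delta h^2| < tol`.
#'
#' @param corr correlation matrix.
#' @param n_factors number of factors to extract.
#' @param tol convergence tolerance on communalities (default 1e-6).
#' @param max_iter iteration cap (default 1000).
#' @return List with unrotated `loadings` (columns ordered by explained
#'   variance, column sums made non-negative), `communalities`, `iterations`,
#'   `heywood` flag.
#' @export
paf <- function(corr, n_factors, tol = 1e-6, max_iter = 1000L) {
  r <- as.matrix(corr)
  p <- ncol(r)
  if (n_factors < 1 || n_factors >= p)
    stop("n_factors must be in 1 .. items - 1")
  h <- smc(r)
  heywood <- FALSE
  for (iter in seq_len(max_iter)) {
    rh <- r
    diag(rh) <- h
    es <- eigen(rh, symmetric = TRUE)
    ev <- pmax(es$values[seq_len(n_factors)], 0)
    L <- es$vectors[, seq_len(n_factors), drop = FALSE] %*%
      diag(sqrt(ev), n_factors)
    h_new <- rowSums(L^2)
    if (any(h_new > 1)) {
      heywood <- TRUE
      h_new <- pmin(h_new, 1)
    }
    if (max(abs(h_new - h)) < tol) {
      h <- h_new
      break
    }
    h <- h_new
    if (iter == max_iter)
      stop("principal axis factoring did not converge in ", max_iter, " iterations")
  }
  if (heywood)
    warning("Heywood case: communality exceeded 1; clipped at 1")
  sgn <- ifelse(colSums(L) < 0, -1, 1)
  L <- L %*% diag(sgn, n_factors)
  dimnames(L) <- list(colnames(r), paste0("F", seq_len(n_factors)))
  list(loadings = L, communalities = stats::setNames(h, colnames(r)),
       iterations = iter, heywood = heywood)
}

# Direct oblimin criterion value and gradient (gamma = 0 is quartimin).
oblimin_vgq <- function(L, gamma = 0) {
  k <- ncol(L)
  p <- nrow(L)
  X <- L^2 %*% (matrix(1, k, k) - diag(k))
  if (gamma != 0)
    X <- (diag(p) - matrix(gamma / p, p, p)) %*% X
  list(f = sum(L^2 * X) / 4, Gq = L * X)
}

#' Oblimin rotation by gradient projection
#'
#' Minimises the direct oblimin criterion (`gamma = 0`: direct quartimin)
#' over oblique rotations using the gradient projection algorithm, with
#' random restarts. The model-implied matrix `L Phi L'` is preserved exactly
#' by construction. Columns of the result are ordered by explained variance
#' with non-negative column sums.
#'
#' @param loadings unrotated loading matrix with >= 2 columns.
#' @param gamma oblimin parameter (default 0).
#' @param n_starts random restarts in addition to the identity start.
#' @param tol gradient-norm convergence tolerance.
#' @param max_iter iteration cap per start.
#' @param seed seed for the random starts.
#' @return List with rotated `loadings`, factor correlation `phi`,
#'   criterion value `f`, and `convergence` flag.
#' @export
oblimin_rotate <- function(loadings, gamma = 0, n_starts = 10L,
                           tol = 1e-6, max_iter = 2000L, seed = 42L) {
  A <- as.matrix(loadings)
  k <- ncol(A)
  if (k < 2) stop("rotation needs at least 2 factors")
  set.seed(seed)
  starts <- c(list(diag(k)), replicate(n_starts, {
    M <- matrix(stats::rnorm(k * k), k)
    M %*% diag(1 / sqrt(colSums(M^2)))
  }, simplify = FALSE))
  best <- NULL
  for (Tmat in starts) {
    res <- gpf_oblq(A, Tmat, gamma, tol, max_iter)
    if (is.null(best) || res$f < best$f) best <- res
  }
  if (!best$convergence)
    stop(sprintf("oblimin rotation did not converge (criterion %.6g, gradient norm %.3g)",
                 best$f, best$grad_norm))
  L <- best$loadings
  phi <- best$phi
  ss <- colSums(L^2)
  ord <- order(ss, decreasing = TRUE)
  L <- L[, ord, drop = FALSE]
  phi <- phi[ord, ord, drop = FALSE]
  sgn <- ifelse(colSums(L) < 0, -1, 1)
  L <- L %*% diag(sgn, k)
  phi <- diag(sgn, k) %*% phi %*% diag(sgn, k)
  dimnames(L) <- list(rownames(A), paste0("F", seq_len(k)))
  dimnames(phi) <- list(colnames(L), colnames(L))
  list(loadings = L, phi = phi, f = best$f, convergence = best$convergence)
}

# Gradient projection for oblique rotation (single start).
gpf_oblq <- function(A, Tmat, gamma, tol, max_iter) {
  k <- ncol(A)
  Ti <- solve(Tmat)
  L <- A %*% t(Ti)
  vg <- oblimin_vgq(L, gamma)
  G <- -t(t(L) %*% vg$Gq %*% Ti)
  f <- vg$f
  al <- 1
  s <- Inf
  for (iter in seq_len(max_iter)) {
    Gp <- G - Tmat %*% diag(colSums(Tmat * G), k)
    s <- sqrt(sum(Gp^2))
    if (s < tol) break
    al <- 2 * al
    for (i in 0:25) {
      X <- Tmat - al * Gp
      Tt <- X %*% diag(1 / sqrt(colSums(X^2)), k)
      Ti <- solve(Tt)
      L <- A %*% t(Ti)
      vg_t <- oblimin_vgq(L, gamma)
      if (vg_t$f < f - 0.5 * s^2 * al) break
      al <- al / 2
    }
    Tmat <- Tt
    f <- vg_t$f
    G <- -t(t(L) %*% vg_t$Gq %*% Ti)
  }
  list(loadings = L, phi = t(Tmat) %*% Tmat, f = f,
       convergence = s < tol, grad_norm = s)
}

#' RMSEA and TLI from chi-square statistics
#'
#' `RMSEA = sqrt(max(chisq - df, 0) / (df (n - 1)))` with a 90% confidence
#' interval obtained by inverting the noncentral chi-square distribution;
#' `TLI = ((chisq_b/df_b) - (chisq/df)) / ((chisq_b/df_b) - 1)`.
#'
#' @param chisq,df model test statistic and degrees of freedom.
#' @param n sample size.
#' @param baseline_chisq,baseline_df independence-baseline statistic; its df
#'   must exceed the model df.
#' @return List with `rmsea`, `rmsea_ci` (length-2, 90%), `tli`, `cfi`.
#' @export
fit_indices <- function(chisq, df, n, baseline_chisq, baseline_df) {
  if (df < 1 || n <= 1) stop("need df >= 1 and n > 1")
  if (baseline_df <= df) stop("baseline df must exceed model df")
  rmsea <- sqrt(max(chisq - df, 0) / (df * (n - 1)))
  ci <- rmsea_ci(chisq, df, n)
  rb <- baseline_chisq / baseline_df
  rm <- chisq / df
  tli <- (rb - rm) / (rb - 1)
  cfi <- 1 - max(chisq - df, 0) / max(chisq - df, baseline_chisq - baseline_df, 0)
  if (!is.finite(cfi)) cfi <- 1
  list(rmsea = rmsea, rmsea_ci = ci, tli = tli, cfi = cfi)
}

# 90% CI for RMSEA by inverting the noncentral chi-square.
rmsea_ci <- function(chisq, df, n, level = 0.90) {
  a <- (1 - level) / 2
  ncp_for <- function(prob) {
    if (stats::pchisq(chisq, df) < prob) return(0)
    stats::uniroot(function(ncp) stats::pchisq(chisq, df, ncp) - prob,
                   lower = 0, upper = max(n * 10, chisq * 10),
                   extendInt = "downX", tol = 1e-8)$root
  }
  lo <- ncp_for(1 - a)
  hi <- ncp_for(a)
  c(sqrt(lo / (df * (n - 1))), sqrt(hi / (df * (n - 1))))
}

# ML discrepancy of a factor solution to a sample correlation matrix.
ml_discrepancy <- function(S, sigma) {
  p <- ncol(S)
  as.numeric(determinant(sigma, TRUE)$modulus) -
    as.numeric(determinant(S, TRUE)$modulus) +
    sum(diag(S %*% solve(sigma))) - p
}

#' Thurstone regression factor scores and their reliability
#'
#' Weights `W = R^-1 (Lambda Phi)` applied to standardised item scores.
#' Score reliability per factor is the squared multiple correlation of the
#' factor on the items, `R^2_j = (Lambda Phi)_j' R^-1 (Lambda Phi)_j`,
#' reported with its square root as correlation-with-factor.
#'
#' @param matrix a [response_matrix()] or numeric matrix over the solution's
#'   items.
#' @param loadings rotated pattern matrix.
#' @param phi factor correlation matrix.
#' @param corr item correlation matrix used for the weights (default: sample
#'   Pearson correlations of `matrix`).
#' @return List with `scores` (n x factors), `r_squared`,
#'   `correlation_with_factor`, `weights`.
#' @export
factor_scores <- function(matrix, loadings, phi = diag(ncol(loadings)),
                          corr = NULL) {
  x <- if (inherits(matrix, "response_matrix")) matrix$values else as.matrix(matrix)
  L <- as.matrix(loadings)
  if (ncol(x) != nrow(L)) stop("matrix columns must match loading rows")
  if (is.null(corr)) corr <- stats::cor(x)
  inv <- tryCatch(solve(corr), error = function(e)
    stop("item correlation matrix is singular"))
  structure_mat <- L %*% phi
  W <- inv %*% structure_mat
  z <- scale(x)
  scores <- z %*% W
  r2 <- diag(t(structure_mat) %*% inv %*% structure_mat)
  r2 <- pmin(pmax(r2, 0), 1)
  colnames(scores) <- colnames(L)
  list(scores = scores, r_squared = stats::setNames(r2, colnames(L)),
       correlation_with_factor = stats::setNames(sqrt(r2), colnames(L)),
       weights = W)
}

#' Exploratory factor analysis by parallel analysis + PAF + oblimin
#'
#' The full Step-2 exploratory fit: factorability diagnostics (KMO,
#' Bartlett), factor retention by [parallel_analysis()] (unless `n_factors`
#' is given), principal axis factoring, oblimin rotation for multi-factor
#' solutions, ML-discrepancy fit indices against the independence baseline,
#' and factor-score reliability.
#'
#' @param matrix a [response_matrix()] or numeric matrix.
#' @param n_factors number of factors; `NULL` to decide by parallel
#'   analysis.
#' @param method correlation type for the item matrix
#'   (`"pearson"`/`"spearman"`/`"polychoric"`).
#' @param gamma oblimin parameter.
#' @param n_resamples,quantile,seed passed to [parallel_analysis()].
#' @return An object of class `efa_paf` with loadings, `phi`,
#'   `communalities`, `variance_explained`, `fit`, `score_reliability`,
#'   `kmo`, `bartlett`, `parallel`.
#' @export
efa_paf <- function(matrix, n_factors = NULL,
                    method = c("pearson", "spearman", "polychoric"),
                    gamma = 0, n_resamples = 1000L, quantile = 0.95,
                    seed = 1L) {
  method <- match.arg(method)
  x <- if (inherits(matrix, "response_matrix")) matrix$values else as.matrix(matrix)
  n <- nrow(x)
  p <- ncol(x)
  corr <- if (method == "polychoric") {
    polychoric_matrix(x)$rho
  } else {
    stats::cor(x, method = method)
  }
  kmo_res <- kmo(corr)
  bart <- bartlett_sphericity(corr, n)
  par_res <- NULL
  if (is.null(n_factors)) {
    par_res <- parallel_analysis(x, n_resamples = n_resamples,
                                 quantile = quantile, seed = seed)
    n_factors <- max(par_res$n_factors, 1L)
  }
  ext <- paf(corr, n_factors)
  if (n_factors >= 2) {
    rot <- oblimin_rotate(ext$loadings, gamma = gamma)
    L <- rot$loadings
    phi <- rot$phi
  } else {
    L <- ext$loadings
    phi <- matrix(1, 1, 1, dimnames = list("F1", "F1"))
  }
  h2 <- rowSums((L %*% phi) * L)
  sigma <- L %*% phi %*% t(L)
  diag(sigma) <- 1
  f_model <- ml_discrepancy(corr, sigma)
  chisq <- (n - 1) * f_model
  df <- ((p - n_factors)^2 - (p + n_factors)) / 2
  chisq_b <- -(n - 1) * as.numeric(determinant(corr, TRUE)$modulus)
  df_b <- p * (p - 1) / 2
  fit <- c(list(chisq = chisq, df = df,
                baseline_chisq = chisq_b, baseline_df = df_b),
           fit_indices(chisq, df, n, chisq_b, df_b))
  ss <- diag(phi %*% t(L) %*% L)
  variance_explained <- list(per_factor = ss / p, total = sum(h2) / p)
  fs <- factor_scores(x, L, phi, corr = corr)
  structure(
    list(loadings = L, phi = phi, communalities = h2,
         variance_explained = variance_explained, fit = fit,
         score_reliability = list(
           r_squared = fs$r_squared,
           correlation_with_factor = fs$correlation_with_factor),
         kmo = kmo_res, bartlett = bart, parallel = par_res,
         n_factors = n_factors, n = n, method = method),
    class = "efa_paf")
}

#' @export
print.efa_paf <- function(x, digits = 2, ...) {
  cat(sprintf("EFA (PAF%s), %d factor(s), n = %d, %s correlations\n",
              if (x$n_factors >= 2) " + oblimin" else "", x$n_factors, x$n,
              x$method))
  cat(sprintf("  KMO = %.2f, Bartlett chi2(%d) = %.1f (p %s)\n",
              x$kmo$overall, x$bartlett$df, x$bartlett$chisq,
              format.pval(x$bartlett$p, digits = 2)))
  cat(sprintf("  TLI = %.3f, RMSEA = %.3f [%.3f, %.3f]\n",
              x$fit$tli, x$fit$rmsea, x$fit$rmsea_ci[1], x$fit$rmsea_ci[2]))
  cat(sprintf("  variance explained: %s (total %.0f%%)\n",
              paste(sprintf("%.0f%%", 100 * x$variance_explained$per_factor),
                    collapse = " + "),
              100 * x$variance_explained$total))
  if (x$n_factors >= 2)
    cat(sprintf("  factor correlation(s): %s\n",
                paste(sprintf("%.2f", x$phi[upper.tri(x$phi)]), collapse = ", ")))
  invisible(x)
}

#' @export
coef.efa_paf <- function(object, ...) object$loadings
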