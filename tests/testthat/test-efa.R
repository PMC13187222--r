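# Factorability diagnostics, parallel analysis, PAF, oblimin, fit indices,
# factor scores.

test_that("KMO matches a residual-regression partial-correlation oracle", {
  set.seed(13)
  x <- matrix(rnorm(200 * 4), 200)
  x[, 2] <- x[, 1] * 0.6 + x[, 2]
  x[, 4] <- x[, 3] * 0.5 + x[, 4]
  R <- stats::cor(x)
  res <- kmo(R)
  # oracle: partial correlations from residuals of linear regressions
  part <- diag(4)
  for (i in 1:3) for (j in (i + 1):4) {
    others <- setdiff(1:4, c(i, j))
    ri <- stats::lm.fit(cbind(1, x[, others]), x[, i])$residuals
    rj <- stats::lm.fit(cbind(1, x[, others]), x[, j])$residuals
    part[i, j] <- part[j, i] <- stats::cor(ri, rj)
  }
  r2 <- R^2; diag(r2) <- 0
  q2 <- part^2; diag(q2) <- 0
  expect_equal(res$overall, sum(r2) / (sum(r2) + sum(q2)), tolerance = 1e-10)
  expect_equal(unname(res$per_item),
               colSums(r2) / (colSums(r2) + colSums(q2)), tolerance = 1e-10)
})

test_that("KMO handles the degenerate identity case and strong one-factor data", {
  expect_equal(kmo(diag(6))$overall, 0)
  R <- matrix(0.8, 10, 10); diag(R) <- 1
  expect_gt(kmo(R)$overall, 0.9)
})

test_that("Bartlett sphericity matches the closed formula and is monotone", {
  b0 <- bartlett_sphericity(diag(5), 100)
  expect_equal(b0$chisq, 0)
  expect_equal(b0$p, 1)

  R <- matrix(0.3, 5, 5); diag(R) <- 1
  b <- bartlett_sphericity(R, 100)
  expect_equal(b$chisq, -(100 - 1 - (2 * 5 + 5) / 6) * log(det(R)),
               tolerance = 1e-10)
  expect_equal(b$df, 10)
  # shrinking toward identity decreases the statistic
  prev <- Inf
  for (w in c(1, 0.7, 0.4, 0.1)) {
    Rw <- w * R + (1 - w) * diag(5)
    cur <- bartlett_sphericity(Rw, 100)$chisq
    expect_lt(cur, prev)
    prev <- cur
  }
})

test_that("parallel analysis retains zero factors for noise and is seed-deterministic", {
  set.seed(14)
  x <- matrix(sample(1:7, 500 * 10, TRUE), 500)
  pa <- parallel_analysis(x, n_resamples = 150, seed = 2)
  expect_equal(pa$n_factors, 0L)
  pa2 <- parallel_analysis(x, n_resamples = 150, seed = 2)
  expect_identical(pa$reference_eigenvalues, pa2$reference_eigenvalues)
  # n_factors weakly decreases as the reference quantile increases
  fx <- make_fixture("two_factor_invariant", seed = 15)$matrix
  nf <- vapply(c(0.5, 0.95, 0.99), function(q)
    parallel_analysis(fx, n_resamples = 150, quantile = q, seed = 2)$n_factors,
    integer(1))
  expect_true(all(diff(nf) <= 0))
  expect_error(parallel_analysis(x[1:5, ], n_resamples = 150), "participants")
  expect_error(parallel_analysis(x, n_resamples = 10), "100")
})

test_that("PAF solves the equicorrelated one-factor model exactly", {
  R <- matrix(0.64, 6, 6); diag(R) <- 1
  fit <- paf(R, 1)
  expect_equal(unname(fit$loadings[, 1]), rep(0.8, 6), tolerance = 1e-6)
  expect_equal(unname(fit$communalities), rep(0.64, 6), tolerance = 1e-6)
})

test_that("PAF + oblimin recovers a known oblique two-factor structure", {
  L <- matrix(0, 10, 2)
  L[1:5, 1] <- c(.8, .75, .7, .65, .6)
  L[6:10, 2] <- c(.8, .7, .7, .6, .55)
  Phi <- matrix(c(1, .5, .5, 1), 2)
  R <- L %*% Phi %*% t(L); diag(R) <- 1
  ext <- paf(R, 2)
  # model-implied off-diagonals reproduced
  imp <- ext$loadings %*% t(ext$loadings)
  expect_lt(max(abs(imp[lower.tri(imp)] - R[lower.tri(R)])), 1e-6)
  rot <- oblimin_rotate(ext$loadings)
  # Tucker congruence with the generating loadings after alignment
  congr <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  cc <- abs(outer(1:2, 1:2, Vectorize(function(i, j)
    congr(rot$loadings[, i], L[, j]))))
  expect_gt(max(cc[1, ]), 0.99)
  expect_gt(max(cc[2, ]), 0.99)
  expect_equal(abs(rot$phi[1, 2]), 0.5, tolerance = 1e-4)
})

test_that("oblimin is a fixed point on perfect simple structure and beats random search", {
  L <- matrix(0, 8, 2)
  L[1:4, 1] <- 0.7
  L[5:8, 2] <- 0.7
  rot <- oblimin_rotate(L)
  expect_equal(sort(abs(round(rot$loadings[rot$loadings != 0], 6))),
               rep(0.7, 8), tolerance = 1e-5)

  set.seed(16)
  A <- matrix(rnorm(16), 8, 2)
  rot2 <- oblimin_rotate(A)
  # oracle: criterion over 1000 random oblique rotations
  crit <- function(Tm) scalenet:::oblimin_vgq(A %*% t(solve(Tm)))$f
  rand_best <- min(replicate(1000, {
    M <- matrix(rnorm(4), 2)
    crit(M %*% diag(1 / sqrt(colSums(M^2))))
  }))
  expect_lte(rot2$f, rand_best + 1e-8)
  # the model-implied matrix is preserved
  expect_lt(max(abs(rot2$loadings %*% rot2$phi %*% t(rot2$loadings) -
                      A %*% t(A))), 1e-8)
})

test_that("RMSEA and TLI match the hand formulas", {
  fi <- fit_indices(100, 50, 201, 1000, 60)
  expect_equal(fi$rmsea, sqrt(50 / (50 * 200)), tolerance = 1e-12)
  expect_equal(fi$tli, ((1000 / 60) - 2) / ((1000 / 60) - 1), tolerance = 1e-12)
  expect_equal(fit_indices(50, 50, 201, 1000, 60)$rmsea, 0)

  set.seed(17)
  for (i in 1:20) {
    df <- sample(5:80, 1)
    chisq <- df * runif(1, 0.5, 3)
    n <- sample(100:1000, 1)
    dfb <- df + sample(1:20, 1)
    chisqb <- dfb * runif(1, 5, 30)
    fi <- fit_indices(chisq, df, n, chisqb, dfb)
    expect_equal(fi$rmsea, sqrt(max(chisq - df, 0) / (df * (n - 1))),
                 tolerance = 1e-10)
    expect_equal(fi$tli,
                 ((chisqb / dfb) - (chisq / df)) / ((chisqb / dfb) - 1),
                 tolerance = 1e-10)
    # CI inversion round-trips through the noncentral chi-square
    if (fi$rmsea_ci[2] > 0) {
      ncp_hi <- fi$rmsea_ci[2]^2 * df * (n - 1)
      expect_equal(stats::pchisq(chisq, df, ncp_hi), 0.05, tolerance = 1e-6)
    }
  }
  expect_error(fit_indices(100, 50, 201, 1000, 40), "baseline")
})

test_that("factor scores reduce to the standardized item for a unit loading", {
  set.seed(18)
  x <- matrix(rnorm(100), 100, 1)
  fs <- factor_scores(x, matrix(1, 1, 1), matrix(1, 1, 1))
  expect_equal(as.numeric(fs$scores), as.numeric(scale(x)), tolerance = 1e-12)
  expect_equal(unname(fs$r_squared), 1, tolerance = 1e-12)
})

test_that("estimated factor scores track the true simulated latents", {
  set.seed(19)
  n <- 2000
  Phi <- matrix(c(1, .5, .5, 1), 2)
  L <- matrix(0, 10, 2); L[1:5, 1] <- 0.75; L[6:10, 2] <- 0.75
  f <- matrix(rnorm(n * 2), n) %*% chol(Phi)
  x <- f %*% t(L) + matrix(rnorm(n * 10), n) %*% diag(sqrt(1 - rowSums(L^2)))
  fs <- factor_scores(x, L, Phi)
  for (j in 1:2)
    expect_gte(stats::cor(fs$scores[, j], f[, j]),
               sqrt(fs$r_squared[j]) - 0.05)
  # population identity: formula R2 equals explicit regression R2
  R <- L %*% Phi %*% t(L); diag(R) <- 1
  Sf <- L %*% Phi
  beta <- qr.solve(R, Sf)           # independent linear-system route
  r2_reg <- diag(t(Sf) %*% beta)
  fs_pop <- factor_scores(x, L, Phi, corr = R)
  expect_equal(unname(fs_pop$r_squared), unname(r2_reg), tolerance = 1e-8)
})

test_that("the EFA wrapper reports a coherent two-factor solution", {
  fx <- make_fixture("two_factor_invariant", seed = 20)$matrix
  case_only <- fx$values[fx$group == "case", ]
  e <- efa_paf(case_only, n_resamples = 150, seed = 3)
  expect_equal(e$n_factors, 2L)
  expect_gt(e$kmo$overall, 0.8)
  expect_lt(e$bartlett$p, 0.001)
  expect_equal(e$phi[1, 2], 0.58, tolerance = 0.12)
  expect_true(all(e$communalities >= 0 & e$communalities <= 1))
  expect_true(abs(sum(e$variance_explained$per_factor) -
                    e$variance_explained$total) < 0.15)
  expect_true(all(e$score_reliability$r_squared <= 1))
  expect_identical(coef(e), e$loadings)
})
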