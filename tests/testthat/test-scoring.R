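# Scoring and univariate statistics.

test_that("score_total applies reverse-coding and matches a naive loop", {
  m <- tiny_matrix(matrix(1L, 2, 7), item_ids = paste0("IP", 1:7))
  tot <- score_total(m, items = c("IP5", "IP6", "IP7"), reverse = "IP6")
  expect_equal(unname(tot), c(9, 9))   # 1 + (8-1) + 1

  m2 <- tiny_matrix(matrix(7L, 2, 18), item_ids = paste0("IP", 1:18))
  expect_equal(unname(score_total(m2)), c(126, 126))

  set.seed(2)
  v <- matrix(sample(1:7, 50 * 65, TRUE), 50)
  m3 <- tiny_matrix(v, item_ids = paste0("IP", 1:65))
  rev <- c("IP6", "IP13", "IP21", "IP55")
  naive <- sapply(seq_len(50), function(i) {
    s <- 0
    for (j in seq_len(65)) {
      x <- v[i, j]
      id <- paste0("IP", j)
      s <- s + if (id %in% rev) 8 - x else x
    }
    s
  })
  expect_equal(unname(score_total(m3, reverse = rev)), naive)
  # permutation invariance in item order
  perm <- sample(m3$item_ids)
  expect_equal(score_total(m3, items = perm, reverse = rev),
               score_total(m3, reverse = rev))
  expect_error(score_total(m3, items = "IP99"), "unknown item")
})

test_that("pooled-SD Cohen's d reproduces published worked examples", {
  expect_equal(round(cohens_d(group_summary(103.43, 17.34, 196),
                              group_summary(49.08, 19.26, 196)), 2), 2.97)
  expect_equal(round(cohens_d(group_summary(106.00, 14.60, 30),
                              group_summary(45.00, 18.36, 30)), 2), 3.68)
  expect_equal(cohens_d(group_summary(5, 2, 10), group_summary(5, 3, 12)), 0)
})

test_that("Cohen's d is antisymmetric and affine invariant", {
  set.seed(3)
  for (i in 1:5) {
    a <- summarise_group(rnorm(20, 1))
    b <- summarise_group(rnorm(25))
    expect_equal(cohens_d(a, b), -cohens_d(b, a))
    resc <- function(g, mult, add)
      group_summary(g$mean * mult + add, g$sd * mult, g$n)
    expect_equal(cohens_d(resc(a, 3.2, -7), resc(b, 3.2, -7)),
                 cohens_d(a, b), tolerance = 1e-12)
  }
  expect_error(cohens_d(group_summary(1, 0, 5), group_summary(2, 0, 5)),
               "undefined")
})

test_that("Welch t matches published values, t.test, and its df bounds", {
  w <- welch_t(group_summary(32.43, 10.66, 30), group_summary(33.73, 9.69, 30))
  expect_equal(round(w$t, 2), -0.49)
  expect_equal(welch_t(group_summary(5, 2, 10), group_summary(5, 2, 10))$t, 0)
  set.seed(4)
  for (i in 1:5) {
    x <- rnorm(12, 1, 2); y <- rnorm(17)
    w <- welch_t(x, y)
    tt <- stats::t.test(x, y)
    expect_equal(w$t, unname(tt$statistic), tolerance = 1e-12)
    expect_equal(w$df, unname(tt$parameter), tolerance = 1e-12)
    expect_equal(w$p, tt$p.value, tolerance = 1e-12)
    expect_gte(w$df, min(12, 17) - 1)
    expect_lte(w$df, 12 + 17 - 2)
  }
})

test_that("Cronbach's alpha matches the equicorrelated closed form and the covariance oracle", {
  sigma <- matrix(0.5, 10, 10); diag(sigma) <- 1
  x <- exact_cov_data(60, sigma)
  expect_equal(cronbach_alpha(x), 10 * 0.5 / (1 + 9 * 0.5), tolerance = 1e-12)

  set.seed(5)
  z <- rnorm(30)
  expect_equal(cronbach_alpha(cbind(z, z)), 1, tolerance = 1e-12)

  v <- matrix(rnorm(40 * 5), 40)
  C <- stats::cov(v)
  oracle <- 5 / 4 * (1 - sum(diag(C)) / sum(C))
  expect_equal(cronbach_alpha(v), oracle, tolerance = 1e-12)
  expect_lte(cronbach_alpha(v), 1)
})

test_that("pearson_r matches a naive sum formula and rejects degenerate input", {
  x <- rnorm(20)
  expect_equal(pearson_r(x, x), 1)
  expect_equal(pearson_r(x, -x), -1)
  set.seed(6)
  y <- rnorm(20)
  naive <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(pearson_r(x, y), naive, tolerance = 1e-12)
  expect_error(pearson_r(x, rep(1, 20)), "zero variance")
})

test_that("HC3 standard errors equal the explicit sandwich formula", {
  set.seed(7)
  n <- 40
  X <- cbind(1, rnorm(n), runif(n))
  y <- X %*% c(2, -1, 0.5) + rnorm(n, sd = abs(X[, 2]) + 0.3)
  fit <- ols_hc3(y, X)
  b <- solve(crossprod(X), crossprod(X, y))
  e <- as.numeric(y - X %*% b)
  h <- diag(X %*% solve(crossprod(X)) %*% t(X))
  meat <- t(X) %*% diag(e^2 / (1 - h)^2) %*% X
  vc <- solve(crossprod(X)) %*% meat %*% solve(crossprod(X))
  expect_equal(unname(fit$se_hc3), sqrt(diag(vc)), tolerance = 1e-10)
  expect_equal(unname(fit$coefficients), as.numeric(b), tolerance = 1e-10)
  expect_equal(unname(fit$t[fit$se_hc3 > 0]),
               unname((fit$coefficients / fit$se_hc3)[fit$se_hc3 > 0]))
  expect_equal(unname(fit$leverage), h, tolerance = 1e-10)
})

test_that("exact linear data gives zero HC3 SEs and R2 of 1", {
  X <- cbind(1, 1:10)
  y <- 3 + 2 * (1:10)
  fit <- suppressWarnings(ols_hc3(y, X))   # lm flags the perfect fit
  expect_equal(unname(fit$se_hc3), c(0, 0), tolerance = 1e-10)
  expect_equal(fit$r_squared, 1)
})

test_that("HC3 agrees with classical OLS SEs under homoscedasticity", {
  set.seed(8)
  n <- 10000
  X <- cbind(1, rnorm(n))
  y <- X %*% c(1, 2) + rnorm(n)
  fit <- ols_hc3(y, X)
  se_ols <- sqrt(diag(solve(crossprod(X)) * sum((y - X %*% solve(crossprod(X), crossprod(X, y)))^2) / (n - 2)))
  expect_true(all(abs(fit$se_hc3 / se_ols - 1) < 0.05))
  expect_error(ols_hc3(y, cbind(X, X[, 2])), "rank deficient")
})
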