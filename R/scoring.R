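#' Group summary statistics
#'
#' A tiny container for the mean, sample standard deviation (n - 1
#' denominator) and size of one group, the form in which published tables
#' report group results.
#'
#' @param mean group mean.
#' @param sd sample standard deviation (must be >= 0).
#' @param n group size (must be >= 2).
#' @return An object of class `group_summary`.
#' @export
group_summary <- function(mean, sd, n) {
  stopifnot(is.finite(mean), is.finite(sd), sd >= 0, n >= 2)
  structure(list(mean = mean, sd = sd, n = as.integer(n)),
            class = "group_summary")
}

#' Summarise one group of a numeric vector
#'
#' @param x numeric vector of scores for one group.
#' @return A [group_summary()].
#' @export
summarise_group <- function(x) {
  group_summary(mean(x), stats::sd(x), length(x))
}

#' Total questionnaire score with reverse-coding
#'
#' The total is the plain sum of ratings over the item subset; a
#' reverse-keyed item on a `1..K` scale contributes `K + 1 - x`.
#'
#' @param matrix a [response_matrix()].
#' @param items item ids to sum over (default: all).
#' @param reverse item ids (within `items`) scored in reverse.
#' @return Named numeric vector of per-participant totals.
#' @export
score_total <- function(matrix, items = matrix$item_ids, reverse = character()) {
  stopifnot(inherits(matrix, "response_matrix"))
  unknown <- setdiff(c(items, reverse), matrix$item_ids)
  if (length(unknown))
    stop("unknown item id(s): ", paste(unknown, collapse = ", "))
  v <- matrix$values[, items, drop = FALSE]
  rev_in <- intersect(reverse, items)
  if (length(rev_in))
    v[, rev_in] <- matrix$n_categories + 1L - v[, rev_in]
  totals <- rowSums(v)
  names(totals) <- matrix$participant_ids
  totals
}

#' Cohen's d from group summaries (pooled SD)
#'
#' `d = (m_a - m_b) / s_p` with the pooled standard deviation
#' `s_p = sqrt(((n_a - 1) s_a^2 + (n_b - 1) s_b^2) / (n_a + n_b - 2))`.
#'
#' @param a,b [group_summary()] objects (or numeric vectors, which are
#'   summarised first).
#' @return Cohen's d (signed, a minus b).
#' @export
cohens_d <- function(a, b) {
  if (is.numeric(a)) a <- summarise_group(a)
  if (is.numeric(b)) b <- summarise_group(b)
  stopifnot(inherits(a, "group_summary"), inherits(b, "group_summary"))
  if (a$sd == 0 && b$sd == 0)
    stop("Cohen's d undefined: both group standard deviations are zero")
  sp <- sqrt(((a$n - 1) * a$sd^2 + (b$n - 1) * b$sd^2) / (a$n + b$n - 2))
  (a$mean - b$mean) / sp
}

#' Welch's t test from group summaries
#'
#' @param a,b [group_summary()] objects (or numeric vectors).
#' @return List with `t`, `df` (Welch-Satterthwaite) and two-sided `p`.
#' @export
welch_t <- function(a, b) {
  if (is.numeric(a)) a <- summarise_group(a)
  if (is.numeric(b)) b <- summarise_group(b)
  stopifnot(inherits(a, "group_summary"), inherits(b, "group_summary"))
  if (a$sd == 0 && b$sd == 0)
    stop("Welch t undefined: both group standard deviations are zero")
  va <- a$sd^2 / a$n
  vb <- b$sd^2 / b$n
  t <- (a$mean - b$mean) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (a$n - 1) + vb^2 / (b$n - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' Item-level Cohen's d for every item of a response matrix
#'
#' Computes case-minus-comparison pooled-SD d per item, after reverse-coding
#' the items named in `reverse` so that all d values are on the keyed scale.
#'
#' @param matrix a [response_matrix()].
#' @param reverse reverse-keyed item ids.
#' @return Named numeric vector of d values, one per item.
#' @export
item_discrimination <- function(matrix, reverse = character()) {
  stopifnot(inherits(matrix, "response_matrix"))
  m <- recode_reversed(matrix, intersect(reverse, matrix$item_ids))
  is_case <- m$group == "case"
  vapply(seq_along(m$item_ids), function(j) {
    cohens_d(m$values[is_case, j], m$values[!is_case, j])
  }, numeric(1)) |> stats::setNames(m$item_ids)
}

#' Cronbach's alpha
#'
#' `alpha = k/(k - 1) * (1 - sum(item variances) / var(total))`, with sample
#' (n - 1) variances throughout.
#'
#' @param matrix a [response_matrix()] or a numeric matrix of item scores.
#' @param items item ids (response_matrix input only; default all).
#' @return Cronbach's alpha (scalar, <= 1).
#' @export
cronbach_alpha <- function(matrix, items = NULL) {
  if (inherits(matrix, "response_matrix")) {
    if (is.null(items)) items <- matrix$item_ids
    v <- matrix$values[, items, drop = FALSE]
  } else {
    v <- as.matrix(matrix)
    if (!is.null(items)) v <- v[, items, drop = FALSE]
  }
  k <- ncol(v)
  if (k < 2) stop("alpha needs at least 2 items")
  total_var <- stats::var(rowSums(v))
  if (total_var == 0) stop("alpha undefined: zero total-score variance")
  item_vars <- apply(v, 2, stats::var)
  k / (k - 1) * (1 - sum(item_vars) / total_var)
}

#' Pearson correlation with input checks
#'
#' @param x,y numeric vectors of equal length >= 3 with nonzero variance.
#' @return Product-moment correlation.
#' @export
pearson_r <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined: zero variance")
  stats::cor(x, y)
}

#' OLS regression with HC3 heteroscedasticity-consistent standard errors
#'
#' Fits `y` on the given design by least squares and reports the HC3
#' sandwich standard errors
#' `(X'X)^-1 X' diag(e_i^2 / (1 - h_i)^2) X (X'X)^-1`, the corresponding t
#' statistics, R-squared and hat-diagonal leverages.
#'
#' @param y numeric response.
#' @param design numeric model matrix (include the intercept column
#'   yourself), or a `formula` with `data` supplied.
#' @param data data frame used when `design` is a formula.
#' @return An object of class `ols_hc3`: list with `coefficients`, `se_hc3`,
#'   `t`, `p`, `r_squared`, `leverage`, and the underlying `lm` fit.
#' @export
ols_hc3 <- function(y, design, data = NULL) {
  if (inherits(design, "formula")) {
    fit <- stats::lm(design, data = data)
  } else {
    design <- as.matrix(design)
    if (nrow(design) != length(y)) stop("design rows must match length(y)")
    if (qr(design)$rank < ncol(design)) stop("design matrix is rank deficient")
    fit <- stats::lm(y ~ design - 1)
  }
  h <- stats::hatvalues(fit)
  if (any(h >= 1 - 1e-12)) stop("leverage of 1: HC3 weights undefined")
  vc <- sandwich::vcovHC(fit, type = "HC3")
  b <- stats::coef(fit)
  se <- sqrt(diag(vc))
  tval <- ifelse(se > 0, b / se, 0)
  rdf <- fit$df.residual
  structure(
    list(coefficients = b, se_hc3 = se, t = tval,
         p = 2 * stats::pt(-abs(tval), rdf),
         r_squared = summary(fit)$r.squared,
         leverage = h, lm_fit = fit),
    class = "ols_hc3")
}

#' @export
print.ols_hc3 <- function(x, ...) {
  cat("OLS fit with HC3 robust standard errors\n")
  tab <- cbind(Estimate = x$coefficients, `HC3 SE` = x$se_hc3,
               t = x$t, `Pr(>|t|)` = x$p)
  stats::printCoefmat(tab, P.values = TRUE, has.Pvalue = TRUE)
  cat(sprintf("R-squared: %.4f\n", x$r_squared))
  invisible(x)
}
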