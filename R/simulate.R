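#' Configuration for the two-group graded-threshold simulator
#'
#' Responses are generated from a graded-response-style discretisation of a
#' normal latent variable: for item i, the latent response is
#' `y* = lambda_i' f + shift_i * [group == case] + e_i`, with factors
#' `f ~ N(0, Phi)`, independent residual `e_i ~ N(0, 1 - communality_i)` (so
#' the latent response has unit variance in the comparison group), and the
#' observed rating is the category of `y*` in the ordered threshold grid.
#' Reverse-keyed items are emitted on the reversed scale (`K + 1 - x`).
#'
#' @param n_per_group integer pair: cases, comparisons.
#' @param n_items number of items (default 65).
#' @param n_factors number of latent factors (default 2).
#' @param loadings item x factor matrix, entries in `[0, 1]`; row
#'   communalities (`diag(L Phi L')`) must not exceed 1. Default: a balanced
#'   block structure with loadings 0.7.
#' @param factor_correlation correlation between factors (scalar, applied to
#'   all off-diagonal cells) or a full positive-definite correlation matrix.
#' @param group_shift per-item latent mean offset applied to the case group;
#'   scalar recycled. A shift proportional to `loadings %*% alpha` corresponds
#'   to a pure latent factor-mean difference (scalar-invariant generation);
#'   arbitrary per-item shifts are allowed for calibrating discrimination
#'   profiles.
#' @param thresholds per-item ordered cut points (length `n_categories - 1`):
#'   a matrix with one row per item, or a single vector recycled to all items.
#'   Default: equally spaced, symmetric about 0 (`-2.5, -1.5, ..., 2.5`).
#' @param reverse_items item ids emitted reverse-keyed. Default
#'   `IP6, IP13, IP21, IP55` when `n_items >= 55`, otherwise none.
#' @param noninvariance optional measurement-noninvariance perturbation for
#'   the case group: a list with optional elements `loadings` (item x factor
#'   matrix added to the case-group loadings) and `thresholds` (item x cut
#'   matrix added to the case-group thresholds). Zero perturbations reproduce
#'   the invariant output exactly.
#' @param n_categories number of ordered categories (default 7).
#' @param seed integer RNG seed.
#'
#' @return An object of class `sim_config`.
#' @seealso [generate_responses()], [induce_d_profile()]
#' @export
sim_config <- function(n_per_group = c(196L, 196L),
                       n_items = 65L,
                       n_factors = 2L,
                       loadings = NULL,
                       factor_correlation = 0.58,
                       group_shift = 0,
                       thresholds = NULL,
                       reverse_items = NULL,
                       noninvariance = NULL,
                       n_categories = 7L,
                       seed = 1L) {
  n_items <- as.integer(n_items)
  n_factors <- as.integer(n_factors)
  stopifnot(length(n_per_group) == 2, all(n_per_group >= 1),
            n_items >= 1, n_factors >= 1)
  item_ids <- paste0("IP", seq_len(n_items))

  if (is.null(loadings)) {
    loadings <- matrix(0, n_items, n_factors)
    block <- rep(seq_len(n_factors), length.out = n_items)
    block <- sort(block)
    loadings[cbind(seq_len(n_items), block)] <- 0.7
  }
  loadings <- as.matrix(loadings)
  if (nrow(loadings) != n_items || ncol(loadings) != n_factors)
    stop("loadings must be n_items x n_factors")

  if (is.matrix(factor_correlation)) {
    phi <- factor_correlation
  } else {
    phi <- matrix(factor_correlation, n_factors, n_factors)
    diag(phi) <- 1
  }
  if (n_factors > 1) {
    ev <- eigen(phi, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 0) stop("factor correlation matrix must be positive definite")
  }

  communality <- rowSums((loadings %*% phi) * loadings)
  if (any(communality > 1 + 1e-12))
    stop("communality > 1 for item(s): ",
         paste(item_ids[communality > 1 + 1e-12], collapse = ", "))

  if (is.null(thresholds))
    thresholds <- seq(-2.5, 2.5, length.out = n_categories - 1L)
  if (!is.matrix(thresholds))
    thresholds <- matrix(thresholds, n_items, n_categories - 1L, byrow = TRUE)
  if (ncol(thresholds) != n_categories - 1L || nrow(thresholds) != n_items)
    stop("thresholds must be n_items x (n_categories - 1)")
  if (any(apply(thresholds, 1, function(r) any(diff(r) <= 0))))
    stop("thresholds must be strictly increasing per item")

  if (is.null(reverse_items))
    reverse_items <- intersect(c("IP6", "IP13", "IP21", "IP55"), item_ids)
  if (length(setdiff(reverse_items, item_ids)))
    stop("reverse_items contains unknown item ids")

  group_shift <- rep_len(group_shift, n_items)

  if (!is.null(noninvariance)) {
    if (!is.null(noninvariance$loadings)) {
      noninvariance$loadings <- as.matrix(noninvariance$loadings)
      stopifnot(dim(noninvariance$loadings) == dim(loadings))
    }
    if (!is.null(noninvariance$thresholds)) {
      noninvariance$thresholds <- as.matrix(noninvariance$thresholds)
      stopifnot(dim(noninvariance$thresholds) == dim(thresholds))
    }
  }

  structure(
    list(n_per_group = as.integer(n_per_group), n_items = n_items,
         n_factors = n_factors, loadings = loadings, phi = phi,
         group_shift = group_shift, thresholds = thresholds,
         reverse_items = as.character(reverse_items),
         noninvariance = noninvariance,
         n_categories = as.integer(n_categories),
         item_ids = item_ids, seed = as.integer(seed)),
    class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("Simulation config: %d + %d participants, %d items, %d factor(s)\n",
              x$n_per_group[1], x$n_per_group[2], x$n_items, x$n_factors))
  cat(sprintf("  reverse-keyed: %s; seed %d\n",
              if (length(x$reverse_items)) paste(x$reverse_items, collapse = ", ")
              else "none", x$seed))
  invisible(x)
}

# Category probabilities of a thresholded normal latent with mean mu, sd sigma.
# tau is the vector of interior cut points; returns length(tau) + 1 probs.
category_probs <- function(tau, mu = 0, sigma = 1) {
  p <- stats::pnorm(c(tau, Inf), mean = mu, sd = sigma) -
    stats::pnorm(c(-Inf, tau), mean = mu, sd = sigma)
  pmax(p, 0)
}

# Mean and variance of the observed 1..K rating implied by the threshold model.
implied_item_moments <- function(tau, mu = 0, sigma = 1) {
  p <- category_probs(tau, mu, sigma)
  k <- seq_along(p)
  m <- sum(k * p)
  v <- sum(k^2 * p) - m^2
  list(mean = m, var = v, probs = p)
}

#' Model-implied observed-scale Cohen's d for a thresholded item
#'
#' For an item with unit latent-response variance in both groups and a case
#' latent mean offset `shift`, computes the pooled-SD standardized mean
#' difference of the observed 1..K rating from the exact category
#' probabilities of the threshold model (equal group sizes assumed for the
#' pooling).
#'
#' @param tau ordered cut points of the item.
#' @param shift case-group latent mean offset.
#' @return The model-implied observed-scale Cohen's d (a scalar).
#' @export
implied_observed_d <- function(tau, shift) {
  a <- implied_item_moments(tau, mu = shift)
  b <- implied_item_moments(tau, mu = 0)
  (a$mean - b$mean) / sqrt((a$var + b$var) / 2)
}

#' Serialise a simulation configuration as JSON
#'
#' @param config a [sim_config()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_sim_config <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  jsonlite::write_json(
    list(n_per_group = config$n_per_group, n_items = config$n_items,
         n_factors = config$n_factors, loadings = config$loadings,
         factor_correlation = config$phi, group_shift = config$group_shift,
         thresholds = config$thresholds, reverse_items = config$reverse_items,
         noninvariance = config$noninvariance,
         n_categories = config$n_categories, seed = config$seed),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Generate a two-group ordinal response matrix
#'
#' Draws from the graded-threshold factor model described in [sim_config()].
#' Deterministic for a fixed config seed.
#'
#' @param config a [sim_config()].
#' @return A [response_matrix()]; cases come first, then comparisons.
#' @export
generate_responses <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n_case <- config$n_per_group[1]
  n_comp <- config$n_per_group[2]
  n <- n_case + n_comp
  p <- config$n_items
  group <- rep(c("case", "comparison"), c(n_case, n_comp))

  chol_phi <- chol(config$phi)
  f <- matrix(stats::rnorm(n * config$n_factors), n) %*% chol_phi

  # per-group measurement parameters (case group may be perturbed)
  pert_l <- matrix(0, p, config$n_factors)
  pert_t <- matrix(0, p, config$n_categories - 1L)
  if (!is.null(config$noninvariance)) {
    if (!is.null(config$noninvariance$loadings)) pert_l <- config$noninvariance$loadings
    if (!is.null(config$noninvariance$thresholds)) pert_t <- config$noninvariance$thresholds
  }
  load_case <- config$loadings + pert_l
  thr_case <- config$thresholds + pert_t
  comm_case <- pmin(rowSums((load_case %*% config$phi) * load_case), 1)
  comm_comp <- rowSums((config$loadings %*% config$phi) * config$loadings)

  eps <- matrix(stats::rnorm(n * p), n, p)
  is_case <- group == "case"
  ystar <- matrix(0, n, p)
  ystar[is_case, ] <- f[is_case, , drop = FALSE] %*% t(load_case) +
    eps[is_case, , drop = FALSE] %*% diag(sqrt(1 - comm_case), p) +
    matrix(config$group_shift, sum(is_case), p, byrow = TRUE)
  ystar[!is_case, ] <- f[!is_case, , drop = FALSE] %*% t(config$loadings) +
    eps[!is_case, , drop = FALSE] %*% diag(sqrt(1 - comm_comp), p)

  x <- matrix(1L, n, p)
  for (j in seq_len(p)) {
    x[is_case, j] <- findInterval(ystar[is_case, j], thr_case[j, ]) + 1L
    x[!is_case, j] <- findInterval(ystar[!is_case, j], config$thresholds[j, ]) + 1L
  }
  rev_idx <- match(config$reverse_items, config$item_ids)
  if (length(rev_idx))
    x[, rev_idx] <- config$n_categories + 1L - x[, rev_idx]

  out <- response_matrix(x, group, item_ids = config$item_ids,
                         n_categories = config$n_categories)
  stopifnot(nlevels(droplevels(out$group)) == 2L)   # both groups present
  out
}

#' Calibrate per-item group shifts to a target discrimination profile
#'
#' Sets `group_shift` so that the model-implied observed-scale Cohen's d of
#' each item (computed from the exact category probabilities of the threshold
#' model, see [implied_observed_d()]) matches `target_d` to within `tol`.
#'
#' @param target_d per-item target d (non-negative; scalar recycled).
#' @param config a [sim_config()].
#' @param tol matching tolerance on the d scale (default 1e-3).
#' @return The config with `group_shift` replaced by the calibrated offsets.
#' @export
induce_d_profile <- function(target_d, config, tol = 1e-3) {
  stopifnot(inherits(config, "sim_config"))
  target_d <- rep_len(target_d, config$n_items)
  if (any(!is.finite(target_d)) || any(target_d < 0))
    stop("target_d must be finite and >= 0")
  shift <- numeric(config$n_items)
  upper <- 12
  for (j in seq_len(config$n_items)) {
    if (target_d[j] == 0) { shift[j] <- 0; next }
    tau <- config$thresholds[j, ]
    d_max <- implied_observed_d(tau, upper)
    if (d_max < target_d[j])
      stop(sprintf(
        "target d = %.3f unreachable for item %s (saturates at %.3f): ratings pile up in the top category",
        target_d[j], config$item_ids[j], d_max))
    root <- stats::uniroot(function(s) implied_observed_d(tau, s) - target_d[j],
                           lower = 0, upper = upper, tol = 1e-9)$root
    if (abs(implied_observed_d(tau, root) - target_d[j]) > tol)
      stop(sprintf("calibration failed for item %s", config$item_ids[j]))
    shift[j] <- root
  }
  config$group_shift <- shift
  config
}
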