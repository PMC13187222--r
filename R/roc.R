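# Discriminative validation: ROC curve, AUC, Youden-optimal threshold,
# confusion-matrix metrics.

#' ROC curve and AUC for a two-group score
#'
#' The threshold grid is the set of midpoints between adjacent distinct
#' observed scores, plus sentinels below and above all scores; at threshold
#' `t` a participant is predicted "case" iff `score > t`. The AUC is the
#' tie-corrected Mann-Whitney statistic (ties credited 1/2), which equals
#' the trapezoidal area under the empirical curve.
#'
#' @param scores numeric vector.
#' @param labels binary labels: a factor/character with `"case"` and
#'   `"comparison"`, or logical/0-1 with `TRUE`/1 = case.
#' @param direction `"auto"` (flip so cases are the higher-scoring class if
#'   their mean is higher), `"case_high"` or `"case_low"`.
#' @return An object of class `roc_result`: `thresholds`, `sensitivity`,
#'   `specificity`, `auc`, `youden_threshold`, `youden_J`, plus the
#'   operating point at the Youden threshold (`sens`, `spec`, `accuracy`,
#'   `confusion`).
#' @export
roc_curve <- function(scores, labels, direction = c("auto", "case_high", "case_low")) {
  direction <- match.arg(direction)
  is_case <- normalise_labels(labels)
  if (!any(is_case) || all(is_case)) stop("both classes must be present")
  if (direction == "auto")
    direction <- if (mean(scores[is_case]) >= mean(scores[!is_case]))
      "case_high" else "case_low"
  s <- if (direction == "case_low") -scores else scores

  us <- sort(unique(s))
  grid <- c(us[1] - 1, if (length(us) > 1) (us[-1] + us[-length(us)]) / 2,
            us[length(us)] + 1)
  n_case <- sum(is_case)
  n_comp <- sum(!is_case)
  sens <- spec <- numeric(length(grid))
  for (i in seq_along(grid)) {
    pred <- s > grid[i]
    sens[i] <- sum(pred & is_case) / n_case
    spec[i] <- sum(!pred & !is_case) / n_comp
  }
  # tie-corrected Mann-Whitney AUC
  r <- rank(s)
  auc <- (sum(r[is_case]) - n_case * (n_case + 1) / 2) / (n_case * n_comp)

  J <- sens + spec - 1
  jmax <- max(J)
  cand <- which(J >= jmax - 1e-12)
  # ties: prefer the more balanced operating point, then the lower threshold
  balance <- abs(sens[cand] - spec[cand])
  cand <- cand[balance <= min(balance) + 1e-12]
  best <- cand[which.min(grid[cand])]
  thr <- grid[best]
  pred <- s > thr
  conf <- confusion_counts(tp = sum(pred & is_case), fp = sum(pred & !is_case),
                           tn = sum(!pred & !is_case), fn = sum(!pred & is_case))
  # report thresholds on the original score scale
  sign_fix <- if (direction == "case_low") -1 else 1
  structure(
    list(thresholds = sign_fix * grid, sensitivity = sens, specificity = spec,
         auc = auc, youden_threshold = sign_fix * thr, youden_J = jmax,
         sens = sens[best], spec = spec[best],
         accuracy = (conf$tp + conf$tn) / (n_case + n_comp),
         confusion = conf, direction = direction),
    class = "roc_result")
}

normalise_labels <- function(labels) {
  if (is.logical(labels)) return(labels)
  if (is.numeric(labels)) return(labels == 1)
  lab <- as.character(labels)
  if (all(lab %in% c("case", "comparison"))) return(lab == "case")
  u <- sort(unique(lab))
  if (length(u) != 2) stop("labels must have exactly 2 levels")
  lab == u[1]
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC: AUC = %.3f, Youden threshold = %.4g (J = %.3f)\n",
              x$auc, x$youden_threshold, x$youden_J))
  cat(sprintf("  at threshold: sensitivity %.3f, specificity %.3f, accuracy %.3f\n",
              x$sens, x$spec, x$accuracy))
  invisible(x)
}

#' @export
plot.roc_result <- function(x, ...) {
  ord <- order(1 - x$specificity, x$sensitivity)
  graphics::plot(1 - x$specificity[ord], x$sensitivity[ord], type = "l",
                 xlab = "1 - specificity", ylab = "sensitivity",
                 main = sprintf("ROC (AUC = %.3f)", x$auc), ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}

#' Youden-optimal operating point of a ROC result
#'
#' Argmax of `J = sensitivity + specificity - 1` over the threshold grid;
#' ties are broken toward the more balanced sensitivity/specificity pair,
#' then toward the lower threshold.
#'
#' @param roc a [roc_curve()] result.
#' @return List with `threshold`, `sensitivity`, `specificity`, `accuracy`,
#'   `J`.
#' @export
youden_optimal <- function(roc) {
  stopifnot(inherits(roc, "roc_result"))
  list(threshold = roc$youden_threshold, sensitivity = roc$sens,
       specificity = roc$spec, accuracy = roc$accuracy, J = roc$youden_J)
}

#' Confusion-matrix counts
#'
#' @param tp,fp,tn,fn non-negative integer counts.
#' @return An object of class `confusion_counts`.
#' @export
confusion_counts <- function(tp, fp, tn, fn) {
  stopifnot(tp >= 0, fp >= 0, tn >= 0, fn >= 0)
  structure(list(tp = as.integer(tp), fp = as.integer(fp),
                 tn = as.integer(tn), fn = as.integer(fn)),
            class = "confusion_counts")
}

#' Sensitivity, specificity and accuracy from confusion counts
#'
#' @param c a [confusion_counts()] object.
#' @return List with `sensitivity = tp/(tp+fn)`,
#'   `specificity = tn/(tn+fp)`, `accuracy = (tp+tn)/total`.
#' @export
confusion_metrics <- function(c) {
  stopifnot(inherits(c, "confusion_counts"))
  if (c$tp + c$fn == 0 || c$tn + c$fp == 0)
    stop("both classes must be non-empty")
  total <- c$tp + c$fp + c$tn + c$fn
  list(sensitivity = c$tp / (c$tp + c$fn),
       specificity = c$tn / (c$tn + c$fp),
       accuracy = (c$tp + c$tn) / total)
}

#' Export a ROC curve as CSV
#'
#' @param roc a [roc_curve()] result.
#' @param path output path; columns `threshold`, `sensitivity`,
#'   `specificity`.
#' @return `path`, invisibly.
#' @export
write_roc <- function(roc, path) {
  stopifnot(inherits(roc, "roc_result"))
  utils::write.csv(data.frame(threshold = roc$thresholds,
                              sensitivity = roc$sensitivity,
                              specificity = roc$specificity),
                   path, row.names = FALSE)
  invisible(path)
}
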