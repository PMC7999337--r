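#' @title ROC/AUC evaluation against FISH truth
#' @description Per-event SV support counts are scored against FISH truth
#'   labels over the (sample, event) grid. Sweeping a threshold over the
#'   unique support scores yields the ROC curve (sensitivity vs
#'   1 - specificity); the area under the curve is computed by the
#'   trapezoid rule, which gives ties half credit and makes the AUC equal
#'   to the Mann-Whitney concordance probability.
#' @name roc_eval
NULL

# align a prediction matrix and truth table over the identical grid;
# returns tibble with columns score, label
align_grid_ <- function(pred, truth, method = NULL) {
  if (!is.null(method)) pred <- pred[pred$method == method, , drop = FALSE]
  if ("method" %in% names(pred) && length(unique(pred$method)) > 1) {
    stop("prediction matrix spans multiple methods; pass `method =` to select one")
  }
  joined <- dplyr::full_join(
    dplyr::select(pred, "sample", "event_id", "score"),
    dplyr::select(truth, "sample", "event_id", "label"),
    by = c("sample", "event_id")
  )
  miss <- joined[is.na(joined$score) | is.na(joined$label), , drop = FALSE]
  if (nrow(miss) > 0) {
    stop("prediction and truth grids differ; mismatched cells: ",
         paste(utils::head(paste0(miss$sample, "/", miss$event_id), 10), collapse = ", "))
  }
  joined
}

#' Confusion counts at a score threshold
#'
#' A cell is predicted positive iff its support score is >= `threshold`.
#'
#' @param pred Long prediction tibble (`sample`, `event_id`, `score`),
#'   e.g. from [build_prediction_matrix()].
#' @param truth Long truth tibble (`sample`, `event_id`, `label`).
#' @param threshold Score threshold.
#' @param method Optional platform label to select from `pred`.
#' @return One-row tibble with `TP`, `FP`, `TN`, `FN`, `P`, `N`,
#'   `sensitivity` (TP/P) and `specificity` (TN/N).
#' @export
confusion_at_threshold <- function(pred, truth, threshold, method = NULL) {
  g <- align_grid_(pred, truth, method)
  yhat <- g$score >= threshold
  tp <- sum(yhat & g$label == 1L)
  fp <- sum(yhat & g$label == 0L)
  p <- sum(g$label == 1L)
  n <- sum(g$label == 0L)
  tibble::tibble(
    TP = tp, FP = fp, TN = n - fp, FN = p - tp, P = p, N = n,
    sensitivity = ifelse(p > 0, tp / p, NA_real_),
    specificity = ifelse(n > 0, (n - fp) / n, NA_real_)
  )
}

# trapezoid AUC over a threshold sweep of scores vs binary labels
auc_trapezoid_ <- function(score, label) {
  thresholds <- c(Inf, sort(unique(score), decreasing = TRUE))
  p <- sum(label == 1L)
  n <- sum(label == 0L)
  tpr <- vapply(thresholds, function(t) sum(score >= t & label == 1L) / p, numeric(1))
  fpr <- vapply(thresholds, function(t) sum(score >= t & label == 0L) / n, numeric(1))
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(thresholds = thresholds, tpr = tpr, fpr = fpr, auc = auc)
}

#' ROC curve and AUC of a prediction matrix against truth
#'
#' @inheritParams confusion_at_threshold
#' @param ci Also compute a percentile-bootstrap confidence interval for
#'   the AUC? Default `FALSE`.
#' @param n_boot Bootstrap replicates when `ci = TRUE`. Default 2000.
#' @param seed Seed for the bootstrap. Default 1.
#' @param conf Confidence level. Default 0.95.
#' @return An object of class `sv_roc`: list with `curve` (tibble
#'   `threshold`, `tpr`, `fpr`), `auc`, `P`, `N`, `method` and, when
#'   requested, `ci_low`/`ci_high`. Supports [tidy()], [glance()],
#'   [ggplot2::autoplot()].
#' @export
roc_curve <- function(pred, truth, method = NULL, ci = FALSE, n_boot = 2000,
                      seed = 1, conf = 0.95) {
  g <- align_grid_(pred, truth, method)
  p <- sum(g$label == 1L)
  n <- sum(g$label == 0L)
  if (p == 0 || n == 0) {
    stop("ROC undefined: need at least one positive and one negative label (P=",
         p, ", N=", n, ")")
  }
  sweep <- auc_trapezoid_(g$score, g$label)
  out <- structure(
    list(
      curve = tibble::tibble(threshold = sweep$thresholds,
                             tpr = sweep$tpr, fpr = sweep$fpr),
      auc = sweep$auc, P = p, N = n, method = method,
      scores = g$score, labels = g$label
    ),
    class = "sv_roc"
  )
  if (ci) {
    interval <- bootstrap_auc_ci(pred, truth, n_boot = n_boot, seed = seed,
                                 conf = conf, method = method)
    out$ci_low <- interval[["ci_low"]]
    out$ci_high <- interval[["ci_high"]]
  }
  out
}

#' Percentile bootstrap confidence interval for the AUC
#'
#' Resamples (sample, event) grid cells with replacement; degenerate
#' resamples (all-positive or all-negative) are redrawn. Reproducible under
#' a fixed seed.
#'
#' @inheritParams roc_curve
#' @param n_boot Number of bootstrap replicates (>= 100). Default 2000.
#' @return Named numeric vector `c(ci_low, ci_high)`.
#' @export
bootstrap_auc_ci <- function(pred, truth, n_boot = 2000, seed = 1, conf = 0.95,
                             method = NULL) {
  stopifnot(n_boot >= 100)
  g <- align_grid_(pred, truth, method)
  m <- nrow(g)
  aucs <- withr::with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      repeat {
        idx <- sample.int(m, m, replace = TRUE)
        lab <- g$label[idx]
        if (any(lab == 1L) && any(lab == 0L)) break
      }
      auc_trapezoid_(g$score[idx], lab)$auc
    }, numeric(1))
  })
  alpha <- (1 - conf) / 2
  q <- stats::quantile(aucs, c(alpha, 1 - alpha), names = FALSE)
  c(ci_low = q[1], ci_high = q[2])
}

#' @export
print.sv_roc <- function(x, ...) {
  cat("<sv_roc> AUC = ", format(x$auc, digits = 4),
      "  (P = ", x$P, ", N = ", x$N, ")\n", sep = "")
  if (!is.null(x$ci_low)) {
    cat("  95% bootstrap CI: [", format(x$ci_low, digits = 4), ", ",
        format(x$ci_high, digits = 4), "]\n", sep = "")
  }
  invisible(x)
}

#' Tidy an sv_roc object into its curve coordinates
#'
#' @param x An `sv_roc` object.
#' @param ... Unused.
#' @return Tibble with `threshold`, `tpr`, `fpr`.
#' @method tidy sv_roc
#' @export
tidy.sv_roc <- function(x, ...) {
  x$curve
}

#' One-row summary of an sv_roc object
#'
#' @param x An `sv_roc` object.
#' @param ... Unused.
#' @return Tibble with `auc`, `ci_low`, `ci_high`, `P`, `N`.
#' @method glance sv_roc
#' @export
glance.sv_roc <- function(x, ...) {
  tibble::tibble(
    auc = x$auc,
    ci_low = x$ci_low %||% NA_real_,
    ci_high = x$ci_high %||% NA_real_,
    P = x$P, N = x$N
  )
}

#' Plot an ROC curve
#'
#' @param object An `sv_roc` object.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot sv_roc
#' @export
autoplot.sv_roc <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step(linewidth = 0.8) +
    ggplot2::geom_point(size = 1.5) +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "False positive rate (1 - specificity)",
      y = "True positive rate (sensitivity)",
      title = sprintf("AUC = %.3f (P = %d, N = %d)", object$auc, object$P, object$N)
    ) +
    ggplot2::theme_minimal()
}
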