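#' Empirical AUC (normalized Mann-Whitney U)
#'
#' The nonparametric area under the ROC curve: the probability that a
#' random case scores higher than a random control, ties counted half --
#' computed via midranks as `U / (n_case * n_control)`.
#'
#' @param scores Per-subject numeric scores (marker values, probabilities).
#' @param labels Label tibble (`subject_id`, `status`) or 0/1 vector.
#' @return AUC in `[0, 1]`.
#' @export
empirical_auc <- function(scores, labels) {
  y <- status_vector(labels)
  if (length(scores) != length(y)) {
    stop_sispanel("`scores` and labels have different lengths.")
  }
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) {
    stop_sispanel("Both classes must be present to compute an AUC.")
  }
  r <- rank(scores)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Youden index
#'
#' `sensitivity + specificity - 1`.
#'
#' @param sensitivity,specificity Values in `[0, 1]`.
#' @return The Youden J statistic in `[-1, 1]`.
#' @export
youden_index <- function(sensitivity, specificity) {
  if (any(sensitivity < 0 | sensitivity > 1 | specificity < 0 | specificity > 1)) {
    stop_sispanel("Sensitivity and specificity must be in [0, 1].")
  }
  sensitivity + specificity - 1
}

#' ROC characterization and Youden-optimal cutoff for one marker
#'
#' Orients the marker so its AUC is >= 0.5 (`high_is_case` when larger
#' values indicate cases, `low_is_case` otherwise -- the latter yields a
#' "case if value <= c" decision rule). Candidate thresholds are the
#' midpoints between consecutive sorted unique values plus +/-Inf, so
#' sensitivity and specificity do not depend on >=/> boundary conventions;
#' the returned threshold maximizes the Youden index, ties broken toward
#' higher specificity.
#'
#' @param values Per-subject marker values (standardized scale in the
#'   standard pipeline).
#' @param labels Label tibble or 0/1 vector.
#' @return One-row tibble: `auc`, `direction`, `youden_threshold`,
#'   `youden_j`, `sensitivity`, `specificity`, `degenerate` (TRUE for a
#'   constant marker, which gets AUC 0.5 and J 0).
#' @export
roc_and_youden <- function(values, labels) {
  y <- status_vector(labels)
  auc0 <- empirical_auc(values, y)
  direction <- if (auc0 >= 0.5) "high_is_case" else "low_is_case"
  auc <- max(auc0, 1 - auc0)

  uq <- sort(unique(values))
  if (length(uq) < 2) {
    return(tibble::tibble(
      auc = 0.5, direction = direction, youden_threshold = NA_real_,
      youden_j = 0, sensitivity = NA_real_, specificity = NA_real_,
      degenerate = TRUE))
  }
  thr <- c(-Inf, (uq[-length(uq)] + uq[-1]) / 2, Inf)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  res <- purrr::map_dfr(thr, function(ct) {
    pred <- if (direction == "high_is_case") as.integer(values >= ct)
            else as.integer(values <= ct)
    tibble::tibble(
      threshold = ct,
      sensitivity = sum(pred == 1 & y == 1) / n1,
      specificity = sum(pred == 0 & y == 0) / n0
    )
  })
  res$j <- youden_index(res$sensitivity, res$specificity)
  ord <- order(-res$j, -res$specificity, -res$sensitivity)
  best <- res[ord[1], ]
  tibble::tibble(
    auc = auc, direction = direction, youden_threshold = best$threshold,
    youden_j = best$j, sensitivity = best$sensitivity,
    specificity = best$specificity, degenerate = FALSE
  )
}

#' Per-marker ROC table
#'
#' Runs [roc_and_youden()] on every requested marker of an expression
#' table.
#'
#' @param expr Expression tibble (standardized scale recommended, so the
#'   reported thresholds live on the standardized scale).
#' @param labels Label tibble or 0/1 vector.
#' @param markers Character vector of marker columns (default: all).
#' @return Tibble with one row per marker (`marker_id` first), sorted by
#'   descending AUC.
#' @export
marker_roc <- function(expr, labels, markers = NULL) {
  y <- status_vector(labels, expr)
  xm <- panel_design_matrix(expr, markers)
  out <- purrr::map_dfr(colnames(xm), function(mk) {
    dplyr::bind_cols(tibble::tibble(marker_id = mk),
                     roc_and_youden(xm[, mk], y))
  })
  out[order(-out$auc, out$marker_id), ]
}

#' Leave-one-out cross-validation of a fixed marker panel
#'
#' For each subject in turn, an unpenalized logistic model on the panel
#' markers is refit on the remaining n - 1 subjects and the held-out
#' subject's case probability is predicted; the subject is classified as a
#' case when the probability is `>= cutoff`. The panel itself is fixed:
#' marker selection is *not* repeated inside the loop, so the estimate
#' carries the usual post-selection optimism and measures the stability of
#' the chosen panel, not of the selection procedure. Folds that hit
#' separation are ridge-stabilized and flagged.
#'
#' An empty panel is allowed and fits intercept-only models -- a useful
#' pathology: on perfectly balanced labels every held-out subject is then
#' misclassified (the held-out case leaves a case minority behind, and
#' vice versa), giving accuracy 0.
#'
#' @param X Standardized expression tibble (or data frame / matrix).
#' @param y Label tibble or 0/1 vector.
#' @param panel Character vector of marker columns (may be empty).
#' @param cutoff Probability threshold (default 0.5; a probability exactly
#'   at the cutoff classifies as case).
#' @return A `loocv_result`: list with `predictions` (tibble `subject_id`,
#'   `prob`, `predicted`, `truth`, `separation`), `metrics` (one-row
#'   tibble as in [in_sample_metrics()]) and `panel`.
#' @export
loocv_panel <- function(X, y, panel, cutoff = 0.5) {
  truth <- status_vector(y, if (is.data.frame(X) && "subject_id" %in% names(X)) X else NULL)
  xm <- panel_design_matrix(X, if (length(panel) > 0) panel else NULL)
  if (length(panel) == 0) xm <- xm[, integer(0), drop = FALSE]
  n <- nrow(xm)
  if (n < 3) stop_sispanel("Need at least 3 subjects for LOOCV.")
  ids <- rownames(xm) %||% sprintf("subject_%d", seq_len(n))

  prob <- numeric(n); sep <- logical(n)
  for (i in seq_len(n)) {
    fit <- fit_logistic_stabilized(xm[-i, , drop = FALSE], truth[-i])
    eta <- fit$intercept +
      if (ncol(xm) > 0) sum(xm[i, ] * fit$coefficients) else 0
    prob[i] <- plogis(eta)
    sep[i] <- fit$separation
  }
  predicted <- as.integer(prob >= cutoff)
  structure(
    list(
      predictions = tibble::tibble(subject_id = ids, prob = prob,
                                   predicted = predicted, truth = truth,
                                   separation = sep),
      metrics = classification_metrics(predicted, truth, cutoff),
      panel = panel
    ),
    class = "loocv_result"
  )
}

#' @export
print.loocv_result <- function(x, ...) {
  m <- x$metrics
  cat(sprintf("<loocv_result> %d held-out predictions, panel of %d marker(s)\n",
              nrow(x$predictions), length(x$panel)))
  cat(sprintf("  accuracy %.3f, sensitivity %.3f, specificity %.3f (cutoff %.2f)\n",
              m$accuracy, m$sensitivity, m$specificity, m$cutoff))
  invisible(x)
}

#' @rdname loocv_panel
#' @param x,object A `loocv_result`.
#' @param ... Unused.
#' @export
tidy.loocv_result <- function(x, ...) {
  x$predictions
}

#' @rdname loocv_panel
#' @export
glance.loocv_result <- function(x, ...) {
  dplyr::bind_cols(x$metrics,
                   tibble::tibble(n = nrow(x$predictions),
                                  n_markers = length(x$panel)))
}

#' @rdname loocv_panel
#' @export
autoplot.loocv_result <- function(object, ...) {
  df <- object$predictions
  df$truth_lab <- factor(ifelse(df$truth == 1, "case", "control"),
                         levels = c("control", "case"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$truth_lab, y = .data$prob)) +
    ggplot2::geom_hline(yintercept = object$metrics$cutoff,
                        linetype = "dashed", linewidth = 0.3) +
    ggplot2::geom_jitter(ggplot2::aes(colour = .data$predicted == .data$truth),
                         width = 0.15, height = 0, size = 2, alpha = 0.8) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "#27ae60", `FALSE` = "#c0392b"),
                                 labels = c(`TRUE` = "correct", `FALSE` = "wrong"),
                                 name = NULL) +
    ggplot2::labs(x = NULL, y = "held-out case probability") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}
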