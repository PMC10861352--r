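#' Logistic biomarker-panel models
#'
#' A `panel_model` stores the intercept and per-marker coefficients of a
#' (possibly lasso-penalized) logistic model on the standardized scale:
#' each coefficient is the change in log-odds of case status per 1 SD of
#' the standardized marker, so `exp(beta)` is the odds-ratio factor per SD.
#'
#' @name panel_model
NULL

new_panel_model <- function(intercept, coefficients, lambda, strategy,
                            fit_meta = list()) {
  stopifnot(is.numeric(coefficients), !is.null(names(coefficients)))
  if (!all(is.finite(c(intercept, coefficients)))) {
    stop_sispanel("Panel model has non-finite coefficients.")
  }
  structure(
    list(intercept = unname(intercept), coefficients = coefficients,
         lambda = lambda, strategy = strategy, fit_meta = fit_meta),
    class = "panel_model"
  )
}

#' @export
print.panel_model <- function(x, ...) {
  nz <- sum(x$coefficients != 0)
  cat(sprintf("<panel_model> %d marker(s) with nonzero coefficient (of %d), intercept %.4g\n",
              nz, length(x$coefficients), x$intercept))
  cat(sprintf("  lambda = %s, strategy = %s%s\n",
              format(x$lambda, digits = 4), x$strategy,
              if (isTRUE(x$fit_meta$separation)) " [separation flagged]" else ""))
  invisible(x)
}

#' @rdname panel_model
#' @param x,object A `panel_model`.
#' @param ... Unused.
#' @return `tidy()`: tibble `term`, `estimate`, `odds_ratio` (the
#'   `exp(estimate)` odds-ratio factor per 1 SD), intercept first.
#' @export
tidy.panel_model <- function(x, ...) {
  tibble::tibble(
    term = c("(Intercept)", names(x$coefficients)),
    estimate = c(x$intercept, unname(x$coefficients)),
    odds_ratio = exp(c(x$intercept, unname(x$coefficients)))
  )
}

#' @rdname panel_model
#' @export
glance.panel_model <- function(x, ...) {
  tibble::tibble(
    n_markers = sum(x$coefficients != 0),
    lambda = x$lambda,
    strategy = x$strategy,
    separation = isTRUE(x$fit_meta$separation),
    aic = x$fit_meta$aic %||% NA_real_,
    logLik = x$fit_meta$loglik %||% NA_real_
  )
}

#' @rdname panel_model
#' @export
autoplot.panel_model <- function(object, ...) {
  td <- tidy(object)
  td <- td[td$term != "(Intercept)" & td$estimate != 0, ]
  td$term <- stats::reorder(td$term, td$estimate)
  ggplot2::ggplot(td, ggplot2::aes(x = .data$estimate, y = .data$term)) +
    ggplot2::geom_segment(ggplot2::aes(x = 0, xend = .data$estimate,
                                       yend = .data$term), linewidth = 0.3) +
    ggplot2::geom_point(size = 2, colour = "#c0392b") +
    ggplot2::geom_vline(xintercept = 0, linewidth = 0.3) +
    ggplot2::labs(x = "coefficient (log odds per 1 SD)", y = NULL) +
    ggplot2::theme_minimal()
}

resolve_lambda_strategy <- function(lambda_strategy) {
  if (is.numeric(lambda_strategy)) {
    if (lambda_strategy < 0) stop_sispanel("`lambda` must be >= 0.",
                                           class = "sispanel_config_error")
    return(list(kind = "fixed", lambda = lambda_strategy))
  }
  if (identical(lambda_strategy, "cv")) return(list(kind = "cv"))
  if (grepl("^support_size:[0-9]+$", lambda_strategy)) {
    k <- as.integer(sub("^support_size:", "", lambda_strategy))
    if (k < 1) stop_sispanel("support_size must be >= 1.",
                             class = "sispanel_config_error")
    return(list(kind = "support_size", k = k))
  }
  stop_sispanel(sprintf("Unknown lambda strategy `%s` (use \"cv\", \"support_size:K\" or a numeric lambda).",
                        lambda_strategy),
                class = "sispanel_config_error")
}

# stratified k-fold assignment, deterministic given the seed
stratified_folds <- function(y, k, seed) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  foldid <- integer(length(y))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    foldid[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  foldid
}

#' Fit a lasso-penalized logistic panel model
#'
#' Minimizes the L1-penalized binomial negative log-likelihood over the
#' supplied (already standardized) markers, intercept unpenalized and no
#' internal re-standardization, so coefficients stay on the per-1-SD scale.
#' The penalty weight is chosen by `lambda_strategy`:
#' * `"cv"` (default): 10-fold stratified cross-validated deviance, lambda
#'   at the minimum mean deviance, folds fixed by `seed`;
#' * `"support_size:K"`: the largest lambda on the path whose support has
#'   exactly K markers (if no path point has exactly K, the largest lambda
#'   with at least K is used and flagged in `fit_meta`);
#' * a numeric value: that lambda (0 = unpenalized maximum likelihood via
#'   iteratively reweighted least squares; complete separation is then
#'   flagged rather than "fixed").
#'
#' @param X Standardized expression tibble (or plain data frame / matrix of
#'   marker columns), typically restricted to the screened markers.
#' @param y Label tibble (`subject_id`, `status`) or 0/1 vector.
#' @param lambda_strategy `"cv"`, `"support_size:K"`, or a single
#'   non-negative number.
#' @param markers Optional character vector restricting `X`'s columns.
#' @param nfolds Folds for the `"cv"` strategy (default 10).
#' @param seed Seed for fold assignment (default 1); the fit itself is
#'   deterministic.
#' @return A [panel_model]; coefficients are stored for every supplied
#'   marker (zeros kept), `fit_meta` records solver diagnostics and a
#'   separation flag.
#' @export
fit_lasso_logistic <- function(X, y, lambda_strategy = "cv", markers = NULL,
                               nfolds = 10, seed = 1) {
  xm <- panel_design_matrix(X, markers)
  y <- status_vector(y, if (is.data.frame(X) && "subject_id" %in% names(X)) X else NULL)
  check_two_groups(y, min_per_group = 2L)
  if (nrow(xm) < 4) stop_sispanel("Need at least 4 subjects.")
  strat <- resolve_lambda_strategy(lambda_strategy)

  if (strat$kind == "fixed" && strat$lambda == 0) {
    fit <- fit_logistic_irls(xm, y, ridge = 0)
    if (!fit$converged && !fit$separation) {
      stop_sispanel(sprintf("Unpenalized logistic fit did not converge in %d iterations.",
                            fit$iter),
                    class = "sispanel_convergence_error")
    }
    return(new_panel_model(
      intercept = fit$intercept, coefficients = fit$coefficients,
      lambda = 0, strategy = "fixed:0",
      fit_meta = list(separation = fit$separation, iter = fit$iter,
                      loglik = fit$loglik, aic = fit$aic)
    ))
  }

  gfit <- glmnet::glmnet(xm, y, family = "binomial", standardize = FALSE,
                         nlambda = 200)
  meta <- list(separation = FALSE)
  if (strat$kind == "cv") {
    foldid <- stratified_folds(y, nfolds, seed)
    cvfit <- glmnet::cv.glmnet(xm, y, family = "binomial",
                               standardize = FALSE, foldid = foldid,
                               type.measure = "deviance")
    lambda <- cvfit$lambda.min
    strategy <- "cv"
    meta$nfolds <- nfolds
    meta$seed <- seed
  } else if (strat$kind == "support_size") {
    df <- gfit$df
    hit <- which(df == strat$k)
    if (length(hit) > 0) {
      lambda <- gfit$lambda[hit[1]]
    } else {
      ge <- which(df >= strat$k)
      if (length(ge) == 0) {
        stop_sispanel(sprintf("No lambda on the path yields a support of %d markers (max support %d).",
                              strat$k, max(df)),
                      class = "sispanel_config_error")
      }
      lambda <- gfit$lambda[ge[1]]
      meta$support_size_approximate <- TRUE
      warn(sprintf("No path point with exactly %d markers; using the largest lambda with >= %d.",
                   strat$k, strat$k))
    }
    strategy <- sprintf("support_size:%d", strat$k)
  } else {
    lambda <- strat$lambda
    strategy <- sprintf("fixed:%g", lambda)
  }

  cf <- as.matrix(coef(gfit, s = lambda, exact = TRUE, x = xm, y = y))
  beta <- setNames(cf[-1, 1], rownames(cf)[-1])
  new_panel_model(intercept = cf[1, 1], coefficients = beta,
                  lambda = lambda, strategy = strategy, fit_meta = meta)
}

panel_design_matrix <- function(X, markers = NULL) {
  xm <- if (is.matrix(X)) X
        else if (is.data.frame(X) && "subject_id" %in% names(X)) marker_matrix(X)
        else as.matrix(X)
  if (!is.null(markers)) {
    miss <- setdiff(markers, colnames(xm))
    if (length(miss) > 0) {
      stop_sispanel(sprintf("Marker column(s) missing from X: %s.",
                            paste(miss, collapse = ", ")))
    }
    xm <- xm[, markers, drop = FALSE]
  }
  storage.mode(xm) <- "double"
  xm
}

# Unpenalized (or ridge-stabilized) logistic regression by Newton/IRLS.
# ridge > 0 adds ridge*I to the Hessian (and the matching gradient term),
# bounding the estimate under complete or quasi-separation.
fit_logistic_irls <- function(xm, y, ridge = 0, max_iter = 100L, tol = 1e-10) {
  X1 <- cbind(`(Intercept)` = 1, xm)
  k <- ncol(X1)
  beta <- numeric(k)
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    eta <- drop(X1 %*% beta)
    mu <- plogis(eta)
    w <- mu * (1 - mu)
    score <- drop(crossprod(X1, y - mu)) - ridge * beta
    H <- crossprod(X1 * w, X1)
    diag(H) <- diag(H) + ridge + 1e-12
    step <- tryCatch(solve(H, score), error = function(e) NULL)
    if (is.null(step)) break
    # halve the step until the (penalized) log-likelihood does not decrease
    ll_old <- logistic_loglik(X1, y, beta) - ridge / 2 * sum(beta^2)
    lam <- 1
    repeat {
      cand <- beta + lam * step
      ll_new <- logistic_loglik(X1, y, cand) - ridge / 2 * sum(cand^2)
      if (is.finite(ll_new) && ll_new >= ll_old - 1e-12) break
      lam <- lam / 2
      if (lam < 1e-8) { cand <- beta; break }
    }
    delta <- max(abs(cand - beta))
    beta <- cand
    if (delta < tol) { converged <- TRUE; break }
  }
  eta <- drop(X1 %*% beta)
  mu <- plogis(eta)
  separation <- (any(mu > 1 - 1e-8 & y == 1) && any(mu < 1e-8 & y == 0)) ||
    (length(beta) > 1 && max(abs(beta[-1])) > 15 && all((mu >= 0.5) == (y == 1)))
  loglik <- logistic_loglik(X1, y, beta)
  aic <- -2 * loglik + 2 * k
  list(intercept = beta[1],
       coefficients = setNames(beta[-1], colnames(xm)),
       loglik = loglik, aic = aic, iter = iter,
       converged = converged || ridge > 0,
       separation = separation, ridge = ridge)
}

logistic_loglik <- function(X1, y, beta) {
  eta <- drop(X1 %*% beta)
  # log(1 + exp(eta)) without overflow
  lse <- ifelse(eta > 0, eta + log1p(exp(-eta)), log1p(exp(eta)))
  sum(y * eta - lse)
}

# Unpenalized fit with automatic ridge stabilization under separation:
# the spec'd behaviour for stepAIC candidates and LOOCV folds.
fit_logistic_stabilized <- function(xm, y, ridge = 1e-6) {
  fit <- fit_logistic_irls(xm, y, ridge = 0)
  if (!fit$converged || fit$separation) {
    fit <- fit_logistic_irls(xm, y, ridge = ridge)
    fit$separation <- TRUE
    # AIC/loglik evaluated at the stabilized estimate, unpenalized definition
    fit$aic <- -2 * fit$loglik + 2 * (ncol(xm) + 1)
  }
  fit
}

#' Markers retained by a fitted panel model
#'
#' Markers whose coefficient magnitude exceeds `tol` (default 1e-8, which
#' distinguishes "excluded by the lasso" from "near-zero but retained").
#' Ordered by descending AUC when a per-marker AUC table is supplied, then
#' by descending `|beta|`, then marker id.
#'
#' @param m A [panel_model].
#' @param tol Zero threshold on `|beta|` (default 1e-8).
#' @param auc Optional named numeric vector or tibble
#'   (`marker_id`, `auc`) used as the primary ordering key.
#' @return Character vector of marker ids.
#' @export
nonzero_support <- function(m, tol = 1e-8, auc = NULL) {
  beta <- m$coefficients
  keep <- names(beta)[abs(beta) > tol]
  if (length(keep) == 0) return(character(0))
  b <- abs(beta[keep])
  a <- rep(NA_real_, length(keep))
  if (!is.null(auc)) {
    if (is.data.frame(auc)) auc <- setNames(auc$auc, auc$marker_id)
    a <- unname(auc[keep])
  }
  ord <- order(-ifelse(is.na(a), -Inf, a), -b, keep)
  keep[ord]
}

#' Odds-ratio factor of a coefficient
#'
#' `exp(beta)`: the multiplicative change in the odds of case status per
#' one-unit (1 SD on the standardized scale) increase of the marker.
#'
#' @param beta Finite coefficient(s).
#' @return `exp(beta)`.
#' @export
odds_ratio_factor <- function(beta) {
  if (any(!is.finite(beta))) stop_sispanel("`beta` must be finite.")
  exp(beta)
}

#' Predicted case probabilities from a panel model
#'
#' `plogis(intercept + sum_j beta_j x_ij)` for each subject. Every marker
#' with a nonzero coefficient must be present as a column of `X`.
#'
#' @param m A [panel_model].
#' @param X Expression tibble or data frame / matrix with marker columns
#'   (standardized, matching the model's scale).
#' @return Numeric vector of probabilities, named by subject id when
#'   available.
#' @export
predict_proba <- function(m, X) {
  beta <- m$coefficients[m$coefficients != 0]
  xm <- if (is.matrix(X)) X
        else if (is.data.frame(X) && "subject_id" %in% names(X)) marker_matrix(X)
        else as.matrix(X)
  miss <- setdiff(names(beta), colnames(xm))
  if (length(miss) > 0) {
    stop_sispanel(sprintf("Marker column(s) required by the model are missing: %s.",
                          paste(miss, collapse = ", ")))
  }
  eta <- rep(m$intercept, nrow(xm)) +
    if (length(beta) > 0) drop(xm[, names(beta), drop = FALSE] %*% beta) else 0
  p <- plogis(eta)
  if (!is.null(rownames(xm))) names(p) <- rownames(xm)
  p
}

#' @export
predict.panel_model <- function(object, newdata, type = c("response", "link"), ...) {
  type <- match.arg(type)
  p <- predict_proba(object, newdata)
  if (type == "link") qlogis(p) else p
}

classification_metrics <- function(predicted, truth, cutoff) {
  tp <- sum(predicted == 1 & truth == 1)
  fp <- sum(predicted == 1 & truth == 0)
  tn <- sum(predicted == 0 & truth == 0)
  fn <- sum(predicted == 0 & truth == 1)
  tibble::tibble(
    tp = tp, fp = fp, tn = tn, fn = fn,
    accuracy = (tp + tn) / (tp + fp + tn + fn),
    sensitivity = tp / (tp + fn),
    specificity = tn / (tn + fp),
    cutoff = cutoff
  )
}

#' In-sample classification metrics of a panel model
#'
#' Subjects are classified as cases when their predicted probability is
#' `>= cutoff` (probability exactly at the cutoff counts as a case).
#'
#' @inheritParams predict_proba
#' @param y Label tibble or 0/1 vector (must contain both classes).
#' @param cutoff Probability threshold in (0, 1), default 0.5.
#' @return One-row tibble: confusion counts `tp`, `fp`, `tn`, `fn`,
#'   `accuracy`, `sensitivity`, `specificity`, `cutoff`.
#' @export
in_sample_metrics <- function(m, X, y, cutoff = 0.5) {
  if (cutoff <= 0 || cutoff >= 1) stop_sispanel("`cutoff` must be in (0, 1).",
                                                class = "sispanel_config_error")
  truth <- status_vector(y, if (is.data.frame(X) && "subject_id" %in% names(X)) X else NULL)
  if (length(unique(truth)) < 2) {
    stop_sispanel("Both classes must be present to compute sensitivity/specificity.")
  }
  prob <- predict_proba(m, X)
  classification_metrics(as.integer(prob >= cutoff), truth, cutoff)
}

#' Backward AIC refinement of a marker panel
#'
#' Starting from the full support, repeatedly removes the single marker
#' whose removal lowers `AIC = -2 logL + 2 (k + 1)` the most (k markers
#' plus intercept), refitting an unpenalized logistic model at each
#' candidate; stops when no removal lowers the AIC. Candidate fits that
#' hit complete or quasi-separation are stabilized with a small ridge
#' (1e-6 on the Hessian diagonal) and flagged. Ties in candidate AIC are
#' broken by marker id, so the procedure is deterministic.
#'
#' @param X Standardized expression tibble (or data frame / matrix).
#' @param y Label tibble or 0/1 vector.
#' @param support Nonempty character vector of markers to start from.
#' @return List: `support` (final marker set, possibly empty), `model`
#'   (unpenalized [panel_model] refit on the final support) and `trace`
#'   (tibble `step`, `removed`, `n_markers`, `aic`, `separation`).
#' @export
step_aic_refine <- function(X, y, support) {
  if (length(support) == 0) stop_sispanel("`support` must be nonempty.")
  xm <- panel_design_matrix(X, support)
  truth <- status_vector(y, if (is.data.frame(X) && "subject_id" %in% names(X)) X else NULL)
  check_two_groups(truth, min_per_group = 2L)

  current <- support
  fit <- fit_logistic_stabilized(xm[, current, drop = FALSE], truth)
  trace <- tibble::tibble(step = 0L, removed = NA_character_,
                          n_markers = length(current), aic = fit$aic,
                          separation = fit$separation)
  step_i <- 0L
  repeat {
    if (length(current) == 0) break
    cand_aic <- setNames(numeric(length(current)), current)
    cand_sep <- setNames(logical(length(current)), current)
    for (mk in current) {
      rest <- setdiff(current, mk)
      f <- fit_logistic_stabilized(xm[, rest, drop = FALSE], truth)
      cand_aic[mk] <- f$aic
      cand_sep[mk] <- f$separation
    }
    ord <- order(cand_aic, names(cand_aic))
    best <- names(cand_aic)[ord[1]]
    if (cand_aic[best] >= fit$aic) break
    current <- setdiff(current, best)
    fit <- fit_logistic_stabilized(xm[, current, drop = FALSE], truth)
    step_i <- step_i + 1L
    trace <- dplyr::bind_rows(trace, tibble::tibble(
      step = step_i, removed = best, n_markers = length(current),
      aic = fit$aic, separation = fit$separation))
  }

  model <- new_panel_model(
    intercept = fit$intercept,
    coefficients = if (length(current) > 0) fit$coefficients
                   else setNames(numeric(0), character(0)),
    lambda = 0, strategy = "step_aic",
    fit_meta = list(separation = fit$separation, loglik = fit$loglik,
                    aic = fit$aic, ridge = fit$ridge)
  )
  list(support = current, model = model, trace = trace)
}
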