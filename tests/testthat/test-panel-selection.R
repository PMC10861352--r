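test_that("extreme penalties recover the analytic limits of the lasso path", {
  sim <- tiny_cohort(p = 6, true_markers = 1:2, delta = 1.5, seed = 14)
  X <- sim$standardized; y <- sim$labels

  # lambda huge: all coefficients exactly 0, intercept = logit(case fraction)
  m_inf <- fit_lasso_logistic(X, y, lambda_strategy = 50)
  expect_true(all(m_inf$coefficients == 0))
  expect_equal(m_inf$intercept, qlogis(mean(y$status)), tolerance = 1e-6)
  expect_identical(nonzero_support(m_inf), character(0))

  # lambda = 0: unpenalized MLE, all coefficients move off zero
  m0 <- fit_lasso_logistic(X, y, lambda_strategy = 0)
  expect_length(nonzero_support(m0), 6)
})

test_that("the unpenalized fit agrees with the IRLS oracle (stats::glm) to 1e-4", {
  sim <- tiny_cohort(p = 2, true_markers = 1:2, delta = c(1, 0.5), seed = 40)
  X <- sim$standardized; y <- sim$labels
  m0 <- fit_lasso_logistic(X, y, lambda_strategy = 0)

  df <- as.data.frame(X[-1]); df$y <- y$status
  oracle <- glm(y ~ ., data = df, family = binomial())
  expect_equal(m0$intercept, unname(coef(oracle)[1]), tolerance = 1e-4)
  expect_equal(unname(m0$coefficients), unname(coef(oracle)[-1]),
               tolerance = 1e-4)
  expect_false(m0$fit_meta$separation)
})

test_that("a perfectly separating predictor is flagged at lambda = 0", {
  X <- tibble::tibble(subject_id = sprintf("s%02d", 1:20),
                      sep = c(rnorm(10, 3, 0.1), rnorm(10, -3, 0.1)))
  y <- tibble::tibble(subject_id = X$subject_id,
                      status = c(rep(1L, 10), rep(0L, 10)))
  m <- fit_lasso_logistic(X, y, lambda_strategy = 0)
  expect_true(m$fit_meta$separation)
})

test_that("cv and support-size strategies are deterministic given the seed and hit the asked support", {
  sim <- tiny_cohort(p = 25, true_markers = 1:4, delta = 1.5, seed = 77)
  X <- sim$standardized; y <- sim$labels
  a <- fit_lasso_logistic(X, y, lambda_strategy = "cv", seed = 5)
  b <- fit_lasso_logistic(X, y, lambda_strategy = "cv", seed = 5)
  expect_identical(a$coefficients, b$coefficients)
  expect_identical(a$lambda, b$lambda)

  k3 <- fit_lasso_logistic(X, y, lambda_strategy = "support_size:3")
  expect_length(nonzero_support(k3), 3)

  expect_error(fit_lasso_logistic(X, y, lambda_strategy = "nonsense"),
               class = "sispanel_config_error")
})

test_that("support extraction separates lasso-excluded from near-zero-retained markers", {
  m <- delirium_panel()
  expect_length(nonzero_support(m), 12)
  s11 <- nonzero_support(m, tol = 0.01)
  expect_length(s11, 11)
  expect_false("TNFSF14" %in% s11)

  # AUC-primary ordering when an AUC table is supplied
  auc <- tibble::tibble(
    marker_id = names(m$coefficients),
    auc = c(0.80, 0.79, 0.78, 0.78, 0.77, 0.75, 0.74, 0.74, 0.74, 0.73,
            0.73, 0.73))
  ord <- nonzero_support(m, auc = auc)
  expect_identical(ord[1:3], c("TARDBP", "YARS2", "PRL"))
  # AUC tie at 0.74 broken by |beta|: CTSS... F2 0.562 > CTSB 0.121 > LILRB4 0.025
  expect_identical(ord[7:9], c("F2", "CTSB", "LILRB4"))
})

test_that("odds-ratio factors reproduce the published worked examples", {
  expect_equal(odds_ratio_factor(0), 1)
  expect_equal(round(odds_ratio_factor(0.562), 2), 1.75)
  expect_equal(round(odds_ratio_factor(-0.595), 2), 0.55)
  expect_error(odds_ratio_factor(Inf))
})

test_that("predicted probabilities follow the logistic closed form", {
  m <- delirium_panel()
  zero <- tibble::tibble(subject_id = "s1",
                         !!!setNames(as.list(rep(0, 12)), names(m$coefficients)))
  expect_equal(unname(predict_proba(m, zero)), 0.5)

  one_sd_f2 <- zero; one_sd_f2$F2 <- 1
  expect_equal(unname(predict_proba(m, one_sd_f2)), plogis(0.562),
               tolerance = 1e-12)

  # logistic limits for a single unit coefficient
  m1 <- sispanel:::new_panel_model(0, c(x = 1), lambda = 0, strategy = "fixed:0")
  expect_equal(unname(predict_proba(m1, tibble::tibble(x = 0))), 0.5)
  expect_equal(unname(predict_proba(m1, tibble::tibble(x = 1e4))), 1)

  expect_error(predict_proba(m, zero[, 1:6]), regexp = "F2")
})

test_that("classification metrics satisfy their confusion-matrix identities", {
  m1 <- sispanel:::new_panel_model(0, c(x = 10), lambda = 0, strategy = "fixed:0")
  # 20 cases at +1, 19 controls at -1, one control at +1 (the false positive)
  X <- tibble::tibble(subject_id = sprintf("s%02d", 1:40),
                      x = c(rep(1, 20), rep(-1, 19), 1))
  y <- c(rep(1L, 20), rep(0L, 20))
  met <- in_sample_metrics(m1, X, y)
  expect_equal(met$sensitivity, 1)
  expect_equal(met$specificity, 0.95)
  expect_equal(met$accuracy, 0.975)
  expect_equal(met$accuracy, (met$tp + met$tn) / 40)

  # probability exactly at the cutoff classifies as case
  m0 <- sispanel:::new_panel_model(0, c(x = 0), lambda = 0, strategy = "fixed:0")
  met0 <- in_sample_metrics(m0, X, y)
  expect_equal(met0$sensitivity, 1)
  expect_equal(met0$specificity, 0)

  expect_error(in_sample_metrics(m1, X, rep(1L, 40)))
  expect_error(in_sample_metrics(m1, X, y, cutoff = 1),
               class = "sispanel_config_error")
})

test_that("intercept-only AIC matches the closed form -2 n ln 2 + 2 on balanced labels", {
  y <- c(rep(1L, 20), rep(0L, 20))
  xm <- matrix(numeric(0), nrow = 40, ncol = 0)
  fit <- sispanel:::fit_logistic_stabilized(xm, y)
  expect_equal(fit$loglik, 40 * log(0.5), tolerance = 1e-9)
  expect_equal(fit$aic, -2 * 40 * log(2^-1) + 2, tolerance = 1e-9)
  expect_equal(fit$aic, 57.4518, tolerance = 1e-4)
})

test_that("a pure-noise marker is usually dropped by backward AIC", {
  # oracle: under H0 the LR statistic is ~ chi-square(1); removal lowers AIC
  # when LR < 2, so P(drop) ~ pchisq(2, 1) = 0.843
  expect_equal(pchisq(2, 1), 0.843, tolerance = 1e-3)
  drops <- 0L
  for (s in 1:100) {
    sim <- tiny_cohort(p = 1, true_markers = integer(0), seed = 1000 + s)
    out <- step_aic_refine(sim$standardized, sim$labels, "M0001")
    drops <- drops + (length(out$support) == 0)
  }
  expect_gte(drops, 80L)
})

test_that("backward AIC keeps a strong marker and drops the noise companion", {
  # the strong marker must always survive; the noise companion is removed
  # whenever its conditional LR statistic is below the AIC penalty of 2,
  # i.e. with probability ~ pchisq(2, 1) = 0.843 under the chi-square null
  # (3-sigma binomial lower bound over 100 replicates: >= 74)
  true_kept <- 0L; noise_dropped <- 0L
  for (s in 1:100) {
    sim <- tiny_cohort(p = 2, true_markers = 1, delta = 3, seed = 2000 + s)
    out <- step_aic_refine(sim$standardized, sim$labels, c("M0001", "M0002"))
    true_kept <- true_kept + ("M0001" %in% out$support)
    noise_dropped <- noise_dropped + !("M0002" %in% out$support)
  }
  expect_identical(true_kept, 100L)
  expect_gte(noise_dropped, 74L)
})

test_that("the AIC trace is monotone decreasing and the final support is nested", {
  sim <- tiny_cohort(p = 8, true_markers = 1:2, delta = 1.5, seed = 60)
  support <- sprintf("M%04d", 1:8)
  out <- step_aic_refine(sim$standardized, sim$labels, support)
  expect_true(all(diff(out$trace$aic) < 0))
  expect_true(all(out$support %in% support))
  expect_identical(sort(names(out$model$coefficients)), sort(out$support))
})

test_that("backward AIC agrees with MASS::stepAIC on a clean fixture", {
  skip_if_not_installed("MASS")
  sim <- tiny_cohort(p = 6, true_markers = 1:2, delta = 1.2, seed = 90)
  df <- as.data.frame(sim$standardized[-1])
  df$y <- sim$labels$status
  full <- glm(y ~ ., data = df, family = binomial())
  ref <- MASS::stepAIC(full, direction = "backward", trace = 0)
  ref_support <- setdiff(names(coef(ref)), "(Intercept)")

  out <- step_aic_refine(sim$standardized, sim$labels, sprintf("M%04d", 1:6))
  expect_setequal(out$support, ref_support)
  expect_equal(out$trace$aic[nrow(out$trace)], AIC(ref), tolerance = 1e-6)
})
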