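test_that("empirical AUC matches hand-enumerated pair counts", {
  expect_equal(empirical_auc(c(3, 4, 1, 2), c(1, 1, 0, 0)), 1)
  expect_equal(empirical_auc(c(1, 2, 1, 2), c(1, 1, 0, 0)), 0.5)
  # cases {2,3,5} vs controls {1,2,4}: 6 wins + 1 tie of 9 pairs
  expect_equal(empirical_auc(c(2, 3, 5, 1, 2, 4), c(1, 1, 1, 0, 0, 0)),
               6.5 / 9)
  expect_error(empirical_auc(1:4, c(1, 1, 1, 1)))
})

test_that("empirical AUC equals the brute-force O(n^2) oracle on 200 random instances", {
  set.seed(202)
  for (i in 1:200) {
    n1 <- sample(2:12, 1); n0 <- sample(2:12, 1)
    scores <- if (i %% 2 == 0) sample(1:6, n1 + n0, replace = TRUE)  # ties
              else rnorm(n1 + n0)
    y <- sample(c(rep(1L, n1), rep(0L, n0)))
    expect_identical(empirical_auc(scores, y), brute_force_auc(scores, y))
  }
})

test_that("empirical AUC is invariant under strictly increasing transforms", {
  set.seed(9)
  s <- rnorm(30); y <- rep(c(1L, 0L), 15)
  a <- empirical_auc(s, y)
  expect_equal(empirical_auc(exp(s), y), a)
  expect_equal(empirical_auc(rank(s), y), a)
})

test_that("the Youden index reproduces the published sensitivity/specificity arithmetic", {
  expect_equal(youden_index(0.95, 0.6), 0.55)
  expect_equal(youden_index(0.7, 0.8), 0.5)
  expect_equal(youden_index(1, 1), 1)
  expect_error(youden_index(1.2, 0.5))
})

test_that("the Youden-optimal threshold is found by exhaustive midpoint scan", {
  vals <- c(0.9, 0.8, 0.7, 0.4, 0.6, 0.3, 0.2, 0.1)
  y <- c(rep(1L, 4), rep(0L, 4))
  r <- roc_and_youden(vals, y)
  expect_identical(r$direction, "high_is_case")
  expect_equal(r$youden_j, 0.75)
  expect_equal(r$youden_threshold, 0.65)
  expect_equal(r$sensitivity, 0.75)
  expect_equal(r$specificity, 1)

  # negation flips the direction, preserving AUC and J
  rn <- roc_and_youden(-vals, y)
  expect_identical(rn$direction, "low_is_case")
  expect_equal(rn$auc, r$auc)
  expect_equal(rn$youden_j, r$youden_j)

  # perfect separation: J = 1
  rp <- roc_and_youden(c(5, 6, 1, 2), c(1, 1, 0, 0))
  expect_equal(rp$youden_j, 1)

  # constant marker: degenerate, AUC 0.5, J 0
  rc <- roc_and_youden(rep(2, 6), rep(c(1L, 0L), 3))
  expect_true(rc$degenerate)
  expect_equal(rc$auc, 0.5)
  expect_equal(rc$youden_j, 0)
})

test_that("reported sensitivity/specificity reproduce youden_j at the returned threshold", {
  set.seed(31)
  for (i in 1:25) {
    n1 <- sample(4:12, 1); n0 <- sample(4:12, 1)
    vals <- round(rnorm(n1 + n0, mean = c(rep(0.8, n1), rep(0, n0))), 1)
    y <- c(rep(1L, n1), rep(0L, n0))
    r <- roc_and_youden(vals, y)
    if (r$degenerate) next
    pred <- if (r$direction == "high_is_case") vals >= r$youden_threshold
            else vals <= r$youden_threshold
    sens <- sum(pred & y == 1) / n1
    spec <- sum(!pred & y == 0) / n0
    expect_equal(sens + spec - 1, r$youden_j, tolerance = 1e-12)
    expect_gte(r$auc, 0.5)
  }
})

test_that("marker_roc ranks the standardized markers by AUC with thresholds on that scale", {
  sim <- tiny_cohort(p = 6, true_markers = 1, delta = 3, seed = 17)
  tab <- marker_roc(sim$standardized, sim$labels)
  expect_identical(tab$marker_id[1], "M0001")
  expect_true(all(diff(tab$auc) <= 0))
  expect_true(all(tab$auc >= 0.5))
})

test_that("LOOCV makes one held-out prediction per subject and the intercept-only pathology is exact", {
  sim <- tiny_cohort(p = 3, true_markers = integer(0), seed = 55)
  res <- loocv_panel(sim$standardized, sim$labels, character(0))
  expect_identical(nrow(res$predictions), 40L)
  expect_identical(res$predictions$subject_id, sim$labels$subject_id)
  # balanced labels: every fold's prevalence votes against the held-out class
  expect_equal(res$metrics$accuracy, 0)
  expect_equal(tidy(res)$prob,
               ifelse(sim$labels$status == 1, 19 / 39, 20 / 39),
               tolerance = 1e-6)
})

test_that("a strong single-marker panel cross-validates accurately", {
  acc <- vapply(1:50, function(s) {
    sim <- tiny_cohort(p = 2, true_markers = 1, delta = 3, seed = 4000 + s)
    loocv_panel(sim$standardized, sim$labels, "M0001")$metrics$accuracy
  }, numeric(1))
  expect_gte(mean(acc), 0.85)
})

test_that("LOOCV accuracy on label-permuted data respects the no-information bound", {
  sim <- tiny_cohort(p = 4, true_markers = 1, delta = 2, seed = 66)
  set.seed(66)
  acc <- vapply(1:40, function(i) {
    perm <- sim$labels
    perm$status <- sample(perm$status)
    loocv_panel(sim$standardized, perm, "M0001")$metrics$accuracy
  }, numeric(1))
  mc_se <- sd(acc) / sqrt(length(acc))
  expect_lte(mean(acc), 0.5 + 3 * mc_se)
})

test_that("loocv_result exposes tidy/glance/autoplot views", {
  sim <- tiny_cohort(p = 2, true_markers = 1, delta = 2, seed = 70)
  res <- loocv_panel(sim$standardized, sim$labels, "M0001")
  expect_identical(nrow(tidy(res)), 40L)
  g <- glance(res)
  expect_equal(g$accuracy, (g$tp + g$tn) / g$n)
  expect_s3_class(autoplot(res), "ggplot")
})
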