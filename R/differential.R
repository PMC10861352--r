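#' Log2 fold change between cases and controls
#'
#' Mean case minus mean control of log2-scale values. By convention fold
#' changes are computed on log2 values before standardization; the group
#' tests are affine-invariant, so they may be run on either representation.
#'
#' @param case_values,control_values Numeric vectors of log2-scale values.
#' @return Mean difference (case - control) on the log2 scale.
#' @export
marker_log2fc <- function(case_values, control_values) {
  if (length(case_values) < 1 || length(control_values) < 1) {
    stop_sispanel("Both groups need at least one value.")
  }
  mean(case_values) - mean(control_values)
}

#' Two-group tests for a single marker
#'
#' Two-sided p-values from the Welch two-sample t-test, the two-sample
#' Kolmogorov-Smirnov test (exact when `n_case * n_control <= 10000` and
#' there are no ties, else asymptotic) and the Mann-Whitney test (exact
#' enumeration when both groups have <= 8 values and there are no ties,
#' else normal approximation with tie and continuity corrections). A
#' degenerate marker (zero variance in both groups) with equal means gets
#' `p_t = 1` by convention; with unequal means, `p_t = 0`.
#'
#' @inheritParams marker_log2fc
#' @return Named list: `p_t`, `p_ks`, `p_mw`, plus the test statistics
#'   `stat_t` (Welch t), `stat_ks` (KS D) and `stat_mw` (centred U,
#'   `U - n_case*n_control/2`).
#' @export
marker_tests <- function(case_values, control_values) {
  if (length(case_values) < 2 || length(control_values) < 2) {
    stop_sispanel("Both groups need at least two values for the t-test.")
  }
  st <- marker_tests_matrix(cbind(case_values), cbind(control_values))
  lapply(st, unname)
}

# Vectorised three-test battery over the columns of two matrices
# (cases: n1 x p, controls: n0 x p). Welch t via closed-form moments + pt();
# KS via ECDF max-gap + psmirnov(); Mann-Whitney via midranks + pwilcox()
# (exact) or the tie/continuity-corrected normal approximation. Each path
# reproduces the corresponding stats:: test to machine precision.
marker_tests_matrix <- function(cases, controls) {
  n1 <- nrow(cases); n0 <- nrow(controls); p <- ncol(cases)

  m1 <- colMeans(cases); m0 <- colMeans(controls)
  v1 <- colSums((cases - rep(m1, each = n1))^2) / (n1 - 1)
  v0 <- colSums((controls - rep(m0, each = n0))^2) / (n0 - 1)
  se2 <- v1 / n1 + v0 / n0
  tstat <- (m1 - m0) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v0 / n0)^2 / (n0 - 1))
  p_t <- 2 * pt(-abs(tstat), df)
  degen <- se2 == 0
  if (any(degen)) {
    eq <- degen & (m1 == m0)
    tstat[eq] <- 0; p_t[eq] <- 1
    ne <- degen & (m1 != m0)
    tstat[ne] <- sign(m1[ne] - m0[ne]) * Inf; p_t[ne] <- 0
  }

  p_ks <- numeric(p); d_ks <- numeric(p)
  p_mw <- numeric(p); u_c <- numeric(p)
  N <- n1 + n0
  ks_exact_size <- n1 * n0 <= 10000
  mw_exact_size <- n1 <= 8 && n0 <= 8
  ks_memo <- new.env(parent = emptyenv())
  for (j in seq_len(p)) {
    x <- cases[, j]; y <- controls[, j]
    pooled <- c(x, y)
    r <- rank(pooled)
    ties <- anyDuplicated(pooled) > 0

    # KS: D = max |F1 - F2| over the pooled sample
    ord <- order(pooled)
    grp <- c(rep(1L, n1), rep(0L, n0))[ord]
    steps <- cumsum(ifelse(grp == 1L, 1 / n1, -1 / n0))
    if (ties) {
      keep <- c(diff(pooled[ord]) != 0, TRUE)
      steps <- steps[keep]
    }
    D <- max(abs(steps))
    d_ks[j] <- D
    exact <- ks_exact_size && !ties
    key <- sprintf("%.12g|%d", D, exact)
    pk <- ks_memo[[key]]
    if (is.null(pk)) {
      pk <- 1 - psmirnov(D, sizes = c(n1, n0), exact = exact)
      ks_memo[[key]] <- pk
    }
    p_ks[j] <- min(max(pk, 0), 1)

    # Mann-Whitney U for the case group
    U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
    u_c[j] <- U - n1 * n0 / 2
    if (mw_exact_size && !ties) {
      pm <- if (U > n1 * n0 / 2) 1 - pwilcox(U - 1, n1, n0) else pwilcox(U, n1, n0)
      p_mw[j] <- min(2 * pm, 1)
    } else {
      tie_tab <- tabulate(match(r, unique(r)))
      sigma <- sqrt((n1 * n0 / 12) *
                      ((N + 1) - sum(tie_tab^3 - tie_tab) / (N * (N - 1))))
      z <- u_c[j] - sign(u_c[j]) * 0.5
      p_mw[j] <- if (sigma == 0) 1 else min(2 * pnorm(-abs(z / sigma)), 1)
    }
  }
  list(p_t = p_t, p_ks = p_ks, p_mw = p_mw,
       stat_t = tstat, stat_ks = d_ks, stat_mw = u_c)
}

#' Per-marker differential statistics
#'
#' Computes, for every marker, the log2 fold change (case mean minus control
#' mean of log2 values before standardization) and two-sided p-values from
#' the Welch t, Kolmogorov-Smirnov and Mann-Whitney tests (see
#' [marker_tests()] for the exact dialects). The tests are run on the log2
#' values; because all three are invariant to the per-marker affine
#' standardization, the p-values are identical on the standardized scale.
#'
#' @param expr Expression tibble on any scale (raw is log2-transformed
#'   internally; a standardized table must carry its `log2_values`).
#' @param labels Label tibble (`subject_id`, `status`) or 0/1 vector aligned
#'   to `expr` rows.
#' @return Tibble with one row per marker: `marker_id`, `log2fc`, `p_t`,
#'   `p_ks`, `p_mw` and the statistics `stat_t`, `stat_ks`, `stat_mw`.
#' @export
marker_stats <- function(expr, labels) {
  y <- status_vector(labels, expr)
  check_two_groups(y, min_per_group = 2L)
  lvals <- log2_values_of(expr)
  cases <- lvals[y == 1, , drop = FALSE]
  controls <- lvals[y == 0, , drop = FALSE]
  st <- marker_tests_matrix(cases, controls)
  tibble::tibble(
    marker_id = colnames(lvals),
    log2fc = colMeans(cases) - colMeans(controls),
    stat_t = st$stat_t, p_t = st$p_t,
    stat_ks = st$stat_ks, p_ks = st$p_ks,
    stat_mw = st$stat_mw, p_mw = st$p_mw
  )
}

#' Volcano classification of differential markers
#'
#' Classifies each marker as `up`, `down` or `ns` by the volcano rule:
#' significant iff `|log2fc| >= fc_min` (inclusive) and the t-test p-value
#' is strictly below `p_max`; the sign of the fold change gives the
#' direction. The t-test p-value is used because the volcano is built from
#' separate two-sample t-tests; no multiple-testing correction is applied
#' at this stage (the screening and selection steps downstream take that
#' role).
#'
#' @param stats Marker-stat tibble from [marker_stats()].
#' @param fc_min Minimum absolute log2 fold change (> 0; default 0.2).
#' @param p_max Strict p-value ceiling (in (0,1); default 0.05).
#' @return `stats` with a `volcano_class` factor column
#'   (levels `up`, `down`, `ns`).
#' @export
volcano_classify <- function(stats, fc_min = 0.2, p_max = 0.05) {
  if (fc_min <= 0) stop_sispanel("`fc_min` must be > 0.",
                                 class = "sispanel_config_error")
  if (p_max <= 0 || p_max >= 1) stop_sispanel("`p_max` must be in (0, 1).",
                                              class = "sispanel_config_error")
  dplyr::mutate(stats, volcano_class = factor(
    dplyr::case_when(
      .data$log2fc >= fc_min & .data$p_t < p_max ~ "up",
      .data$log2fc <= -fc_min & .data$p_t < p_max ~ "down",
      TRUE ~ "ns"
    ),
    levels = c("up", "down", "ns")
  ))
}

#' @rdname volcano_classify
#' @return `volcano_counts()`: one-row tibble with `up`, `down`, `ns`
#'   counts (summing to the number of markers).
#' @export
volcano_counts <- function(stats, fc_min = 0.2, p_max = 0.05) {
  if (!"volcano_class" %in% names(stats)) {
    stats <- volcano_classify(stats, fc_min = fc_min, p_max = p_max)
  }
  tb <- table(stats$volcano_class)
  tibble::tibble(up = as.integer(tb[["up"]]), down = as.integer(tb[["down"]]),
                 ns = as.integer(tb[["ns"]]))
}

#' Volcano plot of per-marker differential statistics
#'
#' @param stats Marker-stat tibble; classified with [volcano_classify()]
#'   first if the `volcano_class` column is absent.
#' @inheritParams volcano_classify
#' @return A ggplot: log2 fold change vs -log10 p (t-test), coloured by
#'   volcano class, with the thresholds drawn.
#' @export
plot_volcano <- function(stats, fc_min = 0.2, p_max = 0.05) {
  if (!"volcano_class" %in% names(stats)) {
    stats <- volcano_classify(stats, fc_min = fc_min, p_max = p_max)
  }
  ggplot2::ggplot(stats, ggplot2::aes(x = .data$log2fc,
                                      y = -log10(.data$p_t),
                                      colour = .data$volcano_class)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::geom_vline(xintercept = c(-fc_min, fc_min), linetype = "dashed",
                        linewidth = 0.3) +
    ggplot2::geom_hline(yintercept = -log10(p_max), linetype = "dashed",
                        linewidth = 0.3) +
    ggplot2::scale_colour_manual(
      values = c(up = "#c0392b", down = "#2980b9", ns = "grey70"),
      name = NULL) +
    ggplot2::labs(x = "log2 fold change (case - control)",
                  y = expression(-log[10]~italic(p)~"(Welch t)")) +
    ggplot2::theme_minimal()
}
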