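#' Design a synthetic case-control proteomic cohort
#'
#' Describes the generative model used by [simulate_cohort()]: `p` markers
#' measured on `n_case + n_control` subjects. Marker log2 intensities are
#' Gaussian with per-marker standard deviation `sigma_log2`; markers listed
#' in `true_markers` have their case-group mean shifted by
#' `delta * sigma_log2` (a standardized effect size on the log2 scale).
#' Markers can be block-equicorrelated: consecutive blocks of `block_size`
#' markers share pairwise correlation `rho`, with independence across
#' blocks. Raw intensities are `2^log2`, so the pipeline's log2 transform
#' round-trips exactly.
#'
#' Defaults mirror the study conditions the pipeline targets: 20 cases vs
#' 20 controls, 1433 markers, 5 planted differential markers with a
#' standardized shift of 2 on the log2 scale, independent markers.
#'
#' @param n_case,n_control Subjects per group (each >= 2).
#' @param p Number of markers (>= 1).
#' @param true_markers Integer indices of the planted differential markers.
#' @param delta Standardized case-vs-control mean shift(s) on the log2
#'   scale, recycled to `length(true_markers)`.
#' @param sigma_log2 Per-marker log2-scale standard deviation(s) (> 0),
#'   recycled to `p`.
#' @param rho Within-block equicorrelation in `[0, 1)`.
#' @param block_size Markers per correlated block (>= 1).
#' @param seed Integer seed governing all randomness of the simulation.
#' @return A `cohort_design` list.
#' @export
cohort_design <- function(n_case = 20, n_control = 20, p = 1433,
                          true_markers = seq_len(5), delta = 2,
                          sigma_log2 = 1, rho = 0, block_size = 1,
                          seed = 1) {
  n_case <- check_count(n_case, "n_case", min = 2L)
  n_control <- check_count(n_control, "n_control", min = 2L)
  p <- check_count(p, "p", min = 1L)
  block_size <- check_count(block_size, "block_size", min = 1L)
  seed <- check_count(seed, "seed", min = 0L)
  true_markers <- as.integer(true_markers)
  if (length(true_markers) > 0 &&
      (anyDuplicated(true_markers) || any(true_markers < 1) || any(true_markers > p))) {
    stop_sispanel("`true_markers` must be distinct indices in 1..p.",
                  class = "sispanel_config_error")
  }
  if (length(true_markers) > p) {
    stop_sispanel("More true markers than markers.", class = "sispanel_config_error")
  }
  if (length(rho) != 1 || rho < 0 || rho >= 1) {
    stop_sispanel("`rho` must be a single value in [0, 1).",
                  class = "sispanel_config_error")
  }
  sigma_log2 <- rep_len(as.numeric(sigma_log2), p)
  if (any(sigma_log2 <= 0)) {
    stop_sispanel("`sigma_log2` must be > 0.", class = "sispanel_config_error")
  }
  delta <- if (length(true_markers) == 0) numeric(0) else
    rep_len(as.numeric(delta), length(true_markers))
  structure(
    list(n_case = n_case, n_control = n_control, p = p,
         true_markers = true_markers, delta = delta,
         sigma_log2 = sigma_log2, rho = rho, block_size = block_size,
         seed = seed),
    class = "cohort_design"
  )
}

#' @export
print.cohort_design <- function(x, ...) {
  cat(sprintf(
    "<cohort_design> %d cases / %d controls, p = %d markers\n  %d planted marker(s), delta = %s (log2-SD units), rho = %g (block %d), seed = %d\n",
    x$n_case, x$n_control, x$p, length(x$true_markers),
    paste(unique(format(x$delta, digits = 3)), collapse = "/"),
    x$rho, x$block_size, x$seed))
  invisible(x)
}

#' Simulate a case-control proteomic cohort
#'
#' Draws a cohort from a [cohort_design()]: Gaussian log2 intensities with
#' the design's per-marker SDs, planted standardized case shifts, optional
#' block equicorrelation, returned as raw-scale (`2^log2`) intensities. The
#' same design (including its seed) always produces bit-identical output.
#' Cases come first (`status = 1`), then controls, with subject ids
#' `S001, S002, ...` in a fixed order.
#'
#' @param design A `cohort_design`.
#' @param seed Optional seed overriding `design$seed`.
#' @return List with `expression` (raw-scale tibble, first column
#'   `subject_id`) and `labels` (tibble `subject_id`, `status`).
#' @export
simulate_cohort <- function(design, seed = NULL) {
  if (!inherits(design, "cohort_design")) {
    design <- do.call(cohort_design, design)
  }
  seed <- if (is.null(seed)) design$seed else check_count(seed, "seed", min = 0L)
  n <- design$n_case + design$n_control
  p <- design$p

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)

  z <- matrix(rnorm(n * p), nrow = n, ncol = p)
  if (design$rho > 0 && design$block_size > 1) {
    block <- ceiling(seq_len(p) / design$block_size)
    shared <- matrix(rnorm(n * max(block)), nrow = n)
    z <- sqrt(design$rho) * shared[, block, drop = FALSE] +
      sqrt(1 - design$rho) * z
  }
  lvals <- sweep(z, 2, design$sigma_log2, `*`)
  if (length(design$true_markers) > 0) {
    shift <- design$delta * design$sigma_log2[design$true_markers]
    case_rows <- seq_len(design$n_case)
    lvals[case_rows, design$true_markers] <-
      sweep(lvals[case_rows, design$true_markers, drop = FALSE], 2, shift, `+`)
  }

  ids <- sprintf("S%0*d", max(3L, nchar(n)), seq_len(n))
  marker_ids <- sprintf("M%0*d", max(4L, nchar(p)), seq_len(p))
  expr <- tibble::as_tibble(as.data.frame(2^lvals))
  names(expr) <- marker_ids
  expr <- dplyr::bind_cols(tibble::tibble(subject_id = ids), expr)
  expr <- new_expression_tbl(expr, scale = "raw")
  labels <- tibble::tibble(
    subject_id = ids,
    status = c(rep(1L, design$n_case), rep(0L, design$n_control))
  )
  list(expression = expr, labels = labels,
       true_markers = marker_ids[design$true_markers])
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' The published 12-marker preoperative delirium panel
#'
#' Coefficients of a published lasso-selected logistic panel of 12 plasma
#' markers discriminating postoperative delirium, on the standardized
#' (per-1-SD) scale. The publication does not report the model intercept,
#' so it is set to 0 here; computations built on this fixture avoid
#' depending on the intercept. Useful as a worked example for odds-ratio
#' arithmetic, support extraction and probability prediction.
#'
#' @return A [panel_model] with 12 coefficients and intercept 0.
#' @export
delirium_panel <- function() {
  coefs <- c(
    TARDBP = -0.595, YARS2 = 0.351, PRL = 0.679, IRF5 = -0.105,
    TNFSF14 = -0.002, ADAM10 = 0.534, CTSB = 0.121, LILRB4 = -0.025,
    F2 = 0.562, UBE2D2 = -0.079, CTSS = -0.608, NTS = -0.326
  )
  new_panel_model(intercept = 0, coefficients = coefs, lambda = NA_real_,
                  strategy = "published",
                  fit_meta = list(source = "published 12-marker delirium panel",
                                  separation = FALSE))
}
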