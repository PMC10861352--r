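#' Run the full biomarker-discovery pipeline
#'
#' Executes the complete discovery chain on a cohort:
#' log2 + standardize -> per-marker differential statistics and volcano
#' classification -> consensus sure-independence screen (top `d_n` per
#' test, three-test intersection) -> lasso-penalized logistic panel
#' selection -> backward AIC refinement -> per-marker ROC/Youden
#' characterization of the lasso support -> leave-one-out cross-validation
#' of the final panel. The marker sets are nested by construction
#' (screen >= lasso support >= final panel) and this is asserted at run
#' time. When `out_dir` is given, every stage table is written as CSV
#' together with a JSON run manifest (inputs, seed, parameters, package
#' version) sufficient to reproduce the run.
#'
#' @param expression Raw or log2 expression tibble (first column
#'   `subject_id`), e.g. from [read_expression()] or [simulate_cohort()].
#' @param labels Label tibble (`subject_id`, `status`).
#' @param d_n Screening retention size per test (default 50).
#' @param fc_min,p_max Volcano thresholds (defaults 0.2 and 0.05).
#' @param lambda_strategy Lasso penalty strategy (see
#'   [fit_lasso_logistic()]); default `"cv"`.
#' @param tol Coefficient zero-threshold for support extraction
#'   (default 1e-8).
#' @param cutoff Classification probability cutoff (default 0.5).
#' @param seed Seed for the cross-validated lambda folds (default 1).
#' @param out_dir Optional output directory for stage tables + manifest.
#' @param quiet Suppress per-stage progress messages (default FALSE).
#' @return A `pipeline_result` list: `standardized`, `stats` (volcano
#'   table), `volcano` (counts), `screen` (screening_result), `lasso`
#'   (panel_model), `lasso_support`, `roc` (per-marker ROC of the lasso
#'   support), `refined` (stepAIC output), `panel` (final marker set),
#'   `in_sample` (metrics of the lasso panel), `loocv` (loocv_result of
#'   the final panel), `params`.
#' @export
run_pipeline <- function(expression, labels, d_n = 50, fc_min = 0.2,
                         p_max = 0.05, lambda_strategy = "cv", tol = 1e-8,
                         cutoff = 0.5, seed = 1, out_dir = NULL,
                         quiet = FALSE) {
  d_n <- check_count(d_n, "d_n", min = 1L)
  seed <- check_count(seed, "seed", min = 0L)
  say <- function(fmt, ...) if (!quiet) message(sprintf(fmt, ...))

  y <- status_vector(labels, expression)
  p_total <- ncol(expression) - 1L
  say("pipeline: n = %d subjects (%d cases / %d controls), p = %d markers",
      nrow(expression), sum(y == 1), sum(y == 0), p_total)
  if (d_n > p_total) {
    stop_sispanel("`d_n` exceeds the number of markers.",
                  class = "sispanel_config_error")
  }

  std <- if (identical(expr_scale(expression), "log2_standardized"))
    expression else log2_standardize(expression)

  stats <- marker_stats(std, labels)
  stats <- volcano_classify(stats, fc_min = fc_min, p_max = p_max)
  vc <- volcano_counts(stats)
  say("volcano: %d up, %d down, %d ns", vc$up, vc$down, vc$ns)

  screen <- consensus_screen(stats, d_n = d_n)
  say("screen: d_n = %d per test -> %d consensus marker(s)",
      d_n, nrow(screen$consensus))
  if (nrow(screen$consensus) == 0) {
    stop_sispanel("Screening stage produced an empty consensus; nothing to model.",
                  class = "sispanel_stage_error")
  }

  screened <- screen$consensus$marker_id
  lasso <- fit_lasso_logistic(std, labels, lambda_strategy = lambda_strategy,
                              markers = screened, seed = seed)
  roc <- marker_roc(std, labels, markers = screened)
  support <- nonzero_support(lasso, tol = tol, auc = roc)
  say("lasso: %d of %d screened markers retained (lambda = %.4g)",
      length(support), length(screened), lasso$lambda)
  if (length(support) == 0) {
    stop_sispanel("Lasso stage retained no markers; nothing to refine.",
                  class = "sispanel_stage_error")
  }
  in_sample <- in_sample_metrics(lasso, std, labels, cutoff = cutoff)

  refined <- step_aic_refine(std, labels, support)
  say("stepAIC: final panel of %d marker(s)", length(refined$support))

  panel <- refined$support
  stopifnot(all(support %in% screened), all(panel %in% support))
  loocv <- if (length(panel) > 0) loocv_panel(std, labels, panel, cutoff = cutoff)
           else loocv_panel(std, labels, character(0), cutoff = cutoff)
  say("LOOCV: accuracy %.3f (sensitivity %.3f, specificity %.3f)",
      loocv$metrics$accuracy, loocv$metrics$sensitivity,
      loocv$metrics$specificity)

  result <- structure(
    list(standardized = std, stats = stats, volcano = vc, screen = screen,
         lasso = lasso, lasso_support = support, roc = roc,
         refined = refined, panel = panel, in_sample = in_sample,
         loocv = loocv,
         params = list(d_n = d_n, fc_min = fc_min, p_max = p_max,
                       lambda_strategy = lambda_strategy, tol = tol,
                       cutoff = cutoff, seed = seed)),
    class = "pipeline_result"
  )
  if (!is.null(out_dir)) write_pipeline_artifacts(result, expression, labels, out_dir)
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  cat(sprintf("  markers: %d total -> %d screened -> %d lasso -> %d final\n",
              nrow(x$stats), nrow(x$screen$consensus),
              length(x$lasso_support), length(x$panel)))
  cat(sprintf("  in-sample accuracy %.3f | LOOCV accuracy %.3f\n",
              x$in_sample$accuracy, x$loocv$metrics$accuracy))
  invisible(x)
}

write_pipeline_artifacts <- function(result, expression, labels, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(out_dir, f)
  readr::write_csv(result$stats, out("volcano.csv"))
  readr::write_csv(tidy(result$screen), out("screening.csv"))
  readr::write_csv(result$roc, out("roc.csv"))
  panel_tbl <- tidy(result$lasso)
  panel_tbl <- panel_tbl[panel_tbl$term != "(Intercept)", ]
  names(panel_tbl) <- c("marker_id", "coefficient", "odds_ratio_factor")
  panel_tbl$in_lasso_support <- as.integer(panel_tbl$marker_id %in% result$lasso_support)
  panel_tbl$in_final_panel <- as.integer(panel_tbl$marker_id %in% result$panel)
  readr::write_csv(panel_tbl, out("panel.csv"))
  readr::write_csv(tidy(result$loocv), out("loocv.csv"))
  readr::write_csv(result$refined$trace, out("aic_trace.csv"))
  jsonlite::write_json(
    list(in_sample = as.list(result$in_sample),
         loocv = as.list(result$loocv$metrics)),
    out("metrics.json"), auto_unbox = TRUE, digits = NA)
  manifest <- list(
    package = "sispanel",
    version = as.character(utils::packageVersion("sispanel")),
    n_subjects = nrow(expression),
    n_markers = ncol(expression) - 1L,
    n_cases = sum(labels$status == 1),
    n_controls = sum(labels$status == 0),
    params = result$params,
    counts = list(volcano_up = result$volcano$up,
                  volcano_down = result$volcano$down,
                  screened = nrow(result$screen$consensus),
                  lasso_support = length(result$lasso_support),
                  final_panel = length(result$panel)),
    lambda = result$lasso$lambda,
    final_panel = result$panel
  )
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(result)
}

#' Export a marker panel as a plain gene list
#'
#' One gene symbol per line, uppercased and deduplicated -- the format
#' expected by online enrichment services (STRING, g:Profiler, ...), which
#' are deliberately outside this package's scope.
#'
#' @param panel Character vector of marker ids, or a [panel_model] /
#'   `pipeline_result` (nonzero support is used).
#' @param path Optional output file; when NULL the lines are returned only.
#' @return Character vector of exported symbols, invisibly when written.
#' @export
export_gene_list <- function(panel, path = NULL) {
  if (inherits(panel, "pipeline_result")) panel <- panel$panel
  if (inherits(panel, "panel_model")) panel <- nonzero_support(panel)
  if (!is.character(panel) || length(panel) == 0) {
    stop_sispanel("Panel is empty; nothing to export.")
  }
  symbols <- unique(toupper(panel))
  if (!is.null(path)) {
    writeLines(symbols, path)
    return(invisible(symbols))
  }
  symbols
}
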