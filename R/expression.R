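#' Expression tables and the log2 + standardize transform
#'
#' An expression table is an ordinary tibble whose first column is
#' `subject_id` and whose remaining columns are numeric marker intensities,
#' carrying a `scale` attribute with one of `"raw"`, `"log2"` or
#' `"log2_standardized"`. Raw intensities are positive relative fluorescence
#' units; all statistical analysis happens on log2-transformed and per-marker
#' standardized values, while fold changes are computed on the log2 values
#' before standardization (kept in the `log2_values` attribute).
#'
#' @name expression-table
NULL

new_expression_tbl <- function(df, scale, log2_values = NULL) {
  df <- tibble::as_tibble(df)
  attr(df, "scale") <- scale
  attr(df, "log2_values") <- log2_values
  df
}

#' Scale of an expression table
#'
#' @param expr An expression tibble.
#' @return `"raw"`, `"log2"` or `"log2_standardized"` (defaults to `"raw"`
#'   when the table carries no scale attribute).
#' @export
expr_scale <- function(expr) {
  attr(expr, "scale") %||% "raw"
}

`%||%` <- function(x, y) if (is.null(x)) y else x

validate_expression <- function(expr, labels = NULL) {
  if (!is.data.frame(expr) || names(expr)[1] != "subject_id") {
    stop_sispanel("Expression table must have `subject_id` as its first column.")
  }
  if (anyDuplicated(expr$subject_id)) {
    stop_sispanel("Duplicate subject ids in expression table.",
                  class = "sispanel_parse_error")
  }
  vals <- marker_matrix(expr)
  if (anyDuplicated(colnames(vals))) {
    stop_sispanel("Duplicate marker ids in expression table.",
                  class = "sispanel_parse_error")
  }
  if (anyNA(vals)) {
    bad <- which(is.na(vals), arr.ind = TRUE)[1, ]
    stop_sispanel(
      sprintf("Missing value at subject `%s`, marker `%s`.",
              rownames(vals)[bad[1]], colnames(vals)[bad[2]]),
      class = "sispanel_parse_error"
    )
  }
  if (identical(expr_scale(expr), "raw") && any(vals <= 0)) {
    stop_sispanel("Raw-scale intensities must be strictly positive.",
                  class = "sispanel_parse_error")
  }
  invisible(expr)
}

#' Read an expression matrix and case-control labels
#'
#' Reads a wide expression table (one row per subject, first column
#' `subject_id`, remaining columns marker intensities) and a two-column label
#' table (`subject_id`, `status` with 1 = case, 0 = control), aligns the
#' labels to the expression row order, and validates both. Comma- and
#' tab-separated files are both accepted (sniffed from the header line).
#'
#' @param path Path to the wide expression table.
#' @param labels_path Path to the label table.
#' @param na_action `"error"` (default) fails on any missing cell;
#'   `"impute_mean"` replaces missing cells by the marker mean and warns.
#' @return A list with elements `expression` (tibble, `scale = "raw"` unless
#'   a `scale` comment is irrelevant -- values are taken as stored) and
#'   `labels` (tibble `subject_id`, `status`).
#' @export
read_expression <- function(path, labels_path, na_action = c("error", "impute_mean")) {
  na_action <- match.arg(na_action)
  expr <- read_delim_sniffed(path)
  if (nrow(expr) == 0 || ncol(expr) < 2) {
    stop_sispanel(sprintf("`%s` has no usable rows/columns.", path),
                  class = "sispanel_parse_error")
  }
  names(expr)[1] <- "subject_id"
  expr$subject_id <- as.character(expr$subject_id)
  non_num <- names(expr)[-1][!vapply(expr[-1], is.numeric, logical(1))]
  if (length(non_num) > 0) {
    stop_sispanel(sprintf("Non-numeric marker column(s): %s.",
                          paste(non_num, collapse = ", ")),
                  class = "sispanel_parse_error")
  }
  if (na_action == "impute_mean" && anyNA(expr)) {
    expr <- dplyr::mutate(expr, dplyr::across(
      -"subject_id", ~ ifelse(is.na(.x), mean(.x, na.rm = TRUE), .x)))
    warn("Missing cells mean-imputed per marker.")
  }
  expr <- new_expression_tbl(expr, scale = "raw")
  validate_expression(expr)

  lab <- read_delim_sniffed(labels_path)
  if (ncol(lab) < 2) {
    stop_sispanel(sprintf("`%s` must have subject_id and status columns.", labels_path),
                  class = "sispanel_parse_error")
  }
  names(lab)[1:2] <- c("subject_id", "status")
  lab$subject_id <- as.character(lab$subject_id)
  if (anyDuplicated(lab$subject_id)) {
    stop_sispanel("Duplicate subject ids in label table.",
                  class = "sispanel_parse_error")
  }
  if (!all(lab$status %in% c(0, 1))) {
    stop_sispanel("Labels must be 0 or 1.", class = "sispanel_parse_error")
  }
  extra <- setdiff(lab$subject_id, expr$subject_id)
  if (length(extra) > 0) {
    stop_sispanel(sprintf("Label subject(s) absent from the expression matrix: %s.",
                          paste(extra, collapse = ", ")),
                  class = "sispanel_alignment_error")
  }
  miss <- setdiff(expr$subject_id, lab$subject_id)
  if (length(miss) > 0) {
    stop_sispanel(sprintf("Expression subject(s) absent from the labels: %s.",
                          paste(miss, collapse = ", ")),
                  class = "sispanel_alignment_error")
  }
  lab <- lab[match(expr$subject_id, lab$subject_id), c("subject_id", "status")]
  lab$status <- as.integer(lab$status)
  list(expression = expr, labels = tibble::as_tibble(lab))
}

read_delim_sniffed <- function(path) {
  if (!file.exists(path)) {
    stop_sispanel(sprintf("File not found: `%s`.", path))
  }
  first <- readLines(path, n = 1L)
  if (length(first) == 0) {
    stop_sispanel(sprintf("`%s` is empty.", path), class = "sispanel_parse_error")
  }
  delim <- if (grepl("\t", first)) "\t" else ","
  readr::read_delim(path, delim = delim, show_col_types = FALSE,
                    progress = FALSE, trim_ws = TRUE)
}

#' Write an expression table / label table to CSV
#'
#' @param expr,labels Tibbles as produced by [read_expression()] or
#'   [simulate_cohort()].
#' @param path Output CSV path.
#' @return The input, invisibly.
#' @export
write_expression <- function(expr, path) {
  readr::write_csv(expr, path)
  invisible(expr)
}

#' @rdname write_expression
#' @export
write_labels <- function(labels, path) {
  readr::write_csv(labels, path)
  invisible(labels)
}

#' Log2-transform and per-marker standardize an expression table
#'
#' Raw intensities are log2-transformed, then every marker column is
#' centred and scaled to unit sample standard deviation (n - 1 denominator)
#' across all subjects jointly (cases and controls pooled). The log2 values
#' prior to standardization are retained in the `log2_values` attribute so
#' fold changes can be computed on the log2 scale. The per-marker tests are
#' invariant to this affine rescaling, so test p-values agree between the
#' log2 and standardized representations.
#'
#' @param expr Expression tibble with scale `"raw"` or `"log2"`.
#' @param zero_variance `"error"` (default) fails when a marker has zero
#'   variance; `"drop"` removes such markers with a warning.
#' @return Expression tibble with scale `"log2_standardized"`.
#' @export
log2_standardize <- function(expr, zero_variance = c("error", "drop")) {
  zero_variance <- match.arg(zero_variance)
  scale_in <- expr_scale(expr)
  if (scale_in == "log2_standardized") {
    stop_sispanel("Expression table is already log2-standardized.",
                  class = "sispanel_scale_error")
  }
  validate_expression(expr)
  vals <- marker_matrix(expr)
  lvals <- if (scale_in == "raw") log2(vals) else vals

  sds <- apply(lvals, 2, sd)
  zero <- colnames(lvals)[sds == 0 | !is.finite(sds)]
  if (length(zero) > 0) {
    if (zero_variance == "error") {
      stop_sispanel(sprintf("Zero-variance marker(s): %s.", paste(zero, collapse = ", ")),
                    class = "sispanel_degenerate_error")
    }
    warn(sprintf("Dropping %d zero-variance marker(s).", length(zero)))
    lvals <- lvals[, !(colnames(lvals) %in% zero), drop = FALSE]
    sds <- sds[!(names(sds) %in% zero)]
  }
  z <- scale(lvals, center = TRUE, scale = sds)

  log2_tbl <- tibble::as_tibble(as.data.frame(lvals))
  log2_tbl <- dplyr::bind_cols(tibble::tibble(subject_id = expr$subject_id), log2_tbl)
  out <- dplyr::bind_cols(tibble::tibble(subject_id = expr$subject_id),
                          tibble::as_tibble(as.data.frame(z)))
  new_expression_tbl(out, scale = "log2_standardized", log2_values = log2_tbl)
}

# log2 (pre-standardization) values for fold changes, whatever the input scale
log2_values_of <- function(expr) {
  switch(expr_scale(expr),
    raw = log2(marker_matrix(expr)),
    log2 = marker_matrix(expr),
    log2_standardized = {
      lv <- attr(expr, "log2_values")
      if (is.null(lv)) {
        stop_sispanel("Standardized table lost its `log2_values` attribute; re-run log2_standardize() on the raw data.")
      }
      marker_matrix(lv)
    }
  )
}
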