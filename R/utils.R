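#' @importFrom rlang abort warn .data
#' @importFrom stats plogis qlogis pt pnorm pwilcox psmirnov rnorm sd glm
#'   binomial coef logLik predict setNames
#' @importFrom utils head
NULL

# single entry point for user-facing errors so messages stay uniform
stop_sispanel <- function(msg, class = "sispanel_error", ...) {
  abort(msg, class = c(class, "sispanel_error"), ...)
}

check_count <- function(x, name, min = 1L) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x != as.integer(x) || x < min) {
    stop_sispanel(
      sprintf("`%s` must be a single integer >= %d (got %s).", name, min,
              paste(format(x), collapse = ", ")),
      class = "sispanel_config_error"
    )
  }
  as.integer(x)
}

# numeric marker matrix from an expression tibble (subject_id + marker columns)
marker_matrix <- function(expr) {
  m <- as.matrix(expr[, setdiff(names(expr), "subject_id"), drop = FALSE])
  rownames(m) <- expr$subject_id
  storage.mode(m) <- "double"
  m
}

# 0/1 status vector aligned to an expression tibble
status_vector <- function(labels, expr = NULL) {
  if (is.data.frame(labels)) {
    y <- labels$status
    ids <- labels$subject_id
    if (!is.null(expr)) {
      miss <- setdiff(expr$subject_id, ids)
      if (length(miss) > 0) {
        stop_sispanel(
          sprintf("Subjects missing from labels: %s.", paste(miss, collapse = ", ")),
          class = "sispanel_alignment_error"
        )
      }
      y <- y[match(expr$subject_id, ids)]
    }
  } else {
    y <- labels
  }
  if (!all(y %in% c(0, 1))) {
    stop_sispanel("Status labels must be 0 (control) or 1 (case).")
  }
  as.integer(y)
}

check_two_groups <- function(y, min_per_group = 1L) {
  if (sum(y == 1) < min_per_group || sum(y == 0) < min_per_group) {
    stop_sispanel(
      sprintf("Need at least %d subjects in each group (got %d cases, %d controls).",
              min_per_group, sum(y == 1), sum(y == 0))
    )
  }
  invisible(y)
}
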