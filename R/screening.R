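#' Recommended screening retention size
#'
#' The sure-independence-screening literature recommends keeping about
#' `n / ln(n)` features before joint modelling; the value is rounded to the
#' nearest integer, halves away from zero. For n = 40 this gives 11; in
#' practice a more conservative size (e.g. 50 per test) is often used.
#'
#' @param n Number of subjects (>= 2).
#' @return A positive integer.
#' @export
recommended_dn <- function(n) {
  n <- check_count(n, "n", min = 2L)
  as.integer(floor(n / log(n) + 0.5))
}

rank_order <- function(stats, test) {
  p_col <- paste0("p_", test)
  s_col <- paste0("stat_", test)
  if (!p_col %in% names(stats)) {
    stop_sispanel(sprintf("Unknown test `%s` (expected one of t, ks, mw).", test),
                  class = "sispanel_config_error")
  }
  # ascending p, then descending |statistic|, then marker id: deterministic
  order(stats[[p_col]], -abs(stats[[s_col]]), stats$marker_id)
}

#' Top markers by a single screening test
#'
#' Markers sorted by ascending p-value of the chosen test; ties broken by
#' larger absolute test statistic, then lexicographic marker id.
#'
#' @param stats Marker-stat tibble from [marker_stats()].
#' @param test One of `"t"`, `"ks"`, `"mw"`.
#' @param d_n Number of markers to retain (<= number of markers).
#' @return Character vector of `d_n` marker ids, most significant first.
#' @export
rank_by_test <- function(stats, test = c("t", "ks", "mw"), d_n) {
  test <- match.arg(test)
  d_n <- check_count(d_n, "d_n", min = 1L)
  if (d_n > nrow(stats)) {
    stop_sispanel("`d_n` exceeds the number of markers.",
                  class = "sispanel_config_error")
  }
  stats$marker_id[rank_order(stats, test)][seq_len(d_n)]
}

#' Consensus sure-independence screen
#'
#' Ranks all markers by each requested test, keeps the `d_n` most
#' significant per test, and intersects the retained sets: only markers
#' appearing in every per-test top list survive the screen. The consensus
#' is ordered by mean rank across the tests (ascending). An empty
#' intersection is returned as a valid (empty) result with a warning;
#' downstream model fitting will then fail loudly.
#'
#' @inheritParams rank_by_test
#' @param d_n Retention size per test (default 50, a conservative choice;
#'   see [recommended_dn()] for the n/ln(n) preset).
#' @param tests Character subset of `c("t", "ks", "mw")` (default all
#'   three).
#' @return A `screening_result`: list with `consensus` (tibble `marker_id`,
#'   `mean_rank`), `ranked` (named list of per-test top-`d_n` id vectors),
#'   `ranks` (full per-test rank tibble), `d_n` and `tests`. [tidy()] gives
#'   the per-marker table with ranks, p-values and consensus membership.
#' @export
consensus_screen <- function(stats, d_n = 50, tests = c("t", "ks", "mw")) {
  d_n <- check_count(d_n, "d_n", min = 1L)
  tests <- match.arg(tests, several.ok = TRUE)
  if (d_n > nrow(stats)) {
    stop_sispanel("`d_n` exceeds the number of markers.",
                  class = "sispanel_config_error")
  }

  rank_tbl <- tibble::tibble(marker_id = stats$marker_id)
  ranked <- list()
  for (te in tests) {
    ord <- rank_order(stats, te)
    rk <- integer(nrow(stats))
    rk[ord] <- seq_len(nrow(stats))
    rank_tbl[[paste0("rank_", te)]] <- rk
    rank_tbl[[paste0("p_", te)]] <- stats[[paste0("p_", te)]]
    ranked[[te]] <- stats$marker_id[ord][seq_len(d_n)]
  }
  consensus_ids <- Reduce(intersect, ranked)
  mean_rank <- rowMeans(as.matrix(
    rank_tbl[, paste0("rank_", tests), drop = FALSE]))
  consensus <- tibble::tibble(
    marker_id = rank_tbl$marker_id, mean_rank = mean_rank
  )
  consensus <- consensus[consensus$marker_id %in% consensus_ids, ]
  consensus <- consensus[order(consensus$mean_rank, consensus$marker_id), ]
  if (nrow(consensus) == 0) {
    warn("Consensus screen is empty: no marker is in every per-test top list.")
  }
  rank_tbl$in_consensus <- as.integer(rank_tbl$marker_id %in% consensus_ids)
  structure(
    list(consensus = tibble::as_tibble(consensus), ranked = ranked,
         ranks = rank_tbl, d_n = d_n, tests = tests),
    class = "screening_result"
  )
}

#' @export
print.screening_result <- function(x, ...) {
  cat(sprintf("<screening_result> d_n = %d per test (%s)\n", x$d_n,
              paste(x$tests, collapse = ", ")))
  cat(sprintf("  consensus: %d marker(s)", nrow(x$consensus)))
  if (nrow(x$consensus) > 0) {
    cat(": ", paste(head(x$consensus$marker_id, 10), collapse = ", "))
    if (nrow(x$consensus) > 10) cat(", ...")
  }
  cat("\n")
  invisible(x)
}

#' @rdname consensus_screen
#' @param x A `screening_result`.
#' @param ... Unused.
#' @export
tidy.screening_result <- function(x, ...) {
  x$ranks
}

#' @rdname consensus_screen
#' @export
glance.screening_result <- function(x, ...) {
  tibble::tibble(d_n = x$d_n, n_tests = length(x$tests),
                 n_consensus = nrow(x$consensus))
}

#' @rdname consensus_screen
#' @param object A `screening_result`.
#' @export
autoplot.screening_result <- function(object, ...) {
  long <- tidyr::pivot_longer(
    object$ranks,
    cols = -c("marker_id", "in_consensus"),
    names_to = c(".value", "test"), names_sep = "_")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$rank, y = -log10(.data$p),
                                     colour = factor(.data$in_consensus))) +
    ggplot2::geom_point(size = 0.8, alpha = 0.7) +
    ggplot2::geom_vline(xintercept = object$d_n, linetype = "dashed",
                        linewidth = 0.3) +
    ggplot2::facet_wrap(~test, nrow = 1) +
    ggplot2::scale_colour_manual(values = c(`0` = "grey70", `1` = "#c0392b"),
                                 labels = c("screened out", "consensus"),
                                 name = NULL) +
    ggplot2::labs(x = "per-test rank", y = expression(-log[10]~italic(p))) +
    ggplot2::theme_minimal()
}
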