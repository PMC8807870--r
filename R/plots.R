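#' Plot the hub size distribution
#'
#' Histogram of the number of elements per hub with the monogamous-pair
#' class highlighted.
#'
#' @param object A `crh_set`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot crh_set
#' @export
autoplot.crh_set <- function(object, ...) {
  df <- object$crhs |>
    dplyr::mutate(kind = ifelse(.data$n_elements == 2, "monogamous pair",
                                "hub (3+ elements)"))
  ggplot(df, aes(x = .data$n_elements, fill = .data$kind)) +
    geom_histogram(binwidth = 1, colour = "grey30", linewidth = 0.2) +
    scale_x_continuous(trans = "log10") +
    labs(x = "elements per CRH (log scale)", y = "CRHs", fill = NULL,
         title = "CRH size distribution") +
    theme_minimal()
}

#' Cumulative degree distribution by node class
#'
#' Empirical CDF of node connections for promoters and distal elements, with
#' a dashed reference at the requested percentile (nearest rank).
#'
#' @param crh_set A `crh_set`.
#' @param percentile Reference percentile to mark (default 80).
#' @return A ggplot object.
#' @export
plot_degree_profile <- function(crh_set, percentile = 80) {
  prof <- degree_profile(crh_set)
  marks <- crh_set$nodes |>
    dplyr::group_by(.data$node_class) |>
    dplyr::summarise(
      at = nearest_rank_percentile(.data$degree, percentile),
      .groups = "drop"
    )
  ggplot(prof, aes(x = .data$degree, y = .data$cum_prop,
                   colour = .data$node_class)) +
    geom_step() +
    geom_vline(data = marks,
               aes(xintercept = .data$at, colour = .data$node_class),
               linetype = "dashed", show.legend = FALSE) +
    labs(x = "connections", y = "cumulative proportion", colour = NULL,
         title = sprintf("Node connectivity (dashed: %dth percentile)",
                         as.integer(percentile))) +
    theme_minimal()
}

#' Forest plot of enrichment odds ratios
#'
#' @param enrichments Tibble of tidied enrichment results (rows from
#'   [tidy()] on `crh_enrichment` objects) with a `label` column.
#' @return A ggplot object.
#' @export
plot_enrichment_forest <- function(enrichments) {
  assert_columns(enrichments,
                 c("label", "odds_ratio", "ci_low", "ci_high"),
                 "enrichment table")
  ggplot(enrichments, aes(x = .data$odds_ratio, y = .data$label)) +
    geom_vline(xintercept = 1, linetype = "dotted") +
    geom_errorbarh(aes(xmin = .data$ci_low, xmax = .data$ci_high),
                   height = 0.15) +
    geom_point(size = 2) +
    scale_x_continuous(trans = "log10") +
    labs(x = "odds ratio (log scale)", y = NULL) +
    theme_minimal()
}

#' Forest plot of logistic-regression odds ratios
#'
#' @param object A `crh_logit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot crh_logit
#' @export
autoplot.crh_logit <- function(object, ...) {
  df <- tidy(object) |>
    dplyr::filter(.data$term != "(Intercept)") |>
    dplyr::rename(label = "term")
  plot_enrichment_forest(df) +
    labs(title = "Gene disease-status model")
}

#' Fold enrichment across significance thresholds
#'
#' @param folds Tibble with columns `p_thresh`, `fold` and optionally
#'   `annotation`.
#' @return A ggplot object.
#' @export
plot_fold_enrichment <- function(folds) {
  assert_columns(folds, c("p_thresh", "fold"), "fold table")
  p <- ggplot(folds, aes(x = factor(.data$p_thresh), y = .data$fold))
  if ("annotation" %in% names(folds)) {
    p <- p + geom_col(aes(fill = .data$annotation), position = "dodge")
  } else {
    p <- p + geom_col()
  }
  p +
    geom_hline(yintercept = 1, linetype = "dotted") +
    labs(x = "association p-value threshold", y = "fold enrichment") +
    theme_minimal()
}
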