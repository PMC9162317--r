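#' Build the data behind a PheWAS Manhattan-style plot
#'
#' One row per converged association, ordered by phecode group then phecode,
#' with signed significance `signed_log10_p` = \eqn{-\log_{10} p} carrying
#' the sign of the beta coefficient (protective associations plot below the
#' axis), and a `label` flag marking the top association (lowest p) within
#' each group. Optionally restricts to parent-level phecodes (at most one
#' decimal place), the convention used to de-clutter phenome plots.
#'
#' @param results A `phewas_result` tibble.
#' @param parent_only Keep only phecodes with at most one decimal place.
#' @return A tibble: `phecode`, `group`, `beta`, `p_value`,
#'   `signed_log10_p`, `label`.
#' @export
manhattan_data <- function(results, parent_only = FALSE) {
  d <- tibble::as_tibble(results) |>
    dplyr::filter(.data$converged)
  if (parent_only) {
    d <- dplyr::filter(d, grepl("^[0-9]+(\\.[0-9])?$", .data$phecode))
  }
  if (any(d$p_value == 0, na.rm = TRUE)) {
    warn("p-values of 0 clamped to the smallest representable positive double.")
    d$p_value[d$p_value == 0] <- .Machine$double.xmin
  }
  d |>
    dplyr::mutate(
      group = phecode_group(.data$phecode),
      signed_log10_p = sign(.data$beta) * -log10(.data$p_value)
    ) |>
    dplyr::arrange(.data$group, suppressWarnings(as.numeric(.data$phecode)),
                   .data$phecode) |>
    dplyr::group_by(.data$group) |>
    dplyr::mutate(label = seq_len(dplyr::n()) == which.min(.data$p_value)) |>
    dplyr::ungroup() |>
    dplyr::select("phecode", "group", "beta", "p_value", "signed_log10_p",
                  "label")
}

#' Odds-ratio comparison table and Venn counts for two sweeps
#'
#' Joins two result sets on phecode and classifies each shared phecode by
#' which analysis reached its significance threshold: `"both"`, `"a_only"`,
#' `"b_only"` or `"neither"`. The Venn counts of the significant sets are
#' attached as an attribute and also returned by [concordance_summary()].
#'
#' @param results_a,results_b `phewas_result` tibbles.
#' @param alpha_a,alpha_b Per-analysis significance thresholds.
#' @return A tibble `phecode`, `or_a`, `or_b`, `p_value_a`, `p_value_b`,
#'   `category`, with attribute `venn` = c(a_only, b_only, both).
#' @export
comparison_scatter <- function(results_a, results_b, alpha_a, alpha_b) {
  a <- tibble::as_tibble(results_a) |> dplyr::filter(.data$converged)
  b <- tibble::as_tibble(results_b) |> dplyr::filter(.data$converged)
  joined <- dplyr::inner_join(a, b, by = "phecode", suffix = c("_a", "_b"))
  if (nrow(joined) == 0) abort("No phecodes shared between the two result sets.")
  out <- joined |>
    dplyr::transmute(
      phecode = .data$phecode,
      or_a = .data$or_a, or_b = .data$or_b,
      p_value_a = .data$p_value_a, p_value_b = .data$p_value_b,
      category = dplyr::case_when(
        .data$p_value_a < alpha_a & .data$p_value_b < alpha_b ~ "both",
        .data$p_value_a < alpha_a ~ "a_only",
        .data$p_value_b < alpha_b ~ "b_only",
        TRUE ~ "neither"
      )
    )
  attr(out, "venn") <- c(a_only = sum(out$category == "a_only"),
                         b_only = sum(out$category == "b_only"),
                         both = sum(out$category == "both"))
  out
}

#' Manhattan-style phenome plot
#'
#' @param results A `phewas_result` tibble.
#' @param threshold Optional phenome-wide significance threshold; drawn as
#'   horizontal dotted lines above and below the axis.
#' @param parent_only Restrict to parent-level phecodes.
#' @return A ggplot object.
#' @export
plot_manhattan <- function(results, threshold = NULL, parent_only = FALSE) {
  d <- manhattan_data(results, parent_only = parent_only)
  d$x <- seq_len(nrow(d))
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$signed_log10_p,
                                       colour = .data$group)) +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey40") +
    ggplot2::labs(x = "phecode (by group)",
                  y = expression(paste("signed ", -log[10], "(p)")),
                  colour = "group") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
  if (!is.null(threshold)) {
    p <- p + ggplot2::geom_hline(yintercept = c(-1, 1) * -log10(threshold),
                                 linetype = "dotted", colour = "red")
  }
  if (any(d$label)) {
    p <- p + ggplot2::geom_text(
      data = d[d$label, ], ggplot2::aes(label = .data$phecode),
      vjust = -0.6, size = 2.7, show.legend = FALSE
    )
  }
  p
}

#' Odds-ratio scatter comparing two phenome sweeps
#'
#' @inheritParams comparison_scatter
#' @return A ggplot object (log-scaled axes, identity line, points coloured
#'   by significance category).
#' @export
plot_or_comparison <- function(results_a, results_b, alpha_a, alpha_b) {
  d <- comparison_scatter(results_a, results_b, alpha_a, alpha_b)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$or_b, y = .data$or_a,
                                  colour = .data$category)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey60") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "OR (B)", y = "OR (A)", colour = "significant in") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @exportS3Method ggplot2::autoplot
autoplot.phewas_result <- function(object, ...) {
  plot_manhattan(object, ...)
}

#' Forest-plot style table for a stratified MR analysis
#'
#' @param x An `mr_stratified` result.
#' @return A ggplot object: per-phecode odds ratios with 95% confidence
#'   intervals by stratum.
#' @export
plot_stratified_forest <- function(x) {
  stopifnot(inherits(x, "mr_stratified"))
  d <- x$results |>
    dplyr::filter(.data$converged) |>
    dplyr::mutate(lo = exp(.data$beta - 1.96 * .data$se),
                  hi = exp(.data$beta + 1.96 * .data$se))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$or, y = .data$phecode,
                                  colour = .data$stratum)) +
    ggplot2::geom_vline(xintercept = 1, colour = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$lo, xmax = .data$hi),
                             position = ggplot2::position_dodge(width = 0.5)) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "OR per SD of height (95% CI)", y = NULL,
                  colour = x$stratum$name) +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.mr_stratified <- function(object, ...) {
  plot_stratified_forest(object)
}
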