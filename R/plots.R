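# ggplot2 views of a run: annual spending-share bars per purchaser category
# and volume-price trajectories behind the pattern classification. Figures
# are descriptive aids; all quantitative results live in the tables.

#' Annual spending shares by purchaser category
#'
#' Stacked bars of each medicine's share of a category's annual spending, one
#' facet per purchaser category.
#'
#' @param run A `"procurement_run"`.
#' @return A ggplot object.
#' @export
plot_spending_shares <- function(run) {
  stopifnot(inherits(run, "procurement_run"))
  dat <- run$annual %>%
    group_by(.data$category, .data$year) %>%
    mutate(share = 100 * .data$expenditure / sum(.data$expenditure)) %>%
    ungroup() %>%
    mutate(category = factor(category_labels()[.data$category],
                             levels = unname(category_labels())))
  ggplot2::ggplot(dat, ggplot2::aes(x = factor(.data$year), y = .data$share,
                                    fill = .data$medicine_code)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(ggplot2::vars(.data$category)) +
    ggplot2::labs(x = "Year", y = "Share of category spending (%)",
                  fill = "Medicine") +
    ggplot2::theme_minimal()
}

#' Volume-price trajectories
#'
#' Annual WAP/mg against annual milligram volume for each medicine, one line
#' per purchaser category; the visual counterpart of [classify_patterns()].
#' Axes are free because price levels differ by orders of magnitude across
#' medicines.
#'
#' @param run A `"procurement_run"`.
#' @return A ggplot object.
#' @export
plot_price_volume <- function(run) {
  stopifnot(inherits(run, "procurement_run"))
  ggplot2::ggplot(run$annual,
                  ggplot2::aes(x = .data$volume_mg, y = .data$wap_per_mg,
                               colour = .data$category)) +
    ggplot2::geom_path(alpha = 0.5) +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(ggplot2::vars(.data$medicine_code), scales = "free") +
    ggplot2::labs(x = "Annual volume (mg)", y = "WAP/mg (reference-month currency)",
                  colour = "Category") +
    ggplot2::theme_minimal()
}

#' Autoplot methods
#'
#' `autoplot()` on a `"procurement_run"` dispatches to
#' [plot_spending_shares()] (`type = "spending"`, default) or
#' [plot_price_volume()] (`type = "price_volume"`). On a
#' `"pattern_classification"` it draws the rank correlations per medicine,
#' coloured by label.
#'
#' @param object A `"procurement_run"` or `"pattern_classification"`.
#' @param type For runs, `"spending"` or `"price_volume"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.procurement_run <- function(object,
                                     type = c("spending", "price_volume"),
                                     ...) {
  switch(match.arg(type),
         spending = plot_spending_shares(object),
         price_volume = plot_price_volume(object))
}

#' @rdname autoplot.procurement_run
#' @export
autoplot.pattern_classification <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$rho, y = .data$medicine_code,
                               colour = .data$label,
                               shape = .data$category)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_point(size = 2) +
    ggplot2::xlim(-1, 1) +
    ggplot2::labs(x = "Rank correlation (annual volume vs WAP/mg)",
                  y = NULL, colour = "Pattern", shape = "Category") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
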