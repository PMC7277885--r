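#' Bar chart of complexity distributions
#'
#' Percentage-stacked bars of an ordinal measure (complexity class,
#' instability band or dependence level) across care settings or wards —
#' the standard display for allocation audits.
#'
#' @param day_rows Output of [expand_to_days()].
#' @param by Grouping axis: `"setting"` or `"ward"`.
#' @param measure `"icc"`, `"news"` or `"micd"`.
#' @return A ggplot object.
#' @export
plot_complexity_distribution <- function(day_rows,
                                         by = c("setting", "ward"),
                                         measure = c("icc", "news", "micd")) {
  by <- match.arg(by)
  measure <- match.arg(measure)
  col <- switch(measure, icc = "icc_level", news = "news_band",
                micd = "micd_level")
  lab <- switch(measure, icc = "Care complexity (ICC)",
                news = "Clinical instability (NEWS band)",
                micd = "Care dependence (mICD level)")
  ggplot2::ggplot(day_rows,
                  ggplot2::aes(x = .data[[by]], fill = .data[[col]])) +
    ggplot2::geom_bar(position = "fill") +
    ggplot2::scale_y_continuous(labels = function(x) paste0(100 * x, "%")) +
    ggplot2::labs(x = by, y = "patient-days", fill = lab) +
    ggplot2::theme_minimal()
}
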