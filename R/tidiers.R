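#' @exportS3Method generics::tidy
tidy.hb_scan_result <- function(x, ...) x$hits

#' @exportS3Method generics::glance
glance.hb_scan_result <- function(x, ...) {
  tibble(n_hits = nrow(x$hits),
         n_intact = sum(x$hits$intactness == "intact"),
         n_degraded = sum(x$hits$intactness == "degraded"),
         n_truncated = sum(x$hits$intactness == "truncated"),
         pool_size = nrow(x$pool),
         iterations = x$iterations,
         saturated = x$saturated)
}

#' @exportS3Method ggplot2::autoplot
autoplot.hb_scan_result <- function(object, ...) {
  ggplot2::ggplot(object$hits,
                  ggplot2::aes(x = .data$score, fill = .data$intactness)) +
    ggplot2::geom_histogram(bins = 30, position = "stack") +
    ggplot2::labs(x = "Smith-Waterman score (matrix units)", y = "hits",
                  fill = NULL) +
    ggplot2::theme_minimal()
}

#' Tile plot of a presence/absence matrix
#'
#' @param matrix_ Wide presence tibble (`family` + taxon columns).
#' @return A ggplot object.
#' @export
plot_presence_matrix <- function(matrix_) {
  long <- tidyr::pivot_longer(matrix_, -"family", names_to = "taxon",
                              values_to = "present")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$taxon, y = .data$family,
                                     fill = .data$present)) +
    ggplot2::geom_tile(color = "grey80") +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "steelblue",
                                          `FALSE` = "white")) +
    ggplot2::labs(x = NULL, y = NULL, fill = "present") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
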