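#' Barcode-gap scatter plot
#'
#' Distance to the nearest heterospecific neighbour against maximum
#' intraspecific distance, one point per (non-singleton) species; points
#' above the 1:1 line have a barcode gap.
#'
#' @param object A [barcode_gap()] tibble.
#' @param ... Ignored.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.barcode_gap <- function(object, ...) {
  df <- object[!is.na(object$max_intra), , drop = FALSE]
  ggplot2::ggplot(df, ggplot2::aes(x = 100 * .data$max_intra,
                                   y = 100 * .data$nn_dist)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey40") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$has_gap), alpha = 0.8) +
    ggplot2::labs(x = "Maximum intraspecific K2P distance (%)",
                  y = "Nearest-neighbour K2P distance (%)",
                  colour = "Barcode gap") +
    ggplot2::theme_minimal()
}

#' OTU size distribution
#'
#' @param object An [otu_partition()].
#' @param ... Ignored.
#' @return A ggplot of OTU sizes.
#' @exportS3Method ggplot2::autoplot
autoplot.otu_partition <- function(object, ...) {
  sizes <- dplyr::count(as_tibble(object), .data$otu_id, name = "size")
  ggplot2::ggplot(sizes, ggplot2::aes(x = .data$size)) +
    ggplot2::geom_bar(fill = "steelblue") +
    ggplot2::labs(x = "Specimens per OTU", y = "OTUs",
                  title = sprintf("%s: %d OTUs",
                                  attr(object, "method") %||% "partition",
                                  n_otus(object))) +
    ggplot2::theme_minimal()
}

#' Per-method OTU counts of a pipeline run
#'
#' @param object A `barcode_pipeline`.
#' @param ... Ignored.
#' @return A ggplot comparing OTU counts per delimiter, the consensus and
#'   the number of morphological species.
#' @exportS3Method ggplot2::autoplot
autoplot.barcode_pipeline <- function(object, ...) {
  df <- tibble(
    method = c(names(object$partitions), "consensus", "species"),
    n = c(vapply(object$partitions, n_otus, integer(1)),
          n_otus(object$consensus),
          length(unique(object$dataset$species)))
  )
  df$method <- factor(df$method, levels = df$method)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$method, y = .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), vjust = -0.4, size = 3) +
    ggplot2::labs(x = NULL, y = "OTUs / species") +
    ggplot2::theme_minimal()
}
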