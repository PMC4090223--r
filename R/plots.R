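#' Plot the read-length distribution
#'
#' Side-by-side bars of read-length percentages per library; a healthy
#' small-RNA library peaks at 22 nt.
#'
#' @param lengths output of [length_distribution()].
#' @return a ggplot object.
#' @export
plot_length_distribution <- function(lengths) {
  ggplot2::ggplot(lengths,
                  ggplot2::aes(x = factor(.data$length), y = .data$pct,
                               fill = .data$library)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "read length (nt)", y = "% of clean reads",
                  fill = "library") +
    ggplot2::theme_minimal()
}

#' Plot common and library-specific tag shares
#'
#' Stacked bars of the common / library-specific percentages on the unique
#' tag and total read bases.
#'
#' @param overlap output of [overlap_stats()].
#' @return a ggplot object.
#' @export
plot_tag_overlap <- function(overlap) {
  long <- overlap |>
    tidyr::pivot_longer(-"basis", names_to = "share", values_to = "pct") |>
    mutate(share = sub("_pct$", "", .data$share))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$basis, y = .data$pct,
                                     fill = .data$share)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "% of tags / reads", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot the annotation class distribution
#'
#' @param class_dist output of [class_distribution()].
#' @return a ggplot object.
#' @export
plot_class_distribution <- function(class_dist) {
  long <- class_dist |>
    select("class", "unique_pct", "total_pct") |>
    tidyr::pivot_longer(-"class", names_to = "basis", values_to = "pct") |>
    mutate(basis = sub("_pct$", "", .data$basis))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$class, y = .data$pct,
                                     fill = .data$basis)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "%", fill = "basis") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Differential-expression scatter plot
#'
#' Normalized expression in library 1 against library 2 on log10 axes, one
#' point per feature, coloured by fold-change category (red: ratio above 2,
#' blue: between 1/2 and 2, green: at or below 1/2). Features with a zero
#' count in either library are excluded from the scatter.
#'
#' @param object a `mir_de` from [de_table()].
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.mir_de <- function(object, ...) {
  df <- tidy(object) |>
    filter(.data$x > 0, .data$y > 0)
  ggplot2::ggplot(df, ggplot2::aes(x = log10(.data$ne_y),
                                   y = log10(.data$ne_x),
                                   colour = .data$category)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::scale_colour_manual(
      values = c(up = "red", mid = "blue", down = "green4")) +
    ggplot2::labs(x = "log10 NE (library 2)", y = "log10 NE (library 1)",
                  colour = "category") +
    ggplot2::theme_minimal()
}
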