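#' @importFrom ggplot2 ggplot aes geom_line geom_point geom_vline geom_col
#'   geom_tile labs theme_minimal scale_fill_gradient autoplot
NULL

#' Plot the variance-explained curve of a module set
#'
#' Shows R-squared against the number of clusters K with the selected K
#' marked; the inflection of this curve chose the module count.
#'
#' @param object A `module_set` from [discover_modules()].
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.module_set <- function(object, ...) {
  ggplot(object$r2_curve, aes(x = .data$k, y = .data$r2)) +
    geom_line(colour = "grey60") +
    geom_line(aes(y = .data$r2_smooth), colour = "steelblue") +
    geom_vline(xintercept = object$k_selected, linetype = "dashed") +
    labs(x = "number of clusters K", y = expression(R^2),
         title = sprintf("Cohort %s: K = %d", object$cohort,
                         object$k_selected)) +
    theme_minimal()
}

#' Plot differential coexpression statistics
#'
#' Bar chart of per-module delta median R-squared, filled by empirical
#' significance.
#'
#' @param stats Tibble from [coexpression_stats()].
#' @param alpha Significance level used for colouring.
#' @return A ggplot object.
#' @export
plot_delta_r2 <- function(stats, alpha = 0.05) {
  ggplot(stats, aes(x = stats::reorder(.data$module_id, .data$delta_r2),
                    y = .data$delta_r2,
                    fill = .data$p_empirical < alpha)) +
    geom_col() +
    ggplot2::coord_flip() +
    labs(x = NULL, y = expression(Delta ~ "median" ~ R^2),
         fill = sprintf("p < %.2g", alpha)) +
    theme_minimal()
}

#' Heatmap of the module inclusion-index matrix
#'
#' @param object A `regulome_set` from [build_regulomes()] (or an inclusion
#'   matrix).
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.regulome_set <- function(object, ...) {
  ii <- if (is.matrix(object)) object else object$inclusion
  df <- tibble::as_tibble(as.table(ii), .name_repair = "minimal")
  names(df) <- c("module_x", "module_y", "inclusion")
  ggplot(df, aes(x = .data$module_x, y = .data$module_y,
                 fill = .data$inclusion)) +
    geom_tile() +
    scale_fill_gradient(low = "white", high = "firebrick", limits = c(0, 1)) +
    labs(x = NULL, y = NULL, fill = "inclusion\nindex") +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Scatter plot of DAPC discriminant axes
#'
#' @param object A `dapc_result` from [dapc()].
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.dapc_result <- function(object, ...) {
  df <- tibble::tibble(
    ld1 = object$ld_scores[, 1],
    ld2 = if (ncol(object$ld_scores) >= 2) object$ld_scores[, 2] else 0,
    group = object$groups
  )
  ggplot(df, aes(x = .data$ld1, y = .data$ld2, colour = .data$group)) +
    geom_point(size = 2) +
    labs(x = "discriminant axis 1", y = "discriminant axis 2",
         colour = "cohort") +
    theme_minimal()
}
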