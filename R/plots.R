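# ggplot2 displays for the main result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a posterior probability map
#'
#' @param object a `probability_map`.
#' @param ... unused.
#' @export
autoplot.probability_map <- function(object, ...) {
  df <- data.frame(
    x = rep(seq_len(ncol(object)), each = nrow(object)),
    y = rep(seq_len(nrow(object)), ncol(object)),
    p = as.vector(unclass(object)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y, fill = .data$p)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1), name = "posterior") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL)
}

#' Plot a scene with the selected candidate's ellipses
#'
#' @param scene luminance matrix.
#' @param decision a `scene_decision`.
#' @param n_arc points per ellipse outline.
#' @export
plot_decision <- function(scene, decision, n_arc = 120L) {
  df <- data.frame(
    x = rep(seq_len(ncol(scene)), each = nrow(scene)),
    y = rep(seq_len(nrow(scene)), ncol(scene)),
    v = as.vector(scene))
  ell <- decision$best_candidate$ellipses
  arcs <- dplyr::bind_rows(lapply(seq_len(nrow(ell)), function(i) {
    e <- ell[i, ]
    t <- seq(0, 2 * pi, length.out = n_arc)
    th <- e$theta * pi / 180
    data.frame(part = e$part,
               x = e$cx + e$a * cos(t) * cos(th) + e$b * sin(t) * sin(th),
               y = e$cy + e$a * cos(t) * sin(th) - e$b * sin(t) * cos(th))
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$v)) +
    ggplot2::scale_fill_gradient(low = "black", high = "white", guide = "none") +
    ggplot2::geom_path(data = arcs,
                       ggplot2::aes(group = .data$part, linetype = .data$part),
                       color = "red", linewidth = 0.8) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = sprintf("%s (posterior %.2f)", decision$label,
                                  decision$posterior),
                  x = NULL, y = NULL)
}

#' Plot the cumulative structure-sharing histogram
#'
#' @param records structure records from [compile_structures()], or a tibble
#'   from [sharing_histogram()].
#' @export
plot_sharing_histogram <- function(records) {
  h <- if (all(c("min_sharing", "n_structures") %in% names(records))) records
       else sharing_histogram(records)
  ggplot2::ggplot(h, ggplot2::aes(x = .data$min_sharing * 100,
                                  y = .data$n_structures)) +
    ggplot2::geom_col(width = 8) +
    ggplot2::labs(x = "shared by at least (% of objects)",
                  y = "number of structures")
}
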