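#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_text geom_segment
#'   geom_histogram geom_vline labs theme_minimal coord_equal
NULL

#' @export
ggplot2::autoplot

#' Plot an MDS configuration
#'
#' Scatter of the configuration with item labels; point size encodes
#' stress-per-point when available.
#'
#' @param object An `mds_config`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mds_config <- function(object, ...) {
  df <- tidy(object)
  p <- ggplot(df, aes(x = .data$dim1,
                      y = if (object$n_dims >= 2) .data$dim2 else 0))
  if ("spp" %in% names(df)) {
    p <- p + geom_point(aes(size = .data$spp), alpha = 0.6)
  } else {
    p <- p + geom_point(alpha = 0.6)
  }
  p + geom_text(aes(label = .data$item_id), vjust = -0.8, size = 3) +
    coord_equal() +
    labs(title = paste0("Interval MDS solution (stress-1 = ",
                        signif(object$stress1, 3), ")"),
         x = "dimension 1", y = "dimension 2", size = "SPP (%)") +
    theme_minimal()
}

#' Plot a Procrustes alignment
#'
#' Target and aligned source overlaid in Procrustes normalized units, with
#' a segment per homologous landmark.
#'
#' @param object A `procrustes_alignment`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.procrustes_alignment <- function(object, ...) {
  df <- tibble::tibble(
    item_id = rep(rownames(object$target), 2),
    x = c(object$target[, 1], object$aligned[, 1]),
    y = c(object$target[, 2], object$aligned[, 2]),
    which = rep(c("target", "aligned"), each = nrow(object$target))
  )
  seg <- tibble::tibble(
    x = object$target[, 1], y = object$target[, 2],
    xend = object$aligned[, 1], yend = object$aligned[, 2]
  )
  ggplot(df, aes(.data$x, .data$y)) +
    geom_segment(data = seg,
                 aes(x = .data$x, y = .data$y,
                     xend = .data$xend, yend = .data$yend),
                 linetype = "dashed", colour = "grey60") +
    geom_point(aes(colour = .data$which)) +
    geom_text(data = df[df$which == "target", ],
              aes(label = .data$item_id), vjust = -0.8, size = 3) +
    coord_equal() +
    labs(title = sprintf("Procrustes alignment (c = %.3f, a = %.3f)",
                         object$congruence, object$alienation),
         x = "dimension 1", y = "dimension 2", colour = NULL) +
    theme_minimal()
}

#' Plot a permutation benchmark
#'
#' Histogram of null stresses with the observed stress marked.
#'
#' @param object A `permutation_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.permutation_report <- function(object, ...) {
  ggplot(tibble::tibble(stress = object$null_stresses),
         aes(.data$stress)) +
    geom_histogram(bins = 30, fill = "grey70") +
    geom_vline(xintercept = object$observed_stress, colour = "red") +
    labs(title = sprintf("Permutation benchmark (p = %.3g)",
                         object$p_value),
         x = "stress-1 of permuted refits", y = "count") +
    theme_minimal()
}

#' Plot a cluster solution
#'
#' Normalized bodily-space coordinates coloured by cluster.
#'
#' @param object A `cluster_solution`.
#' @param config_normalized The normalized configuration the solution was
#'   fit on.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cluster_solution <- function(object, config_normalized, ...) {
  X <- config_matrix(config_normalized)
  df <- tibble::tibble(item_id = rownames(X), dim1 = X[, 1],
                       dim2 = X[, 2])
  df <- dplyr::left_join(df, object$assignments, by = "item_id")
  ggplot(df, aes(.data$dim1, .data$dim2,
                 colour = factor(.data$cluster))) +
    geom_point(size = 3) +
    geom_text(aes(label = .data$item_id), vjust = -0.8, size = 3,
              show.legend = FALSE) +
    coord_equal() +
    labs(title = sprintf("k-means clusters (k = %d, %.1f%% variance)",
                         object$k, object$variance_explained),
         x = "embodiment (normalized)", y = "stimulation (normalized)",
         colour = "cluster") +
    theme_minimal()
}
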