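#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an embedding or encoder training curve
#'
#' @param x A `latent_space` (per-iteration mean loss) or trained
#'   `encoder_model` (per-batch mean Euclidean error, latent units).
#' @return A ggplot.
#' @export
plot_training_curve <- function(x) {
  if (inherits(x, "latent_space")) {
    df <- tibble::tibble(step = seq_along(x$loss_history),
                         loss = x$loss_history)
    ylab <- "mean pair loss"
  } else if (inherits(x, "encoder_model")) {
    df <- tibble::tibble(step = seq_along(x$loss_curve), loss = x$loss_curve)
    ylab <- "mean Euclidean error (latent units)"
  } else {
    stop("no training curve for this object", call. = FALSE)
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$step, y = .data$loss)) +
    ggplot2::geom_line(color = "steelblue") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "iteration", y = ylab) +
    ggplot2::theme_minimal()
}

#' Scatter of a latent space projected to two principal components
#'
#' @param object A `latent_space`.
#' @param taxonomy Optional character vector (one per sequence) to color by.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot latent_space
#' @export
autoplot.latent_space <- function(object, taxonomy = NULL, ...) {
  pca <- stats::prcomp(object$coords, center = TRUE, scale. = FALSE)
  df <- tibble::tibble(PC1 = pca$x[, 1], PC2 = pca$x[, 2])
  if (!is.null(taxonomy)) df$taxonomy <- taxonomy
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$PC1, y = .data$PC2)) +
    ggplot2::theme_minimal() +
    ggplot2::labs(title = "Latent sequence space (PCA projection)")
  if (is.null(taxonomy)) {
    p + ggplot2::geom_point(alpha = 0.6, size = 1)
  } else {
    p + ggplot2::geom_point(ggplot2::aes(color = .data$taxonomy),
                            alpha = 0.7, size = 1)
  }
}

#' Rank-abundance plot of an ASV table
#'
#' @param object An annotated `asv_tbl`.
#' @param ... Unused.
#' @return A ggplot (log-scale abundance by rank, colored by exact reference
#'   match where available).
#' @method autoplot asv_tbl
#' @export
autoplot.asv_tbl <- function(object, ...) {
  df <- tibble::tibble(
    rank = seq_len(nrow(object)),
    relative_abundance = object$relative_abundance
  )
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$rank,
                                        y = .data$relative_abundance))
  if (!is.null(object$exact_match)) {
    df$exact_match <- object$exact_match
    p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$rank,
                                          y = .data$relative_abundance,
                                          color = .data$exact_match))
  }
  p + ggplot2::geom_point() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "abundance rank", y = "relative abundance") +
    ggplot2::theme_minimal()
}

#' Scatter of a phenotype projection
#'
#' @param object A tibble from [phenotype_project()].
#' @param group Optional grouping vector (one per sample) to color by.
#' @param ... Unused.
#' @return A ggplot of the first two principal components.
#' @method autoplot phenotype_projection
#' @export
autoplot.phenotype_projection <- function(object, group = NULL, ...) {
  df <- object
  if (!is.null(group)) df$group <- group
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$PC1, y = .data$PC2)) +
    ggplot2::theme_minimal()
  if (is.null(group)) {
    p + ggplot2::geom_point(size = 2)
  } else {
    p + ggplot2::geom_point(ggplot2::aes(color = .data$group), size = 2)
  }
}
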