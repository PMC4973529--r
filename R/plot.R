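# ggplot2 helpers: origin tracks per animal and G-matrix PCA scatter.

boa_breed_scale <- function() {
  ggplot2::scale_fill_manual(values = c(S = "#1b9e77", LR = "#d95f02",
                                        LW = "#7570b3", UNKNOWN = "grey35"),
                             name = "breed")
}

#' Plot breed-of-origin tracks
#'
#' Two rows per animal (paternal and maternal gamete) per chromosome, with
#' blocks coloured by assigned breed; unassigned stretches are dark grey.
#'
#' @param origins An [origin_matrix()].
#' @param animals_show Animal ids to draw (default: up to 25).
#' @param chrom Chromosome to draw (default: first on the map).
#' @return A ggplot object.
#' @export
plot_origin_track <- function(origins, animals_show = NULL, chrom = NULL) {
  runs <- origin_runs(origins)
  if (is.null(chrom)) chrom <- runs$chrom[1]
  if (is.null(animals_show)) animals_show <- head(animals(origins), 25)
  runs <- dplyr::filter(runs, .data$chrom == !!chrom,
                        .data$animal %in% animals_show)
  runs$lane <- paste(runs$animal, substr(runs$gamete, 1, 3))
  ggplot2::ggplot(runs) +
    ggplot2::geom_rect(ggplot2::aes(xmin = .data$start_bp / 1e6,
                                    xmax = .data$end_bp / 1e6,
                                    ymin = as.integer(factor(.data$lane)) - 0.45,
                                    ymax = as.integer(factor(.data$lane)) + 0.45,
                                    fill = .data$breed)) +
    boa_breed_scale() +
    ggplot2::scale_y_continuous(breaks = seq_along(unique(runs$lane)),
                                labels = sort(unique(runs$lane))) +
    ggplot2::labs(x = "position (Mb)", y = NULL,
                  title = paste("breed-of-origin, chromosome", chrom)) +
    ggplot2::theme_minimal()
}

#' @method autoplot boa_result
#' @export
autoplot.boa_result <- function(object, ...) plot_origin_track(object$origins, ...)

#' Plot G-matrix principal components
#'
#' Scatter of the first two component scores, coloured by labelled
#' population; flagged outliers are circled.
#'
#' @param object A `boa_pca` from [grm_pca_outliers()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot boa_pca
#' @export
autoplot.boa_pca <- function(object, ...) {
  sc <- object$scores
  p <- ggplot2::ggplot(sc, ggplot2::aes(.data$PC1, .data$PC2,
                                        colour = .data$label)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", 100 * object$var_explained[1]),
      y = sprintf("PC2 (%.1f%%)", 100 * object$var_explained[2])) +
    ggplot2::theme_minimal()
  if (any(sc$flagged)) {
    p <- p + ggplot2::geom_point(data = sc[sc$flagged, ], shape = 1,
                                 size = 4, colour = "black")
  }
  p
}
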