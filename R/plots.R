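# ggplot2 figures for the delineation outputs. Every figure has a CSV of
# its plotted coordinates written by run_pipeline(); these functions only
# render.

#' Heatmap of the enviromic kernel with mega-environment annotation
#'
#' @param kernel An [enviromic_kernel()].
#' @param partition Optional [me_partition()] used to order sites by ME.
#' @return A ggplot object.
#' @export
plot_kernel_heatmap <- function(kernel, partition = NULL) {
  K <- kernel$K
  ord <- if (!is.null(partition)) {
    names(sort(partition$assignment[rownames(K)]))
  } else rownames(K)
  df <- expand.grid(row = ord, col = ord, stringsAsFactors = FALSE)
  df$value <- K[cbind(df$row, df$col)]
  df$row <- factor(df$row, levels = ord)
  df$col <- factor(df$col, levels = rev(ord))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$row, y = .data$col,
                                   fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b", midpoint = 0,
                                  name = "K_E") +
    ggplot2::labs(x = NULL, y = NULL,
                  title = "Enviromic kernel (environment similarity)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' GGE which-won-where biplot
#'
#' Genotype and environment scores in PC1-PC2 with the genotype convex
#' hull and the sector boundary rays.
#'
#' @param www A [which_won_where()] result.
#' @param model The `gge_model` it was computed from.
#' @return A ggplot object.
#' @export
plot_gge_biplot <- function(www, model) {
  gs <- as.data.frame(model$genotype_scores[, 1:2])
  gs$label <- rownames(gs)
  es <- as.data.frame(model$env_scores[, 1:2])
  es$label <- rownames(es)
  hull <- gs[www$hull_vertices, ]
  rmax <- max(sqrt(es$PC1^2 + es$PC2^2), sqrt(gs$PC1^2 + gs$PC2^2))
  rays <- data.frame(angle = www$boundaries$boundary_angle)
  rays$x <- 1.1 * rmax * cos(rays$angle)
  rays$y <- 1.1 * rmax * sin(rays$angle)
  pct <- sprintf("%.1f%%", 100 * model$explained[1:2])
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = rays,
                          ggplot2::aes(x = 0, y = 0, xend = .data$x,
                                       yend = .data$y),
                          linetype = "dashed", colour = "grey60") +
    ggplot2::geom_polygon(data = hull,
                          ggplot2::aes(.data$PC1, .data$PC2),
                          fill = NA, colour = "grey40") +
    ggplot2::geom_text(data = es,
                       ggplot2::aes(.data$PC1, .data$PC2,
                                    label = .data$label),
                       colour = "#2166ac", size = 3) +
    ggplot2::geom_text(data = gs,
                       ggplot2::aes(.data$PC1, .data$PC2,
                                    label = .data$label),
                       colour = "#b2182b", size = 3) +
    ggplot2::labs(x = paste0("PC1 (", pct[1], ")"),
                  y = paste0("PC2 (", pct[2], ")"),
                  title = "GGE biplot: which-won-where") +
    ggplot2::coord_equal() +
    ggplot2::theme_minimal()
}

#' Discriminativeness vs representativeness plot
#'
#' @param dr Result of [discrim_vs_repres()].
#' @return A ggplot object.
#' @export
plot_discrim_repres <- function(dr) {
  ggplot2::ggplot(dr, ggplot2::aes(x = .data$cos_aea,
                                   y = .data$vector_length,
                                   colour = .data$class,
                                   label = .data$env)) +
    ggplot2::geom_point() +
    ggplot2::geom_text(vjust = -0.6, size = 3, show.legend = FALSE) +
    ggplot2::geom_vline(xintercept = stats::median(dr$cos_aea),
                        linetype = "dotted") +
    ggplot2::geom_hline(yintercept = stats::median(dr$vector_length),
                        linetype = "dotted") +
    ggplot2::labs(x = "cos(angle to average-environment axis)",
                  y = "environment vector length",
                  title = "Discriminativeness vs representativeness") +
    ggplot2::theme_minimal()
}

#' Bar chart of covariable contributions to the leading PCs
#'
#' @param pca A [pca_covariables()] result.
#' @return A ggplot object.
#' @export
plot_pca_contributions <- function(pca) {
  df <- data.frame(COVARIABLE = names(pca$contrib_pc12),
                   contribution = pca$contrib_pc12)
  df <- df[order(-df$contribution), ]
  df$COVARIABLE <- factor(df$COVARIABLE, levels = df$COVARIABLE)
  ggplot2::ggplot(df, ggplot2::aes(.data$COVARIABLE,
                                   .data$contribution)) +
    ggplot2::geom_col(fill = "#2166ac") +
    ggplot2::labs(x = NULL, y = "% contribution to PC1-PC2",
                  title = "Covariable contributions") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}
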