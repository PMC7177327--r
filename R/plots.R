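#' Plots for pipeline results
#'
#' ggplot2 renderings of the main result types: the GSEA enrichment plot
#' (running sum with hit rug), per-sector intensity violins, per-sample
#' relative quantities, and a grayscale scene preview with detected cells
#' overlaid.
#'
#' @param object A perimir result object.
#' @param ... Unused.
#' @return A ggplot object.
#' @name perimir_plots
NULL

#' @rdname perimir_plots
#' @method autoplot perimir_gsea
#' @export
autoplot.perimir_gsea <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rank, y = .data$running_sum)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_line(colour = "#2c7fb8") +
    ggplot2::geom_rug(
      data = df[df$hit, ], sides = "b", alpha = 0.3, length = ggplot2::unit(0.04, "npc")
    ) +
    ggplot2::labs(
      x = "rank in ordered gene list", y = "running enrichment score",
      title = sprintf("ES = %.3f", object$es),
      subtitle = if (object$n_perm > 0) {
        sprintf(
          "NES = %.2f, p = %.3g, FDR = %.3g (%d permutations)",
          object$nes, object$p_perm, object$fdr, object$n_perm
        )
      }
    ) +
    ggplot2::theme_minimal()
}

#' @rdname perimir_plots
#' @method autoplot perimir_ddct
#' @export
autoplot.perimir_ddct <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$group_label, y = .data$rq, colour = .data$role
  )) +
    ggplot2::geom_jitter(width = 0.1, height = 0, size = 2) +
    ggplot2::stat_summary(fun = mean, geom = "crossbar", width = 0.3, colour = "black") +
    ggplot2::labs(
      x = NULL, y = "relative quantity (2^-dCt, control-centred)",
      title = sprintf(
        "fold change %s vs %s = %.3g",
        object$case_group, object$control_group, object$fold_change
      )
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}

#' Violin plot of per-cell intensities by sector and group
#'
#' @param cells Cell tibble with `group`, `sector`, `norm_intensity`
#'   (in-window cells; `"none"` rows are dropped).
#' @return A ggplot object.
#' @export
plot_sector_intensity <- function(cells) {
  cells <- dplyr::filter(cells, .data$sector != "none")
  ggplot2::ggplot(cells, ggplot2::aes(
    x = .data$sector, y = .data$norm_intensity, fill = .data$group
  )) +
    ggplot2::geom_violin(position = ggplot2::position_dodge(0.8), alpha = 0.7) +
    ggplot2::labs(
      x = "perilesional sector", y = "normalized ISH intensity", fill = NULL
    ) +
    ggplot2::theme_minimal()
}

#' Preview a synthetic scene with detected cells overlaid
#'
#' @param scene A `perimir_scene`.
#' @param cells Optional cell tibble from [detect_cells()].
#' @return A ggplot object (raster of the image, detections as circles).
#' @export
plot_scene <- function(scene, cells = NULL) {
  img <- scene$image
  mpp <- scene$microns_per_pixel
  df <- expand.grid(
    depth_um = (seq_len(nrow(img)) - 0.5) * mpp,
    x_um = (seq_len(ncol(img)) - 0.5) * mpp
  )
  df$gray <- as.vector(img)
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$x_um, .data$depth_um)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$gray)) +
    ggplot2::scale_fill_gradient(low = "black", high = "white", limits = c(0, 1)) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (um from lesion edge)", y = "depth (um)") +
    ggplot2::theme_minimal()
  if (!is.null(cells) && nrow(cells)) {
    p <- p + ggplot2::geom_point(
      data = cells, shape = 1, colour = "red", size = 2
    )
  }
  p
}
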