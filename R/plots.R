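#' Trajectory plot over the PCA projection
#'
#' Scatter of the samples in the two leading principal components,
#' colored by pseudotime, with the fitted ordering drawn as a path — the
#' standard view of a trajectory over bulk microregion profiles.
#'
#' @param traj A [pca_trajectory()] tibble.
#' @param zones Optional zone labels used for point shapes.
#' @return A ggplot object.
#' @export
plot_trajectory <- function(traj, zones = NULL) {
  if (!is.null(zones)) traj$zone <- zones
  p <- ggplot2::ggplot(traj, ggplot2::aes(x = .data$PC1, y = .data$PC2)) +
    ggplot2::geom_path(data = traj[order(traj$z), ],
                       color = "grey70", linewidth = 0.4) +
    ggplot2::scale_color_viridis_c(name = "pseudotime") +
    ggplot2::theme_minimal()
  if (is.null(zones)) {
    p + ggplot2::geom_point(ggplot2::aes(color = .data$z), size = 3)
  } else {
    p + ggplot2::geom_point(
      ggplot2::aes(color = .data$z, shape = .data$zone), size = 3
    )
  }
}

#' @describeIn fit_pseudotime Plot posterior pseudotime per sample with
#'   uncertainty bars, ordered along the trajectory.
#' @param object A `pseudotime_fit`.
#' @param ... Unused.
#' @export
autoplot.pseudotime_fit <- function(object, ...) {
  d <- tidy(object)
  d <- d[order(d$z), ]
  d$roi_id <- factor(d$roi_id, levels = d$roi_id)
  mapping <- if ("zone" %in% names(d)) {
    ggplot2::aes(ymin = .data$z - 2 * .data$z_sd,
                 ymax = .data$z + 2 * .data$z_sd, color = .data$zone)
  } else {
    ggplot2::aes(ymin = .data$z - 2 * .data$z_sd,
                 ymax = .data$z + 2 * .data$z_sd)
  }
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$roi_id, y = .data$z)) +
    ggplot2::geom_pointrange(mapping) +
    ggplot2::labs(x = NULL, y = "pseudotime (z)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
  p
}

#' @describeIn pseudotime_score Score distribution by tertile group.
#' @param object A `scored_cohort`.
#' @param ... Unused.
#' @export
autoplot.scored_cohort <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$group, y = .data$score,
                               fill = .data$group)) +
    ggplot2::geom_violin(alpha = 0.6) +
    ggplot2::geom_jitter(width = 0.15, size = 0.4, alpha = 0.4) +
    ggplot2::guides(fill = "none") +
    ggplot2::labs(x = "pseudotime group", y = "pseudotime-related score") +
    ggplot2::theme_minimal()
}

#' @describeIn km_fit Kaplan-Meier step curves per group.
#' @param object A `km_fit`.
#' @param ... Unused.
#' @export
autoplot.km_fit <- function(object, ...) {
  start <- dplyr::distinct(as_tibble(object), .data$group)
  start$time <- 0; start$estimate <- 1
  d <- dplyr::bind_rows(
    start[, c("group", "time", "estimate")],
    as_tibble(object)[, c("group", "time", "estimate")]
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time, y = .data$estimate,
                                  color = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "time", y = "survival probability") +
    ggplot2::theme_minimal()
}

#' Signature heatmap of the ordered microregions
#'
#' Tile display of the row-scaled signature matrix produced by
#' [signature_heatmap_order()]: columns follow the pseudotime ordering,
#' rows are grouped into the positively and negatively correlated blocks.
#'
#' @param hm Matrix from [signature_heatmap_order()].
#' @return A ggplot object.
#' @export
plot_signature_heatmap <- function(hm) {
  d <- as_tibble(as.data.frame.table(hm, responseName = "value"))
  names(d)[1:2] <- c("gene", "sample")
  d$gene <- factor(d$gene, levels = rev(rownames(hm)))
  d$sample <- factor(d$sample, levels = colnames(hm))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$sample, y = .data$gene,
                                  fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "navy", mid = "white",
                                  high = "firebrick", name = "z-score") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank(),
                   axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}
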