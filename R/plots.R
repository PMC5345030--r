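# Category palette used for restraint annotation throughout: shared local
# pairs blue, extra local pairs green, true non-local red, false yellow.
CATEGORY_COLOURS <- c(
  shared_local = "#2166ac", extra_local = "#1b7837",
  non_local = "#b2182b", false = "#ffd92f", control = "grey60"
)

#' Plot a denaturation profile
#'
#' Mean ensemble RMSD from the native structure against the number of
#' applied restraints, with a coloured box under the axis annotating each
#' rank's category (blue = shared local, green = extra local, red =
#' non-local, yellow = false). Optional control profiles (local-only
#' restraint sets) are drawn as thin lines.
#'
#' @param object a `denat_profile` from [denaturation_profile()].
#' @param controls optional named list of `denat_profile` objects.
#' @param ... unused.
#' @return A ggplot.
#' @export
#' @method autoplot denat_profile
autoplot.denat_profile <- function(object, controls = NULL, ...) {
  df <- tibble::as_tibble(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$k, y = .data$rmsd_mean)) +
    ggplot2::geom_line(colour = "#b2182b", linewidth = 0.8) +
    ggplot2::geom_point(colour = "#b2182b", size = 1.4)
  if (!is.null(controls)) {
    for (nm in names(controls)) {
      cdf <- tibble::as_tibble(controls[[nm]])
      cdf$set <- nm
      p <- p + ggplot2::geom_line(
        data = cdf,
        ggplot2::aes(x = .data$k, y = .data$rmsd_mean),
        colour = if (nm == "rnafold") "#2166ac" else "#1b7837",
        linewidth = 0.4
      )
    }
  }
  ann <- df[df$k > 0 & !is.na(df$category), ]
  if (nrow(ann) > 0) {
    y0 <- -0.05 * max(df$rmsd_mean)
    p <- p + ggplot2::geom_tile(
      data = ann,
      ggplot2::aes(x = .data$k, y = y0, fill = .data$category),
      height = abs(y0), width = 0.9
    ) +
      ggplot2::scale_fill_manual(values = CATEGORY_COLOURS, drop = FALSE)
  }
  p + ggplot2::labs(
    x = "number of applied restraints (ranked order)",
    y = "mean RMSD from native (Å)", fill = "restraint"
  ) + ggplot2::theme_minimal()
}

#' Plot a perturbation sweep
#'
#' @param object a `perturb_sweep` from [perturbation_sweep()].
#' @param ... unused.
#' @return A ggplot.
#' @export
#' @method autoplot perturb_sweep
autoplot.perturb_sweep <- function(object, ...) {
  ggplot2::ggplot(
    tibble::as_tibble(object),
    ggplot2::aes(
      x = .data$level, y = .data$rmsd_mean,
      colour = .data$set, group = .data$set
    )
  ) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "perturbation level (Å / rad per cycle)",
      y = "mean RMSD from native (Å)", colour = "restraint set"
    ) +
    ggplot2::theme_minimal()
}

#' Native-versus-maximum distance-matrix plot
#'
#' The lower-right triangle shows the native pairwise phosphate distances;
#' the upper-left triangle shows the per-pair maximum distance across the
#' ensemble, so loss of contact retention shows up as colour divergence
#' between the triangles.
#'
#' @param models an ensemble (list of traces or a `sim_result`).
#' @param native the native [ptrace()].
#' @return A ggplot.
#' @export
plot_distance_matrix <- function(models, native) {
  mm <- max_distance_matrix(models)
  nd <- coord_dist(as_coords(native))
  L <- nrow(nd)
  idx <- which(upper.tri(nd), arr.ind = TRUE)
  df <- dplyr::bind_rows(
    tibble::tibble(
      i = idx[, 2], j = idx[, 1], d = nd[idx], half = "native"
    ),
    tibble::tibble(
      i = idx[, 1], j = idx[, 2], d = mm[idx], half = "ensemble max"
    )
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$i, y = .data$j, fill = .data$d)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradientn(
      colours = c("#b2182b", "#1b7837", "#2166ac", "black")
    ) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(
      x = "residue", y = "residue", fill = "distance (Å)",
      subtitle = "lower: native; upper: ensemble maximum"
    ) +
    ggplot2::theme_minimal()
}

#' Per-residue RMSD profile plot
#'
#' @inheritParams plot_distance_matrix
#' @return A ggplot.
#' @export
plot_per_residue <- function(models, native) {
  ggplot2::ggplot(
    per_residue_rmsd(models, native),
    ggplot2::aes(x = .data$position, y = .data$rmsd)
  ) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "residue", y = "per-residue RMSD (Å)") +
    ggplot2::theme_minimal()
}
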