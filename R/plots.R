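#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_line geom_tile
#'   geom_errorbar geom_hline geom_col labs theme_minimal scale_x_log10
#'   facet_wrap
#' @export
ggplot2::autoplot

#' Plot an alignment with separating columns highlighted
#'
#' Identity tile map (species x column) with responder/non-responder
#' faceting; separating columns, when supplied, are outlined.
#'
#' @param object A [phenotype_alignment()].
#' @param positions Optional [find_separating_positions()] result.
#' @param columns Optional column range to display (default: all).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot phenotype_alignment
#' @export
autoplot.phenotype_alignment <- function(object, positions = NULL,
                                         columns = NULL, ...) {
  m <- alignment_matrix(object)
  df <- tidyr::expand_grid(species = object$species,
                           column = seq_len(ncol(m))) |>
    dplyr::mutate(identity = as.vector(t(m)),
                  phenotype = rep(object$phenotype, each = ncol(m)))
  if (!is.null(columns)) df <- df[df$column %in% columns, ]
  p <- ggplot(df, aes(x = .data$column, y = .data$species,
                      fill = .data$identity)) +
    geom_tile() +
    facet_wrap(~phenotype, ncol = 1, scales = "free_y") +
    labs(x = "alignment column", y = NULL, fill = "residue") +
    theme_minimal()
  if (!is.null(positions) && nrow(positions) > 0) {
    p <- p + ggplot2::geom_vline(xintercept = positions$column,
                                 linetype = "dashed", colour = "black")
  }
  p
}

#' Plot a dose-response curve with its 4PL fit
#'
#' @param object A [fit_pec50()] result.
#' @param ... Unused.
#' @return A ggplot object: observed responses against molar concentration
#'   (log scale) with the fitted curve and the EC50 marked.
#' @method autoplot pec50_fit
#' @export
autoplot.pec50_fit <- function(object, ...) {
  d <- object$data
  p <- ggplot(d, aes(x = .data$concentration, y = .data$response)) +
    geom_point() +
    scale_x_log10() +
    labs(x = "concentration (M)", y = "response") +
    theme_minimal()
  if (!is.null(object$parameters)) {
    est <- setNames(object$parameters$estimate, object$parameters$term)
    xx <- 10^seq(log10(min(d$concentration)), log10(max(d$concentration)),
                 length.out = 200)
    curve <- tibble(concentration = xx,
                    response = fourpl(log10(xx), est["floor"],
                                      est["ceiling"] - est["floor"],
                                      est["log_ec50"], est["hill"]))
    p <- p + geom_line(data = curve) +
      ggplot2::geom_vline(xintercept = 10^(-object$pec50),
                          linetype = "dotted") +
      labs(subtitle = sprintf("pEC50 = %.2f", object$pec50))
  }
  p
}

#' Plot binding modes of a clustered pose set
#'
#' Pose centroids projected on the x-y plane, coloured by assigned mode and
#' sized by score.
#'
#' @param object A [cluster_poses()] result.
#' @param poses The [pose_set()] that was clustered.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot binding_modes
#' @export
autoplot.binding_modes <- function(object, poses, ...) {
  assignment <- attr(object, "assignment")
  cent <- do.call(rbind, lapply(poses$coords, colMeans))
  df <- tibble(x = cent[, 1], y = cent[, 2],
               mode = factor(assignment), score = poses$score)
  ggplot(df, aes(x = .data$x, y = .data$y, colour = .data$mode,
                 size = -.data$score)) +
    geom_point(alpha = 0.7) +
    labs(x = "x (A)", y = "y (A)", colour = "binding mode",
         size = "-score (kcal/mol)") +
    theme_minimal()
}

#' Plot residue context classifications
#'
#' Minimum ligand and partner distances per residue with the classification
#' cutoffs drawn as horizontal lines.
#'
#' @param object A [classify_residue_context()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot residue_context
#' @export
autoplot.residue_context <- function(object, ...) {
  df <- tidyr::pivot_longer(
    as_tibble(object)[, c("resnum", "class", "dist_ligand", "dist_partner")],
    cols = c("dist_ligand", "dist_partner"),
    names_to = "target", values_to = "distance")
  cut_df <- tibble(target = c("dist_ligand", "dist_partner"),
                   cutoff = c(attr(object, "pocket_cutoff"),
                              attr(object, "interface_cutoff")))
  ggplot(df, aes(x = .data$resnum, y = .data$distance,
                 colour = .data$class)) +
    geom_point() +
    geom_hline(data = cut_df, aes(yintercept = .data$cutoff),
               linetype = "dashed") +
    facet_wrap(~target, ncol = 1, scales = "free_y") +
    labs(x = "residue", y = "min distance (A)", colour = "context") +
    theme_minimal()
}

#' Plot percent-difference results with confidence intervals
#'
#' @param object One or more stacked [percent_diff_ci()] rows (optionally
#'   with extra label columns such as `cytokine` or `compound`).
#' @param label Optional column name used for the x axis.
#' @param ... Unused.
#' @return A ggplot object with the zero line of the significance rule.
#' @method autoplot percent_diff
#' @export
autoplot.percent_diff <- function(object, label = NULL, ...) {
  df <- as_tibble(object)
  df$.label <- if (!is.null(label) && label %in% names(df)) {
    as.character(df[[label]])
  } else {
    as.character(seq_len(nrow(df)))
  }
  ggplot(df, aes(x = .data$.label, y = .data$estimate,
                 colour = .data$significant)) +
    geom_point(size = 2) +
    geom_errorbar(aes(ymin = .data$lower, ymax = .data$upper), width = 0.2) +
    geom_hline(yintercept = 0, linetype = "dashed") +
    labs(x = NULL, y = "% difference from reference",
         colour = "CI lower bound > 0") +
    theme_minimal()
}
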