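#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a 4PL fit into a coefficient table
#'
#' @param x A [fit_pec50()] result.
#' @param ... Unused.
#' @return Tibble with `term` and `estimate` (floor, ceiling, log_ec50,
#'   hill).
#' @method tidy pec50_fit
#' @export
tidy.pec50_fit <- function(x, ...) {
  if (is.null(x$parameters)) return(tibble(term = character(), estimate = numeric()))
  x$parameters
}

#' One-row summary of a 4PL fit
#'
#' @param x A [fit_pec50()] result.
#' @param ... Unused.
#' @return Tibble with `pec50`, `ec50_molar`, `hill`, `rmse`, `converged`,
#'   `bracketed`, `n`.
#' @method glance pec50_fit
#' @export
glance.pec50_fit <- function(x, ...) {
  hill <- if (is.null(x$parameters)) NA_real_ else
    x$parameters$estimate[x$parameters$term == "hill"]
  tibble(pec50 = x$pec50, ec50_molar = 10^(-x$pec50), hill = hill,
         rmse = x$rmse, converged = x$converged, bracketed = x$bracketed,
         n = nrow(x$data %||% tibble()))
}

#' Tidy binding modes into one row per mode
#'
#' @param x A [cluster_poses()] result.
#' @param ... Unused.
#' @return Tibble `mode`, `n_members`, `best_score`, `representative`,
#'   centroid coordinates.
#' @method tidy binding_modes
#' @export
tidy.binding_modes <- function(x, ...) {
  cent <- do.call(rbind, x$centroid)
  tibble(mode = x$mode, n_members = x$n_members, best_score = x$best_score,
         representative = x$representative,
         centroid_x = cent[, 1], centroid_y = cent[, 2], centroid_z = cent[, 3])
}

#' One-row summary of a binding-mode clustering
#'
#' @param x A [cluster_poses()] result.
#' @param ... Unused.
#' @return Tibble `n_modes`, `n_poses`, `best_score`, `score_gap` (top two
#'   modes; `NA` with fewer than two).
#' @method glance binding_modes
#' @export
glance.binding_modes <- function(x, ...) {
  tibble(n_modes = nrow(x), n_poses = sum(x$n_members),
         best_score = min(x$best_score),
         score_gap = gap_of_modes(x$best_score),
         rmsd_threshold = attr(x, "rmsd_threshold"))
}

#' Tidy a superposition
#'
#' @param x A [kabsch_superpose()] result.
#' @param ... Unused.
#' @return One-row tibble `rmsd`, `n`, `degenerate`.
#' @method glance superposition
#' @export
glance.superposition <- function(x, ...) {
  tibble(rmsd = x$rmsd, n = x$n, degenerate = isTRUE(x$degenerate))
}
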