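#' Compute the docking search box around a ligand
#'
#' Axis-aligned bounding box of the ligand atoms with every face pushed
#' outward by the padding (default 6 Angstrom), in the input coordinate
#' frame; the box center is the midpoint of the padded box.
#'
#' @param ligand n x 3 coordinate matrix or a structure tibble of ligand
#'   atoms.
#' @param padding Padding per face in Angstrom (default 6).
#' @return List of class `search_box` with `center` and `size` (each length
#'   3, Angstrom).
#' @examples
#' compute_search_box(matrix(0, 1, 3), padding = 6)
#' @export
compute_search_box <- function(ligand, padding = 6.0) {
  coords <- coords_of(ligand)
  if (nrow(coords) == 0) stop_input("ligand has no atoms")
  if (!is.numeric(padding) || padding < 0) stop_input("padding must be non-negative")
  lo <- apply(coords, 2, min) - padding
  hi <- apply(coords, 2, max) + padding
  structure(list(center = unname((lo + hi) / 2), size = unname(hi - lo)),
            class = "search_box")
}

#' @export
print.search_box <- function(x, ...) {
  cat(sprintf("search_box center (%.3f, %.3f, %.3f), size (%.3f, %.3f, %.3f) A\n",
              x$center[1], x$center[2], x$center[3],
              x$size[1], x$size[2], x$size[3]))
  invisible(x)
}

#' Select the flexible-residue shell around reference ligands
#'
#' A receptor residue joins the shell when any of its atoms lies within its
#' chain role's cutoff of any atom of any reference ligand. The defaults are
#' 3.4 Angstrom for the receptor and accessory chains and 4.0 Angstrom for
#' the partner chain. Several reference ligands (e.g. the native ligand from
#' each species, brought into a common frame by superposition) contribute as
#' a union.
#'
#' @param receptor A `structure_model`.
#' @param reference_ligands A single n x 3 matrix/structure tibble, or a list
#'   of them, already in the receptor frame.
#' @param cutoffs Named cutoff vector per chain role, in Angstrom.
#' @param heavy_only Ignore hydrogens on both sides.
#' @return Tibble of class `flexible_shell`, ordered by chain then residue
#'   number: `chain`, `resnum`, `resname`, `role`, `min_dist`, `cutoff`.
#' @export
select_flexible_shell <- function(receptor, reference_ligands,
                                  cutoffs = c("receptor-A" = 3.4,
                                              "accessory-C" = 3.4,
                                              "partner-B" = 4.0),
                                  heavy_only = FALSE) {
  refs <- if (is.list(reference_ligands) && !is.data.frame(reference_ligands)) {
    reference_ligands
  } else {
    list(reference_ligands)
  }
  if (length(refs) == 0) stop_input("at least one reference ligand is required")
  ref_coords <- do.call(rbind, lapply(refs, coords_of))
  if (nrow(ref_coords) == 0) stop_input("reference ligands have no atoms")

  cand <- receptor[receptor$role %in% names(cutoffs), , drop = FALSE]
  if (heavy_only) cand <- cand[cand$element != "H", , drop = FALSE]
  if (nrow(cand) == 0) stop_input("receptor has no atoms in the cutoff roles")
  grp <- paste(cand$chain, cand$resnum, cand$icode, sep = "|")
  dmin <- group_min_dist(coords_of(cand), grp, ref_coords)

  first <- !duplicated(grp)
  out <- tibble(
    chain = cand$chain[first], resnum = cand$resnum[first],
    icode = cand$icode[first], resname = cand$resname[first],
    role = cand$role[first],
    min_dist = as.numeric(dmin[grp[first]])
  )
  out$cutoff <- unname(cutoffs[out$role])
  out <- out[out$min_dist <= out$cutoff, , drop = FALSE]
  out <- out[order(out$chain, out$resnum, out$icode), ]
  attr(out, "cutoffs") <- cutoffs
  attr(out, "n_reference_ligands") <- length(refs)
  class(out) <- c("flexible_shell", class(out))
  out
}

# "C:120,C:122,B:56" comma list used in engine configs
shell_selection_string <- function(shell) {
  if (nrow(shell) == 0) return("")
  paste(paste0(shell$chain, ":", shell$resnum, shell$icode), collapse = ",")
}

#' Emit an engine-ready docking configuration
#'
#' Writes a Vina/Smina-dialect plain-text config: box center and size,
#' exhaustiveness (number of independent search trajectories, default 48),
#' number of saved binding modes (default 9), and the flexible-residue
#' selection as a `chain:resnum` comma list.
#'
#' @param box A [compute_search_box()] result.
#' @param shell A [select_flexible_shell()] result (may have zero rows).
#' @param receptor_file,ligand_file Paths recorded in the config.
#' @param exhaustiveness Independent search trajectories (48 by default; 96
#'   or 144 are the convergence-check presets).
#' @param num_modes Top-ranked pose clusters to save (default 9).
#' @param path Optional output file; the config text is also returned.
#' @return The config text, invisibly when `path` is given.
#' @export
emit_docking_config <- function(box, shell, receptor_file, ligand_file,
                                exhaustiveness = 48, num_modes = 9,
                                path = NULL) {
  if (!inherits(box, "search_box")) stop_input("box must be a search_box")
  if (is.null(receptor_file) || !nzchar(receptor_file) ||
      is.null(ligand_file) || !nzchar(ligand_file)) {
    stop_input("receptor_file and ligand_file must be non-empty paths")
  }
  num <- function(v) sprintf("%.6f", v)
  lines <- c(
    paste0("receptor = ", receptor_file),
    paste0("ligand = ", ligand_file),
    paste0("center_x = ", num(box$center[1])),
    paste0("center_y = ", num(box$center[2])),
    paste0("center_z = ", num(box$center[3])),
    paste0("size_x = ", num(box$size[1])),
    paste0("size_y = ", num(box$size[2])),
    paste0("size_z = ", num(box$size[3])),
    paste0("exhaustiveness = ", as.integer(exhaustiveness)),
    paste0("num_modes = ", as.integer(num_modes)),
    paste0("flex_residues = ", shell_selection_string(shell))
  )
  text <- paste0(paste(lines, collapse = "\n"), "\n")
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(text))
  }
  text
}

#' Parse an emitted docking configuration
#'
#' Inverse of [emit_docking_config()]; used for round-trip checks and by the
#' pipeline report.
#'
#' @param text Config text or a file path.
#' @return List with `box` (a `search_box`), `exhaustiveness`, `num_modes`,
#'   `receptor`, `ligand`, `flex_residues` (tibble `chain`, `resnum`).
#' @export
parse_docking_config <- function(text) {
  lines <- if (length(text) == 1 && file.exists(text)) readLines(text)
           else strsplit(paste(text, collapse = "\n"), "\n")[[1]]
  kv <- strsplit(lines[nzchar(trimws(lines))], "\\s*=\\s*")
  vals <- setNames(vapply(kv, function(x) if (length(x) > 1) x[2] else "", ""),
                   vapply(kv, `[`, "", 1))
  need <- c("center_x", "center_y", "center_z", "size_x", "size_y", "size_z")
  if (!all(need %in% names(vals))) {
    stop_input("config missing keys: ",
               paste(setdiff(need, names(vals)), collapse = ", "))
  }
  box <- structure(list(
    center = as.numeric(vals[c("center_x", "center_y", "center_z")]),
    size = as.numeric(vals[c("size_x", "size_y", "size_z")])),
    class = "search_box")
  flex <- if (nzchar(vals["flex_residues"] %||% "")) {
    parse_selection(vals[["flex_residues"]])[, c("chain", "from")] |>
      dplyr::rename(resnum = "from")
  } else {
    tibble(chain = character(), resnum = integer())
  }
  list(box = box,
       exhaustiveness = as.integer(vals["exhaustiveness"]),
       num_modes = as.integer(vals["num_modes"]),
       receptor = unname(vals["receptor"]), ligand = unname(vals["ligand"]),
       flex_residues = flex)
}
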