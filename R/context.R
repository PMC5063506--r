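#' Minimum distance from a residue to a target atom set
#'
#' Minimum Euclidean distance over all atom pairs; every atom present in the
#' file participates (hydrogens included when present; set
#' `heavy_only = TRUE` to restrict both sides to heavy atoms).
#'
#' @param model A `structure_model`.
#' @param residue Selection spec for the residue(s), e.g. `"C:5"`.
#' @param target Either a selection spec, a chain role (one of
#'   `"ligand"`, `"partner-B"`, `"receptor-A"`, `"accessory-C"`), or an
#'   n x 3 coordinate matrix.
#' @param heavy_only Drop hydrogens from both sides first.
#' @return Minimum distance in Angstrom.
#' @export
residue_min_distance <- function(model, residue, target, heavy_only = FALSE) {
  sub <- model[selection_mask(model, residue), , drop = FALSE]
  if (heavy_only) sub <- sub[sub$element != "H", , drop = FALSE]
  if (nrow(sub) == 0) stop_input("residue selection matched no atoms")
  tgt <- if (is.matrix(target)) {
    target
  } else if (is.character(target) && all(target %in% CHAIN_ROLES)) {
    ta <- role_atoms(model, target)
    if (heavy_only) ta <- ta[ta$element != "H", , drop = FALSE]
    if (nrow(ta) == 0) stop_input("no atoms with role ", paste(target, collapse = "/"))
    coords_of(ta)
  } else {
    ta <- model[selection_mask(model, target), , drop = FALSE]
    if (heavy_only) ta <- ta[ta$element != "H", , drop = FALSE]
    if (nrow(ta) == 0) stop_input("target selection matched no atoms")
    coords_of(ta)
  }
  min_pair_dist(coords_of(sub), tgt)
}

#' Classify residues as pocket, interface or surface-distal
#'
#' Applies the distance rules used for structural contextualization: a residue
#' with any atom within `pocket_cutoff` of any ligand atom is `pocket`; else,
#' within `interface_cutoff` of the partner chain (the second receptor of the
#' dimer) it is `interface`; otherwise `surface-distal`. A residue inside both
#' cutoffs is classed pocket: ligand proximity is the stronger structural
#' statement.
#'
#' @param model A `structure_model` with a tagged ligand (and, for the
#'   interface class, a `partner-B` chain).
#' @param residues Selection spec for the residues to classify; `NULL`
#'   classifies every accessory-chain residue.
#' @param pocket_cutoff Ligand distance cutoff in Angstrom (default 3.4).
#' @param interface_cutoff Partner-chain cutoff in Angstrom (default 4.0).
#' @param heavy_only Ignore hydrogens on both sides.
#' @return Tibble of class `residue_context`: `chain`, `resnum`, `resname`,
#'   `dist_ligand`, `dist_partner` (`NA` when no partner chain is tagged),
#'   `class`; cutoffs stored as attributes.
#' @export
classify_residue_context <- function(model, residues = NULL,
                                     pocket_cutoff = 3.4,
                                     interface_cutoff = 4.0,
                                     heavy_only = FALSE) {
  if (pocket_cutoff <= 0 || interface_cutoff <= 0) {
    stop_input("cutoffs must be positive")
  }
  work <- if (heavy_only) model[model$element != "H", , drop = FALSE] else model
  lig <- role_atoms(work, "ligand")
  if (nrow(lig) == 0) stop_input("pocket classification requires a tagged ligand")
  partner <- role_atoms(work, "partner-B")

  cand <- if (is.null(residues)) {
    role_atoms(work, "accessory-C")
  } else {
    work[selection_mask(work, residues) & work$role != "ligand", , drop = FALSE]
  }
  if (nrow(cand) == 0) stop_input("no atoms in the residue selection")

  grp <- paste(cand$chain, cand$resnum, cand$icode, sep = "|")
  coords <- coords_of(cand)
  d_lig <- group_min_dist(coords, grp, coords_of(lig))
  d_par <- if (nrow(partner) > 0) {
    group_min_dist(coords, grp, coords_of(partner))
  } else NULL

  first <- !duplicated(grp)
  ids <- grp[first]
  out <- tibble(
    chain = cand$chain[first], resnum = cand$resnum[first],
    icode = cand$icode[first], resname = cand$resname[first],
    dist_ligand = as.numeric(d_lig[ids]),
    dist_partner = if (is.null(d_par)) NA_real_ else as.numeric(d_par[ids])
  )
  out$class <- dplyr::case_when(
    out$dist_ligand <= pocket_cutoff ~ "pocket",
    !is.na(out$dist_partner) & out$dist_partner <= interface_cutoff ~ "interface",
    TRUE ~ "surface-distal"
  )
  out <- out[order(out$chain, out$resnum, out$icode), ]
  attr(out, "pocket_cutoff") <- pocket_cutoff
  attr(out, "interface_cutoff") <- interface_cutoff
  attr(out, "heavy_only") <- heavy_only
  class(out) <- c("residue_context", class(out))
  out
}
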