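CHAIN_ROLES <- c("receptor-A", "accessory-C", "partner-B", "ligand", "other")

#' Construct a structure model
#'
#' A tidy atom table: one row per atom with chain, residue, atom name, element,
#' Cartesian coordinates in Angstrom, and a per-row `role` tag
#' (`receptor-A`, `accessory-C`, `partner-B`, `ligand`, `other`) that encodes
#' the chain-role assignment used throughout the distance rules.
#'
#' @param atoms Data frame with columns `chain`, `resnum`, `resname`, `atom`,
#'   `x`, `y`, `z`; optional `icode`, `element`, `role`, `record`.
#' @param roles Named character vector mapping chain id to role, e.g.
#'   `c(A = "receptor-A", C = "accessory-C", B = "partner-B")`. Unmapped
#'   chains get role `"other"`.
#' @param ligand Selection spec (see [parse_selection()]) marking ligand
#'   atoms, e.g. `"L:201"`; matched rows get role `"ligand"`.
#' @return A tibble of class `structure_model`.
#' @export
structure_model <- function(atoms, roles = NULL, ligand = NULL) {
  req <- c("chain", "resnum", "resname", "atom", "x", "y", "z")
  if (!all(req %in% names(atoms))) {
    stop_input("atoms must have columns ", paste(req, collapse = ", "))
  }
  out <- as_tibble(atoms)
  if (!"icode" %in% names(out)) out$icode <- ""
  if (!"element" %in% names(out)) out$element <- substr(out$atom, 1, 1)
  if (!"record" %in% names(out)) out$record <- "ATOM"
  if (!"role" %in% names(out)) out$role <- "other"
  out$resnum <- as.integer(out$resnum)
  coords <- cbind(out$x, out$y, out$z)
  if (any(!is.finite(coords))) stop_input("non-finite atom coordinates")
  key <- paste(out$chain, out$resnum, out$icode, out$atom)
  if (anyDuplicated(key)) {
    stop_input("duplicated atom key (chain, resnum, icode, atom): ",
               key[duplicated(key)][1])
  }
  if (!is.null(roles)) {
    mapped <- unname(roles[out$chain])
    out$role <- ifelse(is.na(mapped), "other", mapped)
  }
  if (!is.null(ligand)) {
    out$role[selection_mask(out, ligand)] <- "ligand"
    out$record[out$role == "ligand"] <- "HETATM"
  }
  bad <- setdiff(unique(out$role), CHAIN_ROLES)
  if (length(bad) > 0) stop_input("unknown chain role(s): ", paste(bad, collapse = ", "))
  out <- out[, c("record", "chain", "resnum", "icode", "resname", "atom",
                 "element", "x", "y", "z", "role")]
  class(out) <- c("structure_model", class(out))
  out
}

role_atoms <- function(model, role) {
  model[model$role %in% role, , drop = FALSE]
}

ligand_atoms <- function(model) {
  lig <- role_atoms(model, "ligand")
  if (nrow(lig) == 0) stop_input("structure has no atoms tagged with the ligand role")
  lig
}

# replace coordinates, preserving class/attributes
set_coords <- function(model, coords) {
  model$x <- coords[, 1]; model$y <- coords[, 2]; model$z <- coords[, 3]
  model
}

#' Read a PDB file into a structure model
#'
#' Parsing is done with `bio3d`; altloc conflicts keep the highest-occupancy
#' conformer (ties resolved in favour of altloc `A`), insertion codes are
#' preserved, and duplicate atom keys are an error.
#'
#' @param path Path to a PDB file.
#' @param roles,ligand Chain-role map and ligand selection, as in
#'   [structure_model()]. Roles are assigned explicitly, never inferred.
#' @return A `structure_model` tibble.
#' @export
read_structure <- function(path, roles = NULL, ligand = NULL) {
  if (!file.exists(path)) stop_input("structure file not found: ", path)
  pdb <- tryCatch(bio3d::read.pdb(path, verbose = FALSE, rm.alt = FALSE),
                  error = function(e) stop_input("PDB parse error in ", path, ": ",
                                                 conditionMessage(e)))
  at <- pdb$atom
  at$alt[is.na(at$alt)] <- ""
  at$insert[is.na(at$insert)] <- ""
  at$o[is.na(at$o)] <- 1
  key <- paste(at$chain, at$resno, at$insert, at$elety)
  if (all(at$alt == "") && anyDuplicated(key)) {
    stop_input("duplicate atom key in ", path, ": ", key[duplicated(key)][1])
  }
  # altloc: keep highest occupancy, ties -> lexicographically first ('' or 'A');
  # file order of the surviving atoms is preserved
  pref <- order(-at$o, at$alt)
  best <- sort(pref[!duplicated(key[pref])])
  at <- at[best, ]
  elem <- at$elesy
  elem[is.na(elem) | elem == ""] <- substr(trimws(at$elety[is.na(elem) | elem == ""]), 1, 1)
  structure_model(
    tibble(record = at$type, chain = at$chain, resnum = at$resno,
           icode = at$insert, resname = at$resid, atom = at$elety,
           element = elem, x = at$x, y = at$y, z = at$z),
    roles = roles, ligand = ligand)
}

#' Write a structure model as PDB text
#'
#' Coordinates are written at the PDB's fixed 3-decimal precision; ligand-role
#' atoms are emitted as HETATM records.
#'
#' @param model A `structure_model`.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_structure <- function(model, path) {
  type <- ifelse(model$role == "ligand" | model$record == "HETATM",
                 "HETATM", "ATOM")
  bio3d::write.pdb(
    file = path,
    xyz = as.numeric(t(cbind(model$x, model$y, model$z))),
    type = type, resno = model$resnum, resid = model$resname,
    chain = model$chain, insert = ifelse(model$icode == "", NA, model$icode),
    elety = model$atom, o = rep(1, nrow(model)), b = rep(0, nrow(model)))
  invisible(path)
}

#' @export
print.structure_model <- function(x, ...) {
  ch <- dplyr::count(as_tibble(x), .data$chain, .data$role)
  cat("structure_model:", nrow(x), "atoms,",
      length(unique(paste(x$chain, x$resnum, x$icode))), "residues\n")
  print(ch)
  invisible(x)
}
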