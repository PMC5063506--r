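#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the proper rotation (det = +1; reflections are forbidden) and
#' translation minimising the RMSD between paired coordinate sets, via the
#' SVD formulation with the sign correction on the smallest singular vector.
#'
#' @param moving,fixed n x 3 coordinate matrices (or structure tibbles),
#'   paired row by row, n >= 3.
#' @return An object of class `superposition`: `rotation` (3 x 3, det +1),
#'   `translation` (length 3), `rmsd` (Angstrom), `n`. The transform maps
#'   moving coordinates as `x %*% t(rotation) + translation`.
#' @examples
#' pts <- matrix(rnorm(15), 5, 3)
#' kabsch_superpose(pts, pts)$rmsd
#' @export
kabsch_superpose <- function(moving, fixed) {
  p <- coords_of(moving); q <- coords_of(fixed)
  if (nrow(p) != nrow(q)) stop_input("point counts differ: ", nrow(p), " vs ", nrow(q))
  if (nrow(p) < 3) stop_input("need at least 3 paired points")
  cp <- colMeans(p); cq <- colMeans(q)
  pc <- sweep(p, 2, cp); qc <- sweep(q, 2, cq)
  # collinearity check: centred fixed set with rank < 2 leaves the rotation
  # underdetermined about the common axis
  sv <- svd(qc)$d
  degenerate <- sv[2] < 1e-8 * max(sv[1], 1e-12)
  if (degenerate) {
    warn("degenerate (collinear) point set: superposition is not unique; returning a best-effort fit")
  }
  h <- crossprod(pc, qc)
  s <- svd(h)
  d <- sign(det(tcrossprod(s$v, s$u)))
  rot <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  trans <- as.numeric(cq - rot %*% cp)
  diff <- pc %*% t(rot) - qc
  out <- list(rotation = rot, translation = trans,
              rmsd = sqrt(mean(rowSums(diff^2))), n = nrow(p),
              degenerate = degenerate)
  class(out) <- "superposition"
  out
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("superposition over %d atoms, rmsd %.4f A\n", x$n, x$rmsd))
  invisible(x)
}

#' Apply a superposition transform to coordinates or a structure
#'
#' @param x A `structure_model` or an n x 3 matrix.
#' @param superposition A [kabsch_superpose()] result.
#' @return Object of the same type with transformed coordinates.
#' @export
apply_superposition <- function(x, superposition) {
  coords <- apply_transform(coords_of(x), superposition$rotation,
                            superposition$translation)
  if (is.matrix(x)) coords else set_coords(x, coords)
}

# pair atoms of two models on (chain, resnum, icode, atom) or with the
# chain role in place of the chain id
match_atoms <- function(moving, fixed, by = c("chain", "role")) {
  by <- match.arg(by)
  keyfun <- function(m) paste(m[[by]], m$resnum, m$icode, m$atom, sep = "|")
  km <- keyfun(moving); kf <- keyfun(fixed)
  shared <- intersect(km, kf)
  list(moving_idx = match(shared, km), fixed_idx = match(shared, kf),
       unmatched_moving = setdiff(km, kf), unmatched_fixed = setdiff(kf, km))
}

#' Superpose one structure onto another using a residue selection
#'
#' Atoms inside the selection are paired by chain, residue number, insertion
#' code and atom name; the fitted rigid transform is then applied to the
#' whole moving model.
#'
#' @param moving,fixed `structure_model` objects.
#' @param selection Selection spec (see [parse_selection()]) applied to both
#'   models; `NULL` selects everything.
#' @param exclude Optional selection spec removed from the fit (e.g. a mobile
#'   loop).
#' @param by Pair atoms by chain id (default) or by chain role.
#' @return List with `model` (transformed moving model) and `superposition`
#'   (including the pairing size and any unmatched atom keys).
#' @export
superpose_by_selection <- function(moving, fixed, selection = NULL,
                                   exclude = NULL, by = c("chain", "role")) {
  by <- match.arg(by)
  msel <- if (is.null(selection)) rep(TRUE, nrow(moving)) else selection_mask(moving, selection)
  fsel <- if (is.null(selection)) rep(TRUE, nrow(fixed)) else selection_mask(fixed, selection)
  if (!is.null(exclude)) {
    msel <- msel & !selection_mask(moving, exclude)
    fsel <- fsel & !selection_mask(fixed, exclude)
  }
  pairing <- match_atoms(moving[msel, ], fixed[fsel, ], by = by)
  if (length(pairing$moving_idx) < 3) {
    stop_input("fewer than 3 matched atoms in the superposition selection")
  }
  sub_m <- moving[msel, ][pairing$moving_idx, ]
  sub_f <- fixed[fsel, ][pairing$fixed_idx, ]
  sup <- kabsch_superpose(coords_of(sub_m), coords_of(sub_f))
  sup$unmatched_moving <- pairing$unmatched_moving
  sup$unmatched_fixed <- pairing$unmatched_fixed
  list(model = apply_superposition(moving, sup), superposition = sup)
}

#' Conformational RMSD of selected residues between two structures
#'
#' Superposes `other` onto `model` on the fit selection (by default, the
#' residues of interest themselves) and returns the RMSD over the residue
#' atoms. Which atoms enter the comparison can be narrowed with `atoms`
#' (e.g. `"CA"`-only). Atoms missing from either model are reported in a
#' warning and the computation proceeds on the intersection.
#'
#' @param model,other `structure_model` objects (e.g. bound and unbound).
#' @param residues Selection spec for the residues compared.
#' @param fit_selection Selection spec for the superposition fit
#'   (default: `residues`).
#' @param atoms Optional character vector of atom names to restrict to.
#' @param by Pair atoms by chain id (default) or chain role.
#' @return RMSD in Angstrom (with the fitted `superposition` as attribute).
#' @export
conformational_rmsd <- function(model, other, residues, fit_selection = NULL,
                                atoms = NULL, by = c("chain", "role")) {
  by <- match.arg(by)
  fit_selection <- fit_selection %||% residues
  restrict <- function(m, spec) {
    sub <- m[selection_mask(m, spec), , drop = FALSE]
    if (!is.null(atoms)) sub <- sub[sub$atom %in% atoms, , drop = FALSE]
    sub
  }
  fit <- match_atoms(restrict(other, fit_selection), restrict(model, fit_selection), by = by)
  if (length(fit$moving_idx) < 3) stop_input("fewer than 3 matched atoms in fit selection")
  sup <- kabsch_superpose(
    coords_of(restrict(other, fit_selection)[fit$moving_idx, ]),
    coords_of(restrict(model, fit_selection)[fit$fixed_idx, ]))
  moved <- apply_superposition(other, sup)
  a <- restrict(moved, residues); b <- restrict(model, residues)
  pairing <- match_atoms(a, b, by = by)
  miss <- c(pairing$unmatched_moving, pairing$unmatched_fixed)
  if (length(miss) > 0) {
    warn(paste0("atoms missing from one model, using intersection: ",
                paste(head(miss, 5), collapse = "; "),
                if (length(miss) > 5) " ..."))
  }
  if (length(pairing$moving_idx) == 0) stop_input("no shared atoms in residue selection")
  diff <- coords_of(a[pairing$moving_idx, ]) - coords_of(b[pairing$fixed_idx, ])
  out <- sqrt(mean(rowSums(diff^2)))
  attr(out, "superposition") <- sup
  attr(out, "n_atoms") <- length(pairing$moving_idx)
  out
}

#' Graft chains from one complex onto another after shared-part superposition
#'
#' Fits the donor onto the acceptor over a shared selection (e.g. the
#' accessory protein present in both), then appends the requested donor
#' chains to the acceptor. Used to complete a receptor model when one entry
#' lacks a subunit (e.g. adding the receptor chain from a dimerized complex
#' to an accessory-protein-only entry).
#'
#' @param donor,acceptor `structure_model` objects.
#' @param shared_selection Selection spec present in both models (>= 3 atoms).
#' @param graft_chains Character vector of donor chain ids to append.
#' @param chain_map Optional named character vector remapping donor chain ids
#'   on insertion (required when a graft chain id already exists in the
#'   acceptor).
#' @param by Atom pairing key for the fit, chain id (default) or role.
#' @return A `structure_model` with a `provenance` attribute recording the
#'   grafted chains and the fit RMSD.
#' @export
build_chimeric_receptor <- function(donor, acceptor, shared_selection,
                                    graft_chains, chain_map = NULL,
                                    by = c("chain", "role")) {
  by <- match.arg(by)
  fit <- superpose_by_selection(donor, acceptor, selection = shared_selection, by = by)
  graft <- fit$model[fit$model$chain %in% graft_chains, , drop = FALSE]
  if (nrow(graft) == 0) stop_input("no donor atoms in graft chains: ",
                                   paste(graft_chains, collapse = ", "))
  if (!is.null(chain_map)) {
    remapped <- unname(chain_map[graft$chain])
    graft$chain <- ifelse(is.na(remapped), graft$chain, remapped)
  }
  collide <- intersect(unique(graft$chain), unique(acceptor$chain))
  if (length(collide) > 0) {
    stop_input("graft chain id(s) collide with acceptor and no remap given: ",
               paste(collide, collapse = ", "))
  }
  out <- dplyr::bind_rows(as_tibble(acceptor), as_tibble(graft))
  out <- structure_model(out)
  attr(out, "provenance") <- list(
    graft_chains = unique(graft$chain),
    shared_selection = shared_selection,
    fit_rmsd = fit$superposition$rmsd,
    fit_atoms = fit$superposition$n)
  out
}
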